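test_that("heterosis d/m reproduces the published worked examples", {
  # diploid parents and hybrid, fermentative rate: best-parent heterosis
  expect_equal(round(heterosis_dm(1.30, 0.53, 0.73), 2), 1.06)
  # Pmax: essentially no divergence
  expect_equal(round(heterosis_dm(5.37, 5.33, 5.53), 3), -0.011)
  # no divergence at all
  expect_equal(heterosis_dm(4, 4, 4), 0)
  # scale invariance
  expect_equal(heterosis_dm(13, 26, 15), heterosis_dm(1.3, 2.6, 1.5))
  expect_warning(out <- heterosis_dm(1, 1, -1), "mid-parent")
  expect_true(is.na(out))
})

test_that("heritability follows the variance-ratio definition with clamping", {
  expect_equal(heritability(1.0, 0.1), 0.9)
  expect_equal(heritability(1.0, 0.0), 1.0)
  expect_warning(h <- heritability(0.5, 0.6), "clamped")
  expect_equal(h, 0)
  expect_error(heritability(0, 0.1), "positive")
})

test_that("heritability estimates are unbiased on simulated crosses", {
  a <- 0.5; e <- 0.4
  truth <- a^2 / (a^2 + e^2)
  set.seed(77)
  est <- vapply(1:200, function(i) {
    g <- a * sample(c(-1, 1), 117, replace = TRUE)
    y <- g + rnorm(117, 0, e)
    heritability(var(y), e^2)
  }, numeric(1))
  expect_lt(abs(mean(est) - truth), 0.03)
})

test_that("transgression uses the k-SD widened parental range strictly", {
  out <- transgression(c(12.5, 11.0), 5, 10, env_sd = 1, k = 2)
  expect_equal(out$count, 1)            # 12.5 > 12, 11.0 is not
  expect_equal(out$percent, 50)
  expect_equal(transgression(c(6, 7, 9), 5, 10, 1, 2)$count, 0)
  # boundary is strict: equality is not transgressive
  expect_equal(transgression(10, 5, 10, 0, k = 0)$count, 0)
  expect_equal(transgression(10.0001, 5, 10, 0, k = 0)$count, 1)
})

test_that("variance decomposition is exact for deterministic traits", {
  set.seed(3)
  g <- data.frame(q1 = rep(c("P1", "P2"), each = 40),
                  q2 = rep(rep(c("P1", "P2"), each = 20), 2),
                  q3 = rep(rep(c("P1", "P2"), each = 10), 4))
  y <- ifelse(g$q1 == "P2", 1, 0)
  vd <- anova_decomposition(y, g, term_names = names(g))
  expect_equal(vd$table$share_pct[vd$table$term == "q1"], 100,
               tolerance = 1e-9)
  expect_equal(sum(vd$table$share_pct[vd$table$term != "q1"]), 0,
               tolerance = 1e-9)
  expect_named(vd$diagnostics, c("levene_p", "shapiro_p"))
})

test_that("variance shares are bounded and permutation-consistent on noise", {
  set.seed(4)
  g <- data.frame(q1 = sample(c("P1", "P2"), 117, TRUE),
                  q2 = sample(c("P1", "P2"), 117, TRUE),
                  q3 = sample(c("P1", "P2"), 117, TRUE))
  y <- rnorm(117)
  vd <- anova_decomposition(y, g, term_names = names(g))
  expect_true(all(vd$table$share_pct >= 0))
  expect_lte(vd$cumulated_pct, 100)
  expect_lt(vd$cumulated_pct, 25)       # pure noise: small shares
  perm <- sample(117)
  vd2 <- anova_decomposition(y[perm], g[perm, ], term_names = names(g))
  expect_equal(vd$table$share_pct, vd2$table$share_pct,
               tolerance = 1e-9)
})

test_that("a planted 30% single-QTL share is recovered at large n", {
  set.seed(5)
  n <- 5000
  g2 <- sample(c(-1, 1), n, replace = TRUE)
  beta <- 1
  sigma <- sqrt(var(beta * g2) * 0.7 / 0.3)
  y <- beta * g2 + rnorm(n, 0, sigma)
  g <- data.frame(q1 = sample(c("P1", "P2"), n, TRUE),
                  q2 = ifelse(g2 > 0, "P2", "P1"),
                  q3 = sample(c("P1", "P2"), n, TRUE))
  vd <- anova_decomposition(y, g, term_names = names(g))
  share <- vd$table$share_pct[vd$table$term == "q2"]
  # the ANOVA share equals the realized variance fraction of the locus
  expect_lt(abs(share - 100 * cor(y, g2)^2), 1)
  expect_lt(abs(share - 30), 4)
})

test_that("empty genotype combinations drop the affected interaction", {
  g <- data.frame(q1 = rep(c("P1", "P2"), each = 20),
                  q2 = rep(c("P1", "P2"), each = 20))  # fully aliased
  y <- rnorm(40)
  expect_warning(vd <- anova_decomposition(y, g), "dropped interaction")
  expect_false("q1:q2" %in% vd$table$term)
})

test_that("Duncan grouping matches an explicit critical-range oracle", {
  # three groups, means 0 / 0.1 / 3.0, common SD 0.2, n = 10
  means <- c(g1 = 0, g2 = 0.1, g3 = 3.0)
  mse <- 0.2^2; df <- 27; n <- 10
  out <- duncan_groups(means, n, mse, df)
  lett <- setNames(out$letters, out$group)
  # oracle: adjacent gap 2.9 far exceeds R2; 0.1 gap does not
  expect_gt(2.9, duncan_crit(2, df, mse, n))
  expect_lt(0.1, duncan_crit(2, df, mse, n))
  expect_equal(lett[["g3"]], "a")
  expect_equal(lett[["g1"]], lett[["g2"]])
  expect_false(lett[["g1"]] == lett[["g3"]])

  # two clearly separated groups -> distinct letters
  out2 <- duncan_groups(c(a = 0, b = 5), 10, 0.04, 18)
  expect_equal(sort(out2$letters), c("a", "b"))
  # equal means share one letter
  out3 <- duncan_groups(c(a = 1, b = 1, c = 1), 10, 0.04, 27)
  expect_true(all(out3$letters == "a"))
  expect_error(duncan_groups(c(a = 1, b = 2), 10, 0.04, 0), "degrees")
})

test_that("Duncan with two groups agrees with the t-style decision", {
  set.seed(6)
  for (delta in c(0.05, 0.6)) {
    means <- c(a = 0, b = delta)
    mse <- 0.09; n <- 8; df <- 14
    out <- duncan_groups(means, n, mse, df)
    tcrit <- qt(0.975, df) * sqrt(2 * mse / n)
    same_letter <- out$letters[1] == out$letters[2]
    expect_equal(same_letter, delta <= tcrit)
  }
})

test_that("GxE per-environment tests reproduce the published tier", {
  # hemizygote t2 at pH 2.8: 7.46 +/- 0.07 vs 5.6 +/- 0.06 (n = 3)
  mk <- function(mu, se) mu + c(-1, 0, 1) * se * sqrt(3)
  trait <- c(mk(7.46, 0.07), mk(5.6, 0.06),
             mk(6.0, 0.2), mk(5.8, 0.2))
  allele <- rep(rep(c("GN", "SB"), each = 3), 2)
  env <- rep(c(2.8, 3.3), each = 6)
  out <- gxe_analysis(trait, allele, env)
  row <- out$per_env[out$per_env$environment == "2.8", ]
  expect_equal(row$stars, "***")
  expect_equal(row$diff, 7.46 - 5.6, tolerance = 1e-9)
})

test_that("GxE interaction test has nominal size and detects sign flips", {
  set.seed(7)
  # null: allele effect identical in every environment
  pnull <- vapply(1:200, function(i) {
    allele <- rep(rep(c("A", "B"), each = 5), 3)
    env <- rep(c("e1", "e2", "e3"), each = 10)
    eff <- ifelse(allele == "A", 0.5, -0.5)
    gxe_analysis(rnorm(30, eff, 0.3), allele, env)$interaction_p
  }, numeric(1))
  expect_lt(abs(mean(pnull <= 0.05) - 0.05), 0.05)
  # sign-flipping allele effect across pH: overwhelming interaction
  hits <- vapply(1:50, function(i) {
    allele <- rep(rep(c("A", "B"), each = 30), 2)
    env <- rep(c("2.8", "3.3"), each = 60)
    eff <- ifelse(allele == "A", 1, -1) * ifelse(env == "2.8", 1, -1)
    gxe_analysis(rnorm(120, eff, 0.2), allele, env)$interaction_p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
  expect_error(gxe_analysis(rnorm(4), c("A", "A", "B", "B"),
                            c("e1", "e1", "e1", "e1")),
               "2 environments")
})

test_that("the cross-level report assembles heterosis, H2 and transgression", {
  set.seed(8)
  seg <- data.frame(segregant = sprintf("s%03d", 1:117),
                    rate = rnorm(117, 0.65, 0.15))
  par_tr <- data.frame(strain = rep(c("P1", "P2", "hybrid"), each = 3),
                       rate = c(rnorm(3, 0.53, 0.02),
                                rnorm(3, 0.73, 0.02),
                                rnorm(3, 1.30, 0.02)))
  rep_out <- genetics_report(seg, par_tr)
  expect_equal(rep_out$trait, "rate")
  expect_equal(rep_out$d_m,
               heterosis_dm(rep_out$hybrid, rep_out$p1, rep_out$p2))
  expect_true(rep_out$H2 >= 0 && rep_out$H2 <= 1)
  expect_true(rep_out$transgression_pct >= 0 &&
                rep_out$transgression_pct <= 100)
})
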