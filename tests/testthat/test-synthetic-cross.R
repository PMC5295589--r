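test_that("simulated parental sites are unique, distinguishing and deterministic", {
  g <- tiny_genome()
  p <- sim_parents(g, 200, seed = 7)
  expect_equal(nrow(p), 200)
  expect_true(all(p$p1_allele != p$p2_allele))
  expect_false(anyDuplicated(paste(p$chrom, p$pos)) > 0)
  expect_true(all(p$p1_allele %in% c("A", "C", "G", "T")))
  expect_true(all(p$ref == p$p1_allele | p$ref == p$p2_allele))
  # positions inside chromosomes, counts roughly proportional to length
  for (ch in g$chromosomes$name) {
    len <- g$chromosomes$length_bp[g$chromosomes$name == ch]
    expect_true(all(p$pos[p$chrom == ch] >= 1 & p$pos[p$chrom == ch] <= len))
  }
  expect_identical(p, sim_parents(g, 200, seed = 7))

  expect_equal(nrow(sim_parents(g, 0, seed = 1)), 0)
  expect_error(sim_parents(g, sum(g$chromosomes$length_bp) + 1, seed = 1),
               "exceeds")
})

test_that("zero map density gives whole-chromosome parental blocks", {
  g <- tiny_genome(cm_per_kb = 0)
  cr <- make_cross(n_seg = 25, n_snps = 90, seed = 2, genome = g)
  for (ch in unique(cr$markers$chrom)) {
    idx <- which(cr$markers$chrom == ch)
    per_seg <- apply(cr$haplotypes[, idx, drop = FALSE], 1,
                     function(h) length(unique(h)))
    expect_true(all(per_seg == 1))
  }
})

test_that("per-marker allele frequencies match binomial(n, 1/2) expectations", {
  # enumeration: central binomial band covering >= 99% of markers
  n <- 117
  band_p <- pbinom(ceiling(0.65 * n) - 1, n, 0.5) -
    pbinom(floor(0.35 * n), n, 0.5)
  expect_gt(band_p, 0.999)  # the band is generous at n = 117
  cr <- make_cross(n_seg = n, n_snps = 150, seed = 3)
  f2 <- colMeans(cr$haplotypes == 2L)
  expect_gte(mean(f2 >= 0.35 & f2 <= 0.65), 0.99)
})

test_that("recombinant fraction between linked markers follows Haldane", {
  # two markers ~15 kb apart at 0.4 cM/kb: d = 6 cM,
  # r = (1 - exp(-2d/100))/2 ~ 0.0565
  g <- genome_model(data.frame(name = "chr1", length_bp = 40000),
                    cm_per_kb = 0.4)
  p <- data.frame(chrom = "chr1", pos = c(10000, 25000),
                  ref = "A", p1_allele = "A", p2_allele = "C",
                  stringsAsFactors = FALSE)
  n <- 5000
  cr <- sim_cross(p, n, g, seed = 11)
  r_obs <- mean(cr$haplotypes[, 1] != cr$haplotypes[, 2])
  r_exp <- 0.5 * (1 - exp(-2 * 0.06))
  se <- sqrt(r_exp * (1 - r_exp) / n)
  expect_lt(abs(r_obs - r_exp), 3 * se)
})

test_that("distortion flagging tracks the exact binomial rate under the null", {
  # exact expectation: P(chi2 > cutoff) for counts ~ Binomial(117, 1/2)
  n <- 117
  cut <- qchisq(0.95, 1)
  ks <- 0:n
  p_exp <- sum(dbinom(ks[((2 * ks - n)^2 / n) > cut], n, 0.5))
  rates <- vapply(1:4, function(s) {
    cr <- make_cross(n_seg = n, n_snps = 150, seed = 100 + s)
    gm <- build_marker_map(gm_from_cross(cr))
    mean(gm$markers$filter == "distorted")
  }, numeric(1))
  expect_lt(abs(mean(rates) - p_exp), 0.04)
})

test_that("simulated reads respect coverage, error and determinism contracts", {
  cr <- make_cross(n_seg = 30, n_snps = 100, seed = 4)
  rd0 <- sim_reads(cr, mean_coverage = 0, seed = 1)
  expect_true(all(rd0$n_p1 == 0 & rd0$n_p2 == 0))

  rd <- sim_reads(cr, mean_coverage = 5, error_rate = 0, seed = 2)
  depth <- rd$n_p1 + rd$n_p2
  frac0 <- mean(depth == 0)
  p0 <- exp(-5)
  expect_lt(abs(frac0 - p0), 3 * sqrt(p0 * (1 - p0) / nrow(rd)))
  # with zero error every read supports the true haplotype
  hap <- as.vector(t(cr$haplotypes))
  expect_true(all(rd$n_p2[hap == 1L] == 0))
  expect_true(all(rd$n_p1[hap == 2L] == 0))

  expect_identical(rd, sim_reads(cr, mean_coverage = 5, error_rate = 0,
                                 seed = 2))
})

test_that("additive trait model recovers planted locus effects", {
  g <- tiny_genome()
  arch <- qtl_architecture(
    loci = data.frame(chrom = "chrA", pos_bp = 200000, trait = "rate",
                      effect = 0.08, stringsAsFactors = FALSE),
    baseline = c(Pmax = 5.5, rate = 0.5, t2 = 7, t5 = 16.5),
    noise_sd = c(Pmax = 0.08, rate = 0.04, t2 = 0.3, t5 = 0.65),
    genome = g)
  cr <- make_cross(n_seg = 1000, n_snps = 60, seed = 6, genome = g)
  tt <- sim_trait_table(cr, arch, seed = 6)
  lm_idx <- attr(tt, "locus_markers")$marker[1]
  gmk <- cr$haplotypes[, lm_idx]
  diff_obs <- mean(tt$rate[gmk == 2L]) - mean(tt$rate[gmk == 1L])
  se <- 0.04 * sqrt(1 / sum(gmk == 2L) + 1 / sum(gmk == 1L))
  expect_lt(abs(diff_obs - 2 * 0.08), 3 * se)
})

test_that("synthesized curves reproduce their recorded ground-truth traits", {
  g <- tiny_genome()
  arch <- default_architecture(default_genome())
  arch$loci <- arch$loci[0, ]  # no QTL needed here
  arch$noise_sd[] <- 0
  arch$replicate_sd <- 0
  cr <- make_cross(n_seg = 3, n_snps = 30, seed = 8, genome = g)
  ph <- sim_phenotypes(cr, arch, seed = 8, include_parents = FALSE,
                       design = list(times = seq(0.5, 40, 0.5)))
  # identical segregants (no effects, no noise) -> identical curves
  sp <- split(ph$curves$pressure_bar, ph$curves$strain)
  expect_equal(sp[[1]], sp[[2]], tolerance = 1e-12)
  expect_equal(sp[[1]], sp[[3]], tolerance = 1e-12)
  # ground-truth t2 is the analytic 2-bar crossing of the curve
  tr <- ph$truth[1, ]
  fitlike <- synth_5pl(tr$Pmax, tr$rate, tr$t2, tr$t5)
  p <- fitlike$par
  expect_equal(pl5(tr$t2, p["D"], p["C"], p["B"], p["G"]), 2,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(pl5(tr$t5, p["D"], p["C"], p["B"], p["G"]), 5,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("non-physical trait targets are rejected", {
  expect_error(synth_5pl(Pmax = 4.5, rate = 0.5, t2 = 7, t5 = 16),
               "non-physical")
  expect_error(synth_5pl(Pmax = 5.5, rate = 0.5, t2 = 10, t5 = 8),
               "non-physical")
  expect_error(synth_5pl(Pmax = 5.5, rate = -1, t2 = 7, t5 = 16),
               "non-physical")
})

test_that("genotype calls close the loop on noise-free deep sequencing", {
  cr <- make_cross(n_seg = 30, n_snps = 100, seed = 9)
  rd <- sim_reads(cr, mean_coverage = 30, error_rate = 0, seed = 9)
  gm <- call_genotypes(rd, cr$parents)
  called <- !is.na(gm$geno)
  expect_gt(mean(called), 0.999)
  expect_true(all(gm$geno[called] ==
                    cr$haplotypes[gm$segregants, ][called]))
})
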