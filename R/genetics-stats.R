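#' Mid-parent heterosis index d/m
#'
#' `d/m = (hybrid - midparent) / midparent` with
#' `midparent = (p1 + p2)/2`: the hybrid's relative deviation from the
#' parental mean. Vectorised over traits.
#'
#' @param hybrid,p1,p2 trait values.
#' @return d/m; NA with a warning where the mid-parent value is 0.
#' @export
heterosis_dm <- function(hybrid, p1, p2) {
  m <- (p1 + p2) / 2
  out <- (hybrid - m) / m
  if (any(m == 0, na.rm = TRUE)) {
    warning("mid-parent value is 0; d/m undefined")
    out[m == 0] <- NA_real_
  }
  out
}

#' Broad-sense heritability
#'
#' `H^2 = (Vp - Ve) / Vp` where `Vp` is the phenotypic variance among
#' segregants and `Ve` the environmental (replicate) variance, clamped
#' to \[0, 1\].
#'
#' @param seg_var phenotypic variance among segregants (> 0).
#' @param env_var environmental variance (>= 0).
#' @return H-squared in \[0, 1\]; warns when `env_var > seg_var`.
#' @export
heritability <- function(seg_var, env_var) {
  if (any(seg_var <= 0)) stop("seg_var must be positive")
  if (any(env_var < 0)) stop("env_var must be non-negative")
  h2 <- (seg_var - env_var) / seg_var
  if (any(h2 < 0)) {
    warning("env_var exceeds seg_var; heritability clamped to 0")
    h2 <- pmax(h2, 0)
  }
  pmin(h2, 1)
}

#' Transgressive segregation
#'
#' A segregant is transgressive when its trait value lies strictly
#' beyond the parental range widened by `k` environmental SDs:
#' below `min(p1, p2) - k*env_sd` or above `max(p1, p2) + k*env_sd`.
#'
#' @param seg_values segregant trait values.
#' @param p1_mean,p2_mean parental means.
#' @param env_sd environmental SD (>= 0).
#' @param k widening factor in SD units (default 2).
#' @return list: `percent` (0-100), `count`, `n`.
#' @export
transgression <- function(seg_values, p1_mean, p2_mean, env_sd, k = 2.0) {
  stopifnot(env_sd >= 0, k >= 0)
  v <- seg_values[is.finite(seg_values)]
  lo <- min(p1_mean, p2_mean) - k * env_sd
  hi <- max(p1_mean, p2_mean) + k * env_sd
  cnt <- sum(v < lo | v > hi)
  list(percent = 100 * cnt / length(v), count = cnt, n = length(v))
}

#' ANOVA variance decomposition over QTL peak markers
#'
#' Fits the general linear model with all main QTL effects followed by
#' all pairwise interactions, e.g. for three QTL
#' `Y = m + QTL1 + QTL2 + QTL3 + QTL1:QTL2 + QTL2:QTL3 + QTL1:QTL3 + E`,
#' using sequential (order-entered) sums of squares with main effects
#' first. Each term's share is its SS as a percentage of the total SS.
#' Segregants missing a genotype at any peak marker are excluded;
#' interactions whose genotype-combination cells are empty are dropped
#' with a warning. Homoscedasticity (Levene, median-centred) and
#' residual normality (Shapiro-Wilk) are reported as diagnostics.
#'
#' @param trait numeric trait values per segregant.
#' @param genotypes data.frame/matrix of genotype calls at the peak
#'   markers (one column per QTL; coded P1/P2 or 1/2; NA = missing).
#' @param term_names optional names for the QTL terms (defaults to
#'   QTL1, QTL2, ...).
#' @return Object of class `variance_decomposition`: list with `table`
#'   (term, df, ss, share_pct, p_value), `residual_share_pct`,
#'   `cumulated_pct` (non-residual shares), `diagnostics`
#'   (levene_p, shapiro_p), `n`, `dropped_terms`.
#' @export
anova_decomposition <- function(trait, genotypes,
                                term_names = NULL) {
  G <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  k <- ncol(G)
  if (is.null(term_names)) term_names <- paste0("QTL", seq_len(k))
  names(G) <- term_names
  dat <- cbind(data.frame(y = as.numeric(trait)), G)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  for (nm in term_names) dat[[nm]] <- factor(dat[[nm]])
  for (nm in term_names)
    if (nlevels(dat[[nm]]) < 2)
      stop("QTL term ", nm, " has fewer than 2 genotype classes")
  pairs <- if (k >= 2) utils::combn(term_names, 2, simplify = FALSE)
           else list()
  # model order: main effects, then 1:2, 2:3, 1:3 style pair order
  if (k == 3) pairs <- pairs[c(1, 3, 2)]
  dropped <- character()
  inter <- character()
  for (pr in pairs) {
    tab <- table(dat[[pr[1]]], dat[[pr[2]]])
    if (any(tab == 0)) {
      dropped <- c(dropped, paste(pr, collapse = ":"))
    } else inter <- c(inter, paste(pr, collapse = ":"))
  }
  if (length(dropped))
    warning("empty genotype combination; dropped interaction(s): ",
            paste(dropped, collapse = ", "))
  rhs <- paste(c(term_names, inter), collapse = " + ")
  fit <- aov(stats::as.formula(paste("y ~", rhs)), data = dat)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  ss <- an[["Sum Sq"]]
  total <- sum(ss)
  share <- 100 * ss / total
  pv <- an[["Pr(>F)"]]
  is_res <- terms == "Residuals"
  tabout <- data.frame(term = terms[!is_res], df = an$Df[!is_res],
                       ss = ss[!is_res], share_pct = share[!is_res],
                       p_value = pv[!is_res], stringsAsFactors = FALSE)
  grp <- interaction(dat[term_names], drop = TRUE)
  lev_p <- tryCatch(
    car::leveneTest(dat$y, grp, center = median)[["Pr(>F)"]][1],
    error = function(e) NA_real_)
  sh_p <- tryCatch({
    r <- resid(fit)
    if (length(unique(round(r, 12))) < 3 || length(r) < 3 ||
        length(r) > 5000) NA_real_ else shapiro.test(r)$p.value
  }, error = function(e) NA_real_)
  out <- list(table = tabout,
              residual_share_pct = share[is_res],
              cumulated_pct = sum(share[!is_res]),
              diagnostics = c(levene_p = lev_p, shapiro_p = sh_p),
              n = nrow(dat), dropped_terms = dropped)
  class(out) <- "variance_decomposition"
  out
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("variance_decomposition (n = %d):\n", x$n))
  tb <- x$table
  tb$share_pct <- sprintf("%.2f%%", tb$share_pct)
  tb$p_value <- signif(tb$p_value, 3)
  print(tb, row.names = FALSE)
  cat(sprintf("cumulated: %.2f%% | residual: %.2f%%\n",
              x$cumulated_pct, x$residual_share_pct))
  invisible(x)
}

#' Duncan's multiple-range grouping letters
#'
#' Duncan's multiple-range test: sorted group means are compared with
#' critical ranges `R_p = q((1-alpha)^(p-1), p, df) * sqrt(MSE/n_h)`
#' from the studentized-range distribution at Duncan's protection
#' levels, where `p` is the span of the comparison and `n_h` the
#' harmonic mean group size. Range testing is protected: a range
#' declared homogeneous is not subdivided. Groups sharing a letter do
#' not differ significantly.
#'
#' @param means named vector of group means.
#' @param n group sizes (scalar or per group).
#' @param mse residual mean square from the ANOVA (> 0).
#' @param df residual degrees of freedom (> 0).
#' @param alpha significance level (default 0.05).
#' @return data.frame (`group`, `mean`, `letters`) sorted by
#'   decreasing mean.
#' @export
duncan_groups <- function(means, n, mse, df, alpha = 0.05) {
  stopifnot(length(means) >= 2, mse > 0)
  if (df <= 0) stop("residual degrees of freedom must be positive")
  k <- length(means)
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  if (length(n) == 1) n <- rep(n, k)
  nh <- k / sum(1 / n)                      # harmonic mean size
  se <- sqrt(mse / nh)
  crit <- vapply(2:k, function(p)
    qtukey((1 - alpha)^(p - 1), p, df) * se, numeric(1))
  crit <- c(NA, crit)                       # crit[p] for span p
  ord <- order(means, decreasing = TRUE)
  mu <- means[ord]
  homog <- matrix(FALSE, k, k)              # homog[i,j]: span i..j uniform
  test_range <- function(i, j) {
    if (i >= j) { homog[i, j] <<- TRUE; return(invisible()) }
    if (homog[i, j]) return(invisible())
    if (mu[i] - mu[j] <= crit[j - i + 1]) {
      for (a in i:j) for (b in a:j) homog[a, b] <<- TRUE
    } else {
      test_range(i, j - 1)
      test_range(i + 1, j)
    }
  }
  test_range(1, k)
  # maximal homogeneous runs -> letters
  runs <- list()
  for (i in 1:k) {
    j <- i
    while (j < k && homog[i, j + 1]) j <- j + 1
    runs[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, k)
  for (i in 1:k) for (j in 1:k)
    if (i != j && runs[[j]][1] <= runs[[i]][1] &&
        runs[[j]][2] >= runs[[i]][2] &&
        (runs[[j]][1] < runs[[i]][1] || runs[[j]][2] > runs[[i]][2]))
      keep[i] <- FALSE
  runs <- unique(runs[keep])
  letters_out <- rep("", k)
  for (r in seq_along(runs)) {
    span <- runs[[r]][1]:runs[[r]][2]
    letters_out[span] <- paste0(letters_out[span], letters[r])
  }
  data.frame(group = names(mu), mean = unname(mu), letters = letters_out,
             stringsAsFactors = FALSE)
}

#' Allele-by-environment (GxE) analysis
#'
#' For a two-allele hemizygote comparison across environments (base-wine
#' pH levels): per environment, a pooled-variance two-sided t-test of
#' the allele difference with significance tiers
#' `* p<=0.05, ** p<=0.01, *** p<=0.001`; plus the two-way
#' allele-by-environment interaction F-test from
#' `trait ~ allele * environment`.
#'
#' @param trait numeric trait values.
#' @param allele factor/character of allele labels (2 levels).
#' @param environment factor/character of environment labels (>= 2
#'   levels).
#' @return list: `per_env` (environment, n per allele, means, diff,
#'   p_value, stars), `interaction_F`, `interaction_p`,
#'   `interaction_stars`.
#' @export
gxe_analysis <- function(trait, allele, environment) {
  allele <- factor(allele); environment <- factor(environment)
  if (nlevels(allele) != 2) stop("exactly 2 alleles required")
  if (nlevels(environment) < 2) stop("at least 2 environments required")
  cell_n <- table(allele, environment)
  if (any(cell_n == 0)) stop("empty allele x environment cell")
  if (any(cell_n < 2)) stop("at least 2 replicates per cell required")
  star <- function(p) ifelse(p <= 0.001, "***",
                      ifelse(p <= 0.01, "**",
                      ifelse(p <= 0.05, "*", "")))
  rows <- lapply(levels(environment), function(e) {
    sel <- environment == e
    y1 <- trait[sel & allele == levels(allele)[1]]
    y2 <- trait[sel & allele == levels(allele)[2]]
    n1 <- length(y1); n2 <- length(y2)
    sp2 <- ((n1 - 1) * var(y1) + (n2 - 1) * var(y2)) / (n1 + n2 - 2)
    tstat <- (mean(y1) - mean(y2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
    data.frame(environment = e, n1 = n1, n2 = n2,
               mean1 = mean(y1), mean2 = mean(y2),
               diff = mean(y1) - mean(y2), p_value = p,
               stars = star(p), stringsAsFactors = FALSE)
  })
  fit <- aov(trait ~ allele * environment)
  an <- summary(fit)[[1]]
  ia <- which(trimws(rownames(an)) == "allele:environment")
  out <- list(per_env = do.call(rbind, rows),
              interaction_F = an$`F value`[ia],
              interaction_p = an$`Pr(>F)`[ia],
              interaction_stars = star(an$`Pr(>F)`[ia]))
  names(out$per_env)[4:5] <- paste0("mean_", levels(allele))
  out
}

#' Cross-level genetics report
#'
#' Per trait: parental and hybrid means, mid-parent value, heterosis
#' d/m, broad-sense heritability and transgression, from per-strain
#' trait tables.
#'
#' @param seg_traits data.frame of per-segregant trait values (one
#'   column per trait, plus `segregant`/`strain` id columns which are
#'   ignored).
#' @param parent_traits data.frame with replicate trait values for the
#'   reference strains; must contain a `strain` column with levels
#'   `p1_label`, `p2_label`, `hybrid_label`.
#' @param p1_label,p2_label,hybrid_label strain ids in `parent_traits`.
#' @param k transgression widening factor (SD units, default 2).
#' @return data.frame: one row per trait with p1/p2/hybrid means,
#'   midparent, d_m, env_sd, H2, transgression_pct,
#'   transgression_count, n.
#' @export
genetics_report <- function(seg_traits, parent_traits,
                            p1_label = "P1", p2_label = "P2",
                            hybrid_label = "hybrid", k = 2.0) {
  idcols <- intersect(c("segregant", "strain", "replicate", "converged"),
                      names(seg_traits))
  traits <- setdiff(names(seg_traits), idcols)
  rows <- lapply(traits, function(tr) {
    sv <- seg_traits[[tr]]
    sv <- sv[is.finite(sv)]
    pv <- function(lab) parent_traits[[tr]][parent_traits$strain == lab]
    p1 <- pv(p1_label); p2 <- pv(p2_label); hy <- pv(hybrid_label)
    env_sd <- sqrt(mean(c(var(p1), var(p2), var(hy)), na.rm = TRUE))
    if (!is.finite(env_sd)) env_sd <- 0
    tg <- transgression(sv, mean(p1), mean(p2), env_sd, k = k)
    h2 <- if (var(sv) > 0)
      heritability(var(sv), env_sd^2) else NA_real_
    data.frame(trait = tr, p1 = mean(p1), p2 = mean(p2),
               hybrid = mean(hy), midparent = (mean(p1) + mean(p2)) / 2,
               d_m = heterosis_dm(mean(hy), mean(p1), mean(p2)),
               env_sd = env_sd, H2 = h2,
               transgression_pct = tg$percent,
               transgression_count = tg$count, n = length(sv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
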