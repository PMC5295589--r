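#' Direction of improvement for each kinetic trait
#'
#' Fermentation is "better" when pressure builds higher and faster:
#' `Pmax` and `rate` improve upward, the threshold times (`t0.5`, `t2`,
#' `t5`) improve downward.
#'
#' @param trait character vector of trait names.
#' @return logical vector: TRUE if higher values are better.
#' @export
trait_higher_is_better <- function(trait) {
  up <- c("Pmax", "rate")
  grepl("^(Pmax|rate)$", trait) | trait %in% up
}

# signed allele contribution matrix for a set of loci resolved to their
# nearest simulated marker on the same chromosome
resolve_loci <- function(cross, loci) {
  idx <- integer(nrow(loci))
  for (k in seq_len(nrow(loci))) {
    on_chr <- which(cross$markers$chrom == loci$chrom[k])
    if (!length(on_chr))
      stop("no simulated marker on ", loci$chrom[k],
           "; locus cannot be resolved")
    idx[k] <- on_chr[which.min(abs(cross$markers$pos[on_chr] -
                                     loci$pos_bp[k]))]
  }
  idx
}

#' Ground-truth additive trait values of a cross
#'
#' Applies the architecture's additive model: for each trait,
#' `value = baseline + sum over loci of (+effect if P2 inherited,
#' -effect if P1) + Normal(0, noise_sd)`. Loci (including any linked
#' block) are resolved to the nearest simulated marker.
#'
#' @param cross a [sim_cross()] result.
#' @param arch a [qtl_architecture()].
#' @param seed integer seed.
#' @param n_segregants optionally restrict to the first k segregants.
#' @return data.frame: `segregant` plus one column per modelled trait;
#'   attributes `locus_markers` (data.frame chrom/pos_bp/trait/effect/
#'   marker index/marker pos) and `genetic` (noise-free values).
#' @export
sim_trait_table <- function(cross, arch, seed = 1, n_segregants = NULL) {
  stopifnot(inherits(cross, "true_cross"),
            inherits(arch, "qtl_architecture"))
  set.seed(substream_seed(seed, "phenotypes"))
  all_loci <- rbind(arch$loci, arch$linked_block)
  idx <- resolve_loci(cross, all_loci)
  H <- cross$haplotypes
  if (!is.null(n_segregants)) H <- H[seq_len(n_segregants), , drop = FALSE]
  n <- nrow(H)
  traits <- names(arch$baseline)
  out <- data.frame(segregant = rownames(H), stringsAsFactors = FALSE)
  gen <- out
  for (tr in traits) {
    g <- rep(arch$baseline[[tr]], n)
    for (k in which(all_loci$trait == tr)) {
      s <- ifelse(H[, idx[k]] == 2L, 1, -1)
      g <- g + s * all_loci$effect[k]
    }
    gen[[tr]] <- g
    out[[tr]] <- g + rnorm(n, 0, arch$noise_sd[[tr]])
  }
  attr(out, "locus_markers") <- cbind(all_loci,
                                      marker = idx,
                                      marker_pos = cross$markers$pos[idx])
  attr(out, "genetic") <- gen
  out
}

#' Synthesize 5PL parameters matching target kinetic traits
#'
#' Builds an `A = 0` five-parameter logistic whose upper asymptote is
#' `Pmax` and whose curve crosses `x_mid` bar at `t2` and `x_late` bar
#' at `t5` exactly (closed form given the asymmetry `G`); `G` is then
#' solved so the maximum slope matches the `rate` target. With the two
#' crossing times fixed, the attainable maximum slope spans a bounded
#' band; a rate target outside it is clamped to the nearest attainable
#' value and flagged.
#'
#' @param Pmax upper asymptote (bar); must exceed `x_late`.
#' @param rate target maximum slope (bar/day).
#' @param t2,t5 target crossing times (days), `0 < t2 < t5`.
#' @param x_mid,x_late the two pressure thresholds (bar).
#' @return list: `par` (named A, D, C, B, G), `rate` (realised max
#'   slope), `clamped` (logical).
#' @export
synth_5pl <- function(Pmax, rate, t2, t5, x_mid = 2, x_late = 5) {
  if (!is.finite(Pmax) || Pmax <= x_late + 1e-3)
    stop("non-physical kinetics: Pmax must exceed the late threshold")
  if (!is.finite(t2) || !is.finite(t5) || t2 <= 0 || t5 <= t2)
    stop("non-physical kinetics: need 0 < t2 < t5")
  if (!is.finite(rate) || rate <= 0)
    stop("non-physical kinetics: rate must be positive")
  D <- Pmax
  logq <- function(X, G) {            # log((D/X)^(1/G) - 1), overflow-safe
    x <- log(D / X) / G
    if (x > 30) x else log(expm1(x))
  }
  cb_of <- function(G) {
    l2 <- logq(x_mid, G); l5 <- logq(x_late, G)
    B <- (l2 - l5) / (log(t5) - log(t2))
    C <- exp(log(t2) + l2 / B)
    c(C = C, B = B)
  }
  rate_of <- function(G) {
    cb <- cb_of(G)
    pl5_max_rate(D, cb["C"], cb["B"], G)$rate
  }
  lo <- -6; hi <- 6                    # log G search range
  while (is.na(rate_of(exp(lo))) && lo < hi) lo <- lo + 0.25
  f <- function(lg) rate_of(exp(lg)) - rate
  flo <- f(lo); fhi <- f(hi)
  clamped <- FALSE
  if (is.na(flo) || flo >= 0) {        # target at/below attainable minimum
    G <- exp(lo); clamped <- !is.na(flo) && flo > 1e-10
  } else if (fhi <= 0) {               # target at/above attainable maximum
    G <- exp(hi); clamped <- fhi < -1e-10
  } else {
    G <- exp(uniroot(f, c(lo, hi), tol = 1e-12)$root)
  }
  cb <- cb_of(G)
  list(par = c(A = 0, D = D, C = unname(cb["C"]), B = unname(cb["B"]),
               G = G),
       rate = rate_of(G), clamped = clamped)
}

#' Simulate second-fermentation pressure curves for a cross
#'
#' Draws per-bottle trait targets from the additive model (segregants:
#' one bottle each by default; parents and hybrid: `parent_rep`
#' bottles), synthesizes a matching 5PL curve per bottle, converts it
#' to the fermentation temperature, and samples it at the design times
#' with Normal observation noise. The hybrid's genetic value assumes
#' complete dominance of the beneficial allele at every locus.
#'
#' @param cross a [sim_cross()] result.
#' @param arch a [qtl_architecture()].
#' @param design list: `times` (days), `temperature_C`, `t_ref_c`,
#'   `vant_hoff_K`, `n_rep` (bottles per segregant), `parent_rep`.
#' @param seed integer seed.
#' @param include_parents also emit P1, P2 and hybrid bottles.
#' @return list: `curves` (long data.frame strain/replicate/time_days/
#'   pressure_bar/temperature_C), `truth` (per-bottle analytic traits),
#'   `targets` (per-segregant trait table), `arch`, `design`.
#' @export
sim_phenotypes <- function(cross, arch, design = list(), seed = 1,
                           include_parents = TRUE) {
  d <- utils::modifyList(list(times = seq(0.5, 40, by = 0.5),
                              temperature_C = 16, t_ref_c = 10,
                              vant_hoff_K = 2400, n_rep = 1L,
                              parent_rep = 3L), design)
  targets <- sim_trait_table(cross, arch, seed = seed)
  gen <- attr(targets, "genetic")
  set.seed(substream_seed(seed, "curves"))
  traits <- names(arch$baseline)
  need <- c("Pmax", "rate", "t2", "t5")
  if (!all(need %in% traits))
    stop("curve synthesis requires modelled traits Pmax, rate, t2, t5")

  strain_rows <- list()
  add_strain <- function(strain, gvals, n_rep) {
    for (r in seq_len(n_rep)) {
      tv <- vapply(traits, function(tr)
        gvals[[tr]] + rnorm(1, 0, arch$noise_sd[[tr]]), numeric(1))
      strain_rows[[length(strain_rows) + 1L]] <<-
        list(strain = strain, replicate = r, tv = tv)
    }
  }
  # segregants: bottle targets are the (already noisy) table values for
  # bottle 1; extra bottles redraw the biological noise
  for (i in seq_len(nrow(targets))) {
    tv <- vapply(traits, function(tr) targets[[tr]][i], numeric(1))
    strain_rows[[length(strain_rows) + 1L]] <-
      list(strain = targets$segregant[i], replicate = 1L, tv = tv)
    if (d$n_rep > 1L) {
      gv <- as.list(gen[i, traits])
      for (r in 2:d$n_rep) {
        tv <- vapply(traits, function(tr)
          gv[[tr]] + rnorm(1, 0, arch$noise_sd[[tr]]), numeric(1))
        strain_rows[[length(strain_rows) + 1L]] <-
          list(strain = targets$segregant[i], replicate = r, tv = tv)
      }
    }
  }
  if (include_parents) {
    all_loci <- rbind(arch$loci, arch$linked_block)
    gP1 <- gP2 <- gHy <- as.list(arch$baseline)
    for (k in seq_len(nrow(all_loci))) {
      tr <- all_loci$trait[k]; a <- all_loci$effect[k]
      gP1[[tr]] <- gP1[[tr]] - a
      gP2[[tr]] <- gP2[[tr]] + a
      best <- if (trait_higher_is_better(tr)) abs(a) else -abs(a)
      gHy[[tr]] <- gHy[[tr]] + best
    }
    add_strain("P1", gP1, d$parent_rep)
    add_strain("P2", gP2, d$parent_rep)
    add_strain("hybrid", gHy, d$parent_rep)
  }

  curves <- vector("list", length(strain_rows))
  truth <- vector("list", length(strain_rows))
  shift <- exp(d$vant_hoff_K * (1 / (d$t_ref_c + 273.15) -
                                  1 / (d$temperature_C + 273.15)))
  for (j in seq_along(strain_rows)) {
    s <- strain_rows[[j]]
    sp <- synth_5pl(s$tv[["Pmax"]], s$tv[["rate"]], s$tv[["t2"]],
                    s$tv[["t5"]])
    p <- sp$par
    tr <- kinetic_traits(structure(list(par = p, converged = TRUE),
                                   class = "kinetic_fit"))
    truth[[j]] <- cbind(data.frame(strain = s$strain,
                                   replicate = s$replicate,
                                   clamped = sp$clamped,
                                   stringsAsFactors = FALSE),
                        as.data.frame(as.list(tr), check.names = FALSE))
    p_ref <- pl5(d$times, p["D"], p["C"], p["B"], p["G"])
    p_obs <- pmax(0, p_ref * shift + rnorm(length(d$times), 0,
                                           arch$replicate_sd))
    curves[[j]] <- data.frame(strain = s$strain, replicate = s$replicate,
                              time_days = d$times, pressure_bar = p_obs,
                              temperature_C = d$temperature_C,
                              stringsAsFactors = FALSE)
  }
  list(curves = do.call(rbind, curves),
       truth = do.call(rbind, truth),
       targets = targets, arch = arch, design = d)
}
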