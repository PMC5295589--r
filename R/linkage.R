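#' Wilcoxon rank-sum genome scan
#'
#' At every pass marker, tests the trait difference between the P1 and
#' P2 genotype groups with a two-sided Wilcoxon rank-sum test (missing
#' genotypes excluded) and reports the linkage score
#' `LK = -log10(p)`. Markers where either group is smaller than
#' `min_group` get an undefined (NA) score. P-values use exact
#' enumeration when both groups have at most 25 segregants and the
#' trait subset has no ties, and the normal approximation with tie and
#' continuity corrections otherwise.
#'
#' @param gm a `genotype_matrix`; if [build_marker_map()] has been run,
#'   only `pass` markers are scanned.
#' @param trait numeric trait vector, either named by segregant or in
#'   `gm$segregants` order. NA traits are excluded.
#' @param min_group minimum segregants per genotype group (default 10).
#' @param method `"auto"` (exact where applicable), `"approx"`, or
#'   `"exact"` (error where enumeration is impossible).
#' @return data.frame of class `linkage_profile`: `chrom`, `pos`, `lk`,
#'   `n_p1`, `n_p2`; attributes `trait_name` and `min_group`.
#' @export
wilcoxon_scan <- function(gm, trait, min_group = 10,
                          method = c("auto", "approx", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(gm, "genotype_matrix"))
  y <- align_trait(gm, trait)
  keep <- is.finite(y)
  if (sum(keep) < 2 * min_group)
    stop("trait defined for fewer than 2*min_group segregants")
  cols <- if (is.null(gm$pass)) seq_len(ncol(gm$geno)) else gm$pass
  G <- gm$geno[keep, cols, drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) == 1L)
    warning("constant trait: all defined LK scores are 0")
  res <- ranksum_scan_cpp(G, y, as.integer(min_group))
  lk <- res[, 1]
  if (method != "approx") {
    small <- which(!is.na(lk) & res[, 2] <= 25 & res[, 3] <= 25)
    for (j in small) {
      g <- G[, j]; ok <- !is.na(g)
      ys <- y[ok]
      if (anyDuplicated(ys)) {
        if (method == "exact")
          stop("exact mode requested but ties present at marker ", j)
        next
      }
      lk[j] <- -log10(exact_ranksum_p(ys[g[ok] == 1L], ys[g[ok] == 2L]))
    }
    if (method == "exact" && any(!is.na(lk) & (res[, 2] > 25 | res[, 3] > 25)))
      stop("exact mode requested but group sizes exceed 25")
  }
  out <- data.frame(chrom = gm$markers$chrom[cols],
                    pos = gm$markers$pos[cols],
                    lk = lk, n_p1 = res[, 2], n_p2 = res[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("linkage_profile", "data.frame")
  attr(out, "trait_name") <- if (!is.null(attr(trait, "trait_name")))
    attr(trait, "trait_name") else deparse(substitute(trait))[1]
  attr(out, "min_group") <- min_group
  out
}

align_trait <- function(gm, trait) {
  if (!is.null(names(trait))) {
    y <- as.numeric(trait[match(gm$segregants, names(trait))])
  } else {
    if (length(trait) != length(gm$segregants))
      stop("unnamed trait vector must match the number of segregants")
    y <- as.numeric(trait)
  }
  y
}

# exact two-sided rank-sum p via the Wilcoxon U distribution
exact_ranksum_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  r <- rank(c(x1, x2))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- if (U > n1 * n2 / 2)
    2 * (1 - pwilcox(U - 1, n1, n2))
  else
    2 * pwilcox(U, n1, n2)
  min(1, p)
}

#' Permutation-based genome-wide significance threshold
#'
#' Permutes the trait values uniformly across segregants (genotypes
#' fixed), rescans the genome per permutation with the normal
#' approximation, records the genome-wide maximum LK over defined
#' markers, and returns the empirical `1 - alpha` quantile (type-7
#' interpolation) as the family-wise threshold.
#'
#' @inheritParams wilcoxon_scan
#' @param n_perm number of permutations (default 1000).
#' @param alpha family-wise level (default 0.05).
#' @param seed integer seed for the permutation stream.
#' @return Object of class `permutation_null`: list with `max_lk`
#'   (length `n_perm`), `threshold`, `alpha`, `n_perm`, `seed`.
#' @export
permutation_threshold <- function(gm, trait, n_perm = 1000, alpha = 0.05,
                                  seed = 1, min_group = 10) {
  stopifnot(inherits(gm, "genotype_matrix"), n_perm >= 1)
  y <- align_trait(gm, trait)
  keep <- is.finite(y)
  cols <- if (is.null(gm$pass)) seq_len(ncol(gm$geno)) else gm$pass
  G <- gm$geno[keep, cols, drop = FALSE]
  set.seed(substream_seed(seed, "perm"))
  mx <- perm_max_lk_cpp(G, y[keep], as.integer(n_perm),
                        as.integer(min_group))
  out <- list(max_lk = mx,
              threshold = unname(quantile(mx, 1 - alpha, na.rm = TRUE,
                                          type = 7)),
              alpha = alpha, n_perm = n_perm, seed = seed)
  class(out) <- "permutation_null"
  out
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "permutation_null: %d permutations, %.0f%% threshold LK = %.3f\n",
    x$n_perm, 100 * (1 - x$alpha), x$threshold))
  invisible(x)
}

#' Call QTL from a linkage profile
#'
#' Local maxima above the permutation threshold become QTL peaks. The
#' support interval extends from each peak outward to the outermost
#' contiguous flanking markers whose LK stays within `drop` LK units of
#' the peak; overlapping intervals on one chromosome are merged into
#' the call with the higher peak. When genotypes and trait values are
#' supplied, the beneficial parent is the genotype group whose mean
#' trait is better (direction set by `higher_is_better`).
#'
#' @param profile a [wilcoxon_scan()] result.
#' @param null a [permutation_threshold()] result (or a single numeric
#'   threshold).
#' @param drop LK-unit drop defining the support interval (default 1).
#' @param gm,trait optional genotype matrix and trait vector used to
#'   annotate the beneficial parent.
#' @param higher_is_better TRUE when larger trait values are better
#'   (e.g. rate); FALSE for the threshold times.
#' @return data.frame of QTL calls: `trait`, `chrom`, `peak_pos`,
#'   `peak_lk`, `start`, `end`, `threshold`, `beneficial`. Empty when
#'   no marker clears the threshold.
#' @export
call_qtl <- function(profile, null, drop = 1.0, gm = NULL, trait = NULL,
                     higher_is_better = FALSE) {
  thr <- if (inherits(null, "permutation_null")) null$threshold
         else as.numeric(null)
  empty <- data.frame(trait = character(), chrom = character(),
                      peak_pos = numeric(), peak_lk = numeric(),
                      start = numeric(), end = numeric(),
                      threshold = numeric(), beneficial = character(),
                      stringsAsFactors = FALSE)
  tn <- attr(profile, "trait_name")
  if (is.null(tn)) tn <- NA_character_
  calls <- list()
  for (ch in unique(profile$chrom)) {
    sub <- profile[profile$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    lk <- sub$lk
    remaining <- which(!is.na(lk) & lk > thr)
    ivals <- list()
    while (length(remaining)) {
      pk <- remaining[which.max(lk[remaining])]
      lo <- pk
      while (lo > 1 && !is.na(lk[lo - 1]) && lk[lo - 1] >= lk[pk] - drop)
        lo <- lo - 1
      hi <- pk
      while (hi < length(lk) && !is.na(lk[hi + 1]) &&
             lk[hi + 1] >= lk[pk] - drop)
        hi <- hi + 1
      ivals[[length(ivals) + 1L]] <- c(lo = lo, hi = hi, pk = pk)
      remaining <- setdiff(remaining, lo:hi)
    }
    if (!length(ivals)) next
    # merge overlapping intervals, keeping the higher peak
    ord <- order(vapply(ivals, `[[`, numeric(1), "lo"))
    ivals <- ivals[ord]
    merged <- list(ivals[[1]])
    for (iv in ivals[-1]) {
      last <- merged[[length(merged)]]
      if (iv["lo"] <= last["hi"]) {
        pk <- if (lk[iv["pk"]] > lk[last["pk"]]) iv["pk"] else last["pk"]
        merged[[length(merged)]] <- c(lo = unname(last["lo"]),
                                      hi = max(unname(last["hi"]),
                                               unname(iv["hi"])),
                                      pk = unname(pk))
      } else merged[[length(merged) + 1L]] <- iv
    }
    for (iv in merged) {
      ben <- NA_character_
      if (!is.null(gm) && !is.null(trait)) {
        y <- align_trait(gm, trait)
        key <- marker_key(ch, sub$pos[iv["pk"]])
        j <- match(key, marker_key(gm$markers$chrom, gm$markers$pos))
        g <- gm$geno[, j]
        m1 <- mean(y[g == 1L], na.rm = TRUE)
        m2 <- mean(y[g == 2L], na.rm = TRUE)
        ben <- if (xor(m1 > m2, higher_is_better)) "P2" else "P1"
      }
      calls[[length(calls) + 1L]] <- data.frame(
        trait = tn, chrom = ch,
        peak_pos = sub$pos[iv["pk"]], peak_lk = lk[iv["pk"]],
        start = sub$pos[iv["lo"]], end = sub$pos[iv["hi"]],
        threshold = thr, beneficial = ben, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Candidate genes in a QTL support interval
#'
#' Genes overlapping the support interval (1-based inclusive
#' coordinates) that carry a nonsynonymous SNP between the parents,
#' sorted by position.
#'
#' @param qtl one QTL call (a one-row data.frame or list with `chrom`,
#'   `start`, `end`).
#' @param annotation data.frame of gene intervals: `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param ns_snp_flags data.frame (`gene_id`, `has_ns_snp`).
#' @return character vector of gene ids (possibly empty).
#' @export
candidate_genes <- function(qtl, annotation, ns_snp_flags) {
  if (nrow(annotation) == 0) return(character())
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in%
                  names(annotation)),
            all(c("gene_id", "has_ns_snp") %in% names(ns_snp_flags)))
  hit <- annotation$chrom == qtl$chrom &
    annotation$start <= qtl$end & annotation$end >= qtl$start
  g <- annotation[hit, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  fl <- ns_snp_flags$has_ns_snp[match(g$gene_id, ns_snp_flags$gene_id)]
  g$gene_id[!is.na(fl) & fl]
}

#' Plot a linkage profile
#'
#' Simple genome-wide LK plot with chromosomes laid end to end.
#'
#' @param x a `linkage_profile`.
#' @param threshold optional horizontal threshold line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.linkage_profile <- function(x, threshold = NULL, ...) {
  chrs <- unique(x$chrom)
  offs <- c(0, cumsum(vapply(chrs, function(ch)
    max(x$pos[x$chrom == ch]), numeric(1))))
  names(offs) <- c(chrs, "end")
  gx <- x$pos + offs[x$chrom]
  graphics::plot(gx / 1e6, x$lk, type = "p", pch = 16, cex = 0.4,
                 xlab = "genome position (Mb)", ylab = "LK = -log10(p)",
                 ...)
  graphics::abline(v = offs[-1] / 1e6, col = "grey85")
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(x)
}

#' Read gene intervals from a GFF3 annotation
#'
#' Imports gene features (1-based inclusive coordinates) into the
#' plain table [candidate_genes()] expects.
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default "gene").
#' @return data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) == feature]
  id <- if (!is.null(gr$ID)) gr$ID else gr$Name
  data.frame(gene_id = as.character(id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
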