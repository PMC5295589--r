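marker_key <- function(chrom, pos) paste0(chrom, ":", pos)

#' Distinguishing SNPs between two homozygous parents
#'
#' From two per-parent variant lists called against the same reference,
#' retains the sites where the parents differ from each other: sites
#' where exactly one parent differs from the reference (the other
#' parent's allele is then the reference), and sites where both differ
#' with different alternate alleles. Sites where both parents share the
#' same variant are dropped.
#'
#' @param p1_variants,p2_variants data.frames with columns `chrom`,
#'   `pos`, `ref`, `alt` (homozygous calls vs the same reference).
#' @return data.frame (`chrom`, `pos`, `ref`, `p1_allele`,
#'   `p2_allele`), sorted by chromosome then position.
#' @export
distinguishing_snps <- function(p1_variants, p2_variants) {
  need <- c("chrom", "pos", "ref", "alt")
  stopifnot(all(need %in% names(p1_variants)),
            all(need %in% names(p2_variants)))
  check_dups <- function(v, who) {
    k <- marker_key(v$chrom, v$pos)
    if (anyDuplicated(k)) {
      d <- split(v$alt, k)
      bad <- names(d)[vapply(d, function(a) length(unique(a)) > 1,
                             logical(1))]
      if (length(bad))
        stop("conflicting duplicate records for ", who, " at ",
             paste(head(bad, 3), collapse = ", "))
      v <- v[!duplicated(k), , drop = FALSE]
    }
    v
  }
  p1 <- check_dups(p1_variants, "parent 1")
  p2 <- check_dups(p2_variants, "parent 2")
  k1 <- marker_key(p1$chrom, p1$pos)
  k2 <- marker_key(p2$chrom, p2$pos)
  all_k <- union(k1, k2)
  i1 <- match(all_k, k1); i2 <- match(all_k, k2)
  chrom <- ifelse(is.na(i1), p2$chrom[i2], p1$chrom[i1])
  pos   <- ifelse(is.na(i1), p2$pos[i2], p1$pos[i1])
  ref   <- ifelse(is.na(i1), p2$ref[i2], p1$ref[i1])
  ref2  <- ifelse(is.na(i2), ref, p2$ref[i2])
  if (any(ref != ref2))
    stop("reference allele mismatch between parental variant lists")
  a1 <- ifelse(is.na(i1), ref, p1$alt[i1])
  a2 <- ifelse(is.na(i2), ref, p2$alt[i2])
  keep <- a1 != a2
  out <- data.frame(chrom = chrom[keep], pos = pos[keep], ref = ref[keep],
                    p1_allele = a1[keep], p2_allele = a2[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call segregant genotypes from allele counts
#'
#' Rule-based calling at 3-6x coverage: a cell is P1 when
#' `n_p1 >= min_reads` and `n_p2 <= max_conflict` (and symmetrically
#' P2); anything else — zero coverage or conflicting reads — is
#' missing. The defaults (1 read, no conflicting read tolerated) prefer
#' missingness over wrong calls.
#'
#' @param counts long data.frame (`segregant`, `chrom`, `pos`, `n_p1`,
#'   `n_p2`); counts at sites absent from `variants` are dropped with a
#'   warning.
#' @param variants the distinguishing-SNP table (defines marker order).
#' @param min_reads minimum supporting reads for a call (>= 1).
#' @param max_conflict maximum opposing reads tolerated in a call.
#' @return Object of class `genotype_matrix`: list with `geno`
#'   (integer matrix segregants x markers: 1 = P1, 2 = P2, NA),
#'   `markers` (chrom, pos, n_p1, n_p2, n_missing, chisq_p, filter),
#'   `segregants`.
#' @export
call_genotypes <- function(counts, variants, min_reads = 1L,
                           max_conflict = 0L) {
  stopifnot(min_reads >= 1, max_conflict >= 0)
  need <- c("segregant", "chrom", "pos", "n_p1", "n_p2")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$n_p1 < 0 | counts$n_p2 < 0))
    stop("read counts must be non-negative")
  vk <- marker_key(variants$chrom, variants$pos)
  ck <- marker_key(counts$chrom, counts$pos)
  mi <- match(ck, vk)
  if (anyNA(mi)) {
    warning(sum(is.na(mi)), " count rows at sites absent from the ",
            "variant table were ignored")
    counts <- counts[!is.na(mi), , drop = FALSE]
    mi <- mi[!is.na(mi)]
  }
  segs <- unique(counts$segregant)
  si <- match(counts$segregant, segs)
  geno <- matrix(NA_integer_, nrow = length(segs), ncol = length(vk),
                 dimnames = list(segs, vk))
  is_p1 <- counts$n_p1 >= min_reads & counts$n_p2 <= max_conflict
  is_p2 <- counts$n_p2 >= min_reads & counts$n_p1 <= max_conflict
  call <- ifelse(is_p1 & !is_p2, 1L, ifelse(is_p2 & !is_p1, 2L, NA_integer_))
  geno[cbind(si, mi)] <- call
  n1 <- colSums(geno == 1L, na.rm = TRUE)
  n2 <- colSums(geno == 2L, na.rm = TRUE)
  nm <- length(segs) - n1 - n2
  chisq_p <- ifelse(n1 + n2 > 0,
                    pchisq((n1 - n2)^2 / (n1 + n2), df = 1,
                           lower.tail = FALSE),
                    NA_real_)
  gm <- list(geno = geno,
             markers = data.frame(chrom = variants$chrom,
                                  pos = variants$pos,
                                  n_p1 = n1, n_p2 = n2, n_missing = nm,
                                  chisq_p = chisq_p,
                                  filter = NA_character_,
                                  stringsAsFactors = FALSE),
             segregants = segs)
  class(gm) <- "genotype_matrix"
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d segregants x %d markers",
              nrow(x$geno), ncol(x$geno)))
  if (!all(is.na(x$markers$filter))) {
    tab <- table(x$markers$filter)
    cat(" [", paste(names(tab), tab, sep = ":", collapse = ", "), "]")
  }
  cat("\n")
  invisible(x)
}

#' Build the filtered marker map
#'
#' Applies the marker-retention rules: a marker is `distorted` when its
#' 1:1 segregation chi-square test (df = 1, no continuity correction,
#' non-missing calls only) gives p <= `alpha`; `sparse` when its
#' missing fraction exceeds `max_missing_frac`; the remaining markers
#' are thinned to at most one per `spacing_kb` window (half-open
#' windows anchored at position 1), keeping the marker with the fewest
#' missing calls (ties: leftmost); all others in the window are
#' `thinned`. Only `pass` markers feed the genome scan.
#'
#' @param gm a [call_genotypes()] result.
#' @param alpha segregation-distortion level (default 0.05).
#' @param max_missing_frac maximum tolerated missing fraction (0.5).
#' @param spacing_kb window size in kb for the even-spacing rule (15).
#' @return `gm` with `markers$filter` filled in and a `pass` index
#'   vector; errors if every marker is filtered out.
#' @export
build_marker_map <- function(gm, alpha = 0.05, max_missing_frac = 0.5,
                             spacing_kb = 15) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mk <- gm$markers
  if (nrow(mk) == 0) stop("empty genotype matrix")
  n <- nrow(gm$geno)
  status <- rep("candidate", nrow(mk))
  status[!is.na(mk$chisq_p) & mk$chisq_p <= alpha] <- "distorted"
  miss_frac <- mk$n_missing / n
  status[status == "candidate" & miss_frac > max_missing_frac] <- "sparse"
  status[is.na(mk$chisq_p)] <- "sparse"          # never called anywhere
  win <- floor((mk$pos - 1) / (spacing_kb * 1000))
  grp <- paste(mk$chrom, win)
  cand <- which(status == "candidate")
  keep <- unlist(lapply(split(cand, grp[cand]), function(ii) {
    ii[order(mk$n_missing[ii], mk$pos[ii])][1]
  }), use.names = FALSE)
  status[cand] <- "thinned"
  status[keep] <- "pass"
  if (!length(keep)) {
    tab <- table(status)
    stop("all markers filtered out (",
         paste(names(tab), tab, sep = ":", collapse = ", "), ")")
  }
  gm$markers$filter <- status
  gm$pass <- sort(keep)
  gm
}
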