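#' Simulate distinguishing parental SNPs
#'
#' Draws `n_snps` biallelic sites that distinguish two homozygous
#' parents: unique (chromosome, position) pairs, placed uniformly within
#' chromosomes with per-chromosome counts proportional to length, each
#' site carrying distinct P1/P2 alleles from {A,C,G,T}. The reference
#' allele matches one of the two parents at random, so each parent
#' deviates from the reference at roughly half the sites.
#'
#' @param genome a [genome_model()].
#' @param n_snps number of sites (>= 0).
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame (`chrom`, `pos`, `ref`, `p1_allele`, `p2_allele`),
#'   sorted by chromosome then position.
#' @export
sim_parents <- function(genome, n_snps = 1071, seed = 1) {
  stopifnot(inherits(genome, "genome_model"), n_snps >= 0)
  chr <- genome$chromosomes
  if (n_snps > sum(chr$length_bp))
    stop("n_snps exceeds total genome length")
  cols <- c("chrom", "pos", "ref", "p1_allele", "p2_allele")
  if (n_snps == 0) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), p1_allele = character(),
                      p2_allele = character(), stringsAsFactors = FALSE)
    return(out)
  }
  set.seed(substream_seed(seed, "parents"))
  # largest-remainder apportionment of sites to chromosomes
  quota <- n_snps * chr$length_bp / sum(chr$length_bp)
  k <- floor(quota)
  rem <- n_snps - sum(k)
  if (rem > 0) {
    extra <- order(quota - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  k <- pmin(k, chr$length_bp)  # cannot place more sites than bases
  nt <- c("A", "C", "G", "T")
  pieces <- lapply(seq_len(nrow(chr)), function(i) {
    if (k[i] == 0) return(NULL)
    pos <- sort(sample.int(chr$length_bp[i], k[i], replace = FALSE))
    p1 <- sample(nt, k[i], replace = TRUE)
    shift <- sample.int(3L, k[i], replace = TRUE)
    p2 <- nt[(match(p1, nt) - 1L + shift) %% 4L + 1L]
    ref <- ifelse(runif(k[i]) < 0.5, p1, p2)
    data.frame(chrom = chr$name[i], pos = pos, ref = ref,
               p1_allele = p1, p2_allele = p2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[cols]
}

#' Simulate meioses of an F1 cross
#'
#' Places crossovers per segregant and chromosome by a Poisson process
#' with mean `length_kb * cm_per_kb / 100` (Haldane model, no
#' interference), alternates the parental haplotype at each crossover,
#' and starts each chromosome from P1 or P2 with probability 1/2.
#'
#' @param parents variant table from [sim_parents()] (the marker sites).
#' @param n_segregants number of haploid segregants (>= 1).
#' @param genome the [genome_model()] used for lengths and map density.
#' @param seed integer seed.
#' @return Object of class `true_cross`: list with `haplotypes`
#'   (integer matrix segregants x markers, values 1 = P1 and 2 = P2),
#'   `markers` (chrom, pos), `crossovers` (nested list of positions),
#'   `segregants`, `parents`, `genome`.
#' @export
sim_cross <- function(parents, n_segregants, genome = default_genome(),
                      seed = 1) {
  stopifnot(n_segregants >= 1)
  set.seed(substream_seed(seed, "cross"))
  chr <- genome$chromosomes
  m <- nrow(parents)
  ids <- sprintf("seg%03d", seq_len(n_segregants))
  H <- matrix(1L, nrow = n_segregants, ncol = m,
              dimnames = list(ids, paste0(parents$chrom, ":", parents$pos)))
  xov <- vector("list", n_segregants)
  names(xov) <- ids
  for (i in seq_len(n_segregants)) xov[[i]] <- list()
  for (ci in seq_len(nrow(chr))) {
    idx <- which(parents$chrom == chr$name[ci])
    L <- chr$length_bp[ci]
    lambda <- (L / 1000) * genome$cm_per_kb / 100
    nxo <- rpois(n_segregants, lambda)
    start <- rbinom(n_segregants, 1L, 0.5)  # 0 -> P1 first, 1 -> P2 first
    for (i in seq_len(n_segregants)) {
      pos_xo <- sort(runif(nxo[i], min = 0, max = L))
      xov[[i]][[chr$name[ci]]] <- pos_xo
      if (length(idx))
        H[i, idx] <- ((start[i] + findInterval(parents$pos[idx], pos_xo)) %% 2L) + 1L
    }
  }
  out <- list(haplotypes = H,
              markers = parents[c("chrom", "pos")],
              crossovers = xov,
              segregants = ids,
              parents = parents,
              genome = genome)
  class(out) <- "true_cross"
  out
}

#' @export
print.true_cross <- function(x, ...) {
  cat(sprintf("true_cross: %d segregants x %d markers on %d chromosomes\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              nrow(x$genome$chromosomes)))
  invisible(x)
}

#' Simulate low-coverage sequencing reads at marker sites
#'
#' Per segregant x site, sequencing depth is Poisson(`mean_coverage`);
#' each read supports the segregant's true parental allele with
#' probability `1 - error_rate` and the other parental allele otherwise.
#'
#' @param cross a [sim_cross()] result.
#' @param mean_coverage mean sequencing depth (>= 0); the study design
#'   this emulates used 3-6x, default 4.5.
#' @param error_rate per-read error probability in \[0, 1\].
#' @param seed integer seed.
#' @return Long data.frame (`segregant`, `chrom`, `pos`, `n_p1`, `n_p2`,
#'   `n_other`), one row per segregant x site.
#' @export
sim_reads <- function(cross, mean_coverage = 4.5, error_rate = 0.002,
                      seed = 1) {
  stopifnot(inherits(cross, "true_cross"),
            mean_coverage >= 0, error_rate >= 0, error_rate <= 1)
  set.seed(substream_seed(seed, "reads"))
  H <- cross$haplotypes
  n <- nrow(H); m <- ncol(H)
  hap <- as.vector(t(H))                       # segregant-major
  depth <- rpois(n * m, mean_coverage)
  n_true <- rbinom(n * m, depth, 1 - error_rate)
  n_p1 <- ifelse(hap == 1L, n_true, depth - n_true)
  data.frame(segregant = rep(cross$segregants, each = m),
             chrom = rep(cross$markers$chrom, times = n),
             pos = rep(cross$markers$pos, times = n),
             n_p1 = n_p1,
             n_p2 = depth - n_p1,
             n_other = 0L,
             stringsAsFactors = FALSE)
}
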