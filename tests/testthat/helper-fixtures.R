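# Small genomes and crosses used across tests, plus independent
# brute-force oracles kept separate from the implementation paths.

tiny_genome <- function(cm_per_kb = 0.4) {
  genome_model(data.frame(name = c("chrA", "chrB", "chrC"),
                          length_bp = c(400000, 300000, 200000)),
               cm_per_kb = cm_per_kb)
}

make_cross <- function(n_seg = 40, n_snps = 60, seed = 1,
                       genome = tiny_genome()) {
  p <- sim_parents(genome, n_snps, seed = seed)
  sim_cross(p, n_seg, genome, seed = seed)
}

# genotype matrix straight from true haplotypes (no sequencing layer)
gm_from_cross <- function(cross) {
  H <- cross$haplotypes
  n1 <- colSums(H == 1L); n2 <- colSums(H == 2L)
  gm <- list(geno = H,
             markers = data.frame(chrom = cross$markers$chrom,
                                  pos = cross$markers$pos,
                                  n_p1 = n1, n_p2 = n2,
                                  n_missing = 0L,
                                  chisq_p = pchisq((n1 - n2)^2 / (n1 + n2),
                                                   1, lower.tail = FALSE),
                                  filter = NA_character_,
                                  stringsAsFactors = FALSE),
             segregants = cross$segregants)
  class(gm) <- "genotype_matrix"
  gm
}

make_single_marker_gm <- function(groups) {
  n <- length(groups)
  geno <- matrix(groups, ncol = 1,
                 dimnames = list(sprintf("s%02d", seq_len(n)),
                                 "chr1:1000"))
  n1 <- sum(groups == 1L, na.rm = TRUE)
  n2 <- sum(groups == 2L, na.rm = TRUE)
  structure(list(
    geno = geno,
    markers = data.frame(chrom = "chr1", pos = 1000, n_p1 = n1,
                         n_p2 = n2, n_missing = n - n1 - n2,
                         chisq_p = NA_real_, filter = NA_character_,
                         stringsAsFactors = FALSE),
    segregants = rownames(geno)), class = "genotype_matrix")
}

# brute-force two-sided rank-sum p by full enumeration of group
# assignments (symmetric-count definition; valid for tie-free data)
enum_ranksum_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  r <- rank(c(x1, x2))
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  ws <- colSums(matrix(r[sets], nrow = n1))
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}

# explicit Duncan critical-range oracle for equal group sizes
duncan_crit <- function(p, df, mse, n, alpha = 0.05) {
  qtukey((1 - alpha)^(p - 1), p, df) * sqrt(mse / n)
}
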