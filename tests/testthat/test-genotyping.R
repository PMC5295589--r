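test_that("parental variant subtraction keeps only distinguishing sites", {
  p1 <- data.frame(chrom = "chr1", pos = c(100, 200), ref = c("A", "C"),
                   alt = c("G", "T"), stringsAsFactors = FALSE)
  p2 <- data.frame(chrom = "chr1", pos = c(200, 300), ref = c("C", "G"),
                   alt = c("T", "A"), stringsAsFactors = FALSE)
  out <- distinguishing_snps(p1, p2)
  expect_equal(out$pos, c(100, 300))           # shared site 200 dropped
  expect_equal(out$p1_allele, c("G", "G"))     # P1 variant / reference
  expect_equal(out$p2_allele, c("A", "A"))     # reference / P2 variant
  # identical lists leave nothing
  expect_equal(nrow(distinguishing_snps(p1, p1)), 0)
  # both parents variant with different alternates
  q1 <- data.frame(chrom = "chr2", pos = 50, ref = "A", alt = "G")
  q2 <- data.frame(chrom = "chr2", pos = 50, ref = "A", alt = "T")
  bi <- distinguishing_snps(q1, q2)
  expect_equal(bi$p1_allele, "G")
  expect_equal(bi$p2_allele, "T")
  # conflicting duplicate records are an error
  dup <- rbind(q1, data.frame(chrom = "chr2", pos = 50, ref = "A",
                              alt = "C"))
  expect_error(distinguishing_snps(dup, q2), "conflicting duplicate")
})

test_that("genotype calling applies the read-count rule cell by cell", {
  v <- data.frame(chrom = "chr1", pos = c(10, 20, 30), ref = "A",
                  p1_allele = "A", p2_allele = "C",
                  stringsAsFactors = FALSE)
  counts <- data.frame(
    segregant = "s1", chrom = "chr1", pos = c(10, 20, 30),
    n_p1 = c(4, 0, 2), n_p2 = c(0, 0, 1), stringsAsFactors = FALSE)
  gm <- call_genotypes(counts, v, min_reads = 1, max_conflict = 0)
  expect_equal(unname(gm$geno["s1", ]), c(1L, NA, NA))
  # relaxing the conflict tolerance turns the 2/1 cell into a call
  gm2 <- call_genotypes(counts, v, min_reads = 1, max_conflict = 1)
  expect_equal(unname(gm2$geno["s1", 3]), 1L)
  # counts at unknown sites are ignored with a warning
  counts$pos[2] <- 999
  expect_warning(call_genotypes(counts, v), "ignored")
})

test_that("marker filters flag distortion and sparsity as specified", {
  # 58:59 -> chi2 = 0.0085, p ~ 0.93 (pass); 90:27 -> chi2 ~ 33.9 (distorted)
  geno <- cbind(rep(c(1L, 2L), c(58, 59)), rep(c(1L, 2L), c(90, 27)),
                c(rep(c(1L, 2L), c(20, 20)), rep(NA, 77)))
  rownames(geno) <- sprintf("s%03d", 1:117)
  colnames(geno) <- c("chr1:1000", "chr1:20000", "chr1:40000")
  n1 <- colSums(geno == 1L, na.rm = TRUE)
  n2 <- colSums(geno == 2L, na.rm = TRUE)
  gm <- structure(list(
    geno = geno,
    markers = data.frame(chrom = "chr1", pos = c(1000, 20000, 40000),
                         n_p1 = n1, n_p2 = n2,
                         n_missing = 117 - n1 - n2,
                         chisq_p = pchisq((n1 - n2)^2 / (n1 + n2), 1,
                                          lower.tail = FALSE),
                         filter = NA_character_,
                         stringsAsFactors = FALSE),
    segregants = rownames(geno)), class = "genotype_matrix")
  expect_equal(round((58 - 59)^2 / 117, 4), 0.0085)
  expect_equal(gm$markers$chisq_p[1], 0.926, tolerance = 1e-3)
  expect_equal(gm$markers$chisq_p[2], 5.8e-9, tolerance = 0.02)
  out <- build_marker_map(gm)
  expect_equal(out$markers$filter, c("pass", "distorted", "sparse"))
})

test_that("thinning keeps one well-genotyped marker per spacing window", {
  set.seed(1)
  n <- 40
  pos <- c(2000, 9000, 14000, 16000, 150000)
  geno <- matrix(rep(rep(c(1L, 2L), n / 2), length(pos)), nrow = n)
  geno[1:6, 1] <- NA     # first window: marker 2 has fewer missing
  rownames(geno) <- sprintf("s%02d", 1:n)
  colnames(geno) <- paste0("chr1:", pos)
  n1 <- colSums(geno == 1L, na.rm = TRUE)
  n2 <- colSums(geno == 2L, na.rm = TRUE)
  gm <- structure(list(
    geno = geno,
    markers = data.frame(chrom = "chr1", pos = pos, n_p1 = n1, n_p2 = n2,
                         n_missing = n - n1 - n2,
                         chisq_p = pchisq((n1 - n2)^2 / (n1 + n2), 1,
                                          lower.tail = FALSE),
                         filter = NA_character_,
                         stringsAsFactors = FALSE),
    segregants = rownames(geno)), class = "genotype_matrix")
  out <- build_marker_map(gm, spacing_kb = 15)
  # windows [1,15001) and [15001,30001): fewest-missing marker wins,
  # ties go to the leftmost
  expect_equal(out$markers$filter,
               c("thinned", "pass", "thinned", "pass", "pass"))
  # a chromosome with any candidate marker keeps at least one
  expect_true(any(out$markers$filter == "pass"))
})

test_that("an all-filtered map is an error with diagnostics", {
  geno <- matrix(rep(1L, 40), ncol = 2,
                 dimnames = list(sprintf("s%02d", 1:20),
                                 c("chr1:100", "chr1:200")))
  gm <- structure(list(
    geno = geno,
    markers = data.frame(chrom = "chr1", pos = c(100, 200),
                         n_p1 = c(20L, 20L), n_p2 = c(0L, 0L),
                         n_missing = c(0L, 0L),
                         chisq_p = pchisq(20, 1, lower.tail = FALSE),
                         filter = NA_character_,
                         stringsAsFactors = FALSE),
    segregants = rownames(geno)), class = "genotype_matrix")
  expect_error(build_marker_map(gm), "all markers filtered")
})

test_that("zero-error calls reproduce true haplotypes exactly", {
  cr <- make_cross(n_seg = 25, n_snps = 80, seed = 12)
  rd <- sim_reads(cr, mean_coverage = 4.5, error_rate = 0, seed = 12)
  gm <- call_genotypes(rd, cr$parents)
  called <- !is.na(gm$geno)
  expect_true(all(gm$geno[called] == cr$haplotypes[called]))
})
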