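test_that("the scan reproduces the exact rank-sum worked example", {
  gm <- make_single_marker_gm(rep(c(1L, 2L), each = 3))
  y <- c(1, 2, 3, 4, 5, 6)
  prof <- wilcoxon_scan(gm, y, min_group = 2, method = "exact")
  expect_equal(prof$lk, 1.0)      # p = 2/20 = 0.1
  expect_equal(enum_ranksum_p(y[1:3], y[4:6]), 0.1)
})

test_that("approximate and exact p-values agree for all small group sizes", {
  set.seed(21)
  for (m in 2:8) for (n in m:8) {
    y <- sample(seq_len(m + n))  # tie-free
    g <- rep(c(1L, 2L), c(m, n))
    gm <- make_single_marker_gm(g)
    p_enum <- enum_ranksum_p(y[g == 1L], y[g == 2L])
    lk_ex <- wilcoxon_scan(gm, y, min_group = 2, method = "exact")$lk
    lk_ap <- wilcoxon_scan(gm, y, min_group = 2, method = "approx")$lk
    expect_equal(lk_ex, -log10(p_enum), tolerance = 1e-12)
    expect_lt(abs(lk_ap - (-log10(p_enum))), 0.15)
  }
})

test_that("degenerate and under-sized markers are handled as specified", {
  gm <- make_single_marker_gm(rep(c(1L, 2L), each = 10))
  expect_warning(prof <- wilcoxon_scan(gm, rep(1, 20), min_group = 3),
                 "constant trait")
  expect_equal(prof$lk, 0)
  # identical group value multisets -> p = 1, LK = 0
  y2 <- rep(rep(c(5, 7), 5), 2)
  prof2 <- wilcoxon_scan(gm, y2, min_group = 3)
  expect_equal(prof2$lk, 0)
  # group below min_group -> undefined LK, not zero
  gm3 <- make_single_marker_gm(rep(c(1L, 2L), c(17, 3)))
  prof3 <- wilcoxon_scan(gm3, rnorm(20), min_group = 10)
  expect_true(is.na(prof3$lk))
})

test_that("LK is invariant under strictly monotone trait transforms", {
  cr <- make_cross(n_seg = 50, n_snps = 60, seed = 31)
  gm <- gm_from_cross(cr)
  set.seed(31)
  y <- rnorm(50) + (cr$haplotypes[, 10] == 2L)
  p1 <- wilcoxon_scan(gm, y)
  p2 <- wilcoxon_scan(gm, exp(y))
  expect_equal(p1$lk, p2$lk, tolerance = 1e-12)
})

test_that("permutation thresholds are deterministic and monotone in alpha", {
  cr <- make_cross(n_seg = 40, n_snps = 50, seed = 32)
  gm <- gm_from_cross(cr)
  set.seed(99); y <- rnorm(40)
  n1 <- permutation_threshold(gm, y, n_perm = 100, seed = 5)
  n2 <- permutation_threshold(gm, y, n_perm = 100, seed = 5)
  expect_identical(n1$max_lk, n2$max_lk)
  thr01 <- quantile(n1$max_lk, 0.99, type = 7)
  expect_gte(thr01, n1$threshold)
})

test_that("phenotype and genotype permutations give matching null scans", {
  cr <- make_cross(n_seg = 60, n_snps = 50, seed = 33)
  gm <- gm_from_cross(cr)
  set.seed(12); y <- rnorm(60)
  null_pheno <- permutation_threshold(gm, y, n_perm = 150, seed = 7)
  set.seed(8)
  max_geno <- vapply(1:150, function(i) {
    gmi <- gm
    gmi$geno <- gm$geno[sample(60), , drop = FALSE]
    max(wilcoxon_scan(gmi, y, method = "approx")$lk, na.rm = TRUE)
  }, numeric(1))
  ks <- suppressWarnings(ks.test(null_pheno$max_lk, max_geno))
  expect_gt(ks$p.value, 0.01)
})

test_that("QTL calling finds peaks, intervals and beneficial parents", {
  profile <- structure(
    data.frame(chrom = rep(c("chr1", "chr2"), each = 10),
               pos = rep(seq(5000, 95000, by = 10000), 2),
               lk = c(0.2, 0.5, 1.2, 3.0, 4.8, 4.1, 2.9, 0.8, 0.3, 0.2,
                      0.1, 0.2, 0.4, 0.9, 1.1, 4.4, 1.0, 0.5, 0.2, 0.1),
               n_p1 = 20, n_p2 = 20),
    class = c("linkage_profile", "data.frame"))
  attr(profile, "trait_name") <- "t2"
  calls <- call_qtl(profile, 3.5, drop = 1.0)
  expect_equal(nrow(calls), 2)       # one peak per chromosome
  expect_equal(calls$chrom, c("chr1", "chr2"))
  expect_equal(calls$peak_pos[1], 45000)
  # interval contains the peak and respects the 1-LK drop rule
  expect_true(calls$start[1] <= 45000 && calls$end[1] >= 45000)
  # contiguous flanking markers with lk >= 4.8 - 1: only 45000, 55000
  expect_equal(calls$start[1], 45000)
  expect_equal(calls$end[1], 55000)
  # nothing above threshold -> empty
  expect_equal(nrow(call_qtl(profile, 10)), 0)
})

test_that("beneficial parent follows trait direction at the peak", {
  g <- rep(c(1L, 2L), each = 10)
  gm <- make_single_marker_gm(g)
  y <- c(rnorm(10, 10), rnorm(10, 0))   # P2 group has lower values
  profile <- structure(
    data.frame(chrom = "chr1", pos = 1000, lk = 5, n_p1 = 10, n_p2 = 10),
    class = c("linkage_profile", "data.frame"))
  attr(profile, "trait_name") <- "t5"
  calls <- call_qtl(profile, 3, gm = gm, trait = y,
                    higher_is_better = FALSE)
  expect_equal(calls$beneficial, "P2")
  calls2 <- call_qtl(profile, 3, gm = gm, trait = y,
                     higher_is_better = TRUE)
  expect_equal(calls2$beneficial, "P1")
})

test_that("candidate genes require interval overlap and a ns-SNP flag", {
  qtl <- data.frame(chrom = "chrVII", start = 544000, end = 594000)
  ann <- data.frame(gene_id = c("PMA1", "MSB2", "FAR"),
                    chrom = c("chrVII", "chrVII", "chrVII"),
                    start = c(560000, 590000, 700000),
                    end = c(562000, 596000, 702000),
                    stringsAsFactors = FALSE)
  flags <- data.frame(gene_id = c("PMA1", "MSB2", "FAR"),
                      has_ns_snp = c(TRUE, FALSE, TRUE))
  expect_equal(candidate_genes(qtl, ann, flags), "PMA1")
  flags$has_ns_snp[2] <- TRUE
  expect_equal(candidate_genes(qtl, ann, flags), c("PMA1", "MSB2"))
  expect_equal(candidate_genes(qtl, ann[0, ], flags), character())
})
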