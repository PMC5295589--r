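format_num <- function(df, digits = 6) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- signif(df[[j]], digits)
  df
}

config_hash <- function(x) {
  # parameters only: output locations and input paths do not change
  # the scientific configuration
  x <- x[setdiff(sort(names(x)),
                 c("outdir", "stages", "curves_file", "counts_file",
                   "variants_file", "genotypes_file", "traits_file"))]
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 0xFFFFFFF)
}

provenance <- function(seed = NULL, cfg = NULL) {
  c(sprintf("# sparkqtl %s",
            as.character(utils::packageVersion("sparkqtl"))),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    if (!is.null(cfg)) sprintf("# config: %s", config_hash(cfg)))
}

#' Write a table with a provenance header
#'
#' Tab-separated with `#`-prefixed header lines recording package
#' version, seed and configuration hash; numeric columns are written
#' with 6 significant digits.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param seed,cfg optional provenance fields.
#' @param sep field separator (default tab).
#' @export
write_stage_table <- function(df, path, seed = NULL, cfg = NULL,
                              sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance(seed, cfg), con)
  utils::write.table(format_num(as.data.frame(df)), con, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_stage_table()]
#' @param path file path.
#' @param sep field separator.
#' @export
read_stage_table <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write parental variants as a two-sample VCF
#'
#' Minimal VCFv4.2 with the two homozygous parents as sample columns
#' (GT only). REF is the table's reference allele; ALT collects the
#' non-reference parental alleles.
#'
#' @param variants distinguishing-SNP table (`chrom`, `pos`, `ref`,
#'   `p1_allele`, `p2_allele`).
#' @param path output path.
#' @param sample_names the two sample column names.
#' @export
write_parent_vcf <- function(variants, path,
                             sample_names = c("P1", "P2")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sparkqtl",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sample_names),
                     collapse = "\t")), con)
  for (i in seq_len(nrow(variants))) {
    ref <- variants$ref[i]
    alleles <- c(variants$p1_allele[i], variants$p2_allele[i])
    alt <- unique(setdiff(alleles, ref))
    gt <- match(alleles, c(ref, alt)) - 1L
    writeLines(paste(variants$chrom[i], variants$pos[i], ".", ref,
                     paste(alt, collapse = ","), ".", "PASS", ".",
                     "GT", paste0(gt[1], "/", gt[1]),
                     paste0(gt[2], "/", gt[2]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read parental variants from a two-sample VCF
#'
#' Uses vcfR when available. Only biallelic-per-parent SNP records with
#' homozygous genotypes in both samples are used; rows where the two
#' parents carry the same allele are dropped.
#'
#' @param path VCF path.
#' @param samples the two sample columns (defaults to the first two).
#' @return distinguishing-SNP table (`chrom`, `pos`, `ref`,
#'   `p1_allele`, `p2_allele`).
#' @export
read_parent_vcf <- function(path, samples = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(samples)) samples <- colnames(gt)[1:2]
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  allele_of <- function(code, ref, alt) {
    a <- sub("[/|].*", "", code)
    alts <- strsplit(alt, ",", fixed = TRUE)
    hom <- !grepl("[/|]", code) |
      a == sub(".*[/|]", "", code)
    idx <- suppressWarnings(as.integer(a))
    out <- ifelse(idx == 0, ref,
                  mapply(function(al, i) if (i >= 1 && i <= length(al))
                    al[i] else NA_character_, alts, idx))
    out[!hom] <- NA_character_
    out
  }
  p1 <- allele_of(gt[, samples[1]], fix$REF, fix$ALT)
  p2 <- allele_of(gt[, samples[2]], fix$REF, fix$ALT)
  keep <- !is.na(p1) & !is.na(p2) & p1 != p2
  data.frame(chrom = fix$CHROM[keep],
             pos = as.integer(fix$POS[keep]),
             ref = fix$REF[keep], p1_allele = p1[keep],
             p2_allele = p2[keep], stringsAsFactors = FALSE)
}

#' Write a genotype matrix as TSV
#'
#' Rows are segregants, columns are `chrom:pos` markers, cells are
#' P1/P2/NA; marker metadata (counts, chi-square p, filter status) is
#' written alongside.
#'
#' @param gm a `genotype_matrix`.
#' @param path genotype TSV path.
#' @param meta_path marker metadata TSV path (default: path +
#'   ".markers").
#' @param ... passed to [write_stage_table()].
#' @export
write_genotypes_tsv <- function(gm, path,
                                meta_path = paste0(path, ".markers"),
                                ...) {
  lab <- matrix(c("P1", "P2")[gm$geno], nrow = nrow(gm$geno),
                dimnames = dimnames(gm$geno))
  df <- data.frame(segregant = rownames(lab), lab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_stage_table(df, path, ...)
  write_stage_table(gm$markers, meta_path, ...)
  invisible(path)
}

#' Read a genotype matrix written by [write_genotypes_tsv()]
#' @param path genotype TSV path.
#' @param meta_path marker metadata TSV path.
#' @return a `genotype_matrix`.
#' @export
read_genotypes_tsv <- function(path,
                               meta_path = paste0(path, ".markers")) {
  df <- read_stage_table(path)
  segs <- df$segregant
  lab <- as.matrix(df[, -1, drop = FALSE])
  geno <- matrix(match(lab, c("P1", "P2")), nrow = nrow(lab),
                 dimnames = list(segs, colnames(lab)))
  mk <- read_stage_table(meta_path)
  if (!"filter" %in% names(mk)) mk$filter <- NA_character_
  mk$filter <- as.character(mk$filter)
  gm <- list(geno = geno, markers = mk, segregants = segs)
  class(gm) <- "genotype_matrix"
  if (any(!is.na(mk$filter) & mk$filter == "pass"))
    gm$pass <- which(mk$filter == "pass")
  gm
}

#' Validate pipeline input files
#'
#' Per-file format checks (column presence, types, coordinate and
#' monotonicity sanity) reporting the line number of the first
#' violation; unreadable files produce a fail entry rather than an
#' error.
#'
#' @param paths character vector of file paths.
#' @param formats formats per file: `"curves"`, `"counts"`,
#'   `"variants"` or `"genotypes"`; guessed from the header when
#'   missing.
#' @return data.frame (`file`, `format`, `ok`, `message`).
#' @export
validate_inputs <- function(paths, formats = NULL) {
  if (is.null(formats)) formats <- rep(NA_character_, length(paths))
  rows <- mapply(function(p, fmt) {
    res <- tryCatch(validate_one(p, fmt), error = function(e)
      list(format = fmt, ok = FALSE, message = conditionMessage(e)))
    data.frame(file = p, format = res$format %||% NA_character_,
               ok = res$ok, message = res$message,
               stringsAsFactors = FALSE)
  }, paths, formats, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 ||
                             (length(a) == 1 && is.na(a))) b else a

validate_one <- function(path, fmt = NA_character_) {
  if (!file.exists(path)) return(list(format = fmt, ok = FALSE,
                                      message = "file not found"))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                   comment.char = "#",
                                   stringsAsFactors = FALSE,
                                   check.names = FALSE),
                 error = function(e) NULL)
  if (is.null(df)) return(list(format = fmt, ok = FALSE,
                               message = "unreadable file"))
  # data line numbers: header + comment lines precede row 1
  first <- length(grep("^#", readLines(path, n = 50))) + 2L
  if (is.na(fmt)) {
    nm <- names(df)
    fmt <- if (all(c("time_days", "pressure_bar") %in% nm)) "curves"
    else if (all(c("n_p1", "n_p2") %in% nm)) "counts"
    else if (all(c("p1_allele", "p2_allele") %in% nm)) "variants"
    else if ("segregant" %in% nm) "genotypes"
    else return(list(format = NA_character_, ok = FALSE,
                     message = "unrecognised format"))
  }
  fail <- function(msg, row = NULL)
    list(format = fmt, ok = FALSE,
         message = if (is.null(row)) msg
                   else sprintf("%s (line %d)", msg, first + row - 1L))
  need <- switch(fmt,
    curves = c("strain", "replicate", "time_days", "pressure_bar",
               "temperature_C"),
    counts = c("segregant", "chrom", "pos", "n_p1", "n_p2"),
    variants = c("chrom", "pos", "ref", "p1_allele", "p2_allele"),
    genotypes = "segregant")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(fail(paste("missing column(s):", paste(miss, collapse = ", "))))
  if (fmt == "curves") {
    if (any(bad <- !is.finite(df$time_days) | df$time_days < 0))
      return(fail("negative or non-numeric time", which(bad)[1]))
    if (any(bad <- !is.finite(df$pressure_bar) | df$pressure_bar < 0))
      return(fail("negative or non-numeric pressure", which(bad)[1]))
    key <- paste(df$strain, df$replicate)
    for (g in split(seq_len(nrow(df)), key)) {
      tt <- df$time_days[g]
      if (is.unsorted(tt, strictly = TRUE)) {
        r <- g[which(diff(tt) <= 0)[1] + 1L]
        return(fail("non-increasing times within a replicate", r))
      }
    }
  } else if (fmt == "counts") {
    if (any(bad <- df$n_p1 < 0 | df$n_p2 < 0))
      return(fail("negative read count", which(bad)[1]))
    if (any(bad <- df$pos < 1))
      return(fail("non-positive position", which(bad)[1]))
  } else if (fmt == "variants") {
    if (any(bad <- df$p1_allele == df$p2_allele))
      return(fail("identical parental alleles", which(bad)[1]))
    if (anyDuplicated(k <- paste(df$chrom, df$pos)))
      return(fail("duplicated site", which(duplicated(k))[1]))
  } else if (fmt == "genotypes") {
    vals <- unlist(df[-1], use.names = FALSE)
    if (any(bad <- !(is.na(vals) | vals %in% c("P1", "P2", "NA"))))
      return(fail("genotype cells must be P1/P2/NA"))
  }
  list(format = fmt, ok = TRUE, message = "ok")
}
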