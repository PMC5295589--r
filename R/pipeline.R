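#' Default pipeline configuration
#'
#' Flat list of every stage parameter: the synthetic-cross design
#' (117 segregants, 1071 markers on a 12 Mb / 16-chromosome genome,
#' 4.5x coverage with 0.2% read error), kinetic-fit settings
#' (reference 10 deg C, van 't Hoff 2400 K, thresholds 0.5/2/5 bar),
#' marker-map filters (alpha 0.05, <= 50% missing, 15 kb spacing) and
#' scan settings (1000 permutations, alpha 0.05, minimum group 10).
#'
#' @param ... overrides merged over the defaults.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = "sparkqtl-run",
    stages = c("simulate", "kinetics", "genotype", "map", "scan",
               "stats"),
    n_segregants = 117L, n_snps = 1071L,
    cm_per_kb = 0.4, coverage = 4.5, error_rate = 0.002,
    t_ref_c = 10, vant_hoff_K = 2400, thresholds = c(0.5, 2, 5),
    min_reads = 1L, max_conflict = 0L,
    alpha = 0.05, max_missing_frac = 0.5, spacing_kb = 15,
    n_perm = 1000L, min_group = 10L, drop = 1.0,
    scan_traits = c("rate", "t2", "t5"),
    k_transgression = 2.0,
    curves_file = NULL, counts_file = NULL, variants_file = NULL,
    genotypes_file = NULL, traits_file = NULL)
  utils::modifyList(cfg, list(...))
}

validate_config <- function(cfg) {
  req_num <- c("coverage", "error_rate", "alpha", "n_perm", "min_group",
               "spacing_kb", "max_missing_frac")
  for (f in req_num)
    if (is.null(cfg[[f]]) || !is.numeric(cfg[[f]]))
      stop("config field '", f, "' missing or non-numeric")
  if ("simulate" %in% cfg$stages && is.null(cfg$seed))
    stop("config field 'seed' is required when simulation is enabled")
  if (!("simulate" %in% cfg$stages)) {
    if ("kinetics" %in% cfg$stages && is.null(cfg$curves_file))
      stop("config field 'curves_file' required when stage 'kinetics' ",
           "runs without 'simulate'")
    if ("genotype" %in% cfg$stages &&
        (is.null(cfg$counts_file) || is.null(cfg$variants_file)))
      stop("config fields 'counts_file'/'variants_file' required when ",
           "stage 'genotype' runs without 'simulate'")
  }
  for (f in c("curves_file", "counts_file", "variants_file",
              "genotypes_file"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config field '", f, "' points to a missing file: ", cfg[[f]])
  invisible(cfg)
}

#' Run the full mapping pipeline
#'
#' Executes the enabled stages in order
#' simulate -> kinetics -> genotype -> map -> scan -> stats, writing
#' each stage's outputs (with provenance headers) under
#' `cfg$outdir` and logging per-stage counts. Disabled stages read
#' their inputs from the configured files or from earlier on-disk
#' outputs, so single stages can be re-run from intermediates.
#'
#' @param cfg a [pipeline_config()] list or the path to a JSON file
#'   with the same fields.
#' @param quiet suppress progress messages.
#' @return Invisible list with the in-memory stage results: `cross`,
#'   `phenotypes`, `traits`, `gm`, `scans`, `qtl`, `report`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  if (is.character(cfg)) {
    cfg <- utils::modifyList(pipeline_config(),
                             jsonlite::read_json(cfg, simplifyVector = TRUE))
  }
  # earlier on-disk stage outputs serve as default inputs, so single
  # stages can be re-run from intermediates
  for (fd in list(c("curves_file", "curves.csv"),
                  c("counts_file", "allele_counts.tsv"),
                  c("variants_file", "parents.tsv"),
                  c("genotypes_file", "genotypes.tsv"),
                  c("traits_file", "traits.tsv"))) {
    f <- file.path(cfg$outdir, fd[2])
    if (is.null(cfg[[fd[1]]]) && file.exists(f)) cfg[[fd[1]]] <- f
  }
  validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$outdir, "run.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", "sparkqtl", sprintf(...))
    if (!quiet) message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  cat(provenance(cfg$seed, cfg), sep = "\n", file = logfile)
  res <- list()
  out <- function(name) file.path(cfg$outdir, name)
  stage <- function(s) s %in% cfg$stages

  if (stage("simulate")) {
    genome <- default_genome(cm_per_kb = cfg$cm_per_kb)
    arch <- default_architecture(genome)
    parents <- sim_parents(genome, cfg$n_snps, seed = cfg$seed)
    res$cross <- sim_cross(parents, cfg$n_segregants, genome,
                           seed = cfg$seed)
    reads <- sim_reads(res$cross, cfg$coverage, cfg$error_rate,
                       seed = cfg$seed)
    res$phenotypes <- sim_phenotypes(res$cross, arch, seed = cfg$seed)
    write_stage_table(parents, out("parents.tsv"), cfg$seed, cfg)
    write_parent_vcf(parents, out("parents.vcf"))
    write_stage_table(reads, out("allele_counts.tsv"), cfg$seed, cfg)
    write_stage_table(res$phenotypes$curves, out("curves.csv"),
                      cfg$seed, cfg, sep = ",")
    truth <- list(locus_markers = attr(res$phenotypes$targets,
                                       "locus_markers"),
                  bottle_traits = res$phenotypes$truth)
    jsonlite::write_json(truth, out("ground_truth.json"),
                         dataframe = "rows", digits = NA)
    logmsg("simulate: %d segregants, %d markers, %d curve rows",
           cfg$n_segregants, nrow(parents), nrow(res$phenotypes$curves))
    cfg$curves_file <- out("curves.csv")
    cfg$counts_file <- out("allele_counts.tsv")
    cfg$variants_file <- out("parents.tsv")
  }

  if (stage("kinetics")) {
    curves <- read_stage_table(cfg$curves_file, sep = ",")
    fk <- fit_kinetics(curves, cfg$t_ref_c, cfg$vant_hoff_K,
                       cfg$thresholds)
    res$traits <- fk$traits
    write_stage_table(fk$traits, out("traits.tsv"), cfg$seed, cfg)
    pars <- lapply(fk$fits, function(f)
      list(par = as.list(f$par), residual_sd = f$residual_sd,
           converged = f$converged, n = f$n))
    jsonlite::write_json(pars, out("fit_parameters.json"),
                         auto_unbox = TRUE, digits = NA)
    logmsg("kinetics: %d/%d fits converged", sum(fk$traits$converged),
           nrow(fk$traits))
  }

  if (stage("genotype")) {
    counts <- read_stage_table(cfg$counts_file)
    variants <- read_stage_table(cfg$variants_file)
    res$gm <- call_genotypes(counts, variants, cfg$min_reads,
                             cfg$max_conflict)
    logmsg("genotype: %d segregants x %d markers called",
           nrow(res$gm$geno), ncol(res$gm$geno))
  } else if (!is.null(cfg$genotypes_file)) {
    res$gm <- read_genotypes_tsv(cfg$genotypes_file)
  }

  if (stage("map")) {
    if (is.null(res$gm)) stop("stage 'map' needs output of 'genotype'")
    res$gm <- build_marker_map(res$gm, cfg$alpha, cfg$max_missing_frac,
                               cfg$spacing_kb)
    write_genotypes_tsv(res$gm, out("genotypes.tsv"), seed = cfg$seed,
                        cfg = cfg)
    logmsg("map: %d pass markers of %d", length(res$gm$pass),
           ncol(res$gm$geno))
  }

  # allow single-stage re-runs from on-disk intermediates
  recover_traits <- function() {
    f <- cfg$traits_file %||% out("traits.tsv")
    if (is.null(res$traits) && file.exists(f))
      res$traits <<- read_stage_table(f)
  }
  recover_gm <- function() {
    f <- cfg$genotypes_file %||% out("genotypes.tsv")
    if (is.null(res$gm) && file.exists(f))
      res$gm <<- read_genotypes_tsv(f)
  }

  if (stage("scan")) {
    recover_gm(); recover_traits()
    if (is.null(res$gm)) stop("stage 'scan' needs output of 'map'")
    if (is.null(res$traits)) stop("stage 'scan' needs output of 'kinetics'")
    seg <- res$traits[res$traits$strain %in% res$gm$segregants, ]
    res$scans <- list(); res$qtl <- list()
    for (tr in cfg$scan_traits) {
      y <- setNames(seg[[tr]], seg$strain)
      attr(y, "trait_name") <- tr
      prof <- wilcoxon_scan(res$gm, y, cfg$min_group)
      null <- permutation_threshold(res$gm, y, cfg$n_perm, cfg$alpha,
                                    seed = cfg$seed + match(tr, cfg$scan_traits),
                                    min_group = cfg$min_group)
      calls <- call_qtl(prof, null, cfg$drop, gm = res$gm, trait = y,
                        higher_is_better = trait_higher_is_better(tr))
      res$scans[[tr]] <- prof
      res$qtl[[tr]] <- calls
      write_stage_table(prof, out(sprintf("scan_%s.tsv", tr)),
                        cfg$seed, cfg)
      write_stage_table(data.frame(max_lk = null$max_lk),
                        out(sprintf("null_%s.tsv", tr)), cfg$seed, cfg)
      logmsg("scan %s: threshold %.2f, %d QTL called", tr,
             null$threshold, nrow(calls))
    }
    qtl_all <- do.call(rbind, res$qtl)
    jsonlite::write_json(qtl_all, out("qtl_calls.json"),
                         dataframe = "rows", digits = NA)
  }

  if (stage("stats")) {
    recover_traits()
    if (is.null(res$traits)) stop("stage 'stats' needs output of 'kinetics'")
    seg <- res$traits[grepl("^seg", res$traits$strain), ]
    par_tr <- res$traits[res$traits$strain %in%
                           c("P1", "P2", "hybrid"), ]
    if (nrow(par_tr) == 0) {
      logmsg("stats: no parental curves available, report skipped")
    } else {
      drop_cols <- c("replicate", "converged")
      res$report <- genetics_report(
        seg[setdiff(names(seg), drop_cols)], par_tr,
        k = cfg$k_transgression)
      write_stage_table(res$report, out("report.tsv"), cfg$seed, cfg)
      jsonlite::write_json(res$report, out("report.json"),
                           dataframe = "rows", digits = NA)
      logmsg("stats: report for %d traits", nrow(res$report))
    }
  }
  invisible(res)
}
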