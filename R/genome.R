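#' Genome model for the synthetic cross
#'
#' Describes the chromosomes and genetic-map density used by the
#' synthetic-cross generator. The default emulates a 16-chromosome
#' yeast-like genome of 12 Mb with a uniform map density of 0.4 cM/kb,
#' so that ~1071 markers give one marker every ~11 kb.
#'
#' @param chromosomes data.frame with columns `name` (unique character)
#'   and `length_bp` (positive integer).
#' @param cm_per_kb genetic-map density in centimorgan per kilobase
#'   (non-negative). 0 disables recombination.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, cm_per_kb = 0.4) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$name))
    stop("chromosome names must be unique")
  if (any(chromosomes$length_bp <= 0))
    stop("chromosome lengths must be positive")
  if (!is.numeric(cm_per_kb) || length(cm_per_kb) != 1L || cm_per_kb < 0)
    stop("cm_per_kb must be a single non-negative number")
  g <- list(chromosomes = data.frame(name = as.character(chromosomes$name),
                                     length_bp = as.numeric(chromosomes$length_bp),
                                     stringsAsFactors = FALSE),
            cm_per_kb = cm_per_kb)
  class(g) <- "genome_model"
  g
}

#' Default 16-chromosome genome (12 Mb total, 0.4 cM/kb)
#'
#' Chromosome lengths are the S. cerevisiae karyotype proportions scaled
#' to a 12 Mb total; names use the Roman-numeral convention.
#'
#' @param cm_per_kb map density, default 0.4 cM/kb.
#' @return A `genome_model`.
#' @export
default_genome <- function(cm_per_kb = 0.4) {
  kb <- c(230, 813, 316, 1532, 577, 270, 1091, 563,
          440, 745, 666, 1078, 924, 784, 1091, 948)
  len <- round(kb / sum(kb) * 12e6)
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
             "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI")
  genome_model(data.frame(name = paste0("chr", roman), length_bp = len,
                          stringsAsFactors = FALSE),
               cm_per_kb = cm_per_kb)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %.3g Mb total, %.2f cM/kb\n",
              nrow(x$chromosomes), sum(x$chromosomes$length_bp) / 1e6,
              x$cm_per_kb))
  invisible(x)
}

#' QTL architecture for the synthetic cross
#'
#' Each locus has a chromosome, a position, the trait it acts on, and a
#' signed additive effect `a` in trait units: a segregant inheriting the
#' P2 allele gets `+a` on that trait and a P1 inheritor gets `-a`, so the
#' between-group mean difference is `2a` and the genetic variance
#' contributed at allele frequency 1/2 is `a^2`. An optional linked block
#' models several tightly linked loci on one chromosome with alternating
#' beneficial parents (pseudo-overdominance).
#'
#' @param loci data.frame with columns `chrom`, `pos_bp`, `trait`,
#'   `effect` (signed, trait units).
#' @param baseline named numeric vector of trait baselines.
#' @param noise_sd named numeric vector of per-trait biological noise SD
#'   among segregants (trait units, >= 0).
#' @param replicate_sd observation noise SD added to sampled pressure
#'   curves (bar, >= 0).
#' @param linked_block optional data.frame with the same columns as
#'   `loci`; its rows are additional loci on a single chromosome whose
#'   effect signs should alternate.
#' @param genome `genome_model` the loci must lie on (checked).
#' @return Object of class `qtl_architecture`.
#' @export
qtl_architecture <- function(loci, baseline, noise_sd, replicate_sd = 0.05,
                             linked_block = NULL, genome = default_genome()) {
  need <- c("chrom", "pos_bp", "trait", "effect")
  stopifnot(is.data.frame(loci), all(need %in% names(loci)))
  if (!is.null(linked_block)) {
    stopifnot(is.data.frame(linked_block), all(need %in% names(linked_block)))
    if (length(unique(linked_block$chrom)) != 1L)
      stop("linked_block loci must lie on a single chromosome")
    if (nrow(linked_block) < 2L)
      stop("linked_block needs at least 2 loci")
  }
  all_loci <- rbind(loci[need], if (!is.null(linked_block)) linked_block[need])
  chr <- genome$chromosomes
  m <- match(all_loci$chrom, chr$name)
  if (anyNA(m)) stop("locus chromosome not in genome: ",
                     paste(unique(all_loci$chrom[is.na(m)]), collapse = ", "))
  if (any(all_loci$pos_bp < 1 | all_loci$pos_bp > chr$length_bp[m]))
    stop("locus position outside its chromosome")
  if (any(!is.finite(all_loci$effect))) stop("effects must be finite")
  if (any(noise_sd < 0) || replicate_sd < 0) stop("noise SDs must be >= 0")
  traits <- unique(all_loci$trait)
  if (!all(traits %in% names(baseline)) || !all(traits %in% names(noise_sd)))
    stop("baseline and noise_sd must cover every trait with a locus")
  a <- list(loci = loci, linked_block = linked_block, baseline = baseline,
            noise_sd = noise_sd, replicate_sd = replicate_sd)
  class(a) <- "qtl_architecture"
  a
}

#' Default three-QTL architecture
#'
#' Three unlinked QTL, one per kinetic trait, with variance shares on
#' their traits of ~14% (t2, chrIV), ~24% (rate, chrVII) and ~49%
#' (t5, chrXVI) among segregants — the weakest locus on chrIV and the
#' major late-fermentation locus on chrXVI. Effects are derived from the
#' target share rho as `a = noise_sd * sqrt(rho/(1-rho))`. Signs follow
#' the beneficial-parent layout of the cross: P1 (GN-like) carries the
#' faster allele at the t2 and t5 loci, P2 (SB-like) at the rate locus.
#'
#' @param genome `genome_model` used for bounds checking.
#' @return A `qtl_architecture`.
#' @export
default_architecture <- function(genome = default_genome()) {
  noise <- c(Pmax = 0.08, rate = 0.04, t2 = 0.3, t5 = 0.65)
  base <- c(Pmax = 5.5, rate = 0.50, t2 = 7.0, t5 = 16.5)
  sh <- function(rho) sqrt(rho / (1 - rho))
  loci <- data.frame(
    chrom = c("chrIV", "chrVII", "chrXVI"),
    pos_bp = c(570000, 560000, 630000),
    trait = c("t2", "rate", "t5"),
    effect = c(+noise[["t2"]] * sh(0.14),     # P2 allele slows t2
               +noise[["rate"]] * sh(0.24),   # P2 allele speeds rate
               +noise[["t5"]] * sh(0.49)),    # P2 allele slows t5
    stringsAsFactors = FALSE)
  qtl_architecture(loci, baseline = base, noise_sd = noise,
                   replicate_sd = 0.05, genome = genome)
}

#' Linked three-gene block with alternating beneficial alleles
#'
#' A pseudo-overdominance block: three tightly linked loci on one
#' chromosome acting on the same trait with alternating beneficial
#' parents, emulating a proton-pump/regulator/osmosensor gene cluster in
#' repulsion phase. Intended to be passed as `linked_block` to
#' [qtl_architecture()].
#'
#' @param chrom chromosome name (default "chrVII").
#' @param pos_bp positions of the three loci (bp).
#' @param trait trait acted on (default "t2").
#' @param effects signed effects; defaults alternate sign so the
#'   beneficial allele alternates between parents.
#' @return data.frame usable as `linked_block`.
#' @export
linked_block_spec <- function(chrom = "chrVII",
                              pos_bp = c(544000, 560000, 594000),
                              trait = "t2",
                              effects = c(-0.15, -0.15, +0.15)) {
  stopifnot(length(pos_bp) == length(effects), length(pos_bp) >= 2)
  data.frame(chrom = chrom, pos_bp = pos_bp, trait = trait,
             effect = effects, stringsAsFactors = FALSE)
}

# Derive a reproducible substream seed from one master seed and a stage
# name, so cross/reads/phenotype stages are independently reproducible.
# Kept strictly below 2^31.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) + h * 10007) %% .Machine$integer.max)
}
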