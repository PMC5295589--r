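#' Published strain means for the GN x SB cross
#'
#' Second-fermentation kinetic trait means reported for the diploid
#' parental strains (GN, SB), their haploid derivatives (hoGN, hoSB)
#' and the diploid hybrid (HO-BN): `Pmax` (bar), `rate` (bar/day) and
#' the times to 0.5, 2 and 5 bar (days), pressures expressed at
#' 10 deg C. These are the inputs of the worked heterosis examples.
#'
#' @return data.frame with one row per strain.
#' @export
reference_strain_means <- function() {
  path <- system.file("extdata", "reference_strain_means.tsv",
                      package = "sparkqtl")
  read_stage_table(path)
}
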