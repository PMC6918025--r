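# Bundled reference data.

#' Published d-galUA candidate summary for R. toruloides IFO0880
#'
#' Curated mean FPKM (d-galUA, glycerol, d-glc) and gene fitness scores for
#' the seven R. toruloides genes specifically induced on d-galacturonic
#' acid and required for fitness on it: the MFS hexose transporter
#' RTO4_9841, the catabolic pathway enzymes (GAR1, GaaB, GaaC, GaaD
#' homologs), GAL7, and the ZnCys transcription factor RTO4_13270. Useful
#' as a worked example for the quadrant filter.
#'
#' Reference enzyme kinetics for the purified pathway enzymes are exposed
#' by [dgalua_enzyme_kinetics()].
#'
#' @return data.frame with columns `protein_id`, `name`, `description`,
#'   `fpkm_dgalua`, `fpkm_gly`, `fpkm_dglc`, `fitness_dgalua`,
#'   `fitness_gly`, `fitness_dglc`.
#' @export
dgalua_candidate_reference <- function() {
  path <- system.file("extdata", "rto4_dgalua_candidates.tsv",
                      package = "barseqfit", mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

#' Reported kinetic parameters of the d-galUA pathway enzymes
#'
#' Km (mM) and Vmax (nkat/mg) measured for the purified R. toruloides
#' enzymes: the d-galUA reductase RTO4_11882 (GAR1 homolog), the
#' l-galactonate dehydratase RTO4_12062 (GaaB), and the l-glyceraldehyde
#' reductase RTO4_9774 (GaaD).
#'
#' @return data.frame with columns `protein_id`, `enzyme`, `Km`, `Vmax`.
#' @export
dgalua_enzyme_kinetics <- function() {
  data.frame(
    protein_id = c("RTO4_11882", "RTO4_12062", "RTO4_9774"),
    enzyme = c("d-galUA reductase", "l-galactonate dehydratase",
               "l-glyceraldehyde reductase"),
    Km = c(7, 5.8, 0.9),
    Vmax = c(553, 2939, 535),
    stringsAsFactors = FALSE)
}
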