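# Packaged reference data.

#' Published REACTOME over-representation results for the molar proteome
#'
#' The significantly enriched Mus musculus REACTOME pathways reported for
#' the 120-protein differentially expressed set of the low-dietary-protein
#' molar proteome experiment: pathway identifier and name, number of query
#' proteins found in the pathway, pathway size, the printed 4-decimal
#' entity ratio (pathway size over organism-wide background) and the
#' printed entities p-value. The organism-wide background size is not part
#' of the published table; [infer_background()] recovers it from the
#' (size, ratio) pairs.
#'
#' @return data.frame with columns `pathway_id`, `name`, `found`, `total`,
#'   `entities_ratio`, `entities_p` (34 rows).
#' @export
reference_enrichment <- function() {
  utils::read.csv(system.file("extdata", "reactome_mmu_enrichment.csv",
                              package = "dentproteo", mustWork = TRUE),
                  stringsAsFactors = FALSE,
                  colClasses = c(entities_ratio = "numeric",
                                 entities_p = "numeric"))
}
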