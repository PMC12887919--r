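# Identification-quality filtering and batch intersection.
#
# A protein identification is kept when its minimum false-discovery rate
# (q-value) is at most q_max, it is represented by at least min_peptides
# distinct peptides, and by at least min_psms peptide-spectrum matches.
# The defaults encode the usual exclusion rules: q > 0.05 removed, fewer
# than two peptides removed, three or fewer PSMs removed.

#' Quality-filter thresholds
#'
#' @param q_max maximum identification q-value (kept when `q <= q_max`).
#' @param min_peptides minimum distinct peptide count (inclusive).
#' @param min_psms minimum peptide-spectrum-match count (inclusive).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(q_max = 0.05, min_peptides = 2L, min_psms = 4L) {
  if (q_max <= 0 || q_max > 1)
    dp_stop("q_max must lie in (0, 1]", "dentproteo_validation_error")
  if (min_peptides < 0 || min_psms < 0)
    dp_stop("minimum counts must be non-negative",
            "dentproteo_validation_error")
  structure(list(q_max = q_max, min_peptides = as.integer(min_peptides),
                 min_psms = as.integer(min_psms)), class = "qc_thresholds")
}

#' Apply identification-quality filters to one batch
#'
#' Retains exactly the records with `q_value <= q_max`,
#' `n_peptides >= min_peptides` and `n_psms >= min_psms`; record order is
#' preserved and the input is not modified. Per-filter removal counts are
#' attached as attribute `filter_counts`.
#'
#' @param dataset a [group_dataset()].
#' @param thresholds a [qc_thresholds()].
#' @return The filtered [group_dataset()].
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds()) {
  q <- dataset$quant
  fail_q <- !(q$q_value <= thresholds$q_max)
  fail_pep <- !(q$n_peptides >= thresholds$min_peptides)
  fail_psm <- !(q$n_psms >= thresholds$min_psms)
  keep <- !(fail_q | fail_pep | fail_psm)
  keep[is.na(keep)] <- FALSE
  out <- dataset
  out$quant <- q[keep, , drop = FALSE]
  out$abundance <- dataset$abundance[keep, , drop = FALSE]
  if (!is.null(dataset$peptides))
    out$peptides <- dataset$peptides[
      dataset$peptides$accession %in% q$accession[keep], , drop = FALSE]
  attr(out, "filter_counts") <- c(q_value = sum(fail_q, na.rm = TRUE),
                                  peptides = sum(fail_pep, na.rm = TRUE),
                                  psms = sum(fail_psm, na.rm = TRUE),
                                  kept = sum(keep))
  out
}

#' Intersect two filtered batches into the combined group (CG)
#'
#' Returns the accessions unambiguously present in both batches, sorted
#' lexicographically. Symmetric in its arguments.
#'
#' @param a,b [group_dataset()]s (already quality-filtered).
#' @return Sorted character vector of shared accessions.
#' @export
intersect_groups <- function(a, b) {
  sort(intersect(a$quant$accession, b$quant$accession))
}
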