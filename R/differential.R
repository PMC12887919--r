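# Pairwise treatment/control abundance ratios with censoring, per-comparison
# significance from peptide-level log2 ratios, and the cross-batch selection
# of consistently significant proteins (CGSig).

#' Enumerate treatment x control comparisons within each batch
#'
#' One comparison per (treatment, control) specimen pair within a batch:
#' the 2+2 design yields 4 comparisons per batch, 8 in total.
#'
#' @param design a [specimen_design()] table.
#' @return data.frame with columns `comparison_id`, `batch`, `treatment`,
#'   `control`.
#' @export
build_comparisons <- function(design) {
  validate_design(design)
  out <- do.call(rbind, lapply(unique(design$batch), function(b) {
    d <- design[design$batch == b, , drop = FALSE]
    trt <- d$specimen_id[d$arm == "treatment"]
    ctl <- d$specimen_id[d$arm == "control"]
    grid <- expand.grid(control = ctl, treatment = trt,
                        stringsAsFactors = FALSE)
    data.frame(comparison_id = sprintf("%s:%s/%s", b, grid$treatment,
                                       grid$control),
               batch = b, treatment = grid$treatment, control = grid$control,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Normalize specimen abundances to a common total
#'
#' Rescales every specimen's (protein- and peptide-level) abundances so all
#' specimens share the same total protein abundance, taken as the median of
#' the per-specimen totals over observed values. Missing values are left
#' untouched.
#'
#' @param dataset a [group_dataset()].
#' @return The normalized [group_dataset()]; per-specimen scale factors are
#'   attached as attribute `norm_factors`.
#' @export
normalize_abundances <- function(dataset) {
  ab <- dataset$abundance
  totals <- colSums(ab, na.rm = TRUE)
  if (any(totals == 0))
    dp_stop(sprintf("specimen(s) with no observed abundances: %s",
                    paste(colnames(ab)[totals == 0], collapse = ", ")),
            "dentproteo_validation_error")
  target <- stats::median(totals)
  f <- target / totals
  out <- dataset
  out$abundance <- sweep(ab, 2, f, "*")
  if (!is.null(dataset$peptides)) {
    pep <- dataset$peptides
    for (id in colnames(ab)) pep[[id]] <- pep[[id]] * f[[id]]
    out$peptides <- pep
  }
  attr(out, "norm_factors") <- f
  out
}

#' Censored log2 transform of an abundance ratio
#'
#' log2 of the raw ratio, clamped to `[-cap, +cap]`; the default cap 3.32
#' (log2 of a 10-fold change) is the sentinel used for effectively infinite
#' ratios. Vectorized; `NA` ratios stay `NA`.
#'
#' @param raw_ratio positive abundance ratio(s), `NA` allowed.
#' @param cap censoring bound on the log2 scale.
#' @return list with numeric `log2_ratio` and logical `censored`
#'   (`TRUE` iff clamping occurred).
#' @export
censored_log2 <- function(raw_ratio, cap = 3.32) {
  if (cap <= 0) dp_stop("cap must be positive", "dentproteo_validation_error")
  if (any(raw_ratio <= 0, na.rm = TRUE))
    dp_stop("raw_ratio must be positive", "dentproteo_validation_error")
  lr <- log2(raw_ratio)
  censored <- !is.na(lr) & abs(lr) > cap
  lr <- pmin(pmax(lr, -cap), cap)
  list(log2_ratio = lr, censored = censored)
}

# Vectorized one-sample two-sided t-test of each protein's peptide log2
# ratios against zero. Returns NA for proteins with < 2 usable peptide
# ratios; p = 1 for the degenerate all-zero (no effect) case and NA when
# all ratios equal the same non-zero constant.
peptide_ratio_pvalues <- function(peptides, treatment, control) {
  lr <- log2(peptides[[treatment]] / peptides[[control]])
  ok <- is.finite(lr)
  acc <- peptides$accession[ok]
  lr <- lr[ok]
  if (!length(lr)) return(stats::setNames(numeric(0), character(0)))
  n <- rowsum(rep(1, length(lr)), acc)
  s <- rowsum(lr, acc)
  ss <- rowsum(lr^2, acc)
  m <- s / n
  v <- pmax(0, (ss - n * m^2) / pmax(n - 1, 1))
  p <- rep(NA_real_, length(n))
  usable <- n >= 2
  zero_var <- usable & v == 0
  p[zero_var & m == 0] <- 1
  pos_var <- usable & v > 0
  tval <- m[pos_var] / sqrt(v[pos_var] / n[pos_var])
  p[pos_var] <- 2 * stats::pt(-abs(tval), df = n[pos_var] - 1)
  stats::setNames(as.numeric(p), rownames(n))
}

#' Per-comparison p-values for one treatment/control pair
#'
#' For each protein, a two-sided one-sample t-test of its peptide-level
#' log2(treatment/control) ratios against 0 (peptides missing on either
#' side are excluded; proteins with fewer than 2 usable peptide ratios get
#' a missing p); adjusted p-values are Benjamini-Hochberg across all tested
#' proteins within the comparison.
#'
#' @param dataset a [group_dataset()] with peptide-level abundances.
#' @param comparison one row of [build_comparisons()] (or a list with
#'   `treatment` and `control` specimen ids).
#' @param adjust multiplicity adjustment across proteins within the
#'   comparison: `"BH"` (default), `"bonferroni"` or `"none"`.
#' @return data.frame with columns `accession`, `p_value`, `adj_p_value`.
#' @export
comparison_pvalues <- function(dataset, comparison, adjust = "BH") {
  for (id in c(comparison$treatment, comparison$control))
    if (!id %in% colnames(dataset$abundance))
      dp_stop(sprintf("specimen '%s' absent from dataset", id),
              "dentproteo_validation_error")
  if (is.null(dataset$peptides))
    dp_stop("dataset has no peptide-level abundances",
            "dentproteo_validation_error")
  p <- peptide_ratio_pvalues(dataset$peptides, comparison$treatment,
                             comparison$control)
  p <- p[match(dataset$quant$accession, names(p))]
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  method <- match.arg(adjust, c("BH", "bonferroni", "none"))
  adj[ok] <- if (method == "none") p[ok] else stats::p.adjust(p[ok], method)
  data.frame(accession = dataset$quant$accession,
             p_value = as.numeric(p), adj_p_value = adj,
             stringsAsFactors = FALSE)
}

#' Compute all pairwise abundance-ratio results for one batch
#'
#' Normalizes the batch, then for every treatment x control comparison
#' forms the protein-level abundance ratio, its censored log2 transform,
#' and the peptide-based significance of [comparison_pvalues()].
#'
#' @param dataset a quality-filtered [group_dataset()] with peptide-level
#'   abundances.
#' @param comparisons rows of [build_comparisons()] for this batch;
#'   computed from the dataset's design when `NULL`.
#' @param cap censoring bound (log2).
#' @param adjust see [comparison_pvalues()].
#' @param normalize rescale specimens to a common total first (default).
#' @return data.frame of per-protein, per-comparison ratio results with
#'   columns `accession`, `comparison_id`, `batch`, `raw_ratio`,
#'   `log2_ratio`, `censored`, `p_value`, `adj_p_value`, `missing`.
#' @export
compute_ratios <- function(dataset, comparisons = NULL, cap = 3.32,
                           adjust = "BH", normalize = TRUE) {
  if (is.null(comparisons)) {
    comparisons <- build_comparisons(dataset$design)
    comparisons <- comparisons[comparisons$batch == dataset$batch, ,
                               drop = FALSE]
  }
  if (normalize) dataset <- normalize_abundances(dataset)
  ab <- dataset$abundance
  out <- vector("list", nrow(comparisons))
  for (i in seq_len(nrow(comparisons))) {
    cmp <- comparisons[i, ]
    raw <- ab[, cmp$treatment] / ab[, cmp$control]
    cl <- censored_log2(raw, cap)
    pv <- comparison_pvalues(dataset, cmp, adjust = adjust)
    missing <- is.na(raw)
    out[[i]] <- data.frame(
      accession = dataset$quant$accession,
      comparison_id = cmp$comparison_id, batch = cmp$batch,
      raw_ratio = as.numeric(raw), log2_ratio = cl$log2_ratio,
      censored = cl$censored & !missing,
      p_value = ifelse(missing, NA_real_, pv$p_value),
      adj_p_value = ifelse(missing, NA_real_, pv$adj_p_value),
      missing = missing, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select the combined significant set (CGSig)
#'
#' A protein is batch-significant when at least one of its
#' treatment/control comparisons in that batch has an adjusted p-value at
#' or below `alpha`. A protein is discarded when it is missing in more
#' than `max_missing` comparisons, counted across both batches. CGSig is
#' the set of CG proteins that are batch-significant in both batches and
#' not discarded, so every member has at least one significant comparison
#' in each batch.
#'
#' @param ratios_g1,ratios_g2 ratio results from [compute_ratios()] for
#'   batches 1 and 2.
#' @param cg character vector of combined-group accessions
#'   (see [intersect_groups()]); results are restricted to it.
#' @param alpha significance threshold on the adjusted p-value.
#' @param max_missing maximum tolerated number of missing comparisons
#'   (pooled across batches); the default 1 discards proteins missing in
#'   two or more comparisons.
#' @return Sorted character vector of CGSig accessions, with attributes
#'   `n_retained` (batch-significant in both batches) and `n_discarded`
#'   (retained but dropped by the missingness rule).
#' @export
select_cgsig <- function(ratios_g1, ratios_g2, cg, alpha = 0.05,
                         max_missing = 1L) {
  if (alpha <= 0 || alpha > 1)
    dp_stop("alpha must lie in (0, 1]", "dentproteo_validation_error")
  r <- rbind(ratios_g1, ratios_g2)
  r <- r[r$accession %in% cg, , drop = FALSE]
  sig <- !is.na(r$adj_p_value) & r$adj_p_value <= alpha
  sig_by <- tapply(sig, list(r$accession, r$batch), any)
  both <- rownames(sig_by)[rowSums(sig_by, na.rm = TRUE) == 2 &
                             !apply(is.na(sig_by), 1, any)]
  miss <- tapply(r$missing, r$accession, sum)
  discarded <- names(miss)[miss > max_missing]
  out <- sort(setdiff(both, discarded))
  attr(out, "n_retained") <- length(both)
  attr(out, "n_discarded") <- length(intersect(both, discarded))
  out
}
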