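# Per-protein summaries of the significant comparisons: censored mean log2
# fold change when the signal is stable, up/down counts otherwise.

#' Summarize one protein's significant comparisons
#'
#' The significant set is the comparisons with adjusted p at or below
#' `alpha`. The mean log2 fold change averages the *uncensored* significant
#' log2 ratios (censored sentinels still count toward the up/down and
#' censored tallies). The mean is withheld (record flagged unstable) when
#' the uncensored significant set is empty, when `|mean| < epsilon`, or
#' when removing any single value flips the mean's sign — the deterministic
#' version of reporting "xU/yD" instead of an average that one specimen
#' could overturn. Direction comes from the mean's sign when stable and
#' from the majority of significant comparison signs otherwise (tie:
#' `"Mixed"`).
#'
#' @param results ratio-result rows (see [compute_ratios()]) for a single
#'   accession, across all comparisons and batches.
#' @param alpha significance threshold on the adjusted p-value.
#' @param epsilon minimum |mean log2 fold change| considered interpretable.
#' @return One-row data.frame with columns `accession`, `mean_log2fc`
#'   (`NA` when unstable), `direction` (`Up`/`Down`/`Mixed`), `n_up`,
#'   `n_down`, `n_censored`, `stable`.
#' @export
summarize_protein <- function(results, alpha = 0.05, epsilon = 0.3) {
  if (length(unique(results$accession)) != 1)
    dp_stop("results must cover exactly one accession",
            "dentproteo_validation_error")
  sig <- !is.na(results$adj_p_value) & results$adj_p_value <= alpha
  if (!any(sig))
    dp_stop(sprintf("'%s' has no significant comparison (not a CGSig member)",
                    results$accession[1]), "dentproteo_validation_error")
  vals <- results$log2_ratio[sig]
  cens <- results$censored[sig]
  n_up <- sum(vals > 0)
  n_down <- sum(vals < 0)
  unc <- vals[!cens]
  stable <- FALSE
  mean_fc <- NA_real_
  if (length(unc)) {
    m <- mean(unc)
    flip <- if (length(unc) >= 2) {
      loo <- (sum(unc) - unc) / (length(unc) - 1)
      any(sign(loo) != sign(m))
    } else FALSE
    stable <- abs(m) >= epsilon && !flip
    if (stable) mean_fc <- m
  }
  direction <- if (stable) {
    if (mean_fc > 0) "Up" else "Down"
  } else if (n_up > n_down) "Up" else if (n_down > n_up) "Down" else "Mixed"
  data.frame(accession = results$accession[1], mean_log2fc = mean_fc,
             direction = direction, n_up = n_up, n_down = n_down,
             n_censored = sum(cens), stable = stable,
             stringsAsFactors = FALSE)
}

#' Summarize every CGSig protein
#'
#' @param ratios combined ratio results of both batches
#'   (rbind of the two [compute_ratios()] outputs).
#' @param cgsig CGSig accessions from [select_cgsig()].
#' @inheritParams summarize_protein
#' @return data.frame with one [summarize_protein()] row per CGSig member.
#' @export
summarize_cgsig <- function(ratios, cgsig, alpha = 0.05, epsilon = 0.3) {
  out <- do.call(rbind, lapply(cgsig, function(acc)
    summarize_protein(ratios[ratios$accession == acc, , drop = FALSE],
                      alpha = alpha, epsilon = epsilon)))
  if (is.null(out))
    out <- data.frame(accession = character(0), mean_log2fc = numeric(0),
                      direction = character(0), n_up = integer(0),
                      n_down = integer(0), n_censored = integer(0),
                      stable = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the differential-expression report table
#'
#' Rows are grouped by functional category and sorted by mean log2 fold
#' change (ascending) within category; unstable records render an empty
#' average and an `xU/yD` up/down entry.
#'
#' @param records output of [summarize_cgsig()].
#' @param categories named character vector mapping accession to a process
#'   label; unmapped accessions fall under `"Unknown"`.
#' @param genes optional named character vector mapping accession to gene
#'   symbol.
#' @return data.frame with columns `accession`, `gene`, `category`,
#'   `avg_log2` (character; empty when withheld), `up_down`.
#' @export
build_table1 <- function(records, categories = character(0),
                         genes = character(0)) {
  if (!nrow(records))
    return(data.frame(accession = character(0), gene = character(0),
                      category = character(0), avg_log2 = character(0),
                      up_down = character(0), stringsAsFactors = FALSE))
  cat_of <- function(a) {
    v <- unname(categories[a])
    ifelse(is.na(v) | !nzchar(v), "Unknown", v)
  }
  out <- data.frame(
    accession = records$accession,
    gene = ifelse(is.na(genes[records$accession]), "",
                  unname(genes[records$accession])),
    category = cat_of(records$accession),
    avg_log2 = ifelse(records$stable, sprintf("%.2f", records$mean_log2fc), ""),
    up_down = ifelse(records$stable, records$direction,
                     sprintf("%dU/%dD", records$n_up, records$n_down)),
    stringsAsFactors = FALSE)
  ord <- order(out$category, !records$stable, records$mean_log2fc)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
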