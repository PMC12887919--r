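# Pathway over-representation analysis: exact hypergeometric upper tails,
# entity-ratio ranking, background-size inference from published
# (pathway size, entity ratio) pairs, and a descriptive category profile.

#' Hypergeometric upper-tail probability
#'
#' P(X >= x) when x successes are observed among `n` draws without
#' replacement from a background of `N` entities of which `K` belong to the
#' pathway. Terms are accumulated from log-binomial coefficients, so the
#' computation is overflow-free for backgrounds up to at least 1e7, and the
#' result is exactly 1 when `x = 0`.
#'
#' @param x observed overlap count.
#' @param K pathway size.
#' @param n query size.
#' @param N background size.
#' @return The upper-tail probability.
#' @export
hypergeom_upper_tail <- function(x, K, n, N) {
  if (length(x) > 1)
    return(vapply(x, hypergeom_upper_tail, 0, K = K, n = n, N = N))
  if (K > N || n > N || x < 0 || x > min(K, n))
    dp_stop("require 0 <= x <= min(K, n), K <= N, n <= N",
            "dentproteo_validation_error")
  if (x == 0) return(1)
  j <- seq(max(x, n - (N - K)), min(K, n))
  lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  min(1, sum(exp(lt)))
}

#' Over-representation analysis with entity-ratio ranking
#'
#' For each pathway with at least one query member, computes the overlap
#' `x`, the entity ratio `K/N` (pathway size over organism-wide background),
#' the found ratio `x/n`, and the exact hypergeometric upper-tail p-value.
#' Pathways at or below `alpha` are flagged significant and ranked by
#' entity ratio, descending (ties: smaller p first, then pathway id);
#' non-significant pathways follow, unranked. No multiplicity correction is
#' applied by default: significance is declared at the raw entities p.
#'
#' @param query character vector of query accessions (e.g. CGSig).
#' @param pathways pathway list as returned by [read_gmt()].
#' @param N background size (total entities for the organism); defaults to
#'   the inferred Mus proteome background, 11017.
#' @param alpha significance threshold on the entities p-value.
#' @param adjust `"none"` (default) or `"BH"` across pathways.
#' @return data.frame with columns `pathway_id`, `name`, `x`, `K`, `n`,
#'   `N`, `entities_ratio`, `found_ratio`, `p_value`, `significant`,
#'   `rank`, `found_accessions`.
#' @export
enrich <- function(query, pathways, N = 11017, alpha = 0.05,
                   adjust = "none") {
  query <- unique(query)
  if (!length(query))
    dp_stop("empty query", "dentproteo_validation_error")
  n <- length(query)
  if (n > N)
    dp_stop("query larger than background", "dentproteo_validation_error")
  rows <- lapply(pathways, function(p) {
    K <- length(p$members)
    if (K > N)
      dp_stop(sprintf("pathway '%s' larger than background N", p$pathway_id),
              "dentproteo_validation_error")
    found <- intersect(query, p$members)
    x <- length(found)
    if (x == 0) return(NULL)
    data.frame(pathway_id = p$pathway_id, name = p$name, x = x, K = K,
               n = n, N = N, entities_ratio = K / N, found_ratio = x / n,
               p_value = hypergeom_upper_tail(x, K, n, N),
               found_accessions = paste(sort(found), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(pathway_id = character(0), name = character(0),
                      x = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), entities_ratio = numeric(0),
                      found_ratio = numeric(0), p_value = numeric(0),
                      significant = logical(0), rank = integer(0),
                      found_accessions = character(0),
                      stringsAsFactors = FALSE))
  if (match.arg(adjust, c("none", "BH")) == "BH")
    res$p_value <- stats::p.adjust(res$p_value, "BH")
  res$significant <- res$p_value <= alpha
  ord <- order(!res$significant, -res$entities_ratio, res$p_value,
               res$pathway_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- NA_integer_
  res$rank[res$significant] <- seq_len(sum(res$significant))
  res <- res[, c("pathway_id", "name", "x", "K", "n", "N", "entities_ratio",
                 "found_ratio", "p_value", "significant", "rank",
                 "found_accessions")]
  rownames(res) <- NULL
  res
}

#' Infer the background size from printed (size, ratio) pairs
#'
#' Published over-representation tables print each pathway's entity ratio
#' `K/N` rounded to 4 decimals but rarely the organism-wide background `N`
#' itself. This recovers `N` as the integer minimizing
#' `sum((round(K/N, 4) - printed_ratio)^2)`; since 4-decimal rounding makes
#' whole intervals of `N` exact, ties are broken by the continuous
#' least-squares objective `sum((K/N - printed_ratio)^2)`, which has a
#' unique minimizer. The per-pair feasible intervals implied by half-ULP
#' rounding bounds and their intersection are also reported.
#'
#' @param K integer vector of pathway sizes.
#' @param ratio printed entity ratios (4-decimal).
#' @param search integer interval of candidate backgrounds.
#' @return list with `N` (the inferred background), `intervals`
#'   (per-pair feasible `[lower, upper]` matrix), and `intersection`
#'   (common feasible interval; `NA`s with a warning when empty).
#' @export
infer_background <- function(K, ratio, search = c(max(K), 100000L)) {
  stopifnot(length(K) == length(ratio), length(K) >= 1)
  if (!any(ratio > 0))
    dp_stop("need at least one positive ratio", "dentproteo_validation_error")
  half <- 5e-5
  lower <- ceiling(K / (ratio + half))
  upper <- ifelse(ratio - half > 0, floor(K / (ratio - half)), Inf)
  intervals <- cbind(lower = lower, upper = upper)
  lo <- max(lower); hi <- min(upper)
  if (lo > hi) {
    warning("printed-ratio feasible intervals have empty intersection")
    intersection <- c(NA_real_, NA_real_)
  } else intersection <- c(lo, hi)
  cand <- seq(search[1], search[2])
  obj <- vapply(cand, function(NN) sum((round(K / NN, 4) - ratio)^2), 0)
  best <- cand[obj == min(obj)]
  if (length(best) > 1) {
    obj2 <- vapply(best, function(NN) sum((K / NN - ratio)^2), 0)
    best <- best[which.min(obj2)]
  }
  list(N = as.integer(best), intervals = intervals,
       intersection = intersection)
}

#' Descriptive category profile of a query set
#'
#' Counts, per annotation namespace, how many query proteins carry each
#' term (a protein counts once per distinct term) and the proportion of
#' the namespace's annotated query members. Terms of the map absent from
#' the query keep a zero count; query proteins without any annotation in a
#' namespace are tallied as `unannotated`.
#'
#' @param query character vector of accessions.
#' @param category_map data.frame with columns `accession`, `namespace`,
#'   `term` (one row per annotation; may be partial).
#' @return data.frame with columns `namespace`, `term`, `count`,
#'   `proportion`; the per-namespace unannotated counts are attached as
#'   attribute `unannotated`.
#' @export
profile_categories <- function(query, category_map) {
  query <- unique(query)
  if (!length(query)) {
    res <- data.frame(namespace = character(0), term = character(0),
                      count = integer(0), proportion = numeric(0),
                      stringsAsFactors = FALSE)
    attr(res, "unannotated") <- integer(0)
    return(res)
  }
  namespaces <- unique(category_map$namespace)
  out <- list(); unann <- stats::setNames(integer(length(namespaces)),
                                          namespaces)
  for (ns in namespaces) {
    mp <- unique(category_map[category_map$namespace == ns,
                              c("accession", "term")])
    terms <- sort(unique(mp$term))
    hit <- mp[mp$accession %in% query, , drop = FALSE]
    counts <- table(factor(hit$term, levels = terms))
    annotated <- length(unique(hit$accession))
    unann[[ns]] <- length(query) - annotated
    out[[ns]] <- data.frame(namespace = ns, term = terms,
                            count = as.integer(counts),
                            proportion = if (annotated)
                              as.integer(counts) / annotated else 0,
                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(namespace = character(0), term = character(0),
               count = integer(0), proportion = numeric(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "unannotated") <- unann
  res
}
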