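# Landmark-derived phenotypes: straight-line skull length between two
# labelled landmarks and the convex-hull crown footprint of 25 molar
# outline landmarks, compared between arms with Welch's unequal-variance
# t-test (one-sided by default: control greater than treatment).

#' Straight-line distance between two labelled landmarks
#'
#' @param lm a skull [landmark_set()].
#' @param a_label,b_label labels of the two landmarks.
#' @return Euclidean distance in mm.
#' @export
interlandmark_distance <- function(lm,
                                   a_label = "foramen_magnum_apex",
                                   b_label = "maxillae_junction") {
  for (lab in c(a_label, b_label))
    if (!lab %in% lm$labels)
      dp_stop(sprintf("landmark label '%s' not present", lab),
              "dentproteo_validation_error")
  d <- lm$coords[match(a_label, lm$labels), ] -
       lm$coords[match(b_label, lm$labels), ]
  sqrt(sum(d^2))
}

# signed shoelace area of an ordered planar polygon, made positive
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Convex-hull crown footprint area
#'
#' Centers the landmarks, projects them onto the plane spanned by the two
#' dominant principal axes of their covariance, takes the planar convex
#' hull and returns its shoelace area (mm^2). The result is invariant
#' under rigid rotation and translation of the input; interior points do
#' not affect it.
#'
#' @param lm a molar [landmark_set()] (25 landmarks, not all collinear).
#' @return Hull area in mm^2.
#' @export
crown_area <- function(lm) {
  pts <- sweep(lm$coords, 2, colMeans(lm$coords))
  sv <- svd(pts)
  if (sv$d[2] < max(sv$d[1], 1) * 1e-9)
    dp_stop("landmarks are (nearly) collinear; no crown plane",
            "dentproteo_validation_error")
  xy <- pts %*% sv$v[, 1:2]
  hull <- grDevices::chull(xy)
  polygon_area(xy[hull, , drop = FALSE])
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper over [stats::t.test()] with the study's orientation:
#' `a` is the control group and `b` the treatment group, and
#' `alternative = "a_greater"` tests whether the control mean exceeds the
#' treatment mean (the predicted direction when treatment reduces the
#' phenotype). Degrees of freedom follow Welch-Satterthwaite and are
#' reported as a real number.
#'
#' @param a,b numeric vectors (at least 2 values each; at least one group
#'   with positive variance).
#' @param alternative `"a_greater"` (one-sided, default) or `"two_sided"`.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `ci_lower` (lower
#'   95% confidence bound on `mean_a - mean_b`), and `alternative`.
#' @export
welch_test <- function(a, b, alternative = c("a_greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2)
    dp_stop("need at least 2 values per group", "dentproteo_validation_error")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    dp_stop("both groups have zero variance", "dentproteo_validation_error")
  tt <- stats::t.test(a, b, var.equal = FALSE,
                      alternative = switch(alternative,
                                           a_greater = "greater",
                                           two_sided = "two.sided"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       ci_lower = tt$conf.int[1], alternative = alternative)
}

#' Phenotype comparison between arms
#'
#' Computes the per-specimen trait values from landmark sets and runs the
#' control-vs-treatment Welch comparison.
#'
#' @param landmarks list of [landmark_set()]s, one per specimen, all of
#'   the same role.
#' @param design data.frame with columns `specimen_id` and `arm`.
#' @param trait `"skull_length_mm"` (from skull sets) or
#'   `"crown_area_mm2"` (from molar sets).
#' @param alternative see [welch_test()]; `a` = control.
#' @return list with `trait`, per-specimen `values` (named), `mean_control`,
#'   `mean_treatment`, and the [welch_test()] fields `t`, `df`, `p`,
#'   `ci_lower`, `alternative`.
#' @export
phenotype_test <- function(landmarks, design,
                           trait = c("skull_length_mm", "crown_area_mm2"),
                           alternative = "a_greater") {
  trait <- match.arg(trait)
  fun <- switch(trait, skull_length_mm = interlandmark_distance,
                crown_area_mm2 = crown_area)
  vals <- vapply(landmarks, fun, 0)
  names(vals) <- vapply(landmarks, `[[`, "", "specimen_id")
  arm <- design$arm[match(names(vals), design$specimen_id)]
  if (anyNA(arm))
    dp_stop("landmark specimen absent from the design",
            "dentproteo_validation_error")
  wt <- welch_test(vals[arm == "control"], vals[arm == "treatment"],
                   alternative = alternative)
  c(list(trait = trait, values = vals,
         mean_control = wt$mean_a, mean_treatment = wt$mean_b),
    wt[c("t", "df", "p", "ci_lower", "alternative")])
}

#' Phenotype report table
#'
#' One row per trait with group means and Welch statistics.
#'
#' @param skull,molar lists of [landmark_set()]s (either may be `NULL`).
#' @inheritParams phenotype_test
#' @return data.frame with columns `trait`, `mean_control`,
#'   `mean_treatment`, `t`, `df`, `p`, `ci_lower`.
#' @export
phenotype_table <- function(skull = NULL, molar = NULL, design,
                            alternative = "a_greater") {
  rows <- list()
  if (!is.null(skull))
    rows$skull <- phenotype_test(skull, design, "skull_length_mm",
                                 alternative)
  if (!is.null(molar))
    rows$molar <- phenotype_test(molar, design, "crown_area_mm2",
                                 alternative)
  do.call(rbind, lapply(rows, function(r)
    data.frame(trait = r$trait, mean_control = r$mean_control,
               mean_treatment = r$mean_treatment, t = r$t, df = r$df,
               p = r$p, ci_lower = r$ci_lower, stringsAsFactors = FALSE)))
}
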