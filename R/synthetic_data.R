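# Ground-truth synthetic data emulating the two-batch label-free molar
# proteome design: a shared protein universe, per-batch detection, planted
# signed log2 effects in the treatment arm, peptide-level noise, and
# abundance-dependent (MNAR) dropout.

#' Configuration for the synthetic quantification experiment
#'
#' Defaults are sized to the study design this generator emulates: a
#' 2,400-protein universe with per-batch detection probabilities 0.92 and
#' 0.67 (expected ~2,200 and ~1,600 detected proteins with ~1,500 shared),
#' two treatment and two control specimens per batch, 5% of proteins
#' carrying planted effects with |log2 fold change| between 1 and 2.5,
#' peptide-level log2 noise with sd 0.4, and a logistic
#' missing-not-at-random dropout model in log2 abundance.
#'
#' @param n_proteins protein universe size.
#' @param detect_prob_g1,detect_prob_g2 per-protein probability that the
#'   protein is detected at all in batch 1 / batch 2.
#' @param n_treatment,n_control specimens per arm within each batch.
#' @param frac_de fraction of the universe with planted differential
#'   expression.
#' @param effect_range interval of |log2 effect| for planted proteins.
#' @param peptide_noise_sd sd of peptide-level log2 measurement noise.
#' @param n_peptides_range inclusive integer interval for peptides per
#'   protein.
#' @param mnar_threshold,mnar_slope dropout model: an observation with log2
#'   abundance `x` is set missing with probability
#'   `plogis(mnar_slope * (mnar_threshold - x))`.
#' @param ratio_cap censoring bound for log2 abundance ratios.
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution.
#' @param peptide_offset_sd sd of per-peptide log2 ionization offsets.
#' @param frac_fail_q,frac_fail_peptides,frac_fail_psms per-batch fractions
#'   of proteins constructed to fail each identification-quality filter.
#' @param seed integer RNG seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 2400,
                             detect_prob_g1 = 0.92,
                             detect_prob_g2 = 0.67,
                             n_treatment = 2,
                             n_control = 2,
                             frac_de = 0.05,
                             effect_range = c(1, 2.5),
                             peptide_noise_sd = 0.4,
                             n_peptides_range = c(2L, 12L),
                             mnar_threshold = 19,
                             mnar_slope = 1,
                             ratio_cap = 3.32,
                             baseline_mean = 23,
                             baseline_sd = 2,
                             peptide_offset_sd = 1,
                             frac_fail_q = 0.02,
                             frac_fail_peptides = 0.02,
                             frac_fail_psms = 0.02,
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(detect_prob_g1, detect_prob_g2, frac_de,
             frac_fail_q, frac_fail_peptides, frac_fail_psms)
  if (any(probs < 0 | probs > 1))
    dp_stop("probabilities must lie in [0, 1]", "dentproteo_validation_error")
  if (length(effect_range) != 2 || any(effect_range <= 0) ||
      effect_range[1] > effect_range[2])
    dp_stop("effect_range must be a positive increasing interval",
            "dentproteo_validation_error")
  if (ratio_cap <= 0)
    dp_stop("ratio_cap must be positive", "dentproteo_validation_error")
  if (peptide_noise_sd < 0 || baseline_sd < 0 || peptide_offset_sd < 0)
    dp_stop("standard deviations must be non-negative",
            "dentproteo_validation_error")
  if (n_treatment < 1 || n_control < 1)
    dp_stop("each arm needs at least one specimen per batch",
            "dentproteo_validation_error")
  if (n_peptides_range[1] < 1 || n_peptides_range[1] > n_peptides_range[2])
    dp_stop("invalid n_peptides_range", "dentproteo_validation_error")
  structure(cfg, class = "synthetic_config")
}

synthetic_design <- function(n_treatment, n_control) {
  ids <- function(prefix, k, offset) sprintf("%s%d", prefix, offset + seq_len(k))
  g1 <- c(ids("T", n_treatment, 0), ids("C", n_control, 0))
  g2 <- c(ids("T", n_treatment, n_treatment), ids("C", n_control, n_control))
  arm <- rep(c("treatment", "control"), c(n_treatment, n_control))
  specimen_design(
    specimen_id = c(g1, g2),
    batch = rep(c("group1", "group2"), each = n_treatment + n_control),
    arm = c(arm, arm),
    litter_id = rep(c("L1", "L2", "L3", "L4"),
                    c(n_treatment, n_control, n_treatment, n_control)))
}

#' Generate a two-batch synthetic quantification experiment
#'
#' Per protein, a baseline log2 abundance is drawn from a normal
#' distribution (a log-normal on the intensity scale); treatment specimens
#' are shifted by the planted signed log2 effect (0 for null proteins).
#' Peptide-level abundances are the protein abundance times a per-peptide
#' ionization offset times log-normal noise; the protein-level abundance of
#' a specimen is the sum of its peptide intensities. Detection per batch is
#' Bernoulli, and detected observations drop out (protein and peptides
#' together) with the logistic MNAR probability. Identification fields
#' (q-value, peptide count, PSM count) are generated so that configurable
#' fractions of proteins fail each quality filter.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `group1` and `group2` (each a
#'   [group_dataset()] with peptide-level abundances), `design`, and
#'   `truth` (list with `planted`, a named vector of true signed log2
#'   effects, plus bookkeeping of qc-failed accessions per batch).
#' @export
generate_quant_experiment <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  set.seed(config$seed)
  n <- config$n_proteins
  accession <- sprintf("SYN%05d", seq_len(n))
  design <- synthetic_design(config$n_treatment, config$n_control)

  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  n_de <- round(config$frac_de * n)
  planted_idx <- sort(sample.int(n, n_de))
  effect <- numeric(n)
  if (n_de) {
    mag <- stats::runif(n_de, config$effect_range[1], config$effect_range[2])
    effect[planted_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
  }
  m <- sample(seq(config$n_peptides_range[1], config$n_peptides_range[2]),
              n, replace = TRUE)

  detect <- list(group1 = stats::runif(n) < config$detect_prob_g1,
                 group2 = stats::runif(n) < config$detect_prob_g2)
  # every planted protein must surface in at least one batch's table
  orphan <- planted_idx[!(detect$group1[planted_idx] |
                            detect$group2[planted_idx])]
  if (length(orphan)) {
    pick <- sample(c(TRUE, FALSE), length(orphan), replace = TRUE)
    detect$group1[orphan[pick]] <- TRUE
    detect$group2[orphan[!pick]] <- TRUE
  }
  qc_fail <- list()

  make_batch <- function(batch) {
    keep <- which(detect[[batch]])
    bdes <- design[design$batch == batch, , drop = FALSE]
    specs <- bdes$specimen_id
    treat <- as.numeric(bdes$arm == "treatment")

    fail_pep <- stats::runif(length(keep)) < config$frac_fail_peptides
    m_b <- ifelse(fail_pep, 1L, m[keep])
    acc_b <- accession[keep]
    pep_acc <- rep(acc_b, m_b)
    pep_base <- rep(baseline[keep], m_b)
    pep_eff <- rep(effect[keep], m_b)
    pep_id <- unlist(lapply(m_b, function(k) sprintf("pep%02d", seq_len(k))),
                     use.names = FALSE)
    offset <- stats::rnorm(length(pep_acc), 0, config$peptide_offset_sd)

    npep <- length(pep_acc)
    pepmat <- matrix(NA_real_, npep, length(specs),
                     dimnames = list(NULL, specs))
    for (j in seq_along(specs)) {
      lg <- pep_base + pep_eff * treat[j] + offset +
        stats::rnorm(npep, 0, config$peptide_noise_sd)
      pepmat[, j] <- 2^lg
    }
    prot <- rowsum(pepmat, pep_acc, reorder = FALSE)
    # MNAR dropout at the protein-observation level, peptides follow suit
    p_miss <- stats::plogis(config$mnar_slope *
                              (config$mnar_threshold - log2(prot)))
    miss <- matrix(stats::runif(length(prot)) < p_miss, nrow(prot))
    prot[miss] <- NA_real_
    prot_of_pep <- match(pep_acc, acc_b)
    for (j in seq_along(specs))
      pepmat[miss[prot_of_pep, j], j] <- NA_real_

    # ensure every record keeps at least one observation (resurrect one
    # specimen of fully dropped proteins at its pre-dropout value)
    dead <- which(rowSums(!is.na(prot)) == 0)
    if (length(dead)) {
      redo <- rowsum(2^(pep_base + offset + outer(pep_eff, treat)),
                     pep_acc, reorder = FALSE)
      for (i in dead) {
        j <- sample.int(length(specs), 1)
        prot[i, j] <- redo[i, j]
        pepmat[prot_of_pep == i, j] <- redo[i, j] / m_b[i]
      }
    }

    fail_q <- stats::runif(length(keep)) < config$frac_fail_q
    fail_psm <- stats::runif(length(keep)) < config$frac_fail_psms
    q_value <- ifelse(fail_q, stats::runif(length(keep), 0.051, 0.3),
                      stats::runif(length(keep), 0, 0.049))
    n_psms <- ifelse(fail_psm, sample(1:3, length(keep), replace = TRUE),
                     pmax(4L, m_b * sample(2:6, length(keep), replace = TRUE)))
    qc_fail[[batch]] <<- acc_b[fail_q | fail_pep | fail_psm]

    quant <- data.frame(accession = acc_b, gene = sub("SYN", "Gene", acc_b),
                        description = "synthetic protein",
                        q_value = q_value, n_peptides = m_b,
                        n_psms = as.integer(n_psms), stringsAsFactors = FALSE)
    peptides <- data.frame(accession = pep_acc, peptide_id = pep_id,
                           stringsAsFactors = FALSE)
    for (j in seq_along(specs)) peptides[[specs[j]]] <- pepmat[, j]
    group_dataset(batch, quant, prot, design, peptides = peptides)
  }

  group1 <- make_batch("group1")
  group2 <- make_batch("group2")
  planted <- effect[planted_idx]
  names(planted) <- accession[planted_idx]
  truth <- list(planted = planted,
                universe = accession,
                qc_fail = qc_fail,
                enriched_pathways = character(0),
                landmark_effects = NULL)
  list(group1 = group1, group2 = group2, design = design, truth = truth)
}

#' Generate synthetic pathway annotation with planted enrichment
#'
#' Null pathways draw members uniformly from the universe; designated
#' enriched pathways draw an excess fraction of their members from the
#' planted (truly differential) accessions. Pathway sizes are uniform on
#' `size_range`; the default 15-500 follows common over-representation
#' practice of excluding very small and very large gene sets.
#'
#' @param universe character vector of accessions (the background).
#' @param planted accessions carrying true effects (members are drawn from
#'   here for enriched pathways).
#' @param n_pathways total number of pathways.
#' @param size_range inclusive integer interval of pathway sizes.
#' @param n_enriched how many pathways are constructed to be enriched.
#' @param enriched_frac fraction of an enriched pathway's members drawn
#'   from `planted` (capped by `length(planted)`).
#' @param seed integer RNG seed.
#' @return list with `pathways` (GMT-style list, see [read_gmt()]) and
#'   `enriched_ids` (character).
#' @export
generate_pathway_sets <- function(universe, planted, n_pathways,
                                  size_range = c(15L, 500L),
                                  n_enriched = 0, enriched_frac = 0.8,
                                  seed = 1L) {
  if (!length(universe))
    dp_stop("empty universe", "dentproteo_validation_error")
  if (n_pathways == 0) return(list(pathways = list(),
                                   enriched_ids = character(0)))
  if (size_range[2] > length(universe))
    dp_stop("requested pathway size exceeds the universe",
            "dentproteo_validation_error")
  if (n_enriched > n_pathways)
    dp_stop("n_enriched exceeds n_pathways", "dentproteo_validation_error")
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_pathways,
                  replace = TRUE)
  enriched <- seq_len(n_pathways) <= n_enriched
  pathways <- vector("list", n_pathways)
  for (i in seq_len(n_pathways)) {
    k <- sizes[i]
    if (enriched[i]) {
      k_pl <- min(round(enriched_frac * k), length(planted))
      mem <- c(sample(planted, k_pl),
               sample(setdiff(universe, planted), k - k_pl))
    } else {
      mem <- sample(universe, k)
    }
    pathways[[i]] <- list(pathway_id = sprintf("PWY%04d", i),
                          name = if (enriched[i]) sprintf("enriched pathway %d", i)
                                 else sprintf("null pathway %d", i),
                          members = mem)
  }
  list(pathways = pathways,
       enriched_ids = sprintf("PWY%04d", which(enriched)))
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate synthetic landmark sets with known group effects
#'
#' Skull sets are two labelled points placed exactly
#' `base + effect[arm]` mm apart in a random 3D orientation, each endpoint
#' jittered with isotropic Gaussian noise of per-coordinate sd
#' `skull_noise_sd / sqrt(2)` so the measured length has sd approximately
#' `skull_noise_sd`. Molar sets are 25 points on a planar closed curve
#' (an inscribed 2:1 ellipse polygon) rescaled so the convex-hull area is
#' exactly the per-specimen target, then rigidly rotated into a random 3D
#' orientation and translated. Defaults reproduce the observed group means
#' of the feeding experiment this generator emulates.
#'
#' @param n_treatment,n_control specimens per arm.
#' @param skull_base control-group mean skull length (mm).
#' @param skull_effect treatment minus control mean skull length (mm).
#' @param skull_noise_sd sd of the measured skull length (mm).
#' @param crown_base control-group mean crown area (mm^2).
#' @param crown_effect treatment minus control mean crown area (mm^2).
#' @param crown_area_sd between-specimen sd of crown area (mm^2).
#' @param landmark_noise_sd per-coordinate Gaussian jitter on molar
#'   landmarks (mm); 0 keeps the hull area exact.
#' @param seed integer RNG seed.
#' @return list with `skull` and `molar` (lists of [landmark_set()]),
#'   `design` (data.frame specimen_id/arm), and `effects` (named vector of
#'   true group mean differences).
#' @export
generate_landmark_sets <- function(n_treatment = 24, n_control = 26,
                                   skull_base = 19.02755,
                                   skull_effect = 0.17256,
                                   skull_noise_sd = 0.7,
                                   crown_base = 1.021672,
                                   crown_effect = 0.011901,
                                   crown_area_sd = 0.036,
                                   landmark_noise_sd = 0,
                                   seed = 1L) {
  if (n_treatment < 2 || n_control < 2)
    dp_stop("need at least 2 specimens per arm", "dentproteo_validation_error")
  if (skull_noise_sd < 0 || crown_area_sd < 0 || landmark_noise_sd < 0)
    dp_stop("noise sds must be non-negative", "dentproteo_validation_error")
  set.seed(seed)
  design <- data.frame(
    specimen_id = c(sprintf("LT%02d", seq_len(n_treatment)),
                    sprintf("LC%02d", seq_len(n_control))),
    arm = rep(c("treatment", "control"), c(n_treatment, n_control)),
    stringsAsFactors = FALSE)

  # unit template: 25-gon inscribed in a 2:1 ellipse, hull area normalized to 1
  tt <- 2 * pi * (0:24) / 25
  template <- cbind(2 * cos(tt), sin(tt), 0)
  a0 <- polygon_area(template[, 1:2])
  template <- template / sqrt(a0)

  skull <- vector("list", nrow(design))
  molar <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    trt <- design$arm[i] == "treatment"
    # skull: segment of exact length in random orientation + endpoint jitter
    len <- skull_base + if (trt) skull_effect else 0
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    p0 <- stats::rnorm(3, 0, 5)
    pts <- rbind(p0, p0 + len * dir)
    if (skull_noise_sd > 0)
      pts <- pts + matrix(stats::rnorm(6, 0, skull_noise_sd / sqrt(2)), 2)
    skull[[i]] <- landmark_set(design$specimen_id[i],
                               c("foramen_magnum_apex", "maxillae_junction"),
                               pts, role = "skull")
    # molar: planar template scaled to target hull area, rigid 3D motion
    area <- crown_base + (if (trt) crown_effect else 0) +
      (if (crown_area_sd > 0) stats::rnorm(1, 0, crown_area_sd) else 0)
    if (area <= 0)
      dp_stop("drawn crown area is non-positive; reduce crown_area_sd",
              "dentproteo_validation_error")
    pts25 <- template * sqrt(area)
    pts25 <- pts25 %*% t(random_rotation())
    pts25 <- sweep(pts25, 2, stats::rnorm(3, 0, 5), "+")
    if (landmark_noise_sd > 0)
      pts25 <- pts25 + matrix(stats::rnorm(75, 0, landmark_noise_sd), 25)
    molar[[i]] <- landmark_set(design$specimen_id[i],
                               sprintf("crown_%02d", 1:25), pts25,
                               role = "molar")
  }
  list(skull = skull, molar = molar, design = design,
       effects = c(skull_length_mm = skull_effect,
                   crown_area_mm2 = crown_effect))
}
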