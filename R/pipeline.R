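# End-to-end orchestration: QC filtering per batch, batch intersection,
# ratio/significance computation, CGSig selection, fold-change and
# enrichment reports, landmark phenotyping, volcano exports, and a
# machine-readable run manifest.

#' Pipeline configuration
#'
#' Either `synthetic` is a list of [synthetic_config()] arguments (synthetic
#' mode: inputs are generated) or the `group1`/`group2`/`design` paths must
#' point to quantification tables in the [read_quant_table()] dialect.
#'
#' @param output_dir directory for all outputs (created if needed).
#' @param seed top-level seed; every stage seed is derived from it
#'   deterministically as `(seed * 1009 + stage) mod (2^31 - 1)`.
#' @param synthetic list of [synthetic_config()] overrides, or `NULL` for
#'   file mode.
#' @param group1,group2 paths to per-batch protein tables (file mode).
#' @param peptides_g1,peptides_g2 optional companion peptide tables.
#' @param design path to the specimen design TSV (file mode).
#' @param gmt path to a GMT pathway file; in synthetic mode `NULL` means
#'   pathways are generated (`n_pathways`, `n_enriched`, `enriched_frac`,
#'   `pathway_sizes`).
#' @param categories optional CSV path with columns `accession`,`category`
#'   for the report table.
#' @param landmark_skull_dir,landmark_molar_dir optional directories of
#'   fiducial files (file mode); `landmark_design` maps their specimen ids
#'   to arms. In synthetic mode landmarks are generated (`landmarks` list
#'   of [generate_landmark_sets()] overrides).
#' @param landmark_design path to a TSV with `specimen_id` and `arm`.
#' @param landmarks list of [generate_landmark_sets()] overrides
#'   (synthetic mode).
#' @param thresholds a [qc_thresholds()].
#' @param alpha adjusted-p significance threshold.
#' @param cap log2 censoring bound.
#' @param epsilon stability threshold for the mean fold change.
#' @param max_missing missingness tolerance of [select_cgsig()].
#' @param background enrichment background size `N`; defaults to the
#'   synthetic universe size in synthetic mode and to 11017 otherwise.
#' @param alternative sidedness of the phenotype tests.
#' @param n_pathways,n_enriched,enriched_frac,pathway_sizes synthetic
#'   pathway annotation parameters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed = 1L, synthetic = NULL,
                            group1 = NULL, group2 = NULL,
                            peptides_g1 = NULL, peptides_g2 = NULL,
                            design = NULL, gmt = NULL, categories = NULL,
                            landmark_skull_dir = NULL,
                            landmark_molar_dir = NULL,
                            landmark_design = NULL, landmarks = list(),
                            thresholds = qc_thresholds(), alpha = 0.05,
                            cap = 3.32, epsilon = 0.3, max_missing = 1L,
                            background = NULL, alternative = "a_greater",
                            n_pathways = 100L, n_enriched = 5L,
                            enriched_frac = 0.8,
                            pathway_sizes = c(15L, 500L)) {
  cfg <- as.list(environment())
  if (alpha <= 0 || alpha > 1 || cap <= 0 || epsilon < 0 || max_missing < 0)
    dp_stop("numeric parameter outside its documented range",
            "dentproteo_validation_error")
  if (is.null(synthetic)) {
    for (p in c(group1, group2, design))
      if (!file.exists(p))
        dp_stop(sprintf("input path does not exist: %s", p),
                "dentproteo_validation_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; keys are [pipeline_config()] arguments.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$thresholds)) raw$thresholds <- do.call(qc_thresholds,
                                                          raw$thresholds)
  do.call(pipeline_config, raw)
}

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage) %% 2147483647)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg[order(names(cfg))], f, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: per-batch QC filtering; batch intersection (CG);
#' normalization, pairwise ratios and per-comparison significance; CGSig
#' selection; fold-change summarization (`table1.csv`); pathway
#' over-representation (`table2.csv`); landmark phenotyping
#' (`table3.csv`); per-comparison volcano exports; and a JSON manifest
#' with the configuration hash, seed and stage-by-stage record counts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return The manifest, invisibly also written to
#'   `<output_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outfile <- function(name) file.path(config$output_dir, name)

  truth <- NULL; pathways <- NULL; lms <- NULL; lm_design <- NULL
  if (!is.null(config$synthetic)) {
    sargs <- config$synthetic
    sargs$seed <- stage_seed(config$seed, 1L)
    scfg <- do.call(synthetic_config, sargs)
    exp <- generate_quant_experiment(scfg)
    g1 <- exp$group1; g2 <- exp$group2; design <- exp$design
    truth <- exp$truth
    if (is.null(config$gmt)) {
      ps <- generate_pathway_sets(truth$universe, names(truth$planted),
                                  n_pathways = config$n_pathways,
                                  size_range = config$pathway_sizes,
                                  n_enriched = config$n_enriched,
                                  enriched_frac = config$enriched_frac,
                                  seed = stage_seed(config$seed, 2L))
      pathways <- ps$pathways
      truth$enriched_pathways <- ps$enriched_ids
    } else pathways <- read_gmt(config$gmt)
    largs <- config$landmarks
    largs$seed <- stage_seed(config$seed, 3L)
    lgen <- do.call(generate_landmark_sets, largs)
    lms <- lgen[c("skull", "molar")]
    lm_design <- lgen$design
    truth$landmark_effects <- lgen$effects
    background <- if (is.null(config$background)) scfg$n_proteins
                  else config$background
  } else {
    design <- read_design(config$design)
    g1 <- read_quant_table(config$group1, design,
                           peptide_path = config$peptides_g1)
    g2 <- read_quant_table(config$group2, design,
                           peptide_path = config$peptides_g2)
    pathways <- if (!is.null(config$gmt)) read_gmt(config$gmt)
    if (!is.null(config$landmark_design)) {
      lm_design <- utils::read.delim(config$landmark_design,
                                     stringsAsFactors = FALSE)
      read_dir <- function(dir, role) if (!is.null(dir))
        lapply(list.files(dir, full.names = TRUE), read_landmarks,
               role = role)
      lms <- list(skull = read_dir(config$landmark_skull_dir, "skull"),
                  molar = read_dir(config$landmark_molar_dir, "molar"))
    }
    background <- if (is.null(config$background)) 11017L
                  else config$background
  }

  n_mapped <- c(group1 = nrow(g1$quant), group2 = nrow(g2$quant))
  q1 <- apply_qc(g1, config$thresholds)
  q2 <- apply_qc(g2, config$thresholds)
  say("qc: group1 %d -> %d, group2 %d -> %d", n_mapped[1], nrow(q1$quant),
      n_mapped[2], nrow(q2$quant))

  cg <- intersect_groups(q1, q2)
  writeLines(cg, outfile("cg.txt"))
  say("combined group: %d proteins", length(cg))

  r1 <- compute_ratios(q1, cap = config$cap)
  r2 <- compute_ratios(q2, cap = config$cap)
  ratios <- rbind(r1, r2)
  utils::write.csv(ratios, outfile("ratios.csv"), row.names = FALSE)

  cgsig <- select_cgsig(r1, r2, cg, alpha = config$alpha,
                        max_missing = config$max_missing)
  writeLines(cgsig, outfile("cgsig.txt"))
  say("retained %d, discarded %d for missingness, CGSig %d",
      attr(cgsig, "n_retained"), attr(cgsig, "n_discarded"), length(cgsig))

  records <- summarize_cgsig(ratios, cgsig, alpha = config$alpha,
                             epsilon = config$epsilon)
  categories <- character(0)
  if (!is.null(config$categories)) {
    cm <- utils::read.csv(config$categories, stringsAsFactors = FALSE)
    categories <- stats::setNames(cm$category, cm$accession)
  }
  genes <- stats::setNames(g1$quant$gene, g1$quant$accession)
  utils::write.csv(build_table1(records, categories, genes),
                   outfile("table1.csv"), row.names = FALSE)

  enr <- NULL
  if (!is.null(pathways) && length(cgsig)) {
    enr <- enrich(cgsig, pathways, N = background, alpha = 0.05)
    utils::write.csv(enr, outfile("table2.csv"), row.names = FALSE)
    say("enrichment: %d pathways hit, %d significant", nrow(enr),
        sum(enr$significant))
  }

  pheno <- NULL
  if (!is.null(lms) && !is.null(lm_design)) {
    pheno <- phenotype_table(lms$skull, lms$molar, lm_design,
                             alternative = config$alternative)
    utils::write.csv(pheno, outfile("table3.csv"), row.names = FALSE)
  }

  volcano_dir <- outfile("volcano")
  dir.create(volcano_dir, showWarnings = FALSE)
  for (cid in unique(ratios$comparison_id)) {
    v <- ratios[ratios$comparison_id == cid & !ratios$missing, ]
    utils::write.csv(
      data.frame(accession = v$accession, log2_ratio = v$log2_ratio,
                 neg_log10_adj_p = -log10(v$adj_p_value)),
      file.path(volcano_dir, paste0(gsub("[:/]", "_", cid), ".csv")),
      row.names = FALSE)
  }

  if (!is.null(truth))
    jsonlite::write_json(
      list(planted = as.list(truth$planted),
           enriched_pathways = truth$enriched_pathways,
           landmark_effects = as.list(truth$landmark_effects)),
      outfile("truth.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "dentproteo",
    version = as.character(utils::packageVersion("dentproteo")),
    seed = config$seed,
    config_hash = config_hash(unclass(config)),
    parameters = list(alpha = config$alpha, cap = config$cap,
                      epsilon = config$epsilon,
                      max_missing = config$max_missing,
                      background = background,
                      thresholds = unclass(config$thresholds)),
    counts = list(
      mapped_group1 = unname(n_mapped[1]),
      mapped_group2 = unname(n_mapped[2]),
      qc_group1 = nrow(q1$quant), qc_group2 = nrow(q2$quant),
      cg = length(cg),
      retained = attr(cgsig, "n_retained"),
      discarded_missing = attr(cgsig, "n_discarded"),
      cgsig = length(cgsig),
      pathways_tested = if (is.null(enr)) 0L else nrow(enr),
      enriched = if (is.null(enr)) 0L else sum(enr$significant)))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
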