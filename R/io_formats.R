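# Readers/writers for the external formats the pipeline touches:
# protein quantification tables (TSV), peptide-level abundance tables (TSV),
# pathway sets (GMT), specimen design tables (TSV), and landmark files
# (3D-Slicer-style fiducial CSV).

dp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dentproteo_error")))
}

#' Specimen design table
#'
#' Builds and validates the design table describing every specimen in the
#' experiment: which LC-MS/MS batch it was acquired in, which dietary arm it
#' belongs to, and its litter of origin.
#'
#' @param specimen_id character vector of unique specimen identifiers.
#' @param batch batch label per specimen, one of `"group1"`, `"group2"`.
#' @param arm `"treatment"` or `"control"` per specimen.
#' @param litter_id litter identifier per specimen.
#' @param sex optional sex per specimen (`NA` allowed).
#' @return A `data.frame` with class `specimen_design`.
#' @export
specimen_design <- function(specimen_id, batch, arm, litter_id,
                            sex = NA_character_) {
  d <- data.frame(specimen_id = as.character(specimen_id),
                  batch = as.character(batch),
                  arm = as.character(arm),
                  litter_id = as.character(litter_id),
                  sex = rep_len(as.character(sex), length(specimen_id)),
                  stringsAsFactors = FALSE)
  validate_design(d)
  class(d) <- c("specimen_design", "data.frame")
  d
}

validate_design <- function(d) {
  if (anyDuplicated(d$specimen_id))
    dp_stop("duplicate specimen_id in design", "dentproteo_validation_error")
  if (!all(d$batch %in% c("group1", "group2")))
    dp_stop("batch must be 'group1' or 'group2'", "dentproteo_validation_error")
  if (!all(d$arm %in% c("treatment", "control")))
    dp_stop("arm must be 'treatment' or 'control'", "dentproteo_validation_error")
  for (b in unique(d$batch)) {
    arms <- d$arm[d$batch == b]
    if (!all(c("treatment", "control") %in% arms))
      dp_stop(sprintf("batch '%s' lacks a treatment or control specimen", b),
              "dentproteo_validation_error")
  }
  invisible(d)
}

#' One batch of protein quantification data
#'
#' Container for a single LC-MS/MS batch: the per-protein identification
#' metadata, the protein-level abundance matrix (one column per specimen,
#' `NA` = missing), optional peptide-level abundances, and the design rows
#' for the batch's specimens.
#'
#' @param batch batch label (`"group1"` or `"group2"`).
#' @param quant `data.frame` with columns `accession`, `gene`,
#'   `description`, `q_value`, `n_peptides`, `n_psms`.
#' @param abundance numeric matrix, rows named by accession (same order as
#'   `quant`), columns named by specimen id; entries positive or `NA`.
#' @param design design rows (see [specimen_design()]) covering at least
#'   the abundance columns.
#' @param peptides optional peptide-level abundance table: `data.frame`
#'   with columns `accession`, `peptide_id` and one numeric column per
#'   specimen.
#' @return An object of class `group_dataset`.
#' @export
group_dataset <- function(batch, quant, abundance, design, peptides = NULL) {
  if (anyDuplicated(quant$accession))
    dp_stop("duplicate accession in quantification table",
            "dentproteo_duplicate_error")
  if (any(quant$q_value < 0 | quant$q_value > 1, na.rm = TRUE))
    dp_stop("q_value outside [0, 1]", "dentproteo_validation_error")
  if (nrow(quant) != nrow(abundance))
    dp_stop("quant and abundance row counts differ",
            "dentproteo_validation_error")
  rownames(abundance) <- quant$accession
  if (!all(colnames(abundance) %in% design$specimen_id))
    dp_stop("abundance columns contain specimens absent from the design",
            "dentproteo_validation_error")
  if (any(abundance <= 0, na.rm = TRUE))
    dp_stop("abundances must be positive (missing values are empty cells, not 0)",
            "dentproteo_validation_error")
  has_obs <- rowSums(!is.na(abundance)) > 0
  if (nrow(quant) && any(quant$n_peptides >= 1 & !has_obs))
    dp_stop("record with n_peptides >= 1 but no observed abundance",
            "dentproteo_validation_error")
  design <- design[design$batch == batch, , drop = FALSE]
  structure(list(batch = batch, quant = quant, abundance = abundance,
                 peptides = peptides, design = design),
            class = "group_dataset")
}

#' @export
print.group_dataset <- function(x, ...) {
  cat(sprintf("<group_dataset> batch %s: %d proteins x %d specimens%s\n",
              x$batch, nrow(x$quant), ncol(x$abundance),
              if (is.null(x$peptides)) "" else
                sprintf(" (+%d peptide rows)", nrow(x$peptides))))
  invisible(x)
}

abundance_col <- function(id) paste0("Abundance: ", id)

#' Read a protein quantification table
#'
#' Parses the tab-separated per-protein export dialect: mandatory columns
#' `Accession`, `q-value`, `Peptides`, `PSMs`; optional `Gene` and
#' `Description`; and one `Abundance: <specimen_id>` column per designed
#' specimen of the batch. Column order is irrelevant; unparseable or empty
#' abundance cells become missing (`NA`).
#'
#' @param path path to the TSV file.
#' @param design design table (see [specimen_design()]).
#' @param batch batch label; inferred from the abundance columns when `NULL`.
#' @param peptide_path optional path of a companion peptide-level table
#'   (see [read_peptide_table()]).
#' @return A [group_dataset()].
#' @export
read_quant_table <- function(path, design, batch = NULL, peptide_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("Accession", "q-value", "Peptides", "PSMs")) {
    if (!col %in% names(tab))
      dp_stop(sprintf("mandatory column '%s' missing from %s", col, path),
              "dentproteo_format_error")
  }
  ab_cols <- grep("^Abundance: ", names(tab), value = TRUE)
  ids <- sub("^Abundance: ", "", ab_cols)
  ord <- order(match(ids, design$specimen_id))   # canonical design order
  ab_cols <- ab_cols[ord]; ids <- ids[ord]
  if (is.null(batch)) {
    batches <- unique(design$batch[match(ids, design$specimen_id)])
    batches <- batches[!is.na(batches)]
    if (length(batches) != 1)
      dp_stop("cannot infer a unique batch from the abundance columns",
              "dentproteo_format_error")
    batch <- batches
  }
  if (anyDuplicated(tab$Accession))
    dp_stop(sprintf("duplicate accession in %s", path),
            "dentproteo_duplicate_error")
  num <- function(x) suppressWarnings(as.numeric(x))
  quant <- data.frame(
    accession = tab$Accession,
    gene = if ("Gene" %in% names(tab)) tab$Gene else NA_character_,
    description = if ("Description" %in% names(tab)) tab$Description
                  else NA_character_,
    q_value = num(tab[["q-value"]]),
    n_peptides = as.integer(num(tab$Peptides)),
    n_psms = as.integer(num(tab$PSMs)),
    stringsAsFactors = FALSE)
  abundance <- vapply(ab_cols, function(cl) num(tab[[cl]]),
                      numeric(nrow(tab)))
  abundance <- matrix(abundance, nrow = nrow(tab),
                      dimnames = list(quant$accession, ids))
  peptides <- if (!is.null(peptide_path)) read_peptide_table(peptide_path)
  group_dataset(batch, quant, abundance, design, peptides = peptides)
}

#' Write a protein quantification table
#'
#' Emits the dialect accepted by [read_quant_table()]; missing abundances
#' are written as empty cells.
#'
#' @param dataset a [group_dataset()].
#' @param path output file path.
#' @export
write_quant_table <- function(dataset, path) {
  q <- dataset$quant
  out <- data.frame(Accession = q$accession, Gene = q$gene,
                    Description = q$description, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out[["q-value"]] <- q$q_value
  out[["Peptides"]] <- q$n_peptides
  out[["PSMs"]] <- q$n_psms
  ab <- dataset$abundance
  for (id in colnames(ab)) out[[abundance_col(id)]] <- ab[, id]
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a peptide-level abundance table
#'
#' Long-format companion to the protein table: tab-separated with columns
#' `Accession`, `Peptide` and one `Abundance: <specimen_id>` column per
#' specimen. Missing cells are empty.
#'
#' @param path file path.
#' @return A `data.frame` with columns `accession`, `peptide_id` and one
#'   numeric abundance column per specimen.
#' @export
read_peptide_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("Accession", "Peptide"))
    if (!col %in% names(tab))
      dp_stop(sprintf("mandatory column '%s' missing from %s", col, path),
              "dentproteo_format_error")
  ab_cols <- grep("^Abundance: ", names(tab), value = TRUE)
  out <- data.frame(accession = tab$Accession, peptide_id = tab$Peptide,
                    stringsAsFactors = FALSE)
  for (cl in ab_cols)
    out[[sub("^Abundance: ", "", cl)]] <-
      suppressWarnings(as.numeric(tab[[cl]]))
  out
}

#' @rdname read_peptide_table
#' @param peptides peptide table as returned by [read_peptide_table()].
#' @export
write_peptide_table <- function(peptides, path) {
  out <- data.frame(Accession = peptides$accession,
                    Peptide = peptides$peptide_id,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (id in setdiff(names(peptides), c("accession", "peptide_id")))
    out[[abundance_col(id)]] <- peptides[[id]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT pathway annotation file
#'
#' Each non-empty line is `id<TAB>name<TAB>member<TAB>member...`. Duplicate
#' members within a line are removed; a pathway's size `K` is the number of
#' distinct members.
#'
#' @param path path to the GMT file.
#' @return A list of pathway sets, each a list with elements `pathway_id`,
#'   `name` and `members` (character vector, deduplicated).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 3)
      dp_stop(sprintf("GMT line %d has fewer than 3 fields", i),
              "dentproteo_format_error")
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      dp_stop(sprintf("GMT line %d has no members", i),
              "dentproteo_format_error")
    out[[i]] <- list(pathway_id = fields[[1]], name = fields[[2]],
                     members = members)
  }
  out
}

#' @rdname read_gmt
#' @param pathways list of pathway sets.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$pathway_id, p$name, p$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Ordered 3D landmark set for one specimen
#'
#' @param specimen_id specimen identifier.
#' @param labels landmark labels, in anatomical order.
#' @param coords numeric matrix (n x 3) of xyz coordinates in mm.
#' @param role `"skull"` (exactly 2 landmarks) or `"molar"` (exactly 25);
#'   inferred from the landmark count when `NULL`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(specimen_id, labels, coords, role = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || !all(is.finite(coords)))
    dp_stop("landmark coordinates must be a finite n x 3 matrix",
            "dentproteo_validation_error")
  n <- nrow(coords)
  if (is.null(role)) {
    role <- if (n == 2) "skull" else if (n == 25) "molar" else
      dp_stop(sprintf("cannot infer role from %d landmarks", n),
              "dentproteo_validation_error")
  }
  needed <- switch(role, skull = 2L, molar = 25L,
                   dp_stop(sprintf("unknown landmark role '%s'", role),
                           "dentproteo_validation_error"))
  if (n != needed)
    dp_stop(sprintf("role '%s' requires %d landmarks, got %d",
                    role, needed, n), "dentproteo_validation_error")
  rownames(coords) <- labels
  structure(list(specimen_id = specimen_id, labels = as.character(labels),
                 coords = coords, role = role), class = "landmark_set")
}

#' Read a fiducial landmark file
#'
#' Parses 3D-Slicer-style fiducial markup: comment lines start with `#`,
#' data rows are comma-separated `id,x,y,z,...` with the landmark label in
#' the 12th field when present (full Slicer layout), in the 5th for the
#' compact `id,x,y,z,label` dialect, and falling back to the row id.
#'
#' @param path path to the landmark file.
#' @param specimen_id specimen identifier; defaults to the file name.
#' @param role declared role, or `NULL` to infer from the landmark count.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, specimen_id = NULL, role = NULL) {
  if (is.null(specimen_id))
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    dp_stop(sprintf("no landmark rows in %s", path), "dentproteo_format_error")
  rows <- strsplit(lines, ",", fixed = TRUE)
  coords <- matrix(NA_real_, length(rows), 3)
  labels <- character(length(rows))
  for (i in seq_along(rows)) {
    f <- trimws(rows[[i]])
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (length(f) < 4 || anyNA(xyz))
      dp_stop(sprintf("non-numeric coordinate on landmark row %d of %s",
                      i, path), "dentproteo_format_error")
    coords[i, ] <- xyz
    labels[[i]] <- if (length(f) >= 12) f[[12]]
                   else if (length(f) >= 5) f[[5]] else f[[1]]
  }
  landmark_set(specimen_id, labels, coords, role = role)
}

#' @rdname read_landmarks
#' @param lm a [landmark_set()].
#' @export
write_landmarks <- function(lm, path) {
  header <- c("# Markups fiducial file (compact dialect)",
              "# columns = id,x,y,z,label")
  rows <- sprintf("%d,%.10g,%.10g,%.10g,%s", seq_len(nrow(lm$coords)),
                  lm$coords[, 1], lm$coords[, 2], lm$coords[, 3], lm$labels)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read/write a specimen design table (TSV)
#'
#' @param path file path.
#' @return A [specimen_design()] table.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("specimen_id", "batch", "arm", "litter_id"))
    if (!col %in% names(tab))
      dp_stop(sprintf("mandatory column '%s' missing from %s", col, path),
              "dentproteo_format_error")
  specimen_design(tab$specimen_id, tab$batch, tab$arm, tab$litter_id,
                  sex = if ("sex" %in% names(tab)) tab$sex else NA)
}

#' @rdname read_design
#' @param design a [specimen_design()] table.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     na = "", row.names = FALSE)
  invisible(path)
}
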