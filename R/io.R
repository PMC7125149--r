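# Readers and writers for the plain-text formats the pipeline touches:
# abundance TSV (isoform x sample), sample-sheet TSV, GMT gene sets, result
# tables. All readers validate before returning; no malformed file reaches a
# compute step.

#' Validate an abundance table against its sample sheet
#'
#' Checks the joint invariants of an isoform-by-sample abundance tibble and
#' its sample sheet: unique isoform and sample ids, exact agreement between
#' sheet rows and matrix columns, non-negative finite abundances, fraction
#' labels from `c("input", "monosome", "polysome")`, exactly two stages, and
#' at least two replicates per (stage, fraction) cell.
#'
#' @param abundance Tibble with `isoform_id` plus one numeric column per sample.
#' @param samples Tibble with `sample_id`, `stage`, `fraction`, `replicate`.
#' @return Invisibly, a list with `abundance`, `samples` and the ordered
#'   `stages` vector (earlier stage first, taken from sheet order).
#' @export
validate_abundance <- function(abundance, samples) {
  if (!is.data.frame(abundance) || !"isoform_id" %in% names(abundance)) {
    abort("`abundance` must be a data frame with an `isoform_id` column.",
          class = "polystate_validation_error")
  }
  required <- c("sample_id", "stage", "fraction", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    abort(paste0("Sample sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "polystate_validation_error")
  }
  dup_iso <- abundance$isoform_id[duplicated(abundance$isoform_id)]
  if (length(dup_iso)) {
    abort(paste0("Duplicate isoform id(s): ",
                 paste(unique(dup_iso), collapse = ", ")),
          class = "polystate_validation_error")
  }
  dup_sample <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup_sample)) {
    abort(paste0("Duplicate sample id(s): ",
                 paste(unique(dup_sample), collapse = ", ")),
          class = "polystate_validation_error")
  }
  matrix_samples <- setdiff(names(abundance), "isoform_id")
  if (!setequal(matrix_samples, samples$sample_id)) {
    off <- c(setdiff(matrix_samples, samples$sample_id),
             setdiff(samples$sample_id, matrix_samples))
    abort(paste0("Matrix columns and sample sheet disagree on: ",
                 paste(off, collapse = ", ")),
          class = "polystate_validation_error")
  }
  bad_fraction <- !samples$fraction %in% .fractions
  if (any(bad_fraction)) {
    abort(sprintf(
      "Unknown fraction label '%s' for sample '%s' (allowed: %s).",
      samples$fraction[bad_fraction][1], samples$sample_id[bad_fraction][1],
      paste(.fractions, collapse = ", ")),
      class = "polystate_validation_error")
  }
  vals <- as.matrix(abundance[matrix_samples])
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    abort("Abundance values must be numeric and finite with no missing entries.",
          class = "polystate_validation_error")
  }
  if (any(vals < 0)) {
    bad_row <- which(rowSums(vals < 0) > 0)[1]
    abort(sprintf("Negative abundance for isoform '%s'.",
                  abundance$isoform_id[bad_row]),
          class = "polystate_validation_error")
  }
  stages <- unique(samples$stage)
  if (length(stages) != 2L) {
    abort("Exactly two stages are required (earlier listed first in the sheet).",
          class = "polystate_validation_error")
  }
  cell_n <- dplyr::count(samples, .data$stage, .data$fraction)
  if (any(cell_n$n < 2L)) {
    abort("Every (stage, fraction) cell needs at least 2 replicates.",
          class = "polystate_validation_error")
  }
  invisible(list(abundance = as_tibble(abundance),
                 samples = as_tibble(samples),
                 stages = stages))
}

#' Read an abundance matrix and its sample sheet
#'
#' Reads a tab-delimited isoform-by-sample abundance table (first column
#' `isoform_id`, one column per sample) together with a sample sheet
#' (`sample_id`, `stage`, `fraction`, `replicate`) and validates them jointly.
#' Row and column order are preserved from the files; the earlier stage is the
#' one listed first in the sample sheet.
#'
#' @param matrix_path Path to the abundance TSV.
#' @param sample_sheet_path Path to the sample-sheet TSV.
#' @return A list with tibbles `abundance` and `samples`.
#' @export
read_abundance <- function(matrix_path, sample_sheet_path) {
  abundance <- readr::read_tsv(matrix_path, show_col_types = FALSE,
                               progress = FALSE)
  samples <- readr::read_tsv(sample_sheet_path, show_col_types = FALSE,
                             progress = FALSE,
                             col_types = readr::cols(
                               sample_id = "c", stage = "c",
                               fraction = "c", replicate = "i"))
  checked <- validate_abundance(abundance, samples)
  list(abundance = checked$abundance, samples = checked$samples)
}

#' Write an abundance matrix and sample sheet to TSV
#'
#' @param sim A list with `abundance` and `samples` tibbles (and optionally
#'   `truth`), as returned by [simulate_polysome_experiment()] or
#'   [read_abundance()].
#' @param matrix_path,sample_sheet_path,truth_path Output paths; `truth_path`
#'   is only used when `sim$truth` is present.
#' @return Invisibly, the paths written.
#' @export
write_abundance <- function(sim, matrix_path, sample_sheet_path,
                            truth_path = NULL) {
  readr::write_tsv(sim$abundance, matrix_path, progress = FALSE)
  readr::write_tsv(sim$samples, sample_sheet_path, progress = FALSE)
  paths <- c(matrix_path, sample_sheet_path)
  if (!is.null(sim$truth) && !is.null(truth_path)) {
    readr::write_tsv(sim$truth, truth_path, progress = FALSE)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per tab-separated line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members within
#' a line are collapsed; the description column does not contribute members.
#'
#' @param path Path to the GMT file.
#' @return A named list of unique character vectors, with set descriptions in
#'   the `"descriptions"` attribute. An empty file gives an empty collection.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(structure(list(), descriptions = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.",
                  short[1]),
          class = "polystate_parse_error")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) {
    abort("GMT file contains duplicate set names.",
          class = "polystate_parse_error")
  }
  structure(sets, descriptions = setNames(
    vapply(fields, `[[`, "", 2L), names(sets)))
}

#' Write result tables to TSV files
#'
#' Writes each named tibble to `<out_dir>/<name>.tsv` with a header and a
#' stable column order. Re-running on identical inputs produces byte-identical
#' files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a named character vector of file paths.
#' @export
write_results <- function(tables, out_dir) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("`tables` must be a fully named list.",
          class = "polystate_validation_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(tables[[nm]]), path, progress = FALSE)
    path
  }, character(1))
  invisible(paths)
}
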