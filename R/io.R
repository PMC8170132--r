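#' Read an MRM transition-area export
#'
#' Reads a transition CSV with columns `peptide, sequence, condition,
#' timepoint_h, replicate, transition_id, area`. Skyline-style "Transition
#' Results" exports with different column names can be mapped via `col_map`.
#'
#' @param path CSV file.
#' @param col_map optional named character vector mapping required column
#'   names to the names used in the file, e.g.
#'   `c(peptide = "Peptide", area = "Area", ...)`.
#' @return tibble of transition areas.
#' @export
read_transitions <- function(path, col_map = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      check_that(col_map[[std]] %in% names(x), "col_map",
                 sprintf("file has no column '%s' (mapped to '%s')", col_map[[std]], std))
      names(x)[names(x) == col_map[[std]]] <- std
    }
  }
  needed <- c("peptide", "condition", "timepoint_h", "replicate", "transition_id", "area")
  check_that(all(needed %in% names(x)), "path",
             paste("transition file must provide columns:", paste(needed, collapse = ", ")))
  dplyr::mutate(x, condition = as.character(.data$condition))
}

#' Read a per-sample beta-2-microglobulin peak-area table
#' @param path CSV with columns `condition, timepoint_h, replicate, b2m_area`.
#' @return tibble.
#' @export
read_b2m <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_that(all(c("condition", "replicate", "b2m_area") %in% names(x)),
             "path", "b2m file must provide condition, replicate, b2m_area")
  dplyr::mutate(x, condition = as.character(.data$condition))
}

#' Read fluorescence-polarisation traces
#' @param path CSV with columns `condition, time_h` and either `S, P` or `mP`.
#' @return tibble.
#' @export
read_fp_traces <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_that("time_h" %in% names(x) &&
               (all(c("S", "P") %in% names(x)) || "mP" %in% names(x)),
             "path", "FP trace file must provide time_h and S/P or mP")
  x
}

#' Read a gel densitometry table
#' @param path CSV with columns `assay, replicate, chase_min, temperature_C,
#'   band, intensity`.
#' @return tibble.
#' @export
read_gels <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_that(all(c("assay", "chase_min", "band", "intensity") %in% names(x)),
             "path", "gel file must provide assay, chase_min, band, intensity")
  x
}

#' Read an LFQ protein-intensity matrix with its group assignment
#' @param path TSV with `protein_id`, optional flag columns, sample columns.
#' @return tibble.
#' @export
read_lfq_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write the synthetic MRM dataset as CSV files
#'
#' Writes `transitions.csv`, `b2m.csv` and `mrm_truth.csv` into `dir`.
#' @param sim output of [gen_mrm_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_mrm_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$transitions, file.path(dir, "transitions.csv"))
  readr::write_csv(sim$b2m, file.path(dir, "b2m.csv"))
  readr::write_csv(sim$truth, file.path(dir, "mrm_truth.csv"))
  invisible(dir)
}
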