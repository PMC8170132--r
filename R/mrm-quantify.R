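#' Normalised abundance profiles from MRM transition areas
#'
#' Converts a transition-area table into per-peptide, per-condition normalised
#' abundance profiles. For each (peptide, condition, replicate) the abundance
#' is the summed area of the detected transitions divided by that sample's
#' beta-2-microglobulin UV peak area (the yield of purified class I
#' complexes); undetected transitions contribute zero. Replicates are averaged
#' per condition and every value is finally divided by the peptide's maximum
#' condition mean (the constant-exposure condition participates in this
#' maximum), so the largest mean is exactly 1 whenever any signal exists.
#'
#' @param transitions tibble with columns `peptide, condition, timepoint_h,
#'   replicate, transition_id, area` (a `sequence` column, if present, is
#'   carried through). `area` 0 or NA means the transition was not detected.
#' @param b2m tibble with columns `condition, replicate, b2m_area` giving the
#'   per-sample normaliser; every sample in `transitions` must be covered.
#' @param detection_floor areas at or below this value count as undetected
#'   (default 0, i.e. any positive area is a detection).
#' @return tibble with one row per (peptide, condition): `peptide`,
#'   (`sequence`,) `condition`, `timepoint_h`, `mean_norm_abundance`,
#'   `sd_norm_abundance`, `n_replicates`, `n_detected_replicates`,
#'   `norm_replicates` (list column of per-replicate normalised values) and
#'   `zero_at_t0` (TRUE when more than half of the t = 0 replicates had no
#'   detected transition).
#' @export
quantify <- function(transitions, b2m, detection_floor = 0) {
  needed <- c("peptide", "condition", "timepoint_h", "replicate", "transition_id", "area")
  check_that(all(needed %in% names(transitions)), "transitions",
             paste("must have columns", paste(needed, collapse = ", ")))
  check_that(all(c("condition", "replicate", "b2m_area") %in% names(b2m)),
             "b2m", "must have columns condition, replicate, b2m_area")
  check_that(all(b2m$b2m_area > 0), "b2m", "b2m_area must be > 0")
  check_that(all(is.na(transitions$area) | transitions$area >= 0),
             "transitions", "areas must be >= 0")

  missing_b2m <- dplyr::anti_join(
    dplyr::distinct(transitions, .data$condition, .data$replicate),
    b2m, by = c("condition", "replicate"))
  if (nrow(missing_b2m) > 0) {
    abort(sprintf(
      "missing b2m_area for sample(s): %s",
      paste(sprintf("(condition=%s, replicate=%s)",
                    missing_b2m$condition, missing_b2m$replicate),
            collapse = ", ")))
  }

  has_seq <- "sequence" %in% names(transitions)
  tr <- dplyr::mutate(transitions,
                      detected = !is.na(.data$area) & .data$area > detection_floor,
                      area_used = ifelse(.data$detected, .data$area, 0))

  by_rep <- tr |>
    dplyr::group_by(.data$peptide, .data$condition, .data$timepoint_h, .data$replicate) |>
    dplyr::summarise(total_area = sum(.data$area_used),
                     any_detected = any(.data$detected), .groups = "drop") |>
    dplyr::left_join(b2m[, c("condition", "replicate", "b2m_area")],
                     by = c("condition", "replicate")) |>
    dplyr::mutate(abundance = .data$total_area / .data$b2m_area)

  by_cond <- by_rep |>
    dplyr::group_by(.data$peptide, .data$condition, .data$timepoint_h) |>
    dplyr::summarise(mean_abundance = mean(.data$abundance),
                     sd_abundance = if (dplyr::n() > 1) sd(.data$abundance) else NA_real_,
                     n_replicates = dplyr::n(),
                     n_detected_replicates = sum(.data$any_detected),
                     replicates = list(.data$abundance), .groups = "drop")

  norm <- by_cond |>
    dplyr::group_by(.data$peptide) |>
    dplyr::mutate(peak = max(.data$mean_abundance)) |>
    dplyr::ungroup()

  zeros <- unique(norm$peptide[norm$peak == 0])
  if (length(zeros) > 0) {
    warn(sprintf("peptide(s) with no detected signal in any condition: %s",
                 paste(zeros, collapse = ", ")))
  }
  norm <- dplyr::mutate(norm,
                        scale = ifelse(.data$peak > 0, .data$peak, 1),
                        mean_norm_abundance = .data$mean_abundance / .data$scale,
                        sd_norm_abundance = .data$sd_abundance / .data$scale,
                        norm_replicates = Map(`/`, .data$replicates, .data$scale))

  t0_flag <- norm |>
    dplyr::filter(!is.na(.data$timepoint_h) & .data$timepoint_h == 0) |>
    dplyr::mutate(zero_at_t0 = (.data$n_replicates - .data$n_detected_replicates) >
                    .data$n_replicates / 2) |>
    dplyr::select("peptide", "zero_at_t0")

  out <- norm |>
    dplyr::left_join(t0_flag, by = "peptide") |>
    dplyr::select("peptide", "condition", "timepoint_h", "mean_norm_abundance",
                  "sd_norm_abundance", "n_replicates", "n_detected_replicates",
                  "norm_replicates", "zero_at_t0")

  if (has_seq) {
    seqs <- dplyr::distinct(transitions, .data$peptide, .data$sequence)
    out <- dplyr::left_join(out, seqs, by = "peptide") |>
      dplyr::relocate("sequence", .after = "peptide")
  }
  dplyr::arrange(out, .data$peptide, !is.na(.data$timepoint_h), .data$timepoint_h)
}

#' Least-squares slope of the abundance time course
#'
#' Fits an ordinary least-squares regression of normalised abundance against
#' exposure time (hours) over the time-course conditions; the constant-exposure
#' condition is excluded. By default the regression is fit to the per-condition
#' replicate means (the quantity plotted in abundance time courses); set
#' `fit_to = "replicates"` to fit every replicate value individually.
#'
#' @param profiles output of [quantify()] (one or more peptides).
#' @param fit_to `"means"` (default) or `"replicates"`.
#' @return tibble `peptide, slope, intercept, n_timepoints` with slope in
#'   normalised abundance per hour.
#' @export
fit_slope <- function(profiles, fit_to = c("means", "replicates")) {
  fit_to <- match.arg(fit_to)
  tc <- dplyr::filter(profiles, !is.na(.data$timepoint_h))
  out <- tc |>
    dplyr::group_by(.data$peptide) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$timepoint_h) < 3) {
        abort(sprintf("peptide %s: need >= 3 time points for regression, got %d",
                      key$peptide, dplyr::n_distinct(d$timepoint_h)))
      }
      if (fit_to == "means") {
        x <- d$timepoint_h
        y <- d$mean_norm_abundance
      } else {
        x <- rep(d$timepoint_h, lengths(d$norm_replicates))
        y <- unlist(d$norm_replicates)
      }
      fit <- lm(y ~ x)
      tibble::tibble(slope = unname(coef(fit)[2]),
                     intercept = unname(coef(fit)[1]),
                     n_timepoints = dplyr::n_distinct(d$timepoint_h))
    }) |>
    dplyr::ungroup()
  out
}
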