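#' Thresholds for the four-way drug-impact classification
#'
#' Houses the decision thresholds used by [classify_peptides()]:
#' a peptide is *inhibited* when its abundance-vs-time slope is below
#' `-slope_threshold`, *facilitated* or *dependent* when above
#' `+slope_threshold` (split on whether the peptide was undetected before
#' exposure), and otherwise *minimal* unless the constant-exposure signal
#' exceeds `constant_ratio_threshold` times the untreated signal, in which
#' case it is promoted to *facilitated*. Slopes exactly at the threshold fall
#' into *minimal* (the rule set uses strict inequalities on both sides, so the
#' closed boundary is assigned to the neutral class).
#'
#' @param slope_threshold slope magnitude cut, normalised abundance per hour.
#' @param constant_ratio_threshold constant-to-untreated signal ratio above
#'   which a slope-neutral peptide is still called facilitated.
#' @param fit_to passed to [fit_slope()] (`"means"` or `"replicates"`).
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(slope_threshold = 0.02,
                              constant_ratio_threshold = 2,
                              fit_to = "means") {
  check_that(is.numeric(slope_threshold) && slope_threshold > 0,
             "slope_threshold", "must be > 0")
  check_that(is.numeric(constant_ratio_threshold) && constant_ratio_threshold > 0,
             "constant_ratio_threshold", "must be > 0")
  structure(list(slope_threshold = slope_threshold,
                 constant_ratio_threshold = constant_ratio_threshold,
                 fit_to = fit_to),
            class = "classifier_config")
}

#' Classify each peptide's drug impact from its abundance profile
#'
#' Applies the four-way rule set to the output of [quantify()]:
#' \describe{
#'   \item{inhibited}{slope < -threshold (`rule_fired = "slope_negative"`).}
#'   \item{dependent}{slope > +threshold and the peptide was undetected at
#'     t = 0 in more than half of the replicates (`"slope_positive_zero"`).}
#'   \item{facilitated}{slope > +threshold with pre-exposure signal
#'     (`"slope_positive_baseline"`), or |slope| <= threshold with a
#'     constant-to-untreated signal ratio above the configured cut
#'     (`"constant_twofold_exception"`).}
#'   \item{minimal}{everything else (`"slope_small"`).}
#' }
#'
#' @param profiles output of [quantify()].
#' @param config a [classifier_config()].
#' @return tibble `peptide, (sequence,) category, slope, intercept,
#'   rule_fired, constant_ratio, zero_at_t0`. `constant_ratio` is the
#'   constant-exposure mean divided by the untreated (t = 0) mean, NA when no
#'   constant condition was measured, Inf when only the constant condition has
#'   signal.
#' @export
classify_peptides <- function(profiles, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  slopes <- fit_slope(profiles, fit_to = config$fit_to)

  per_pep <- profiles |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(
      constant_mean = if (any(.data$condition == "constant"))
        .data$mean_norm_abundance[.data$condition == "constant"][1] else NA_real_,
      t0_mean = if (any(!is.na(.data$timepoint_h) & .data$timepoint_h == 0))
        .data$mean_norm_abundance[!is.na(.data$timepoint_h) & .data$timepoint_h == 0][1]
      else NA_real_,
      zero_at_t0 = .data$zero_at_t0[1],
      .groups = "drop") |>
    dplyr::mutate(constant_ratio = .data$constant_mean / .data$t0_mean)

  calls <- dplyr::left_join(slopes, per_pep, by = "peptide")

  thr <- config$slope_threshold
  rthr <- config$constant_ratio_threshold
  calls <- calls |>
    dplyr::mutate(
      exception = !is.na(.data$constant_ratio) & !is.nan(.data$constant_ratio) &
        .data$constant_ratio > rthr,
      rule_fired = dplyr::case_when(
        .data$slope < -thr ~ "slope_negative",
        .data$slope > thr & .data$zero_at_t0 %in% TRUE ~ "slope_positive_zero",
        .data$slope > thr ~ "slope_positive_baseline",
        .data$exception ~ "constant_twofold_exception",
        TRUE ~ "slope_small"),
      category = dplyr::case_when(
        .data$rule_fired == "slope_negative" ~ "inhibited",
        .data$rule_fired == "slope_positive_zero" ~ "dependent",
        .data$rule_fired %in% c("slope_positive_baseline",
                                "constant_twofold_exception") ~ "facilitated",
        TRUE ~ "minimal"))

  out <- dplyr::select(calls, "peptide", "category", "slope", "intercept",
                       "rule_fired", "constant_ratio", "zero_at_t0")
  if ("sequence" %in% names(profiles)) {
    seqs <- dplyr::distinct(profiles, .data$peptide, .data$sequence)
    out <- dplyr::left_join(out, seqs, by = "peptide") |>
      dplyr::relocate("sequence", .after = "peptide")
  }
  out
}

#' Category counts and C-terminal residue tallies
#'
#' Summarises a set of category calls into per-category counts (all four
#' categories always reported, zeros included) and, when sequences are
#' available, a per-category tally of C-terminal residues — the anchor
#' position whose preference the drug shifts.
#'
#' @param calls output of [classify_peptides()].
#' @return list with `category_counts` (tibble `category, n`) and
#'   `cterm_tally` (tibble `category, residue, n`, or NULL without sequences).
#' @export
summarise_categories <- function(calls) {
  levels <- c("inhibited", "minimal", "facilitated", "dependent")
  counts <- tibble::tibble(category = levels) |>
    dplyr::left_join(dplyr::count(calls, .data$category), by = "category") |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n))

  tally <- NULL
  if ("sequence" %in% names(calls) && nrow(calls) > 0 && !all(is.na(calls$sequence))) {
    tally <- calls |>
      dplyr::filter(!is.na(.data$sequence)) |>
      dplyr::mutate(residue = substr(.data$sequence, nchar(.data$sequence),
                                     nchar(.data$sequence))) |>
      dplyr::count(.data$category, .data$residue, name = "n") |>
      dplyr::arrange(.data$category, dplyr::desc(.data$n))
  }
  list(category_counts = counts, cterm_tally = tally)
}
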