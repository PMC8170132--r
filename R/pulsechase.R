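#' Percentage of EndoH-resistant material
#'
#' Maturation readout of a pulse-chase assay: the fraction of labelled MHC I
#' heavy chain that has acquired resistance to endoglycosidase-H digestion
#' (i.e. has trafficked past the ER/cis-Golgi), as a percentage of the total
#' resistant plus sensitive material: 100 EHR / (EHR + EHS).
#'
#' @param ehr,ehs EndoH-resistant and EndoH-sensitive band intensities
#'   (arbitrary densitometry units, vectorised).
#' @return percentage in \[0, 100\].
#' @examples
#' percent_endoh_resistant(25, 75)  # 25
#' @export
percent_endoh_resistant <- function(ehr, ehs) {
  if (any(ehr < 0) || any(ehs < 0)) abort("band intensities must be >= 0")
  if (any(ehr + ehs == 0)) abort("EHR + EHS must be > 0")
  100 * ehr / (ehr + ehs)
}

#' Recovery after thermal challenge, relative to the 4 degree reference
#'
#' Thermostability readout of a pulse-chase assay: the MHC I band intensity is
#' first normalised to the IgG heavy-chain loading control of its lane, then
#' expressed as a percentage of the matching unchallenged (4 C) lane:
#' 100 (mhc / igg) / (mhc_ref / igg_ref). Values above 100 are possible under
#' densitometry noise and are reported with a warning rather than clamped.
#'
#' @param mhc,igg challenged-lane MHC and IgG band intensities.
#' @param mhc_ref,igg_ref matching 4 C reference-lane intensities.
#' @return percentage recovery (>= 0, may exceed 100).
#' @examples
#' thermostability_recovery(30, 1, 60, 1)  # 50
#' @export
thermostability_recovery <- function(mhc, igg, mhc_ref, igg_ref) {
  if (any(c(mhc, igg, mhc_ref, igg_ref) < 0)) abort("band intensities must be >= 0")
  if (any(igg == 0) || any(igg_ref == 0)) abort("IgG loading-control bands must be > 0")
  if (any(mhc_ref == 0)) abort("4 C reference MHC band must be > 0")
  out <- 100 * (mhc / igg) / (mhc_ref / igg_ref)
  if (any(out > 100)) {
    warn("recovery above 100% (densitometry noise); values reported unclamped")
  }
  out
}

#' Maturation time course from a gel table
#'
#' Computes the percentage of EndoH-resistant material per replicate and
#' chase time from a long-format gel densitometry table.
#'
#' @param gels tibble with columns `assay, replicate, chase_min, band,
#'   intensity`; rows with `assay == "maturation"` and bands `EHR`/`EHS` are
#'   used.
#' @return tibble `replicate, chase_min, percent_ehr`.
#' @export
maturation_timecourse <- function(gels) {
  mat <- dplyr::filter(gels, .data$assay == "maturation")
  wide <- tidyr::pivot_wider(
    dplyr::select(mat, "replicate", "chase_min", "band", "intensity"),
    names_from = "band", values_from = "intensity")
  check_that(all(c("EHR", "EHS") %in% names(wide)), "gels",
             "maturation rows must provide EHR and EHS bands")
  dplyr::transmute(wide, replicate = .data$replicate, chase_min = .data$chase_min,
                   percent_ehr = percent_endoh_resistant(.data$EHR, .data$EHS))
}

#' Thermostability time course from a gel table
#'
#' Joins every thermally challenged lane (37/50 C) to its 4 C reference at
#' the same replicate and chase time and computes the IgG-normalised
#' percentage recovery.
#'
#' @param gels tibble with columns `assay, replicate, chase_min,
#'   temperature_C, band, intensity`; rows with `assay == "thermostability"`
#'   and bands `MHC`/`IgG` are used. Every (replicate, chase time) must
#'   include a 4 C lane.
#' @return tibble `replicate, chase_min, temperature_C, percent_recovery`.
#' @export
thermostability_timecourse <- function(gels) {
  th <- dplyr::filter(gels, .data$assay == "thermostability")
  wide <- tidyr::pivot_wider(
    dplyr::select(th, "replicate", "chase_min", "temperature_C", "band", "intensity"),
    names_from = "band", values_from = "intensity")
  check_that(all(c("MHC", "IgG") %in% names(wide)), "gels",
             "thermostability rows must provide MHC and IgG bands")
  ref <- dplyr::filter(wide, .data$temperature_C == 4) |>
    dplyr::select("replicate", "chase_min", MHC_ref = "MHC", IgG_ref = "IgG")
  test <- dplyr::filter(wide, .data$temperature_C != 4)
  joined <- dplyr::inner_join(test, ref, by = c("replicate", "chase_min"))
  if (nrow(joined) < nrow(test)) {
    abort("every thermostability sample needs a matching 4 C reference lane")
  }
  dplyr::transmute(joined, replicate = .data$replicate,
                   chase_min = .data$chase_min,
                   temperature_C = .data$temperature_C,
                   percent_recovery = thermostability_recovery(
                     .data$MHC, .data$IgG, .data$MHC_ref, .data$IgG_ref))
}

#' Mean and standard deviation across replicate experiments
#'
#' Summarises per-replicate percentages into the mean +/- sample SD per
#' grouping cell (assay condition, chase time, temperature, ...), the form in
#' which pulse-chase time courses are plotted. Cells with a single replicate
#' report an NA standard deviation and are flagged.
#'
#' @param records tibble of per-replicate values.
#' @param value name of the value column to summarise.
#' @param ... grouping columns (tidy-select, unquoted).
#' @return tibble with grouping columns plus `mean, sd, n, single_replicate`.
#' @export
summarise_timecourse <- function(records, value, ...) {
  val <- rlang::enquo(value)
  records |>
    dplyr::group_by(...) |>
    dplyr::summarise(mean = mean(!!val),
                     sd = if (dplyr::n() > 1) sd(!!val) else NA_real_,
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(single_replicate = .data$n == 1)
}
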