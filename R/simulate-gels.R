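#' Generate synthetic pulse-chase gel densitometry tables
#'
#' Emulates the band-quantitation output of two radio-label pulse-chase
#' assays on MHC I molecules:
#'
#' * maturation: at each chase time the labelled heavy chain partitions into
#'   an EndoH-resistant (EHR, post-ER) and an EndoH-sensitive (EHS, ER
#'   resident) band; the planted fraction of EHR material fixes the band
#'   ratio.
#' * thermostability: at each chase time the lysate is split and challenged
#'   at 4/37/50 degrees C before immunoprecipitation; the planted per-
#'   temperature survival fraction scales the MHC band relative to the 4 C
#'   reference, and every lane carries an IgG heavy-chain loading-control
#'   band (Coomassie) against which the MHC band is later normalised.
#'
#' Band intensities carry multiplicative lognormal noise; ratios computed
#' downstream reproduce the planted values up to that noise.
#'
#' @param ehr_fraction named numeric vector of planted EHR fractions in
#'   (0, 1], names are chase times in minutes. Defaults follow the maturation
#'   regime of a chaperone-sufficient cell (~85 percent EHR by 60 min).
#' @param survival named list: one entry per temperature (e.g. `"37"`, `"50"`),
#'   each a numeric vector of survival fractions named by chase minute.
#'   A 4 C reference lane (survival 1) is always emitted.
#' @param n_replicates replicate experiments per assay.
#' @param total_intensity total labelled material per maturation lane pair
#'   (arbitrary densitometry units).
#' @param mhc_intensity MHC band intensity at 4 C (arbitrary units).
#' @param igg_intensity mean IgG loading-control intensity.
#' @param noise_cv lognormal CV applied to every band.
#' @param seed integer seed.
#' @return tibble `assay, replicate, chase_min, temperature_C, band, intensity`
#'   with `band` in `EHR`/`EHS` (maturation, `temperature_C` NA) or
#'   `MHC`/`IgG` (thermostability), plus an attribute-free `truth` tibble in a
#'   list: `list(gels, truth)`.
#' @export
gen_pulsechase_gels <- function(ehr_fraction = c(`0` = 0.05, `20` = 0.45,
                                                 `60` = 0.85, `120` = 0.90),
                                survival = list(
                                  `37` = c(`0` = 0.85, `20` = 0.80, `60` = 0.75, `120` = 0.70),
                                  `50` = c(`0` = 0.45, `20` = 0.40, `60` = 0.35, `120` = 0.30)),
                                n_replicates = 3,
                                total_intensity = 100,
                                mhc_intensity = 100,
                                igg_intensity = 50,
                                noise_cv = 0.1,
                                seed = 1L) {
  check_that(is.numeric(ehr_fraction) && !is.null(names(ehr_fraction)) &&
               all(ehr_fraction >= 0 & ehr_fraction <= 1),
             "ehr_fraction", "must be named fractions in [0, 1]")
  check_that(is.list(survival) && length(survival) >= 1 &&
               all(vapply(survival, function(s) all(s >= 0), logical(1))),
             "survival", "must be a per-temperature list of non-negative fractions")
  check_that(all(c(total_intensity, mhc_intensity, igg_intensity) > 0),
             "total_intensity", "band intensities must be > 0")
  check_that(noise_cv >= 0, "noise_cv", "must be >= 0")
  set.seed(as.integer(seed))

  mat <- tidyr::crossing(replicate = seq_len(n_replicates),
                         chase_min = as.numeric(names(ehr_fraction)))
  mat$f <- unname(ehr_fraction[as.character(mat$chase_min)])
  maturation <- dplyr::bind_rows(
    tibble::tibble(assay = "maturation", replicate = mat$replicate,
                   chase_min = mat$chase_min, temperature_C = NA_real_,
                   band = "EHR",
                   intensity = total_intensity * mat$f * rlnorm_cv(nrow(mat), noise_cv)),
    tibble::tibble(assay = "maturation", replicate = mat$replicate,
                   chase_min = mat$chase_min, temperature_C = NA_real_,
                   band = "EHS",
                   intensity = total_intensity * (1 - mat$f) * rlnorm_cv(nrow(mat), noise_cv))
  )

  temps <- c(4, as.numeric(names(survival)))
  chase_t <- as.numeric(names(survival[[1]]))
  thermo_grid <- tidyr::crossing(replicate = seq_len(n_replicates),
                                 chase_min = chase_t, temperature_C = temps)
  surv <- unname(mapply(function(temp, chase) {
    if (temp == 4) 1 else unname(survival[[as.character(temp)]][as.character(chase)])
  }, thermo_grid$temperature_C, thermo_grid$chase_min))
  thermo <- dplyr::bind_rows(
    tibble::tibble(assay = "thermostability", replicate = thermo_grid$replicate,
                   chase_min = thermo_grid$chase_min,
                   temperature_C = thermo_grid$temperature_C, band = "MHC",
                   intensity = mhc_intensity * surv *
                     rlnorm_cv(nrow(thermo_grid), noise_cv)),
    tibble::tibble(assay = "thermostability", replicate = thermo_grid$replicate,
                   chase_min = thermo_grid$chase_min,
                   temperature_C = thermo_grid$temperature_C, band = "IgG",
                   intensity = igg_intensity * rlnorm_cv(nrow(thermo_grid), noise_cv))
  )

  truth <- dplyr::bind_rows(
    tibble::tibble(assay = "maturation", chase_min = as.numeric(names(ehr_fraction)),
                   temperature_C = NA_real_, planted = 100 * unname(ehr_fraction)),
    dplyr::bind_rows(lapply(names(survival), function(temp) {
      tibble::tibble(assay = "thermostability",
                     chase_min = as.numeric(names(survival[[temp]])),
                     temperature_C = as.numeric(temp),
                     planted = 100 * unname(survival[[temp]]))
    }))
  )

  gels <- dplyr::arrange(dplyr::bind_rows(maturation, thermo),
                         .data$assay, .data$replicate, .data$chase_min,
                         .data$temperature_C, .data$band)
  list(gels = gels, truth = truth)
}
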