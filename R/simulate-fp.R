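#' Configuration for the synthetic fluorescence-polarisation trace generator
#'
#' Models the binding of a fluorescently labelled peptide to peptide-receptive
#' MHC I molecules followed in a plate reader. The observable is
#' millipolarisation, mP = 1000 (S - G P) / (S + G P), where S and P are the
#' background-subtracted parallel and perpendicular channel count rates and G
#' the instrument grating factor. Binding follows pseudo-first-order kinetics:
#'
#' * association: mP(t) = mp_free + (mp_bound - mp_free) (1 - exp(-k t))
#' * dissociation: mP(t) = mp_free + (mp_bound - mp_free) exp(-k t)
#'
#' @param conditions subset of `c("intrinsic", "abacavir", "tapasin", "both")`:
#'   peptide alone, with excess drug, with the loading chaperone, or both.
#' @param k_assoc,k_dissoc named per-condition observed association and
#'   dissociation rate constants (per hour). Defaults encode the qualitative
#'   hierarchy seen for drug-facilitated peptides: drug and chaperone each
#'   accelerate loading, together fastest; drug slows dissociation, chaperone
#'   accelerates it.
#' @param mp_free millipolarisation of the unbound labelled peptide (50 mP).
#' @param mp_bound millipolarisation at full binding.
#' @param g_factor instrument grating factor (> 0).
#' @param times_h sampling times in hours (non-decreasing).
#' @param noise_sd_mp Gaussian measurement noise, expressed in mP. Noise is
#'   added to the S and P channel counts; the channel-count sd is calibrated
#'   per time point (delta method) so the propagated mP noise has this sd.
#' @param p_counts perpendicular-channel count level the generator solves the
#'   parallel channel against (raw counts are never reported by plate-reader
#'   software, only mP, so the absolute level is arbitrary).
#' @param seed integer seed.
#' @return an object of class `fp_sim_config`.
#' @export
fp_sim_config <- function(conditions = c("intrinsic", "abacavir", "tapasin", "both"),
                          k_assoc = c(intrinsic = 0.1, abacavir = 0.5,
                                      tapasin = 0.8, both = 1.5),
                          k_dissoc = c(intrinsic = 0.2, abacavir = 0.02,
                                       tapasin = 0.5, both = 0.1),
                          mp_free = 50,
                          mp_bound = 300,
                          g_factor = 1,
                          times_h = seq(0, 6, by = 0.1),
                          noise_sd_mp = 2,
                          p_counts = 1000,
                          seed = 1L) {
  all_cond <- c("intrinsic", "abacavir", "tapasin", "both")
  check_that(length(conditions) >= 1 && all(conditions %in% all_cond),
             "conditions", "must be a subset of intrinsic/abacavir/tapasin/both")
  check_that(all(conditions %in% names(k_assoc)), "k_assoc",
             "must name a rate for every condition")
  check_that(all(conditions %in% names(k_dissoc)), "k_dissoc",
             "must name a rate for every condition")
  check_that(all(k_assoc[conditions] > 0), "k_assoc", "rates must be > 0")
  check_that(all(k_dissoc[conditions] > 0), "k_dissoc", "rates must be > 0")
  check_that(is.numeric(mp_bound) && mp_bound > mp_free, "mp_bound",
             "must exceed mp_free")
  check_that(mp_bound < 1000 && mp_free > -1000, "mp_bound",
             "millipolarisation must lie in (-1000, 1000)")
  check_that(is.numeric(g_factor) && g_factor > 0, "g_factor", "must be > 0")
  check_that(is.numeric(times_h) && !is.unsorted(times_h), "times_h",
             "must be non-decreasing")
  check_that(is.numeric(noise_sd_mp) && noise_sd_mp >= 0, "noise_sd_mp", "must be >= 0")
  check_that(is.numeric(p_counts) && p_counts > 0, "p_counts", "must be > 0")

  structure(
    list(conditions = conditions, k_assoc = k_assoc, k_dissoc = k_dissoc,
         mp_free = mp_free, mp_bound = mp_bound, g_factor = g_factor,
         times_h = times_h, noise_sd_mp = noise_sd_mp, p_counts = p_counts,
         seed = as.integer(seed)),
    class = "fp_sim_config")
}

## Invert mP = 1000 (S - G P)/(S + G P) for S at fixed P.
channels_for_mp <- function(mp, g, p) {
  list(S = g * p * (1000 + mp) / (1000 - mp), P = rep(p, length(mp)))
}

#' Generate synthetic fluorescence-polarisation traces
#'
#' Emits per-condition (S, P) channel counts such that converting them with
#' the configured grating factor recovers the exponential binding model up to
#' the configured noise. With `noise_sd_mp = 0` the round trip through
#' [mp_from_channels()] reproduces the model mP to numerical precision.
#'
#' @param config an [fp_sim_config()].
#' @param mode `"association"` or `"dissociation"`.
#' @return a list with `traces` (tibble `condition, time_h, S, P, mP`, where
#'   `mP` is converted back from the noisy channels) and `truth` (tibble
#'   `condition, mode, k_true, mp_free, mp_bound`).
#' @export
gen_fp_trace <- function(config = fp_sim_config(),
                         mode = c("association", "dissociation")) {
  stopifnot(inherits(config, "fp_sim_config"))
  mode <- match.arg(mode)
  set.seed(config$seed)

  rates <- if (mode == "association") config$k_assoc else config$k_dissoc
  amp <- config$mp_bound - config$mp_free

  traces <- lapply(config$conditions, function(cond) {
    k <- unname(rates[[cond]])
    mp_model <- if (mode == "association") {
      config$mp_free + amp * (1 - exp(-k * config$times_h))
    } else {
      config$mp_free + amp * exp(-k * config$times_h)
    }
    ch <- channels_for_mp(mp_model, config$g_factor, config$p_counts)
    if (config$noise_sd_mp > 0) {
      ## Delta method: sd of mP under independent channel noise sigma_c is
      ## sigma_c * sqrt((dmP/dS)^2 + (dmP/dP)^2); solve for sigma_c.
      denom <- (ch$S + config$g_factor * ch$P)^2
      dS <- 1000 * 2 * config$g_factor * ch$P / denom
      dP <- -1000 * 2 * config$g_factor * ch$S / denom
      sigma_c <- config$noise_sd_mp / sqrt(dS^2 + dP^2)
      ch$S <- ch$S + rnorm(length(ch$S), sd = sigma_c)
      ch$P <- ch$P + rnorm(length(ch$P), sd = sigma_c)
    }
    tibble::tibble(condition = cond, time_h = config$times_h,
                   S = ch$S, P = ch$P,
                   mP = mp_from_channels(ch$S, ch$P, config$g_factor))
  })

  list(
    traces = dplyr::bind_rows(traces),
    truth = tibble::tibble(condition = config$conditions, mode = mode,
                           k_true = unname(rates[config$conditions]),
                           mp_free = config$mp_free, mp_bound = config$mp_bound)
  )
}
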