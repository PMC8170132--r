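#' Configuration for the synthetic MRM time-course generator
#'
#' Describes a targeted-MS experiment in which an MHC-I-expressing cell line is
#' exposed to a groove-binding drug for increasing lengths of time (plus a
#' constant-exposure condition), the class I peptidome is immunoaffinity
#' purified, and a panel of peptides is tracked by MRM transitions. Each
#' peptide belongs to one of four planted impact categories whose normalised
#' abundance trajectories y(t) are:
#'
#' * `inhibited`:   y = exp(-decay_rate * t)
#' * `minimal`:     y = baseline_level (constant)
#' * `facilitated`: y = b + (1 - b) * (1 - exp(-rise_rate * t)), b = facilitated_baseline
#' * `dependent`:   y = 1 - exp(-rise_rate * t) (exactly zero before exposure)
#'
#' The constant-exposure condition is simulated at each trajectory's asymptote
#' (0 for inhibited, the plateau for rising categories, the baseline for
#' minimal).
#'
#' @param n_peptides_per_category named integer vector with entries
#'   `inhibited`, `minimal`, `facilitated`, `dependent`. Defaults mirror the
#'   58-peptide study design (6/20/8/24).
#' @param timepoints_h drug-exposure durations in hours, strictly increasing,
#'   starting at 0 (untreated).
#' @param include_constant also simulate a constant-exposure condition.
#' @param n_replicates biological replicates per condition.
#' @param n_transitions integer range (length 2) of MRM transitions per peptide.
#' @param noise_cv multiplicative lognormal coefficient of variation applied to
#'   every transition area.
#' @param decay_rate,rise_rate trajectory rates, per hour.
#' @param facilitated_baseline pre-exposure level of facilitated peptides
#'   (fraction of plateau).
#' @param baseline_level level of minimal-impact peptides.
#' @param peak_area_scale raw area corresponding to normalised abundance 1 at
#'   the reference beta-2-microglobulin yield.
#' @param b2m_area_mean,b2m_area_cv mean and lognormal CV of the per-sample
#'   beta-2-microglobulin UV peak area (the class-I yield normaliser);
#'   transition areas scale with the sample's realised yield.
#' @param detection_floor raw area below which a transition is reported absent
#'   (area 0).
#' @param cterm_profile named list mapping category to a character vector of
#'   C-terminal residues cycled over that category's peptides. Defaults follow
#'   the anchor-residue composition reported for the 58-peptide panel
#'   (e.g. Trp-rich minimal-impact peptides; Ile/Leu/Val-terminating
#'   drug-dependent peptides).
#' @param seed integer seed; identical config + seed gives identical tables.
#' @return an object of class `mrm_sim_config`.
#' @export
mrm_sim_config <- function(n_peptides_per_category = c(inhibited = 6, minimal = 20,
                                                       facilitated = 8, dependent = 24),
                           timepoints_h = c(0, 2, 4, 6, 12, 16),
                           include_constant = TRUE,
                           n_replicates = 3,
                           n_transitions = c(3L, 5L),
                           noise_cv = 0.2,
                           decay_rate = 0.15,
                           rise_rate = 0.12,
                           facilitated_baseline = 0.2,
                           baseline_level = 1,
                           peak_area_scale = 1e5,
                           b2m_area_mean = 2000,
                           b2m_area_cv = 0.1,
                           detection_floor = 500,
                           cterm_profile = NULL,
                           seed = 1L) {
  cats <- c("inhibited", "minimal", "facilitated", "dependent")
  check_that(is.numeric(n_peptides_per_category) &&
               all(cats %in% names(n_peptides_per_category)) &&
               all(n_peptides_per_category >= 0),
             "n_peptides_per_category",
             "must be a named non-negative vector with entries inhibited/minimal/facilitated/dependent")
  check_that(is.numeric(timepoints_h) && length(timepoints_h) >= 2 &&
               all(diff(timepoints_h) > 0) && timepoints_h[1] == 0,
             "timepoints_h", "must be strictly increasing hours starting at 0")
  check_that(is.numeric(n_replicates) && n_replicates >= 1, "n_replicates", "must be >= 1")
  check_that(is.numeric(n_transitions) && length(n_transitions) == 2 &&
               all(n_transitions >= 1) && n_transitions[1] <= n_transitions[2],
             "n_transitions", "must be an increasing range of counts >= 1")
  check_that(is.numeric(noise_cv) && noise_cv >= 0, "noise_cv", "must be >= 0")
  check_that(is.numeric(decay_rate) && decay_rate >= 0, "decay_rate", "must be >= 0")
  check_that(is.numeric(rise_rate) && rise_rate >= 0, "rise_rate", "must be >= 0")
  check_that(is.numeric(facilitated_baseline) && facilitated_baseline > 0 &&
               facilitated_baseline < 1,
             "facilitated_baseline", "must be in (0, 1)")
  check_that(is.numeric(baseline_level) && baseline_level > 0, "baseline_level", "must be > 0")
  check_that(is.numeric(peak_area_scale) && peak_area_scale > 0, "peak_area_scale", "must be > 0")
  check_that(is.numeric(b2m_area_mean) && b2m_area_mean > 0, "b2m_area_mean", "must be > 0")
  check_that(is.numeric(b2m_area_cv) && b2m_area_cv >= 0, "b2m_area_cv", "must be >= 0")
  check_that(is.numeric(detection_floor) && detection_floor >= 0, "detection_floor", "must be >= 0")

  if (is.null(cterm_profile)) {
    cterm_profile <- list(
      inhibited   = c(rep("F", 3), rep("L", 3)),
      minimal     = c(rep("W", 15), "F", "F", "Y", "I", "L"),
      facilitated = c(rep("I", 3), rep("L", 4), "W"),
      dependent   = c(rep("I", 13), rep("L", 3), rep("V", 8))
    )
  }
  check_that(is.list(cterm_profile) && all(cats %in% names(cterm_profile)),
             "cterm_profile", "must name every category")
  check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed", "must be a scalar")

  structure(
    list(n_peptides_per_category = n_peptides_per_category[cats],
         timepoints_h = timepoints_h, include_constant = include_constant,
         n_replicates = as.integer(n_replicates),
         n_transitions = as.integer(n_transitions), noise_cv = noise_cv,
         decay_rate = decay_rate, rise_rate = rise_rate,
         facilitated_baseline = facilitated_baseline,
         baseline_level = baseline_level, peak_area_scale = peak_area_scale,
         b2m_area_mean = b2m_area_mean, b2m_area_cv = b2m_area_cv,
         detection_floor = detection_floor, cterm_profile = cterm_profile,
         seed = as.integer(seed)),
    class = "mrm_sim_config")
}

## Trajectory of normalised abundance for one category. t = Inf gives the
## constant-exposure asymptote.
mrm_trajectory <- function(category, t, config) {
  switch(category,
    inhibited   = ifelse(is.infinite(t), 0, exp(-config$decay_rate * t)),
    minimal     = rep(config$baseline_level, length(t)),
    facilitated = {
      b <- config$facilitated_baseline
      ifelse(is.infinite(t), 1, b + (1 - b) * (1 - exp(-config$rise_rate * t)))
    },
    dependent   = ifelse(is.infinite(t), 1, 1 - exp(-config$rise_rate * t)),
    abort(sprintf("unknown category '%s'", category))
  )
}

## Random 9-mer with a position-2 anchor typical of the allotype and a planted
## C-terminal residue.
random_sequence <- function(cterm) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p2 <- c("S", "T", "A", "V")
  paste0(paste(c(sample(aa, 1), sample(p2, 1), sample(aa, 6, replace = TRUE)),
               collapse = ""), cterm)
}

#' Generate a synthetic MRM transition-area dataset with planted ground truth
#'
#' Produces one row per (peptide, condition, replicate, transition). Raw areas
#' are the category trajectory times the sample's beta-2-microglobulin yield
#' factor and a per-transition weight, under multiplicative lognormal
#' replicate noise; areas falling below `detection_floor` are reported as 0
#' (explicit absence). Drug-dependent peptides therefore have every transition
#' absent in every untreated (t = 0) replicate by construction.
#'
#' @param config an [mrm_sim_config()].
#' @return a list of three tibbles:
#' \describe{
#'   \item{transitions}{`peptide, sequence, condition, timepoint_h, replicate,
#'     transition_id, area`. `condition` is the exposure time in hours as a
#'     string, or `"constant"`; `timepoint_h` is numeric (NA for constant).}
#'   \item{b2m}{`condition, timepoint_h, replicate, b2m_area` — the per-sample
#'     class-I yield normaliser.}
#'   \item{truth}{`peptide, sequence, category, true_slope_sign`.}
#' }
#' @export
gen_mrm_dataset <- function(config = mrm_sim_config()) {
  stopifnot(inherits(config, "mrm_sim_config"))
  set.seed(config$seed)

  counts <- config$n_peptides_per_category
  categories <- rep(names(counts), counts)
  n_pep <- length(categories)
  ids <- sprintf("pep%03d", seq_len(n_pep))

  sequences <- character(n_pep)
  for (cat in names(counts)) {
    idx <- which(categories == cat)
    if (!length(idx)) next
    cterm <- rep_len(config$cterm_profile[[cat]], length(idx))
    sequences[idx] <- vapply(cterm, random_sequence, character(1))
  }

  conditions <- tibble::tibble(
    condition = c(as.character(config$timepoints_h),
                  if (config$include_constant) "constant"),
    timepoint_h = c(config$timepoints_h, if (config$include_constant) NA_real_)
  )

  samples <- tidyr::crossing(conditions, replicate = seq_len(config$n_replicates))
  samples$b2m_area <- config$b2m_area_mean * rlnorm_cv(nrow(samples), config$b2m_area_cv)

  per_pep <- lapply(seq_len(n_pep), function(i) {
    n_tr <- if (config$n_transitions[1] == config$n_transitions[2]) {
      config$n_transitions[1]
    } else {
      sample(seq(config$n_transitions[1], config$n_transitions[2]), 1)
    }
    w <- runif(n_tr, 0.5, 1.5)
    w <- w / sum(w)
    rows <- tidyr::crossing(samples, transition_id = sprintf("y%d", seq_len(n_tr)))
    rows$peptide <- ids[i]
    rows$sequence <- sequences[i]
    rows <- rows[order(match(rows$condition, conditions$condition),
                       rows$replicate, rows$transition_id), ]
    y_row <- mrm_trajectory(categories[i],
                            ifelse(is.na(rows$timepoint_h), Inf, rows$timepoint_h),
                            config)
    w_row <- w[match(rows$transition_id, sprintf("y%d", seq_len(n_tr)))]
    area <- config$peak_area_scale * y_row * w_row *
      (rows$b2m_area / config$b2m_area_mean) *
      rlnorm_cv(nrow(rows), config$noise_cv)
    rows$area <- ifelse(area < config$detection_floor, 0, area)
    rows[, c("peptide", "sequence", "condition", "timepoint_h",
             "replicate", "transition_id", "area")]
  })

  transitions <- dplyr::bind_rows(per_pep)
  truth <- tibble::tibble(
    peptide = ids, sequence = sequences, category = categories,
    true_slope_sign = c(inhibited = -1, minimal = 0,
                        facilitated = 1, dependent = 1)[categories]
  )

  list(transitions = transitions,
       b2m = samples[, c("condition", "timepoint_h", "replicate", "b2m_area")],
       truth = truth)
}
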