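#' Configuration for the synthetic label-free-quantitation matrix generator
#'
#' Emulates a MaxQuant-style proteinGroups intensity matrix for a two-group
#' whole-proteome comparison (e.g. drug treated vs untreated cultures, three
#' biological replicates each). Per-protein log2 intensities are drawn from a
#' between-protein normal distribution; replicate values add within-protein
#' technical noise; a planted subset of proteins carries a log2 fold change in
#' the treated group. Missing values are generated missing-not-at-random by a
#' logistic left-censoring model: P(missing | log2 intensity x) =
#' plogis(missing_intercept + missing_slope * x), so low-abundance
#' measurements drop out preferentially, as in data-dependent acquisition.
#'
#' @param n_proteins number of proteins. The default mirrors the size of a
#'   proteome comparison in which ~2,300 proteins are reliably quantified.
#' @param n_per_group samples per group (>= 2).
#' @param log2_mean,log2_sd between-protein distribution of mean log2 LFQ
#'   intensity.
#' @param within_sd within-protein replicate sd on the log2 scale.
#' @param n_true_effects number of proteins carrying a planted effect.
#' @param effect_log2fc planted log2 fold change (treated minus untreated).
#' @param missing_intercept,missing_slope logistic missingness parameters;
#'   `missing_slope = 0` with `missing_intercept = -Inf` disables missingness.
#' @param n_contaminants,n_decoys,n_site_only counts of flagged entries
#'   (removed by downstream filtering) appended to the matrix.
#' @param seed integer seed.
#' @return an object of class `lfq_sim_config`.
#' @export
lfq_sim_config <- function(n_proteins = 2306,
                           n_per_group = 3,
                           log2_mean = 26,
                           log2_sd = 2,
                           within_sd = 0.2,
                           n_true_effects = 0,
                           effect_log2fc = 0,
                           missing_intercept = 33.75,
                           missing_slope = -1.5,
                           n_contaminants = 0,
                           n_decoys = 0,
                           n_site_only = 0,
                           seed = 1L) {
  check_that(is.numeric(n_proteins) && n_proteins >= 1, "n_proteins", "must be >= 1")
  check_that(is.numeric(n_per_group) && n_per_group >= 2, "n_per_group", "must be >= 2")
  check_that(is.numeric(log2_sd) && log2_sd > 0, "log2_sd", "must be > 0")
  check_that(is.numeric(within_sd) && within_sd > 0, "within_sd", "must be > 0")
  check_that(is.numeric(n_true_effects) && n_true_effects >= 0 &&
               n_true_effects <= n_proteins,
             "n_true_effects", "must be between 0 and n_proteins")
  p_range <- stats::plogis(missing_intercept +
                             missing_slope * c(log2_mean - 6 * log2_sd,
                                               log2_mean + 6 * log2_sd))
  check_that(all(p_range >= 0 & p_range <= 1), "missing_slope",
             "missing probabilities must lie in [0, 1]")
  structure(
    list(n_proteins = as.integer(n_proteins), n_per_group = as.integer(n_per_group),
         log2_mean = log2_mean, log2_sd = log2_sd, within_sd = within_sd,
         n_true_effects = as.integer(n_true_effects), effect_log2fc = effect_log2fc,
         missing_intercept = missing_intercept, missing_slope = missing_slope,
         n_contaminants = as.integer(n_contaminants), n_decoys = as.integer(n_decoys),
         n_site_only = as.integer(n_site_only), seed = as.integer(seed)),
    class = "lfq_sim_config")
}

#' Generate a synthetic LFQ protein-intensity matrix with planted effects
#'
#' @param config an [lfq_sim_config()].
#' @return a list with:
#' \describe{
#'   \item{matrix}{tibble `protein_id, reverse, contaminant, only_by_site`
#'     plus one linear-intensity column per sample (`treated_1..n`,
#'     `untreated_1..n`); missing entries are NA.}
#'   \item{groups}{tibble `sample, group`.}
#'   \item{truth}{tibble `protein_id, log2fc` (0 for null proteins).}
#' }
#' @export
gen_lfq_matrix <- function(config = lfq_sim_config()) {
  stopifnot(inherits(config, "lfq_sim_config"))
  set.seed(config$seed)

  n <- config$n_proteins
  ng <- config$n_per_group
  samples <- c(sprintf("treated_%d", seq_len(ng)), sprintf("untreated_%d", seq_len(ng)))
  groups <- tibble::tibble(sample = samples,
                           group = rep(c("treated", "untreated"), each = ng))

  base <- rnorm(n, config$log2_mean, config$log2_sd)
  log2fc <- rep(0, n)
  if (config$n_true_effects > 0) {
    log2fc[seq_len(config$n_true_effects)] <- config$effect_log2fc
  }

  log2_mat <- matrix(rnorm(n * 2 * ng, sd = config$within_sd), nrow = n) + base
  treated_cols <- seq_len(ng)
  log2_mat[, treated_cols] <- log2_mat[, treated_cols] + log2fc

  p_missing <- stats::plogis(config$missing_intercept + config$missing_slope * log2_mat)
  miss <- matrix(runif(length(log2_mat)) < p_missing, nrow = n)
  intensity <- 2^log2_mat
  intensity[miss] <- NA_real_
  colnames(intensity) <- samples

  ids <- sprintf("P%05d", seq_len(n))
  mat <- tibble::tibble(protein_id = ids, reverse = FALSE,
                        contaminant = FALSE, only_by_site = FALSE)
  mat <- dplyr::bind_cols(mat, tibble::as_tibble(intensity))

  flagged <- function(n_flag, prefix, which_flag) {
    if (n_flag == 0) return(NULL)
    extra_log2 <- matrix(rnorm(n_flag * 2 * ng, config$log2_mean, config$log2_sd),
                         nrow = n_flag)
    extra <- 2^extra_log2
    colnames(extra) <- samples
    out <- tibble::tibble(protein_id = sprintf("%s%03d", prefix, seq_len(n_flag)),
                          reverse = which_flag == "reverse",
                          contaminant = which_flag == "contaminant",
                          only_by_site = which_flag == "only_by_site")
    dplyr::bind_cols(out, tibble::as_tibble(extra))
  }
  mat <- dplyr::bind_rows(mat,
                          flagged(config$n_decoys, "REV", "reverse"),
                          flagged(config$n_contaminants, "CON", "contaminant"),
                          flagged(config$n_site_only, "SITE", "only_by_site"))

  list(matrix = mat, groups = groups,
       truth = tibble::tibble(protein_id = ids, log2fc = log2fc))
}
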