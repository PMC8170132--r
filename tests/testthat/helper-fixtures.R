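# Shared fixture builders; everything is constructed in code at test time.

# Independent closed-form least-squares slope (the oracle fit_slope is
# checked against): cov(t, y) / var(t) written out directly.
ols_slope_oracle <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# Build a quantify()-shaped profile table directly from per-condition means,
# so classification rules can be exercised on exact hand-chosen numbers.
profile_from_means <- function(peptide, timepoints, means, constant = NULL,
                               zero_at_t0 = FALSE, sequence = NULL) {
  tb <- tibble::tibble(
    peptide = peptide,
    condition = as.character(timepoints),
    timepoint_h = timepoints,
    mean_norm_abundance = means,
    sd_norm_abundance = 0,
    n_replicates = 3L,
    n_detected_replicates = ifelse(means > 0, 3L, 0L),
    norm_replicates = lapply(means, function(m) rep(m, 3)),
    zero_at_t0 = zero_at_t0
  )
  if (!is.null(constant)) {
    tb <- dplyr::bind_rows(tb, dplyr::mutate(tb[1, ],
      condition = "constant", timepoint_h = NA_real_,
      mean_norm_abundance = constant,
      n_detected_replicates = ifelse(constant > 0, 3L, 0L),
      norm_replicates = list(rep(constant, 3))))
  }
  if (!is.null(sequence)) tb$sequence <- sequence
  tb
}

# Minimal hand-built transition + b2m tables: one peptide, named conditions,
# each a list of replicate transition-area vectors, with per-sample b2m areas.
transitions_from_areas <- function(peptide, cond_areas, b2m_area) {
  rows <- list()
  b2m_rows <- list()
  for (cond in names(cond_areas)) {
    reps <- cond_areas[[cond]]
    for (r in seq_along(reps)) {
      areas <- reps[[r]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        peptide = peptide, condition = cond,
        timepoint_h = suppressWarnings(as.numeric(cond)),
        replicate = r, transition_id = sprintf("y%d", seq_along(areas)),
        area = areas)
      b2m_rows[[length(b2m_rows) + 1]] <- tibble::tibble(
        condition = cond, timepoint_h = suppressWarnings(as.numeric(cond)),
        replicate = r, b2m_area = b2m_area)
    }
  }
  list(transitions = dplyr::bind_rows(rows), b2m = dplyr::bind_rows(b2m_rows))
}

# Noiseless exponential binding traces for fit round trips.
assoc_trace <- function(k, t = seq(0, 6, by = 0.05), baseline = 50, A = 200,
                        condition = "test") {
  tibble::tibble(condition = condition, time_h = t,
                 mP = baseline + A * (1 - exp(-k * t)))
}
dissoc_trace <- function(k, t = seq(0, 24, by = 0.25), baseline = 50, A = 200,
                         condition = "test") {
  tibble::tibble(condition = condition, time_h = t,
                 mP = baseline + A * exp(-k * t))
}

# Small complete log2 matrix for the moderated t / permutation machinery.
log2_matrix <- function(n = 200, seed = 1, spike_rows = integer(0),
                        spike_fc = 0, within_sd = 0.2) {
  set.seed(seed)
  base <- rnorm(n, 26, 2)
  X <- matrix(rnorm(n * 6, sd = within_sd), nrow = n) + base
  X[spike_rows, 1:3] <- X[spike_rows, 1:3] + spike_fc
  colnames(X) <- c(sprintf("treated_%d", 1:3), sprintf("untreated_%d", 1:3))
  dplyr::bind_cols(tibble::tibble(protein_id = sprintf("P%04d", seq_len(n))),
                   tibble::as_tibble(X))
}

lfq_groups <- function() {
  tibble::tibble(sample = c(sprintf("treated_%d", 1:3), sprintf("untreated_%d", 1:3)),
                 group = rep(c("treated", "untreated"), each = 3))
}
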