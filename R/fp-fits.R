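## Pull an mP vector out of a trace tibble, converting from channels if needed.
trace_mp <- function(trace, g_factor = 1) {
  if ("mP" %in% names(trace)) return(trace$mP)
  if (all(c("S", "P") %in% names(trace))) {
    return(mp_from_channels(trace$S, trace$P, g_factor))
  }
  abort("trace must carry an mP column or S and P channel columns")
}

binding_fit_row <- function(condition, mode, k, amplitude, baseline, sigma,
                            n_points, converged, no_binding = FALSE,
                            resolvable = TRUE, k_upper = NA_real_,
                            fitted = NULL) {
  tibble::tibble(
    condition = condition, mode = mode, k_per_h = k,
    half_life_h = ifelse(is.na(k), NA_real_, log(2) / k),
    amplitude_mp = amplitude, baseline_mp = baseline, sigma_mp = sigma,
    n_points = n_points, converged = converged, no_binding = no_binding,
    resolvable = resolvable, k_upper_per_h = k_upper,
    fitted = list(fitted))
}

## Log-linearised starting value for the rate constant. z must be the
## remaining fraction (in (0, 1]) at each time.
init_rate <- function(t, z) {
  keep <- z > 0.02 & z <= 1 & t >= 0
  if (sum(keep) >= 2 && stats::var(t[keep]) > 0) {
    k0 <- -unname(coef(lm(log(z[keep]) ~ t[keep]))[2])
    if (is.finite(k0) && k0 > 0) return(k0)
  }
  tpos <- t[t > 0]
  if (length(tpos)) 1 / median(tpos) else 1
}

#' Fit pseudo-first-order association kinetics to a polarisation trace
#'
#' Least-squares fit of mP(t) = baseline + A (1 - exp(-k t)) by
#' Levenberg-Marquardt. The baseline is fixed at the unbound-peptide level
#' (50 mP by default) unless `fix_baseline = FALSE`, in which case it is
#' co-fitted. Traces whose span above baseline is smaller than
#' `no_binding_min` are flagged `no_binding` instead of fitted: with no
#' observable amplitude the rate is unidentifiable.
#'
#' @param trace tibble with `time_h` and either `mP` or `S`/`P` columns; an
#'   optional `condition` column labels the output.
#' @param fix_baseline keep the baseline at `mp_free` (default) or co-fit it.
#' @param mp_free unbound-peptide polarisation, mP.
#' @param g_factor grating factor used when converting channels.
#' @param no_binding_min minimum amplitude (mP) regarded as real binding.
#' @return a one-row tibble (`condition, mode, k_per_h, half_life_h,
#'   amplitude_mp, baseline_mp, sigma_mp, n_points, converged, no_binding,
#'   resolvable, k_upper_per_h, fitted`), where `fitted` is a list column
#'   holding the fitted curve.
#' @export
fit_association <- function(trace, fix_baseline = TRUE, mp_free = 50,
                            g_factor = 1, no_binding_min = 10) {
  t <- trace$time_h
  if (length(t) < 5) abort("association fit needs at least 5 time points")
  mp <- trace_mp(trace, g_factor)
  cond <- if ("condition" %in% names(trace)) trace$condition[1] else NA_character_

  b0 <- mp_free
  a0 <- max(mp) - b0
  if (a0 < no_binding_min) {
    return(binding_fit_row(cond, "association", NA_real_, a0, b0,
                           sd(mp - b0), length(t), converged = TRUE,
                           no_binding = TRUE))
  }
  k0 <- init_rate(t, pmin(pmax(1 - (mp - b0) / a0, 1e-6), 1))

  fit <- tryCatch({
    if (fix_baseline) {
      minpack.lm::nlsLM(mp ~ b0 + A * (1 - exp(-k * t)),
                        start = list(A = a0, k = k0),
                        lower = c(A = 0, k = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(mp ~ b + A * (1 - exp(-k * t)),
                        start = list(b = b0, A = a0, k = k0),
                        lower = c(b = -1000, A = 0, k = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    abort(sprintf(
      "association fit did not converge (best iterate near A = %.3g, k = %.3g): %s",
      a0, k0, conditionMessage(e)))
  })

  est <- coef(fit)
  b_hat <- if (fix_baseline) b0 else unname(est["b"])
  curve <- tibble::tibble(time_h = t, mP = mp,
                          mP_fit = b_hat + unname(est["A"]) *
                            (1 - exp(-unname(est["k"]) * t)))
  binding_fit_row(cond, "association", unname(est["k"]), unname(est["A"]),
                  b_hat, sd(residuals(fit)), length(t),
                  converged = fit$convInfo$isConv %||% TRUE, fitted = curve)
}

#' Fit pseudo-first-order dissociation kinetics to a polarisation trace
#'
#' Least-squares fit of mP(t) = baseline + (mP0 - baseline) exp(-k_off t),
#' returning the off-rate and its half-life ln 2 / k_off. When the fitted
#' decay over the observation window is smaller than 5 percent of the
#' starting amplitude the off-rate is not resolvable from the data: the fit
#' is flagged (`resolvable = FALSE`) and only an upper bound on k_off is
#' reported, rather than a point estimate.
#'
#' @inheritParams fit_association
#' @return a one-row tibble as for [fit_association()], `mode =
#'   "dissociation"`; `amplitude_mp` is the fitted starting amplitude above
#'   baseline.
#' @export
fit_dissociation <- function(trace, fix_baseline = TRUE, mp_free = 50,
                             g_factor = 1) {
  t <- trace$time_h
  if (length(t) < 5) abort("dissociation fit needs at least 5 time points")
  mp <- trace_mp(trace, g_factor)
  cond <- if ("condition" %in% names(trace)) trace$condition[1] else NA_character_

  b0 <- mp_free
  a0 <- mp[which.min(t)] - b0
  if (a0 <= 0) abort("trace starts at or below baseline; nothing to dissociate")
  span <- diff(range(t))

  ## No observable decay across the window: the off-rate is unidentifiable,
  ## so report an upper bound instead of attempting a degenerate fit.
  observed_decay <- (mp[which.min(t)] - mp[which.max(t)]) / a0
  if (observed_decay < 0.05) {
    return(binding_fit_row(cond, "dissociation", NA_real_, a0, b0,
                           sd(mp - mean(mp)), length(t), converged = TRUE,
                           resolvable = FALSE, k_upper = -log(0.95) / span,
                           fitted = tibble::tibble(time_h = t, mP = mp,
                                                   mP_fit = mean(mp))))
  }
  k0 <- init_rate(t, pmin(pmax((mp - b0) / a0, 1e-6), 1))

  fit <- tryCatch({
    if (fix_baseline) {
      minpack.lm::nlsLM(mp ~ b0 + A * exp(-k * t),
                        start = list(A = a0, k = k0),
                        lower = c(A = 0, k = 1e-10),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(mp ~ b + A * exp(-k * t),
                        start = list(b = b0, A = a0, k = k0),
                        lower = c(b = -1000, A = 0, k = 1e-10),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    abort(sprintf(
      "dissociation fit did not converge (best iterate near A = %.3g, k = %.3g): %s",
      a0, k0, conditionMessage(e)))
  })

  est <- coef(fit)
  b_hat <- if (fix_baseline) b0 else unname(est["b"])
  k_hat <- unname(est["k"])
  resolvable <- k_hat * span > -log(0.95)
  curve <- tibble::tibble(time_h = t, mP = mp,
                          mP_fit = b_hat + unname(est["A"]) * exp(-k_hat * t))
  if (!resolvable) {
    return(binding_fit_row(cond, "dissociation", NA_real_, unname(est["A"]),
                           b_hat, sd(residuals(fit)), length(t),
                           converged = fit$convInfo$isConv %||% TRUE,
                           resolvable = FALSE,
                           k_upper = -log(0.95) / span, fitted = curve))
  }
  binding_fit_row(cond, "dissociation", k_hat, unname(est["A"]), b_hat,
                  sd(residuals(fit)), length(t),
                  converged = fit$convInfo$isConv %||% TRUE, fitted = curve)
}

#' Fit every condition of a multi-condition trace table
#'
#' @param traces tibble with `condition, time_h` and `mP` or `S`/`P`.
#' @param mode `"association"` or `"dissociation"`.
#' @param ... passed to [fit_association()] / [fit_dissociation()].
#' @return tibble with one fit row per condition.
#' @export
fit_fp_traces <- function(traces, mode = c("association", "dissociation"), ...) {
  mode <- match.arg(mode)
  fitter <- if (mode == "association") fit_association else fit_dissociation
  dplyr::bind_rows(lapply(split(traces, traces$condition),
                          function(tr) fitter(tr, ...)))
}

#' Enhancement factor of a condition over intrinsic binding
#'
#' For each time point shared by the two traces the polarisation measured in
#' the presence of the co-factor (chaperone, drug, or both) is divided by the
#' intrinsic polarisation and expressed as a percentage; the enhancement
#' factor is the mean of these per-time-point percentages. Time points are
#' matched exactly when the sampling grids coincide, otherwise by nearest
#' neighbour within `time_tol` (default 1 percent of the intrinsic trace
#' span). Only points with positive intrinsic polarisation enter the mean.
#'
#' @param intrinsic,condition trace tibbles with `time_h` and `mP` (or
#'   `S`/`P`) columns.
#' @param time_tol matching tolerance in hours (NULL for the default).
#' @param g_factor grating factor for channel conversion.
#' @return list with `condition` (label, if present), `factor` (percent),
#'   `ratios` (tibble `time_h, ratio_pct`) and `n` (time points used).
#' @examples
#' a <- tibble::tibble(time_h = c(1, 2), mP = c(100, 200))
#' b <- tibble::tibble(time_h = c(1, 2), mP = c(150, 240))
#' enhancement_factor(a, b)$factor  # 135
#' @export
enhancement_factor <- function(intrinsic, condition, time_tol = NULL, g_factor = 1) {
  mp_i <- trace_mp(intrinsic, g_factor)
  mp_c <- trace_mp(condition, g_factor)
  t_i <- intrinsic$time_h
  t_c <- condition$time_h
  if (all(mp_i <= 0)) abort("intrinsic trace has no positive polarisation")

  if (length(t_i) == length(t_c) && isTRUE(all.equal(t_i, t_c))) {
    idx_i <- seq_along(t_i)
    idx_c <- seq_along(t_c)
  } else {
    span <- diff(range(t_i))
    tol <- if (is.null(time_tol)) 0.01 * span else time_tol
    idx_i <- vapply(t_c, function(tt) which.min(abs(t_i - tt)), integer(1))
    ok <- abs(t_i[idx_i] - t_c) <= tol
    idx_c <- which(ok)
    idx_i <- idx_i[ok]
    if (!length(idx_c)) abort("no overlapping time points within tolerance")
  }

  keep <- mp_i[idx_i] > 0
  if (!any(keep)) abort("no matched time points with positive intrinsic polarisation")
  ratios <- tibble::tibble(
    time_h = t_c[idx_c][keep],
    ratio_pct = 100 * mp_c[idx_c][keep] / mp_i[idx_i][keep])

  list(condition = if ("condition" %in% names(condition))
         condition$condition[1] else NA_character_,
       factor = mean(ratios$ratio_pct), ratios = ratios, n = nrow(ratios))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
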