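test_that("millipolarisation conversion matches hand arithmetic and its limits", {
  expect_equal(mp_from_channels(100, 100, 1), 0)
  expect_equal(mp_from_channels(150, 50, 1), 500)
  expect_equal(mp_from_channels(123, 0, 1), 1000)
  expect_error(mp_from_channels(-1, 10, 1), "non-negative")
  expect_error(mp_from_channels(0, 0, 1), "> 0")
  expect_error(mp_from_channels(10, 10, 0), "G")

  # antisymmetry: swapping S with G*P flips the sign
  set.seed(4)
  for (i in 1:20) {
    S <- runif(1, 1, 2000); P <- runif(1, 1, 2000); G <- runif(1, 0.5, 2)
    expect_equal(mp_from_channels(G * P, S / G, G), -mp_from_channels(S, P, G),
                 tolerance = 1e-9)
  }
})

test_that("bound fraction maps linearly onto polarisation", {
  expect_equal(fraction_to_mp(0), 50)
  expect_equal(fraction_to_mp(1, mp_free = 50, mp_bound = 320), 320)
  expect_equal(fraction_to_mp(0.5, mp_free = 50, mp_bound = 250), 150)
  expect_error(fraction_to_mp(1.2), "\\[0, 1\\]")
  expect_error(fraction_to_mp(0.5, mp_free = 100, mp_bound = 90), "mp_bound")
  f <- seq(0, 1, by = 0.05)
  expect_true(all(diff(fraction_to_mp(f)) > 0))
})

test_that("association fits recover noiseless parameters to high precision", {
  fit <- fit_association(assoc_trace(k = 0.5, A = 200))
  expect_true(fit$converged)
  expect_equal(fit$k_per_h, 0.5, tolerance = 1e-6)
  expect_equal(fit$amplitude_mp, 200, tolerance = 1e-4 / 200)
  expect_equal(fit$baseline_mp, 50)

  # co-fitted baseline also lands on the truth
  fit2 <- fit_association(assoc_trace(k = 0.5, baseline = 80), fix_baseline = FALSE)
  expect_equal(fit2$baseline_mp, 80, tolerance = 1e-4)
  expect_equal(fit2$k_per_h, 0.5, tolerance = 1e-5)
})

test_that("flat association traces are flagged as no binding, short traces error", {
  flat <- tibble::tibble(time_h = seq(0, 6, 0.5), mP = rep(50, 13))
  fit <- fit_association(flat)
  expect_true(fit$no_binding)
  expect_true(is.na(fit$k_per_h))
  expect_error(fit_association(assoc_trace(0.5, t = c(0, 1, 2, 3))), "5 time points")
  expect_error(fit_dissociation(dissoc_trace(0.1, t = c(0, 1, 2, 3))), "5 time points")
})

test_that("dissociation fits return the off-rate and half-life", {
  fit <- fit_dissociation(dissoc_trace(k = 0.1))
  expect_equal(fit$k_per_h, 0.1, tolerance = 1e-6)
  expect_equal(fit$half_life_h, log(2) / 0.1, tolerance = 1e-4)
})

test_that("undetectably slow dissociation reports a bound, not a point estimate", {
  nodecay <- tibble::tibble(time_h = seq(0, 6, 0.5), mP = rep(250, 13))
  fit <- fit_dissociation(nodecay)
  expect_false(fit$resolvable)
  expect_true(is.na(fit$k_per_h))
  expect_gt(fit$k_upper_per_h, 0)
})

test_that("fitted off-rate ordering survives measurement noise", {
  for (s in 1:10) {
    cfg_slow <- fp_sim_config(conditions = "intrinsic", k_dissoc = c(intrinsic = 0.05),
                              times_h = seq(0, 24, 0.5), noise_sd_mp = 2, seed = s)
    cfg_fast <- fp_sim_config(conditions = "intrinsic", k_dissoc = c(intrinsic = 0.5),
                              times_h = seq(0, 24, 0.5), noise_sd_mp = 2, seed = s + 500)
    k_slow <- fit_dissociation(gen_fp_trace(cfg_slow, "dissociation")$traces)$k_per_h
    k_fast <- fit_dissociation(gen_fp_trace(cfg_fast, "dissociation")$traces)$k_per_h
    expect_lt(k_slow, k_fast)
  }
})

test_that("simulate-fit round trips keep the median rate error under 5 percent", {
  rel_err <- vapply(1:12, function(s) {
    cfg <- fp_sim_config(conditions = "abacavir", k_assoc = c(abacavir = 2),
                         times_h = seq(0, 6, length.out = 60), noise_sd_mp = 2,
                         seed = s)
    fit <- fit_association(gen_fp_trace(cfg, "association")$traces)
    abs(fit$k_per_h - 2) / 2
  }, numeric(1))
  expect_lt(median(rel_err), 0.05)
})

test_that("enhancement factors match hand-computed means", {
  base <- tibble::tibble(time_h = c(1, 2), mP = c(100, 200))
  expect_equal(enhancement_factor(base, base)$factor, 100)
  expect_equal(enhancement_factor(base, dplyr::mutate(base, mP = mP * 2))$factor, 200)
  cond <- tibble::tibble(time_h = c(1, 2), mP = c(150, 240))
  ef <- enhancement_factor(base, cond)
  expect_equal(ef$factor, 135)
  expect_equal(ef$ratios$ratio_pct, c(150, 120))
})

test_that("enhancement is invariant to a common rescaling and matches by nearest time", {
  base <- tibble::tibble(time_h = 0:5, mP = c(60, 100, 150, 180, 200, 210))
  cond <- dplyr::mutate(base, mP = mP * 1.7)
  f1 <- enhancement_factor(base, cond)$factor
  f2 <- enhancement_factor(dplyr::mutate(base, mP = mP * 3),
                           dplyr::mutate(cond, mP = mP * 3))$factor
  expect_equal(f1, f2, tolerance = 1e-12)

  jitter <- dplyr::mutate(cond, time_h = time_h + 0.01)
  expect_equal(enhancement_factor(base, jitter, time_tol = 0.05)$factor, f1,
               tolerance = 1e-12)
  expect_error(enhancement_factor(base, dplyr::mutate(cond, time_h = time_h + 100),
                                  time_tol = 0.05), "overlap")
  neg <- dplyr::mutate(base, mP = -mP)
  expect_error(enhancement_factor(neg, cond), "positive polarisation")
})
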