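test_that("generators are deterministic under a fixed config and seed", {
  cfg <- mrm_sim_config(n_peptides_per_category = c(inhibited = 2, minimal = 2,
                                                    facilitated = 2, dependent = 2),
                        seed = 42)
  expect_identical(gen_mrm_dataset(cfg), gen_mrm_dataset(cfg))

  fcfg <- fp_sim_config(times_h = seq(0, 4, by = 0.2), seed = 42)
  expect_identical(gen_fp_trace(fcfg, "association"), gen_fp_trace(fcfg, "association"))

  expect_identical(gen_pulsechase_gels(seed = 42), gen_pulsechase_gels(seed = 42))

  lcfg <- lfq_sim_config(n_proteins = 50, seed = 42)
  expect_identical(gen_lfq_matrix(lcfg), gen_lfq_matrix(lcfg))
})

test_that("invalid generator configs are rejected with the field named", {
  expect_error(mrm_sim_config(noise_cv = -0.1), "noise_cv")
  expect_error(mrm_sim_config(timepoints_h = c(0, 4, 2)), "timepoints_h")
  expect_error(mrm_sim_config(n_replicates = 0), "n_replicates")
  expect_error(fp_sim_config(mp_bound = 10), "mp_bound")
  expect_error(fp_sim_config(k_assoc = c(intrinsic = -1, abacavir = 1,
                                         tapasin = 1, both = 1)), "k_assoc")
  expect_error(fp_sim_config(g_factor = 0), "g_factor")
  expect_error(lfq_sim_config(n_per_group = 1), "n_per_group")
  expect_error(gen_pulsechase_gels(total_intensity = -5), "intensit")
})

test_that("zero-noise minimal-impact peptides have identical areas at every time point", {
  cfg <- mrm_sim_config(n_peptides_per_category = c(inhibited = 0, minimal = 1,
                                                    facilitated = 0, dependent = 0),
                        noise_cv = 0, b2m_area_cv = 0, seed = 3)
  tr <- gen_mrm_dataset(cfg)$transitions
  per_tp <- tr |>
    dplyr::group_by(transition_id, replicate) |>
    dplyr::summarise(n_distinct_area = dplyr::n_distinct(round(area, 9)),
                     .groups = "drop")
  expect_true(all(per_tp$n_distinct_area == 1))
})

test_that("dependent peptides are absent at t = 0 in every replicate", {
  cfg <- mrm_sim_config(seed = 5)  # default noise
  sim <- gen_mrm_dataset(cfg)
  dep <- sim$truth$peptide[sim$truth$category == "dependent"]
  t0 <- dplyr::filter(sim$transitions, peptide %in% dep, timepoint_h == 0)
  expect_gt(nrow(t0), 0)
  expect_true(all(t0$area == 0))
})

test_that("FP traces follow the exponential model and channels round-trip exactly", {
  cfg <- fp_sim_config(noise_sd_mp = 0, times_h = seq(0, 8, by = 0.5), seed = 1)
  assoc <- gen_fp_trace(cfg, "association")
  # at t = 0 association starts at the unbound baseline
  t0 <- dplyr::filter(assoc$traces, time_h == 0)
  expect_equal(t0$mP, rep(cfg$mp_free, nrow(t0)), tolerance = 1e-9)

  # model mP reconstructed through the channel equation to <= 1e-9 mP
  k <- cfg$k_assoc["abacavir"]
  tr <- dplyr::filter(assoc$traces, condition == "abacavir")
  model <- cfg$mp_free + (cfg$mp_bound - cfg$mp_free) * (1 - exp(-k * tr$time_h))
  expect_lt(max(abs(mp_from_channels(tr$S, tr$P, cfg$g_factor) - model)), 1e-9)

  # dissociation half-life identity: at t = ln2/k the amplitude has halved
  k_off <- 0.5
  dcfg <- fp_sim_config(conditions = "intrinsic",
                        k_dissoc = c(intrinsic = k_off),
                        times_h = c(0, log(2) / k_off, 5), noise_sd_mp = 0, seed = 1)
  dis <- gen_fp_trace(dcfg, "dissociation")$traces
  amp <- dcfg$mp_bound - dcfg$mp_free
  expect_equal(dis$mP[2] - dcfg$mp_free, amp / 2, tolerance = 1e-9)

  expect_error(gen_fp_trace(cfg, "equilibrium"), "arg")
})

test_that("channel noise calibrated in mP units propagates at the requested sd", {
  sds <- vapply(1:30, function(s) {
    cfg <- fp_sim_config(conditions = "intrinsic", times_h = rep(3, 200),
                         noise_sd_mp = 2, seed = s)
    sd(gen_fp_trace(cfg, "association")$traces$mP)
  }, numeric(1))
  expect_equal(mean(sds), 2, tolerance = 0.1)
})

test_that("planted gel ratios are recovered exactly at zero noise", {
  sim <- gen_pulsechase_gels(ehr_fraction = c(`0` = 0.25), survival = list(`37` = c(`0` = 1)),
                             n_replicates = 1, noise_cv = 0, seed = 1)
  mat <- dplyr::filter(sim$gels, assay == "maturation")
  expect_equal(mat$intensity[mat$band == "EHR"] /
                 sum(mat$intensity), 0.25, tolerance = 1e-12)

  th <- dplyr::filter(sim$gels, assay == "thermostability")
  r37 <- with(dplyr::filter(th, temperature_C == 37),
              intensity[band == "MHC"] / intensity[band == "IgG"])
  r4 <- with(dplyr::filter(th, temperature_C == 4),
             intensity[band == "MHC"] / intensity[band == "IgG"])
  expect_equal(r37, r4, tolerance = 1e-12)
})

test_that("LFQ generator plants effects and missingness as configured", {
  # no planted effects -> all true log2 fold changes are zero
  sim0 <- gen_lfq_matrix(lfq_sim_config(n_proteins = 40, seed = 2))
  expect_true(all(sim0$truth$log2fc == 0))

  # degenerate logistic model (p = 0 everywhere) -> complete matrix
  off <- gen_lfq_matrix(lfq_sim_config(n_proteins = 40, missing_intercept = -Inf,
                                       missing_slope = 0, seed = 2))
  vals <- as.matrix(off$matrix[lfq_groups()$sample])
  expect_false(anyNA(vals))

  # planted effects land on the stated proteins with the stated log2FC
  sim1 <- gen_lfq_matrix(lfq_sim_config(n_proteins = 40, n_true_effects = 3,
                                        effect_log2fc = 2, missing_intercept = -Inf,
                                        missing_slope = 0, within_sd = 0.01, seed = 2))
  m <- as.matrix(sim1$matrix[lfq_groups()$sample])
  diffs <- rowMeans(log2(m[, 1:3])) - rowMeans(log2(m[, 4:6]))
  expect_equal(unname(diffs[1:3]), rep(2, 3), tolerance = 0.1)
  expect_equal(unname(mean(diffs[4:40])), 0, tolerance = 0.1)
})

test_that("realised missingness matches the logistic model's analytic expectation", {
  cfg <- lfq_sim_config(n_proteins = 300, seed = 1)
  marginal_sd <- sqrt(cfg$log2_sd^2 + cfg$within_sd^2)
  expected <- stats::integrate(function(x) {
    stats::plogis(cfg$missing_intercept + cfg$missing_slope * x) *
      stats::dnorm(x, cfg$log2_mean, marginal_sd)
  }, -Inf, Inf)$value

  fractions <- vapply(1:50, function(s) {
    sim <- gen_lfq_matrix(lfq_sim_config(n_proteins = 300, seed = s))
    vals <- as.matrix(sim$matrix[lfq_groups()$sample])
    mean(is.na(vals))
  }, numeric(1))
  expect_lt(abs(mean(fractions) - expected), 0.006)  # Monte-Carlo error margin
})
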