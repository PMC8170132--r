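test_that("abundance is summed detected area over b2m, then max-normalised", {
  # condition "0": replicate sums 6000, 7200, 4800 over b2m 2 -> 3000/3600/2400,
  # mean 3000; condition "16": sums 12000 -> mean 6000 -> peak; norm = 0.5 vs 1
  fx <- transitions_from_areas(
    "pepA",
    list(`0` = list(c(1000, 2000, 3000), c(1200, 2400, 3600), c(800, 1600, 2400)),
         `8` = list(c(2000, 2000, 2000), c(2000, 2000, 2000), c(2000, 2000, 2000)),
         `16` = list(c(4000, 4000, 4000), c(4000, 4000, 4000), c(4000, 4000, 4000))),
    b2m_area = 2)
  prof <- quantify(fx$transitions, fx$b2m)
  expect_equal(prof$mean_norm_abundance[prof$condition == "0"], 0.5)
  expect_equal(prof$mean_norm_abundance[prof$condition == "16"], 1)
  expect_equal(sort(prof$norm_replicates[prof$condition == "0"][[1]]) * 6000,
               c(2400, 3000, 3600))

  # single condition with any signal self-normalises to exactly 1
  single <- transitions_from_areas("pepB", list(`0` = list(c(10, 20))), b2m_area = 4)
  p1 <- quantify(single$transitions, single$b2m)
  expect_identical(p1$mean_norm_abundance, 1)
})

test_that("undetected transitions contribute zero and the t0 absence flag follows majority rule", {
  fx <- transitions_from_areas(
    "pepC",
    list(`0` = list(c(0, 0, 0), c(0, 0, 0), c(100, 200, 0)),
         `16` = list(c(500, 500, 0), c(500, 500, 0), c(500, 500, 0))),
    b2m_area = 1)
  prof <- quantify(fx$transitions, fx$b2m)
  expect_true(all(prof$zero_at_t0))               # 2 of 3 undetected at t = 0
  # t0 mean abundance (0 + 0 + 300)/3 = 100, peak mean 1000 -> normalised 0.1
  expect_equal(prof$mean_norm_abundance[prof$condition == "0"], 0.1, tolerance = 1e-12)

  fx2 <- transitions_from_areas(
    "pepD",
    list(`0` = list(c(100, 0), c(100, 0), c(0, 0)),
         `16` = list(c(500, 0), c(500, 0), c(500, 0))),
    b2m_area = 1)
  expect_false(all(quantify(fx2$transitions, fx2$b2m)$zero_at_t0))  # only 1 of 3
})

test_that("missing b2m areas error naming the sample; all-zero peptides warn", {
  fx <- transitions_from_areas("pepA", list(`0` = list(c(1, 2))), b2m_area = 1)
  expect_error(quantify(fx$transitions, fx$b2m[0, ]), "condition=0, replicate=1")

  zero <- transitions_from_areas("pepZ", list(`0` = list(c(0, 0))), b2m_area = 1)
  expect_warning(pz <- quantify(zero$transitions, zero$b2m), "pepZ")
  expect_equal(pz$mean_norm_abundance, 0)
})

test_that("normalised abundance is invariant to per-sample rescaling", {
  for (s in 1:5) {
    set.seed(s)
    cfg <- mrm_sim_config(n_peptides_per_category = c(inhibited = 1, minimal = 1,
                                                      facilitated = 1, dependent = 1),
                          seed = s)
    sim <- gen_mrm_dataset(cfg)
    scale_tbl <- dplyr::mutate(sim$b2m, fac = runif(dplyr::n(), 0.5, 5))
    tr2 <- sim$transitions |>
      dplyr::left_join(scale_tbl[, c("condition", "replicate", "fac")],
                       by = c("condition", "replicate")) |>
      dplyr::mutate(area = area * fac, fac = NULL)
    b2m2 <- dplyr::mutate(scale_tbl, b2m_area = b2m_area * fac, fac = NULL)
    p1 <- quantify(sim$transitions, sim$b2m)
    p2 <- quantify(tr2, b2m2)
    expect_equal(p2$mean_norm_abundance, p1$mean_norm_abundance, tolerance = 1e-12)
  }
})

test_that("fit_slope agrees with the closed-form least-squares oracle", {
  t <- c(0, 2, 4, 6, 12, 16)

  y_dec <- c(0.8, 0.6, 0.5, 0.4, 0.2, 0.1)
  s_dec <- fit_slope(profile_from_means("p1", t, y_dec))$slope
  expect_equal(s_dec, -7.733333333 / 189.3333333, tolerance = 1e-6)
  expect_equal(s_dec, ols_slope_oracle(t, y_dec), tolerance = 1e-10)

  y_inc <- c(0, 0, 0.1, 0.2, 0.5, 0.8)
  s_inc <- fit_slope(profile_from_means("p2", t, y_inc))$slope
  expect_equal(s_inc, 9.733333333 / 189.3333333, tolerance = 1e-6)
  expect_equal(s_inc, ols_slope_oracle(t, y_inc), tolerance = 1e-10)

  expect_equal(fit_slope(profile_from_means("p3", t, rep(0.7, 6)))$slope, 0,
               tolerance = 1e-12)

  set.seed(99)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    tt <- sort(runif(n, 0, 16))
    yy <- runif(n)
    got <- fit_slope(profile_from_means("p", tt, yy))$slope
    expect_equal(got, ols_slope_oracle(tt, yy), tolerance = 1e-10)
  }

  expect_error(fit_slope(profile_from_means("p", c(0, 16), c(0, 1))),
               "3 time points")
})

test_that("slope can also be fit to individual replicates", {
  t <- c(0, 2, 4, 6, 12, 16)
  prof <- profile_from_means("p", t, c(0.8, 0.6, 0.5, 0.4, 0.2, 0.1))
  # replicates equal their mean here, so both fits agree
  expect_equal(fit_slope(prof, fit_to = "replicates")$slope,
               fit_slope(prof, fit_to = "means")$slope, tolerance = 1e-12)
})

test_that("the four-way rule set fires the documented branches", {
  t <- c(0, 2, 4, 6, 12, 16)
  cfg <- classifier_config()

  dec <- classify_peptides(profile_from_means("p", t, c(0.8, 0.6, 0.5, 0.4, 0.2, 0.1)), cfg)
  expect_equal(dec$category, "inhibited")
  expect_equal(dec$rule_fired, "slope_negative")

  dep <- classify_peptides(profile_from_means("p", t, c(0, 0, 0.1, 0.2, 0.5, 0.8),
                                              zero_at_t0 = TRUE), cfg)
  expect_equal(dep$category, "dependent")
  expect_equal(dep$rule_fired, "slope_positive_zero")

  fac <- classify_peptides(profile_from_means("p", t, c(0.1, 0.1, 0.2, 0.3, 0.6, 0.9),
                                              zero_at_t0 = FALSE), cfg)
  expect_equal(fac$category, "facilitated")
  expect_equal(fac$rule_fired, "slope_positive_baseline")

  # shallow slope (+0.01/h) but constant-exposure signal 2.5x untreated
  y_flat <- 0.3 + 0.01 * t
  exc <- classify_peptides(profile_from_means("p", t, y_flat, constant = 0.75), cfg)
  expect_equal(exc$category, "facilitated")
  expect_equal(exc$rule_fired, "constant_twofold_exception")
  expect_equal(exc$constant_ratio, 2.5)

  noexc <- classify_peptides(profile_from_means("p", t, y_flat, constant = 0.55), cfg)
  expect_equal(noexc$category, "minimal")

  # strict inequalities: slopes just inside the band stay minimal, slopes
  # just outside it switch category (locates the threshold to 1e-4/h)
  for (sgn in c(-1, 1)) {
    inside <- classify_peptides(profile_from_means("p", t, 0.5 + sgn * 0.0199 * t), cfg)
    expect_equal(inside$category, "minimal")
    outside <- classify_peptides(profile_from_means("p", t, 0.5 + sgn * 0.0201 * t), cfg)
    expect_equal(outside$category, if (sgn < 0) "inhibited" else "facilitated")
  }
})

test_that("classification is invariant to row order of the inputs", {
  cfg <- mrm_sim_config(n_peptides_per_category = c(inhibited = 2, minimal = 2,
                                                    facilitated = 2, dependent = 2),
                        seed = 17)
  sim <- gen_mrm_dataset(cfg)
  calls1 <- classify_peptides(quantify(sim$transitions, sim$b2m))
  set.seed(1)
  shuf <- sim$transitions[sample(nrow(sim$transitions)), ]
  shuf_b2m <- sim$b2m[sample(nrow(sim$b2m)), ]
  calls2 <- classify_peptides(quantify(shuf, shuf_b2m))
  expect_equal(dplyr::arrange(calls1, peptide), dplyr::arrange(calls2, peptide))
})

test_that("zero-noise synthetic cohorts are classified back to their planted category", {
  cfg <- mrm_sim_config(n_peptides_per_category = c(inhibited = 3, minimal = 3,
                                                    facilitated = 3, dependent = 3),
                        noise_cv = 0, b2m_area_cv = 0, seed = 23)
  sim <- gen_mrm_dataset(cfg)
  calls <- classify_peptides(quantify(sim$transitions, sim$b2m))
  joined <- dplyr::inner_join(calls, sim$truth, by = "peptide",
                              suffix = c("", "_true"))
  expect_identical(joined$category, joined$category_true)
})

test_that("precursor m/z follows monoisotopic masses plus a proton", {
  expect_equal(round(precursor_mz("C14H18N6O"), 1), 287.2)
  expect_equal(precursor_mz("H"), 1.0078250319 + 1.007276466, tolerance = 1e-9)
  expect_equal(precursor_mz(""), 1.007276466, tolerance = 1e-9)
  expect_equal(precursor_mz(c(C = 14, H = 18, N = 6, O = 1)),
               precursor_mz("C14H18N6O"), tolerance = 1e-12)
  # doubly charged ion of the same molecule
  m <- precursor_mz("C14H18N6O") - 1.007276466
  expect_equal(precursor_mz("C14H18N6O", charge = 2), (m + 2 * 1.007276466) / 2,
               tolerance = 1e-9)
  expect_error(precursor_mz("C3Xx2"), "unknown element")
})

test_that("category summaries count calls and tally C-terminal residues", {
  calls <- tibble::tibble(
    peptide = c("A", "B", "C"),
    sequence = c("KTFTTQETI", "LSSPVTKSI", "ITTKAISRW"),
    category = c("inhibited", "inhibited", "minimal"))
  s <- summarise_categories(calls)
  expect_equal(setNames(s$category_counts$n, s$category_counts$category),
               c(inhibited = 2L, minimal = 1L, facilitated = 0L, dependent = 0L))
  inh <- dplyr::filter(s$cterm_tally, category == "inhibited")
  expect_equal(setNames(inh$n, inh$residue), c(I = 2L))

  empty <- summarise_categories(calls[0, ])
  expect_true(all(empty$category_counts$n == 0))
})
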