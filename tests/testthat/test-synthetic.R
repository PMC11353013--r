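test_that("generators are deterministic under a fixed seed", {
  a <- generate_viability_matrix(noise_sd = 0.05, seed = 5)
  b <- generate_viability_matrix(noise_sd = 0.05, seed = 5)
  expect_identical(a$viability, b$viability)
  c2 <- generate_viability_matrix(noise_sd = 0.05, seed = 6)
  expect_false(identical(a$viability, c2$viability))

  pa <- generate_screen_panel(seed = 3)
  pb <- generate_screen_panel(seed = 3)
  expect_identical(pa$ground_truth, pb$ground_truth)
  expect_identical(pa$matrices[[1]]$viability, pb$matrices[[1]]$viability)
})

test_that("zero-amplitude matrices are exactly Bliss-independent before noise", {
  m <- generate_viability_matrix(bump = list(amplitude = 0,
                                             center = c(0.1, 0.1),
                                             width = 0.5), noise_sd = 0)
  s <- synergy_analysis(m, smooth = FALSE)
  expect_lt(max(abs(s$bliss_excess)), 1e-12)
})

test_that("the generating bump is recovered as Bliss excess (generator as oracle)", {
  bump <- list(amplitude = 0.2, center = c(0.3, 0.2), width = 0.5)
  # floors keep the separable product above the bump, so nothing truncates
  m <- generate_viability_matrix(
    margin_a = ll_margin(lower = 0.5, ec50 = 0.1, hill = 1.5),
    margin_b = ll_margin(lower = 0.6, ec50 = 0.05, hill = 1.5),
    bump = bump, noise_sd = 0)
  s <- synergy_analysis(m, smooth = FALSE)
  g <- combotrans:::synergy_bump(m$doses_a, m$doses_b, bump$amplitude,
                                 bump$center, bump$width)
  # no truncation at these margins, so excess == bump exactly
  expect_equal(s$bliss_excess, g, tolerance = 1e-12)
  expect_equal(s$bliss_score, combotrans:::top_mean(g, 0.1),
               tolerance = 1e-12)
})

test_that("margins of bumped matrices stay exactly log-logistic", {
  m <- generate_viability_matrix(
    bump = list(amplitude = 0.4, center = c(0.3, 0.2), width = 0.6),
    noise_sd = 0)
  gt <- attr(m, "ground_truth")
  ma <- gt$margin_a
  expect_equal(m$viability[, 1],
               ll_fun(m$doses_a, ma$upper, ma$lower, ma$ec50, ma$hill))
})

test_that("panel group contrasts match their configuration", {
  spec <- default_panel_spec()
  diffs <- sapply(1:5, function(s) {
    panel <- generate_screen_panel(spec, seed = s)
    scores <- sapply(panel$matrices, function(m)
      synergy_analysis(m, smooth = FALSE)$bliss_score)
    grp <- panel$ground_truth$group
    mean(scores[grp == "NRAS_Q61"]) - mean(scores[grp == "BRAF_V600"])
  })
  expect_true(all(diffs > 0.1))
})

test_that("configured log10 IC50 group separation is recovered by refitting", {
  spec <- default_panel_spec()
  # two groups differing only by 0.6 decades in the drug-B potency
  spec$groups <- list(
    lo = modifyList(spec$groups$BRAF_V600,
                    list(n = 12, log10_ic50_b = c(mean = -1.8, sd = 0.2))),
    hi = modifyList(spec$groups$BRAF_V600,
                    list(n = 12, log10_ic50_b = c(mean = -1.2, sd = 0.2))))
  spec$noise_sd <- 0.02
  panel <- generate_screen_panel(spec, seed = 4)
  fitted <- sapply(panel$matrices, function(m) {
    f <- fit_dose_response(m$doses_b, m$viability[1, ], "LL4")
    log10(f$ec50)
  })
  grp <- panel$ground_truth$group
  sep <- mean(fitted[grp == "hi"]) - mean(fitted[grp == "lo"])
  expect_lt(abs(sep - 0.6), 0.25)
})

test_that("xenograft volume series honor rate sign and refit exactly", {
  x <- generate_xenograft_volumes(v0 = 240, rate = log(2) / 18,
                                  noise_sd = 0)
  # doubling at day 18 on the noiseless curve
  gt <- attr(x, "ground_truth")
  expect_equal(gt$v0 * exp(gt$rate * 18), 480)
  # log-linear regression recovers the rate exactly without noise
  fit <- lm(log(volume_mm3) ~ day, data = x)
  expect_equal(unname(coef(fit)[2]), log(2) / 18, tolerance = 1e-10)
  expect_equal(unname(exp(coef(fit)[1])), 240, tolerance = 1e-8)

  dec <- generate_xenograft_volumes(v0 = 240, rate = -0.05, noise_sd = 0)
  expect_true(all(diff(dec$volume_mm3) < 0))
})

test_that("TGI cohort generator feeds exact per-subject recovery", {
  cohort <- generate_tgi_cohort(n_subjects = 2, noise_sd = 0, seed = 9)
  for (id in cohort$ground_truth$subject_id) {
    sub <- cohort$data[cohort$data$subject_id == id, ]
    gt <- cohort$ground_truth[cohort$ground_truth$subject_id == id, ]
    f <- fit_tgi(sub$week, sub$tumor_size)
    expect_lt(abs(f$kg - gt$kg) / gt$kg, 1e-3)
    expect_lt(abs(f$ks - gt$ks) / gt$ks, 1e-3)
  }
})

test_that("empty and degenerate panel specs are handled", {
  spec <- default_panel_spec()
  spec$groups <- lapply(spec$groups, function(g) { g$n <- 0; g })
  panel <- generate_screen_panel(spec, seed = 1)
  expect_length(panel$matrices, 0)
  expect_error(generate_screen_panel(list(groups = list()), seed = 1),
               "empty")
})

test_that("a bump center outside the dose grid warns but still generates", {
  expect_warning(
    m <- generate_viability_matrix(
      bump = list(amplitude = 0.2, center = c(100, 100), width = 0.5)),
    "outside")
  expect_s3_class(m, "combination_matrix")
})
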