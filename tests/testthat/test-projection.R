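# constant-concentration fake population helper
const_pop <- function(free_levels, times = seq(0, 26 * 24, by = 12)) {
  out <- do.call(rbind, lapply(seq_along(free_levels), function(i)
    data.frame(individual_id = i, time_h = times,
               total_ngml = NA_real_, free_uM = free_levels[i])))
  attr(out, "ss_window_h") <- c(22, 26) * 24
  out
}

surface_fixture <- function() {
  m <- generate_viability_matrix(
    margin_a = ll_margin(lower = 0.2, ec50 = 0.1, hill = 1.5),
    margin_b = ll_margin(lower = 0.3, ec50 = 0.05, hill = 1.2),
    bump = list(amplitude = 0.15, center = c(0.3, 0.2), width = 0.5),
    noise_sd = 0)
  build_gr_surface(m, smooth = FALSE)
}

test_that("point projection at grid nodes returns stored surface values", {
  surf <- surface_fixture()
  i <- 4; j <- 5
  pr <- project_point(surf, surf$free_doses_a[i], surf$free_doses_b[j])
  expect_equal(pr$gr, surf$gr[i, j])
  expect_equal(pr$bliss_excess, surf$bliss_excess[i, j])
})

test_that("margin queries reduce to single-agent values with no synergy", {
  surf <- surface_fixture()
  pr <- project_point(surf, surf$free_doses_a[6], 0)
  expect_equal(pr$gr, surf$gr[6, 1])
  expect_lt(abs(pr$bliss_excess), 1e-10)
})

test_that("projection on a symmetric surface commutes with axis swap", {
  d <- c(0, 10^seq(-2, 0, length.out = 7))
  z <- outer(seq_along(d), seq_along(d), function(i, j) 0.1 * (i + j))
  surf <- list(free_doses_a = d, free_doses_b = d, gr = z,
               bliss_excess = z)
  a <- project_point(surf, 0.03, 0.3)
  b <- project_point(surf, 0.3, 0.03)
  expect_equal(a$gr, b$gr)
})

test_that("a variability-free population collapses to one trajectory", {
  surf <- surface_fixture()
  popA <- const_pop(rep(0.02, 10))
  popB <- const_pop(rep(0.01, 10))
  ed <- project_population(popA, popB, surf, n_patients = 5, seed = 2)
  expect_equal(unname(diff(ed$gr_quantiles[c(1, 5)])), 0)
  expect_equal(length(unique(round(ed$per_patient_mean$gr, 12))), 1L)
  # hourly sampling over the window: n_patients x (window + 1) samples
  expect_equal(nrow(ed$samples), 5 * 49)
})

test_that("population pairing errors are caught", {
  surf <- surface_fixture()
  expect_error(project_population(const_pop(rep(0.02, 4)),
                                  const_pop(rep(0.01, 6)), surf,
                                  n_patients = 4),
               "pairing")
  expect_error(project_population(const_pop(rep(0.02, 4)),
                                  const_pop(rep(0.01, 4)), surf,
                                  n_patients = 10),
               "pairing")
})

test_that("synergy-box membership matches a direct counting oracle", {
  # surface with synergy only inside a known free-dose box
  d <- c(0, 10^seq(-3, 0, length.out = 10))
  inbox <- function(x) x >= 0.05 & x <= 0.5
  z <- outer(d, d, function(a, b) ifelse(inbox(a) & inbox(b), 1, 0))
  surf <- list(free_doses_a = d, free_doses_b = d,
               gr = z * 0, bliss_excess = z)
  set.seed(8)
  # patient exposures sit on grid nodes straddling the box boundary, so
  # the projected indicator is exact and countable
  conc <- sample(d[2:10], 40, replace = TRUE)
  popA <- const_pop(conc); popB <- const_pop(rep(0.1, 40))
  ed <- project_population(popA, popB, surf, n_patients = 40, seed = 1)
  frac <- mean(ed$per_patient_mean$bliss_excess > 0.5)
  direct <- mean(inbox(conc))
  expect_equal(frac, direct)
})

test_that("regimen-level mean projection lies inside the population band", {
  surf <- surface_fixture()
  set.seed(21)
  concA <- 0.05 * exp(rnorm(30, 0, 0.4))
  concB <- 0.02 * exp(rnorm(30, 0, 0.4))
  popA <- const_pop(concA); popB <- const_pop(concB)
  ed <- project_population(popA, popB, surf, n_patients = 30, seed = 3)
  mean_pr <- project_point(surf, mean(concA), mean(concB))
  expect_gte(mean_pr$gr, ed$gr_quantiles[["5%"]])
  expect_lte(mean_pr$gr, ed$gr_quantiles[["95%"]])
})

test_that("wider PK variability widens the projected GR spread", {
  surf <- surface_fixture()
  iqr_at <- function(omega, seed) {
    set.seed(seed)
    concA <- 0.05 * exp(rnorm(30, 0, omega))
    ed <- project_population(const_pop(concA), const_pop(rep(0.02, 30)),
                             surf, n_patients = 30, seed = 1)
    unname(ed$gr_quantiles[["75%"]] - ed$gr_quantiles[["25%"]])
  }
  wins <- sum(sapply(1:5, function(s) iqr_at(0.6, s) >= iqr_at(0.15, s)))
  expect_gte(wins, 4)
})
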