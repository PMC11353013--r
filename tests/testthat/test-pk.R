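typ <- list(ka = 0.5, cl_f = 5, v_f = 100)

test_that("closed-form single-dose curve matches an ODE integration oracle", {
  times <- seq(0, 48, by = 0.25)
  closed <- combotrans:::conc_superposition(times, 0, 100, typ$ka,
                                            typ$cl_f, typ$v_f)
  ke <- typ$cl_f / typ$v_f
  rhs <- function(t, y, p)
    list(c(-typ$ka * y[1], typ$ka * y[1] / typ$v_f - ke * y[2]))
  ode <- deSolve::lsoda(c(A = 100, C = 0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  ref <- ode[, "C"]
  keep <- ref > max(ref) * 1e-3
  expect_lt(max(abs(closed[keep] - ref[keep]) / ref[keep]), 1e-6)
})

test_that("the ka == ke limiting form is used instead of dividing by zero", {
  times <- seq(0, 24, by = 0.5)
  ka <- 0.2
  c_lim <- combotrans:::conc_superposition(times, 0, 50, ka, ka * 100, 100)
  expect_true(all(is.finite(c_lim)))
  # limit agrees with the two-exponential form at ke = ka(1 +/- eps)
  c_eps <- combotrans:::conc_superposition(times, 0, 50, ka,
                                           ka * 100 * (1 + 1e-7), 100)
  expect_equal(c_lim, c_eps, tolerance = 1e-5)
})

test_that("PK is dose-linear and zero dose gives zero concentration", {
  reg1 <- regimen("drug", 100, "QD", 10)
  p1 <- simulate_individual_pk(typ, reg1, dt = 0.5)
  p2 <- simulate_individual_pk(typ, regimen("drug", 200, "QD", 10), dt = 0.5)
  expect_equal(p2$total_ngml, 2 * p1$total_ngml, tolerance = 1e-12)
  z <- combotrans:::conc_superposition(seq(0, 24, 1), c(0, 12), 0,
                                       typ$ka, typ$cl_f, typ$v_f)
  expect_true(all(z == 0))
})

test_that("omega = 0 steady-state average equals dose rate over clearance", {
  model <- pop_pk_model(ka = 0.5, cl_f = 5, v_f = 100, mw = 478.93,
                        fu_plasma = 0.00258)
  reg <- regimen("belva", 100, "QD", 30)
  pop <- simulate_population_pk(model, reg, n = 3, seed = 1)
  # all individuals identical at omega = 0
  one <- pop[pop$individual_id == 1, ]
  two <- pop[pop$individual_id == 2, ]
  expect_equal(one$total_ngml, two$total_ngml)
  w <- one$time_h >= 22 * 24 & one$time_h <= 26 * 24
  cavg <- mean(one$total_ngml[w])
  cavg_theory <- 100 / (5 * 24) * 1000          # mg/L -> ng/mL
  expect_lt(abs(cavg - cavg_theory) / cavg_theory, 0.02)
})

test_that("BID at half dose matches QD steady-state average within 1%", {
  pop_qd <- simulate_population_pk(
    pop_pk_model(0.5, 5, 100, mw = 478.93, fu_plasma = 0.00258),
    regimen("belva", 200, "QD", 30), n = 1, seed = 1, dt = 0.25)
  pop_bid <- simulate_population_pk(
    pop_pk_model(0.5, 5, 100, mw = 478.93, fu_plasma = 0.00258),
    regimen("belva", 100, "BID", 30), n = 1, seed = 1, dt = 0.25)
  m_qd <- exposure_summary(pop_qd)$mean
  m_bid <- exposure_summary(pop_bid)$mean
  expect_lt(abs(m_qd - m_bid) / m_qd, 0.01)
})

test_that("steady-state accumulation matches the closed-form ratio", {
  ke <- typ$cl_f / typ$v_f
  reg <- regimen("drug", 100, "QD", 30)
  p <- simulate_individual_pk(typ, reg, dt = 0.25)
  trough1 <- p$total_ngml[p$time_h == 23.75]
  trough_ss <- p$total_ngml[p$time_h == 29 * 24 - 0.25]
  r_theory <- 1 / (1 - exp(-ke * 24))
  expect_lt(abs(trough_ss / trough1 - r_theory) / r_theory, 0.005)
})

test_that("lognormal parameter draws have the right geometric mean", {
  model <- pop_pk_model(0.5, 13, 800, omega_cl = 0.3, omega_v = 0.3,
                        omega_ka = 0.5, mw = 531.3, fu_plasma = 0.052)
  reg <- regimen("cobi", 40, "QD", 2)
  pop <- simulate_population_pk(model, reg, n = 500, seed = 11, dt = 1)
  pars <- attr(pop, "parameters")
  gm_cl <- exp(mean(log(pars$cl_f)))
  se <- 0.3 / sqrt(500)
  expect_lt(abs(log(gm_cl) - log(13)), 3 * se)
})

test_that("identical seeds reproduce profiles bit-identically", {
  model <- default_pk_model("cobimetinib")
  reg <- regimen("cobi", 20, "QOD", 8)
  a <- simulate_population_pk(model, reg, n = 5, seed = 99, dt = 1)
  b <- simulate_population_pk(model, reg, n = 5, seed = 99, dt = 1)
  expect_identical(a$total_ngml, b$total_ngml)
  c2 <- simulate_population_pk(model, reg, n = 5, seed = 100, dt = 1)
  expect_false(identical(a$total_ngml, c2$total_ngml))
})

test_that("free molar conversion applies the printed constants literally", {
  expect_equal(to_free_molar(478.93, 478.93, 0.00258), 0.00258)
  expect_equal(to_free_molar(531.3, 531.3, 0.052), 0.052)
  expect_equal(to_free_molar(0, 478.93, 0.00258), 0)
  # 478.93 ng/mL of belvarafenib is exactly 1 uM total
  expect_equal(478.93 / 478.93, 1)
})

test_that("exposure summary averages the window then the population", {
  fake <- data.frame(individual_id = rep(1:2, each = 5),
                     time_h = rep(seq(528, 624, length.out = 5), 2),
                     free_uM = c(rep(1, 5), rep(3, 5)))
  attr(fake, "ss_window_h") <- c(528, 624)
  es <- exposure_summary(fake)
  expect_equal(es$mean, 2)
  expect_equal(es$sd, sqrt(2))
  one <- fake[fake$individual_id == 1, ]
  attr(one, "ss_window_h") <- c(528, 624)
  expect_equal(exposure_summary(one)$sd, 0)
  expect_error(exposure_summary(fake, window_h = c(1000, 1001)), "window")
})
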