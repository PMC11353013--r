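#' Define a dosing regimen
#' @param drug drug name.
#' @param dose_mg dose per administration in mg, > 0.
#' @param schedule `"QD"` (every 24 h), `"BID"` (every 12 h), or `"QOD"`
#'   (every 48 h, first dose at t = 0).
#' @param duration_days total simulated duration in days.
#' @return A `regimen` list.
#' @export
regimen <- function(drug, dose_mg, schedule = c("QD", "BID", "QOD"),
                    duration_days = 30) {
  schedule <- match.arg(schedule)
  stopifnot(dose_mg > 0, duration_days > 0)
  structure(list(drug = drug, dose_mg = dose_mg, schedule = schedule,
                 duration_days = duration_days),
            class = "regimen")
}

regimen_dose_times <- function(reg) {
  tau <- switch(reg$schedule, QD = 24, BID = 12, QOD = 48)
  seq(0, reg$duration_days * 24 - 1e-9, by = tau)
}

#' Define a one-compartment population PK model
#'
#' Typical values of a first-order-absorption one-compartment oral PK
#' model plus lognormal interindividual variability standard deviations.
#'
#' @param ka absorption rate constant, 1/h.
#' @param cl_f apparent clearance CL/F, L/h.
#' @param v_f apparent volume V/F, L.
#' @param omega_ka,omega_cl,omega_v lognormal interindividual SDs.
#' @param mw molecular weight, g/mol.
#' @param fu_plasma fraction unbound in plasma.
#' @return A `pop_pk_model` list.
#' @export
pop_pk_model <- function(ka, cl_f, v_f,
                         omega_ka = 0, omega_cl = 0, omega_v = 0,
                         mw, fu_plasma) {
  stopifnot(ka > 0, cl_f > 0, v_f > 0, mw > 0,
            omega_ka >= 0, omega_cl >= 0, omega_v >= 0,
            fu_plasma > 0, fu_plasma <= 1)
  structure(list(ka = ka, cl_f = cl_f, v_f = v_f,
                 omega_ka = omega_ka, omega_cl = omega_cl, omega_v = omega_v,
                 mw = mw, fu_plasma = fu_plasma),
            class = "pop_pk_model")
}

#' Default population PK models for the two drugs
#'
#' Generic one-compartment parameterizations whose mid-regimen mean
#' steady-state free concentrations fall inside the in vitro free-dose
#' grids of the combination assay; they are calibration anchors for the
#' translation workflow, not estimates for the real compounds.
#'
#' @param drug `"belvarafenib"` or `"cobimetinib"`.
#' @return A [pop_pk_model()].
#' @export
default_pk_model <- function(drug = c("belvarafenib", "cobimetinib")) {
  drug <- match.arg(drug)
  cons <- default_assay_constants()
  if (drug == "belvarafenib")
    pop_pk_model(ka = 0.5, cl_f = 5, v_f = 100,
                 omega_ka = 0.5, omega_cl = 0.3, omega_v = 0.3,
                 mw = cons$mw_a, fu_plasma = cons$fu_plasma_a)
  else
    pop_pk_model(ka = 0.5, cl_f = 13, v_f = 800,
                 omega_ka = 0.5, omega_cl = 0.3, omega_v = 0.3,
                 mw = cons$mw_b, fu_plasma = cons$fu_plasma_b)
}

#' Simulate one individual's concentration-time profile
#'
#' Closed-form superposition of first-order absorption doses:
#' \deqn{C(t) = \sum_{t_d \le t} \frac{D k_a}{V (k_a - k_e)}
#'   (e^{-k_e (t - t_d)} - e^{-k_a (t - t_d)})}
#' with `ke = CL/V`; the analytic limit `(D/V) ka t e^{-ka t}` is used
#' when `ka == ke`. With dose in mg and volume in L, concentrations come
#' out in mg/L and are reported as ng/mL (x1000).
#'
#' @param params list with `ka` (1/h), `cl_f` (L/h), `v_f` (L) — realized
#'   individual values.
#' @param reg a [regimen()] with `duration_days >= 30` for steady-state
#'   work (shorter runs are allowed for unit checks).
#' @param dt simulation grid step in h, <= 1.
#' @param individual_id identifier stored in the output.
#' @param mw,fu_plasma optional; when supplied, a `free_uM` column is
#'   added via [to_free_molar()].
#' @return data.frame of class `pk_profile`: `individual_id`, `time_h`,
#'   `total_ngml` (and `free_uM` when convertible), with the regimen and
#'   the steady-state window (days 22-26) as attributes.
#' @export
simulate_individual_pk <- function(params, reg, dt = 0.25,
                                   individual_id = 1L,
                                   mw = NULL, fu_plasma = NULL) {
  stopifnot(dt <= 1, dt > 0)
  times <- seq(0, reg$duration_days * 24, by = dt)
  conc <- conc_superposition(times, regimen_dose_times(reg),
                             reg$dose_mg, params$ka, params$cl_f,
                             params$v_f)
  out <- data.frame(individual_id = individual_id, time_h = times,
                    total_ngml = conc * 1000)  # mg/L -> ng/mL
  if (!is.null(mw) && !is.null(fu_plasma))
    out$free_uM <- to_free_molar(out$total_ngml, mw, fu_plasma)
  attr(out, "regimen") <- reg
  attr(out, "ss_window_h") <- c(22, 26) * 24
  class(out) <- c("pk_profile", "data.frame")
  out
}

# vectorized dose superposition; concentrations in mg/L
conc_superposition <- function(times, dose_times, dose_mg, ka, cl, v) {
  ke <- cl / v
  conc <- numeric(length(times))
  for (td in dose_times) {
    el <- times - td
    on <- el >= 0
    if (!any(on)) next
    e <- el[on]
    if (abs(ka - ke) < 1e-10) {
      c1 <- (dose_mg / v) * ka * e * exp(-ka * e)
    } else {
      c1 <- dose_mg * ka / (v * (ka - ke)) * (exp(-ke * e) - exp(-ka * e))
    }
    conc[on] <- conc[on] + c1
  }
  conc
}

#' Simulate a population of PK profiles
#'
#' Individual parameters are drawn as `theta * exp(eta)` with
#' `eta ~ N(0, omega^2)` independently per parameter and individual; each
#' individual is simulated for the regimen duration (default 30 days) and
#' the days 22-26 window is flagged as the steady-state analysis window.
#'
#' @param model a [pop_pk_model()].
#' @param reg a [regimen()].
#' @param n number of individuals.
#' @param seed RNG seed (required for reproducibility).
#' @param dt grid step in h.
#' @return data.frame of class `pk_population` stacking individual
#'   profiles (`individual_id`, `time_h`, `total_ngml`, `free_uM`), with
#'   the realized parameters in `attr(, "parameters")`.
#' @export
simulate_population_pk <- function(model, reg, n = 500, seed, dt = 0.25) {
  stopifnot(n >= 1)
  if (missing(seed)) stop("seed must be supplied explicitly", call. = FALSE)
  set.seed(seed)
  draw <- function(theta, omega) {
    x <- theta * exp(stats::rnorm(n, 0, omega))
    bad <- !is.finite(x)
    nres <- 0L
    while (any(bad)) {
      nres <- nres + sum(bad)
      x[bad] <- theta * exp(stats::rnorm(sum(bad), 0, omega))
      bad <- !is.finite(x)
    }
    if (nres > 0L) message(nres, " non-finite parameter draw(s) resampled")
    x
  }
  pars <- data.frame(individual_id = seq_len(n),
                     ka = draw(model$ka, model$omega_ka),
                     cl_f = draw(model$cl_f, model$omega_cl),
                     v_f = draw(model$v_f, model$omega_v))
  profs <- lapply(seq_len(n), function(i)
    simulate_individual_pk(pars[i, ], reg, dt = dt, individual_id = i,
                           mw = model$mw, fu_plasma = model$fu_plasma))
  out <- do.call(rbind, profs)
  attr(out, "parameters") <- pars
  attr(out, "regimen") <- reg
  attr(out, "ss_window_h") <- c(22, 26) * 24
  class(out) <- c("pk_population", "data.frame")
  out
}

#' Convert a total plasma concentration to free molar units
#'
#' `free uM = (total ng/mL / MW g/mol) * fu`: ng/mL is ug/L, and ug/L
#' divided by g/mol gives umol/L directly.
#'
#' @param total_ngml total plasma concentration, ng/mL.
#' @param mw molecular weight, g/mol.
#' @param fu_plasma fraction unbound in plasma.
#' @return free concentration in uM.
#' @export
to_free_molar <- function(total_ngml, mw, fu_plasma) {
  stopifnot(mw > 0, fu_plasma > 0)
  if (any(total_ngml < 0)) stop("concentration must be >= 0", call. = FALSE)
  total_ngml / mw * fu_plasma
}

#' Steady-state exposure summary of a PK population
#'
#' Time-averages each individual's free concentration over the
#' steady-state window (days 22-26 by default), then summarizes across
#' the population.
#'
#' @param population a `pk_population` (or single `pk_profile`).
#' @param window_h length-2 window in h since first dose; defaults to the
#'   population's stored steady-state window.
#' @return list with `mean` and `sd` (sample SD) of the per-individual
#'   window means of free concentration (uM), plus `per_individual`.
#' @export
exposure_summary <- function(population, window_h = NULL) {
  if (is.null(window_h)) window_h <- attr(population, "ss_window_h")
  if (is.null(window_h)) stop("no steady-state window available",
                              call. = FALSE)
  w <- population$time_h >= window_h[1] & population$time_h <= window_h[2]
  if (!any(w)) stop("steady-state window is empty", call. = FALSE)
  if (is.null(population$free_uM))
    stop("population has no free_uM column", call. = FALSE)
  per <- tapply(population$free_uM[w], population$individual_id[w], mean)
  list(mean = mean(per),
       sd = if (length(per) > 1) stats::sd(per) else 0,
       per_individual = as.numeric(per))
}
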