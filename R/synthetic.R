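#' Log-logistic margin parameter helper
#' @param upper,lower asymptotic viabilities; @param ec50 uM; @param hill
#'   slope.
#' @return named list usable as a generating margin.
#' @export
ll_margin <- function(upper = 1, lower = 0, ec50 = 0.1, hill = 1.5) {
  stopifnot(ec50 > 0, hill > 0, lower <= upper)
  list(upper = upper, lower = lower, ec50 = ec50, hill = hill)
}

#' Half-log checkerboard dose grid
#' @param top top dose in uM.
#' @param n_nonzero number of nonzero doses (half-log spaced down from
#'   `top`).
#' @param include_zero prepend the untreated dose.
#' @return dose vector in uM, ascending.
#' @export
halflog_doses <- function(top = 10, n_nonzero = 8, include_zero = TRUE) {
  d <- top * 10^(-0.5 * (seq_len(n_nonzero) - 1))
  d <- sort(d)
  if (include_zero) c(0, d) else d
}

# Gaussian synergy bump in log10-dose space; zero on the margins so the
# single agents stay exactly log-logistic.
synergy_bump <- function(da, db, amplitude, center, width) {
  if (amplitude == 0) return(matrix(0, length(da), length(db)))
  g <- matrix(0, length(da), length(db))
  ia <- da > 0; ib <- db > 0
  d2 <- outer((log10(da[ia]) - log10(center[1]))^2,
              (log10(db[ib]) - log10(center[2]))^2, `+`)
  g[ia, ib] <- amplitude * exp(-d2 / (2 * width^2))
  g
}

#' Generate a synthetic drug-combination viability matrix
#'
#' Viability is a separable product of two log-logistic single-agent
#' surfaces (exact Bliss independence on the inhibition scale) minus a
#' localized synergy deviation — an isotropic Gaussian bump in log10-dose
#' space, zero on the single-agent margins — truncated at 0 and degraded
#' with multiplicative lognormal noise.
#'
#' @param margin_a,margin_b generating margins, as [ll_margin()] lists.
#' @param doses_a,doses_b dose grids in uM (zero dose included by
#'   default).
#' @param bump list with `amplitude` (>= 0), `center` (uM pair),
#'   `width` (decades).
#' @param noise_sd SD of the lognormal viability noise.
#' @param seed RNG seed.
#' @param ... passed to [combination_matrix()].
#' @return A [combination_matrix()] with the noiseless truth and the
#'   generator inputs in `attr(, "ground_truth")`.
#' @export
generate_viability_matrix <- function(margin_a = ll_margin(),
                                      margin_b = ll_margin(ec50 = 0.05),
                                      doses_a = halflog_doses(10),
                                      doses_b = halflog_doses(10),
                                      bump = list(amplitude = 0,
                                                  center = c(0.1, 0.05),
                                                  width = 0.5),
                                      noise_sd = 0, seed = 1, ...) {
  stopifnot(bump$amplitude >= 0, noise_sd >= 0)
  nzc <- function(ds, ctr) ctr >= min(ds[ds > 0]) && ctr <= max(ds)
  if (bump$amplitude > 0 &&
      (!nzc(doses_a, bump$center[1]) || !nzc(doses_b, bump$center[2])))
    warning("synergy bump center lies outside the dose grid", call. = FALSE)
  va <- ll_eval(doses_a, margin_a$upper, margin_a$lower, margin_a$ec50,
                margin_a$hill)
  vb <- ll_eval(doses_b, margin_b$upper, margin_b$lower, margin_b$ec50,
                margin_b$hill)
  truth <- pmax(outer(va, vb) -
                  synergy_bump(doses_a, doses_b, bump$amplitude,
                               bump$center, bump$width), 0)
  set.seed(seed)
  noise <- matrix(exp(stats::rnorm(length(truth), 0, noise_sd)),
                  nrow(truth), ncol(truth))
  m <- combination_matrix(truth * noise, doses_a, doses_b, ...)
  attr(m, "ground_truth") <- list(margin_a = margin_a, margin_b = margin_b,
                                  bump = bump, noise_sd = noise_sd,
                                  seed = seed, noiseless = truth)
  m
}

#' Default screen panel specification
#'
#' A 43-line panel in three mutation groups emulating the contrast seen
#' in panRAF + MEK inhibitor screens: BRAF-mutant-like lines respond
#' potently to the MEK inhibitor with near-zero synergy, NRAS-mutant-like
#' lines have a shallower, less potent MEK-inhibitor response but a
#' positive localized synergy bump; wild-type-like lines sit in between
#' with modest synergy. Drug A is the panRAF inhibitor (9 half-log doses
#' from 10 uM), drug B the MEK inhibitor (from 5 uM).
#'
#' @return list of per-group specs plus shared settings.
#' @export
default_panel_spec <- function() {
  list(
    groups = list(
      BRAF_V600 = list(n = 15,
                       log10_ic50_a = c(mean = -0.3, sd = 0.3),
                       log10_ic50_b = c(mean = -2.0, sd = 0.3),
                       emax_a = 0.25, emax_b = 0.05, hill = 1.5,
                       bump_amplitude = c(mean = 0.02, sd = 0.01)),
      NRAS_Q61 = list(n = 14,
                      log10_ic50_a = c(mean = 0.0, sd = 0.3),
                      log10_ic50_b = c(mean = -1.2, sd = 0.3),
                      emax_a = 0.45, emax_b = 0.35, hill = 1.2,
                      bump_amplitude = c(mean = 0.30, sd = 0.05)),
      WT = list(n = 14,
                log10_ic50_a = c(mean = 0.3, sd = 0.4),
                log10_ic50_b = c(mean = -0.8, sd = 0.4),
                emax_a = 0.55, emax_b = 0.45, hill = 1.0,
                bump_amplitude = c(mean = 0.15, sd = 0.05))),
    doses_a = halflog_doses(10), doses_b = halflog_doses(5),
    bump_center = c(0.3, 0.05), bump_width = 0.6,
    noise_sd = 0.05)
}

#' Generate a synthetic combination screen panel
#'
#' Draws per-line single-agent parameters and synergy amplitudes from the
#' group distributions of a panel spec and generates one combination
#' matrix per line.
#'
#' @param spec panel specification, as [default_panel_spec()].
#' @param seed RNG seed.
#' @return list with `matrices` (named list of [combination_matrix()])
#'   and `ground_truth` (data.frame of generating parameters per line).
#' @export
generate_screen_panel <- function(spec = default_panel_spec(), seed = 1) {
  if (!length(spec$groups)) stop("empty panel spec", call. = FALSE)
  set.seed(seed)
  mats <- list(); gt <- list()
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    if (g$n == 0) next
    for (i in seq_len(g$n)) {
      id <- sprintf("%s_%02d", gname, i)
      ic50_a <- 10^stats::rnorm(1, g$log10_ic50_a["mean"],
                                g$log10_ic50_a["sd"])
      ic50_b <- 10^stats::rnorm(1, g$log10_ic50_b["mean"],
                                g$log10_ic50_b["sd"])
      amp <- max(stats::rnorm(1, g$bump_amplitude["mean"],
                              g$bump_amplitude["sd"]), 0)
      line_seed <- sample.int(.Machine$integer.max - 1, 1)
      mats[[id]] <- generate_viability_matrix(
        margin_a = ll_margin(lower = g$emax_a, ec50 = ic50_a,
                             hill = g$hill),
        margin_b = ll_margin(lower = g$emax_b, ec50 = ic50_b,
                             hill = g$hill),
        doses_a = spec$doses_a, doses_b = spec$doses_b,
        bump = list(amplitude = amp, center = spec$bump_center,
                    width = spec$bump_width),
        noise_sd = spec$noise_sd, seed = line_seed,
        cell_line = id)
      gt[[id]] <- data.frame(cell_line = id, group = gname,
                             ec50_a = ic50_a, ec50_b = ic50_b,
                             emax_a = g$emax_a, emax_b = g$emax_b,
                             bump_amplitude = amp, seed = line_seed)
    }
  }
  list(matrices = mats, ground_truth = do.call(rbind, gt))
}

#' Generate a synthetic xenograft tumor-volume series
#'
#' Exponential growth measured twice weekly over 21 days with
#' multiplicative lognormal measurement noise.
#'
#' @param v0 initial volume, mm^3.
#' @param rate net growth rate, 1/day.
#' @param noise_sd lognormal measurement noise SD.
#' @param days measurement days.
#' @param seed RNG seed.
#' @return data.frame `day`, `volume_mm3`, with the noiseless truth in
#'   `attr(, "ground_truth")`.
#' @export
generate_xenograft_volumes <- function(v0 = 240, rate = log(2) / 18,
                                       noise_sd = 0,
                                       days = c(0, 3, 7, 10, 14, 17, 21),
                                       seed = 1) {
  stopifnot(v0 > 0, noise_sd >= 0)
  truth <- v0 * exp(rate * days)
  set.seed(seed)
  obs <- truth * exp(stats::rnorm(length(days), 0, noise_sd))
  out <- data.frame(day = days, volume_mm3 = obs)
  attr(out, "ground_truth") <- list(v0 = v0, rate = rate,
                                    noiseless = truth)
  out
}

#' Generate a synthetic clinical TGI cohort
#'
#' Per-subject biexponential parameters drawn lognormally around group
#' means; tumor sizes observed on a fixed week schedule with
#' multiplicative lognormal noise.
#'
#' @param n_subjects subjects per group.
#' @param groups data.frame with `group`, `kg`, `ks` (group geometric
#'   means, 1/week).
#' @param ts0 baseline tumor size common to all subjects.
#' @param omega lognormal SD of the per-subject parameters.
#' @param weeks observation schedule.
#' @param noise_sd lognormal observation noise SD.
#' @param seed RNG seed.
#' @return list with `data` (long: `subject_id`, `group`, `week`,
#'   `tumor_size`) and `ground_truth` (per-subject kg/ks).
#' @export
generate_tgi_cohort <- function(n_subjects = 20,
                                groups = data.frame(
                                  group = c("BRAF_V600", "NRAS_Q61"),
                                  kg = c(0.03, 0.06),
                                  ks = c(0.25, 0.12)),
                                ts0 = 50, omega = 0.3,
                                weeks = seq(0, 52, by = 4),
                                noise_sd = 0, seed = 1) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  data <- list(); gt <- list()
  for (i in seq_len(nrow(groups))) {
    for (s in seq_len(n_subjects)) {
      id <- sprintf("%s_%03d", groups$group[i], s)
      kg <- groups$kg[i] * exp(stats::rnorm(1, 0, omega))
      ks <- groups$ks[i] * exp(stats::rnorm(1, 0, omega))
      ts <- simulate_tumor_size(list(ts0 = ts0, kg = kg, ks = ks), weeks)
      obs <- ts * exp(stats::rnorm(length(weeks), 0, noise_sd))
      data[[id]] <- data.frame(subject_id = id, group = groups$group[i],
                               week = weeks, tumor_size = obs)
      gt[[id]] <- data.frame(subject_id = id, group = groups$group[i],
                             ts0 = ts0, kg = kg, ks = ks)
    }
  }
  list(data = do.call(rbind, data), ground_truth = do.call(rbind, gt))
}
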