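#' Fit a log-logistic dose-response curve
#'
#' Least-squares fit of relative viability against dose with the
#' log-logistic model
#' \deqn{v(d) = lower + (upper - lower) / (1 + (d/ec50)^h)}
#' in either the three-parameter form (`"LL3u"`, upper asymptote fixed at 1
#' for control-normalized data) or the four-parameter form (`"LL4"`, upper
#' free). Fitting uses Levenberg-Marquardt least squares with five
#' deterministic multi-starts (ec50 at the 0.1-0.9 dose quantiles, Hill
#' slope 1 or 2); the best sum of squares wins. A fit that fails to
#' converge from every start is returned as a flagged flat curve at the
#' mean viability.
#'
#' @param doses dose vector in uM; may include 0 (evaluates to the upper
#'   asymptote). At least 4 distinct nonzero doses are required.
#' @param viabilities relative viability at each dose.
#' @param model_form `"auto"` picks `"LL3u"` when the zero-dose / lowest
#'   response is within 0.1 of 1, else `"LL4"`.
#' @return A `dose_response_curve`: fields `upper`, `lower`, `ec50` (uM),
#'   `hill`, `ic50_abs` (uM, `NA` if the curve never crosses viability
#'   0.5), `emax` (fitted viability at the maximum tested dose), `auc`
#'   (mean fractional inhibition of the fitted curve on the tested
#'   log10-dose grid), `converged`, plus the data.
#' @export
fit_dose_response <- function(doses, viabilities,
                              model_form = c("auto", "LL3u", "LL4")) {
  model_form <- match.arg(model_form)
  doses <- as.numeric(doses); v <- as.numeric(viabilities)
  if (length(doses) != length(v)) stop("doses/viabilities length mismatch",
                                       call. = FALSE)
  if (any(!is.finite(v))) stop("viabilities must be finite", call. = FALSE)
  nz <- unique(doses[doses > 0])
  if (length(nz) < 4)
    stop("fit-degenerate: need >= 4 distinct nonzero doses", call. = FALSE)
  v0 <- if (any(doses == 0)) mean(v[doses == 0]) else v[which.min(doses)]
  if (model_form == "auto")
    model_form <- if (abs(v0 - 1) > 0.1) "LL4" else "LL3u"

  ll <- function(d, upper, lower, ec50, h)
    lower + (upper - lower) / (1 + (d / ec50)^h)

  starts <- ll_starts(doses, v, model_form)
  best <- NULL; best_sse <- Inf
  dat <- data.frame(d = doses, v = v)
  for (st in starts) {
    fit <- tryCatch({
      if (model_form == "LL3u") {
        minpack.lm::nlsLM(
          v ~ lower + (1 - lower) / (1 + exp(h * (log(d) - lec))),
          data = dat,
          start = list(lower = st$lower, lec = log(st$ec50), h = st$h),
          lower = c(-0.5, log(min(nz)) - 12, 0.05),
          upper = c(1.2, log(max(nz)) + 12, 20),
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
      } else {
        minpack.lm::nlsLM(
          v ~ lower + (upper - lower) / (1 + exp(h * (log(d) - lec))),
          data = dat,
          start = list(upper = st$upper, lower = st$lower,
                       lec = log(st$ec50), h = st$h),
          lower = c(0, -0.5, log(min(nz)) - 12, 0.05),
          upper = c(2, 1.2, log(max(nz)) + 12, 20),
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (sse < best_sse) { best_sse <- sse; best <- fit }
  }

  if (is.null(best)) {
    # flat-curve fallback, flagged unconverged
    mu <- mean(v)
    return(new_drc(upper = mu, lower = mu, ec50 = stats::median(nz), hill = 1,
                   doses = doses, viabilities = v, model_form = model_form,
                   converged = FALSE))
  }
  cf <- stats::coef(best)
  upper <- if (model_form == "LL3u") 1 else unname(cf["upper"])
  new_drc(upper = upper, lower = unname(cf["lower"]),
          ec50 = exp(unname(cf["lec"])), hill = unname(cf["h"]),
          doses = doses, viabilities = v, model_form = model_form,
          converged = TRUE)
}

# note: log(d) with d = 0 yields -Inf and exp(h*(-Inf - lec)) = 0 for h > 0,
# so the zero-dose row contributes v = upper, exactly the model limit.

ll_starts <- function(doses, v, model_form) {
  nz <- sort(unique(doses[doses > 0]))
  qs <- stats::quantile(nz, c(0.1, 0.3, 0.5, 0.7, 0.9), names = FALSE,
                        type = 7)
  hs <- c(1, 2, 1, 2, 1)
  lower0 <- max(min(v), 0)
  upper0 <- min(max(v), 1.2)
  lapply(seq_along(qs), function(i)
    list(ec50 = qs[i], h = hs[i], lower = lower0, upper = upper0))
}

new_drc <- function(upper, lower, ec50, hill, doses, viabilities,
                    model_form, converged) {
  ic50 <- ll_ic50(upper, lower, ec50, hill)
  dmax <- max(doses)
  emax <- ll_eval(dmax, upper, lower, ec50, hill)
  grid <- sort(unique(doses[doses > 0]))
  auc <- mean(1 - ll_eval(grid, upper, lower, ec50, hill))
  structure(
    list(model_form = model_form, upper = upper, lower = lower,
         ec50 = ec50, hill = hill, ic50_abs = ic50, emax = emax, auc = auc,
         converged = converged, doses = doses, viabilities = viabilities),
    class = "dose_response_curve")
}

ll_eval <- function(d, upper, lower, ec50, h) {
  out <- lower + (upper - lower) / (1 + (d / ec50)^h)
  out[d == 0] <- upper
  out
}

# absolute IC50: dose at which the fitted curve crosses viability 0.5;
# NA when the curve never reaches 0.5 (floor above, or ceiling below).
ll_ic50 <- function(upper, lower, ec50, h) {
  if (!(lower < 0.5 && upper > 0.5)) return(NA_real_)
  x <- (upper - 0.5) / (0.5 - lower)
  ec50 * x^(1 / h)
}

#' Evaluate a fitted dose-response curve
#' @param object a `dose_response_curve`.
#' @param newdata optional list/data.frame with element `d` (doses in uM);
#'   defaults to the fitted doses.
#' @param ... unused.
#' @return fitted relative viability.
#' @export
predict.dose_response_curve <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$doses else
    if (is.list(newdata)) newdata$d else as.numeric(newdata)
  ll_eval(d, object$upper, object$lower, object$ec50, object$hill)
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("<dose_response_curve> %s%s\n", x$model_form,
              if (x$converged) "" else " (UNCONVERGED, flat fallback)"))
  cat(sprintf("  upper %.4g  lower %.4g  ec50 %.4g uM  hill %.4g\n",
              x$upper, x$lower, x$ec50, x$hill))
  cat(sprintf("  IC50(abs) %s uM  Emax %.4g  AUC %.4g\n",
              ifelse(is.na(x$ic50_abs), "undefined", signif(x$ic50_abs, 4)),
              x$emax, x$auc))
  invisible(x)
}

#' Single-agent metrics over a dose range
#'
#' Restricts a fitted curve's summary metrics to a dose interval: absolute
#' IC50 (reported only when the crossing lies inside the range), fitted
#' viability at the top of the range (Emax), and mean fractional inhibition
#' on the fitted-dose grid restricted to the range (AUC).
#'
#' @param curve a `dose_response_curve`.
#' @param dose_range numeric length-2 interval in uM.
#' @return list with `ic50_abs`, `emax`, `auc`.
#' @export
single_agent_metrics <- function(curve, dose_range) {
  if (length(dose_range) != 2 || dose_range[2] <= dose_range[1])
    stop("dose_range must be an increasing length-2 interval", call. = FALSE)
  ic50 <- curve$ic50_abs
  if (!is.na(ic50) && (ic50 < dose_range[1] || ic50 > dose_range[2]))
    ic50 <- NA_real_
  grid <- sort(unique(curve$doses[curve$doses >= dose_range[1] &
                                  curve$doses <= dose_range[2] &
                                  curve$doses > 0]))
  if (!length(grid))
    grid <- 10^seq(log10(dose_range[1]), log10(dose_range[2]), length.out = 9)
  fit <- ll_eval(grid, curve$upper, curve$lower, curve$ec50, curve$hill)
  list(ic50_abs = ic50,
       emax = ll_eval(dose_range[2], curve$upper, curve$lower, curve$ec50,
                      curve$hill),
       auc = mean(1 - fit))
}

#' Smooth a combination matrix by crossed dose-response fits
#'
#' De-noises a checkerboard viability matrix by fitting a log-logistic
#' curve along drug A at every fixed dose of drug B, another along drug B
#' at every fixed dose of drug A, and averaging the two fitted surfaces.
#' The sweep is applied as an alternating projection: the crossed fits
#' are repeated on the smoothed surface until it stops changing (or
#' `max_sweeps` is reached), which removes residual noise structure that
#' a single sweep leaves behind while preserving surfaces that are
#' already consistent with log-logistic slices (those are fixed points).
#' Slices whose fit fails keep their current values (with a warning).
#'
#' @param m a [combination_matrix()] with at least 4 nonzero doses per axis.
#' @param max_sweeps maximum number of alternating-projection sweeps.
#' @param tol stop when the largest cell change in a sweep falls below
#'   this value.
#' @return numeric matrix of smoothed viability, same dimensions as input.
#' @export
smooth_combination_matrix <- function(m, max_sweeps = 4, tol = 5e-4) {
  v <- m$viability
  da <- m$doses_a; db <- m$doses_b
  if (length(unique(da[da > 0])) < 4 || length(unique(db[db > 0])) < 4)
    stop("need >= 4 nonzero doses per axis to smooth", call. = FALSE)
  fit_slice <- function(d, y) {
    tryCatch({
      cur <- fit_dose_response(d, y, model_form = "LL4")
      if (!cur$converged) stop("unconverged")
      predict(cur, list(d = d))
    }, error = function(e) NULL)
  }
  failed <- 0L
  for (sweep in seq_len(max_sweeps)) {
    sa <- v; sb <- v
    for (j in seq_along(db)) {           # along drug A at fixed B dose
      f <- fit_slice(da, v[, j])
      if (is.null(f)) failed <- failed + 1L else sa[, j] <- f
    }
    for (i in seq_along(da)) {           # along drug B at fixed A dose
      f <- fit_slice(db, v[i, ])
      if (is.null(f)) failed <- failed + 1L else sb[i, ] <- f
    }
    vnew <- (sa + sb) / 2
    delta <- max(abs(vnew - v))
    v <- vnew
    if (delta < tol) break
  }
  if (failed > 0L)
    warning(failed, " slice fit(s) failed; current values kept",
            call. = FALSE)
  v
}
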