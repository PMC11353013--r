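#' Biexponential tumor-growth-inhibition model
#'
#' Clinical tumor size under treatment as the sum of a shrinking and a
#' regrowing compartment:
#' \deqn{TS(t) = TS_0 (e^{-K_S t} + e^{K_G t} - 1)}
#' with growth rate constant `kg` and shrinkage rate constant `ks`, both
#' in 1/week.
#'
#' @param params list with `ts0` (> 0), `kg` (>= 0, 1/week), `ks`
#'   (>= 0, 1/week).
#' @param times weeks, >= 0.
#' @return tumor sizes at `times` (units of `ts0`).
#' @export
simulate_tumor_size <- function(params, times) {
  stopifnot(params$ts0 > 0, params$kg >= 0, params$ks >= 0,
            all(times >= 0))
  params$ts0 * (exp(-params$ks * times) + exp(params$kg * times) - 1)
}

#' Time of the tumor-size nadir
#' @param kg,ks rate constants in 1/week, with `ks > kg > 0` for an
#'   interior nadir.
#' @return `log(ks/kg) / (ks + kg)` weeks.
#' @export
tgi_nadir_time <- function(kg, ks) {
  stopifnot(kg > 0, ks > kg)
  log(ks / kg) / (ks + kg)
}

#' Fit the biexponential TGI model to one subject's series
#'
#' Nonlinear least squares on log tumor size with non-negativity
#' constraints on both rate constants, multi-started over a (kg, ks)
#' grid. Monotone-increasing series land on the `ks = 0` boundary and
#' are flagged.
#'
#' @param times observation times in weeks.
#' @param sizes observed tumor sizes, > 0.
#' @param fix_ts0 optional known baseline size; when NULL ts0 is
#'   estimated.
#' @return list with `ts0`, `kg`, `ks` (1/week), `converged`,
#'   `boundary_ks` (TRUE when ks pinned at 0), and `sse` on the log
#'   scale.
#' @export
fit_tgi <- function(times, sizes, fix_ts0 = NULL) {
  stopifnot(length(times) == length(sizes))
  if (length(times) < 4) stop("need >= 4 observations", call. = FALSE)
  if (any(sizes <= 0)) stop("sizes must be > 0", call. = FALSE)
  ly <- log(sizes)
  obj <- function(th) {
    ts0 <- if (is.null(fix_ts0)) exp(th[1]) else fix_ts0
    kg <- th[length(th) - 1]; ks <- th[length(th)]
    mu <- ts0 * (exp(-ks * times) + exp(kg * times) - 1)
    if (any(mu <= 0)) return(1e10)
    sum((log(mu) - ly)^2)
  }
  grad <- function(th) {
    ts0 <- if (is.null(fix_ts0)) exp(th[1]) else fix_ts0
    kg <- th[length(th) - 1]; ks <- th[length(th)]
    shape <- exp(-ks * times) + exp(kg * times) - 1
    mu <- ts0 * shape
    if (any(mu <= 0)) return(rep(0, length(th)))
    r <- 2 * (log(mu) - ly)
    gkg <- sum(r * times * exp(kg * times) / shape)
    gks <- sum(r * (-times) * exp(-ks * times) / shape)
    if (is.null(fix_ts0)) c(sum(r), gkg, gks) else c(gkg, gks)
  }
  grid <- expand.grid(kg = c(0.005, 0.03, 0.1, 0.3),
                      ks = c(0.005, 0.05, 0.2, 0.8))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    th0 <- c(if (is.null(fix_ts0)) log(max(sizes[times == min(times)])),
             grid$kg[i], grid$ks[i])
    lo <- c(if (is.null(fix_ts0)) -Inf, 0, 0)
    fit <- tryCatch(
      stats::optim(th0, obj, gr = grad, method = "L-BFGS-B", lower = lo,
                   control = list(maxit = 2000, factr = 10,
                                  pgtol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("TGI fit failed from every start", call. = FALSE)
  th <- best$par
  ts0 <- if (is.null(fix_ts0)) exp(th[1]) else fix_ts0
  kg <- th[length(th) - 1]; ks <- th[length(th)]
  list(ts0 = ts0, kg = kg, ks = ks,
       converged = best$convergence == 0,
       boundary_ks = ks < 1e-8, sse = best$value)
}

#' Simulate cohort-level tumor dynamics from group mean parameters
#'
#' One deterministic biexponential trajectory per group from a common
#' baseline size (default 50) over a common horizon (default 52 weeks).
#'
#' @param group_params data.frame with columns `group`, `kg`, `ks`
#'   (1/week).
#' @param ts0 shared baseline tumor size.
#' @param horizon_weeks trajectory length in weeks.
#' @param by_weeks output grid step.
#' @return long data.frame: `group`, `week`, `tumor_size`.
#' @export
simulate_cohort <- function(group_params, ts0 = 50, horizon_weeks = 52,
                            by_weeks = 1) {
  stopifnot(horizon_weeks > 0)
  weeks <- seq(0, horizon_weeks, by = by_weeks)
  do.call(rbind, lapply(seq_len(nrow(group_params)), function(i)
    data.frame(group = group_params$group[i], week = weeks,
               tumor_size = simulate_tumor_size(
                 list(ts0 = ts0, kg = group_params$kg[i],
                      ks = group_params$ks[i]), weeks))))
}
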