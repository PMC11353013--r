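#' Project a single free-dose pair onto the GR and Bliss-excess surfaces
#' @param surface a `gr_surface` (carries both value matrices on shared
#'   free-dose axes).
#' @param free_a,free_b free concentrations in uM.
#' @return list with `gr` and `bliss_excess` at the query point.
#' @export
project_point <- function(surface, free_a, free_b) {
  list(gr = interpolate_surface(surface, free_a, free_b, what = "gr"),
       bliss_excess = interpolate_surface(surface, free_a, free_b,
                                          what = "bliss_excess"))
}

#' Project a virtual patient population onto in vitro response surfaces
#'
#' For each sampled patient, free concentrations of the two drugs are
#' read once per hour over a window inside the steady-state days (48 h
#' starting at day 23 by default, covering at least two QD/BID cycles and
#' one full QOD cycle) and projected onto the GR and Bliss-excess
#' surfaces; pooled samples are summarized into quantiles.
#'
#' @param pop_a,pop_b `pk_population` objects for drug A and drug B;
#'   patient i receives profile i of each drug (paired by index).
#' @param surface a `gr_surface`.
#' @param n_patients number of patients sampled (without replacement)
#'   from the population.
#' @param window_h projection window length in h.
#' @param start_h window start in h since first dose (day 23).
#' @param seed RNG seed for the patient sample.
#' @return An `effect_distribution`: `samples` (long data.frame with
#'   `individual_id`, `time_h`, `free_a`, `free_b`, `gr`,
#'   `bliss_excess`), `gr_quantiles`, `bliss_quantiles`
#'   (5/25/50/75/95%), and `per_patient_mean`.
#' @export
project_population <- function(pop_a, pop_b, surface, n_patients = 75,
                               window_h = 48, start_h = 23 * 24, seed = 1) {
  na <- length(unique(pop_a$individual_id))
  nb <- length(unique(pop_b$individual_id))
  if (na != nb)
    stop("pairing error: populations have different sizes (", na, " vs ",
         nb, ")", call. = FALSE)
  if (n_patients > na)
    stop("pairing error: fewer profiles than n_patients", call. = FALSE)
  set.seed(seed)
  ids <- sort(sample(unique(pop_a$individual_id), n_patients))
  hours <- seq(start_h, start_h + window_h, by = 1)
  grab <- function(pop, id) {
    p <- pop[pop$individual_id == id, ]
    stats::approx(p$time_h, p$free_uM, xout = hours, rule = 2)$y
  }
  rows <- lapply(ids, function(id) {
    fa <- grab(pop_a, id); fb <- grab(pop_b, id)
    pr <- project_point(surface, fa, fb)
    data.frame(individual_id = id, time_h = hours, free_a = fa, free_b = fb,
               gr = pr$gr, bliss_excess = pr$bliss_excess)
  })
  samples <- do.call(rbind, rows)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  per_patient <- stats::aggregate(
    cbind(gr, bliss_excess) ~ individual_id, data = samples, FUN = mean)
  structure(
    list(samples = samples,
         gr_quantiles = stats::quantile(samples$gr, qs),
         bliss_quantiles = stats::quantile(samples$bliss_excess, qs),
         per_patient_mean = per_patient,
         n_patients = n_patients, window_h = window_h, start_h = start_h),
    class = "effect_distribution")
}

#' @export
print.effect_distribution <- function(x, ...) {
  cat(sprintf("<effect_distribution> %d patients x %d hourly samples\n",
              x$n_patients, nrow(x$samples) / x$n_patients))
  cat("  GR quantiles:   ",
      paste(sprintf("%s=%.3f", names(x$gr_quantiles), x$gr_quantiles),
            collapse = "  "), "\n")
  cat("  Bliss quantiles:",
      paste(sprintf("%s=%.3f", names(x$bliss_quantiles), x$bliss_quantiles),
            collapse = "  "), "\n")
  invisible(x)
}
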