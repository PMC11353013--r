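#' Convert relative viability to the GR growth-rate-inhibition metric
#'
#' The GR metric normalizes an endpoint viability readout by the growth
#' rate of untreated cells, reconstructed from the untreated doubling
#' time:
#' \deqn{GR = 2^{1 + \log_2(v) \cdot T_d / T} - 1}
#' with `v` relative viability, `T` the treatment duration, and `T_d` the
#' untreated doubling time. GR = 1 means untreated growth, 0 complete
#' cytostasis, negative values net cell loss.
#'
#' @param viability relative viability, > 0.
#' @param treatment_hours assay duration `T` in hours.
#' @param doubling_time untreated doubling time `T_d` in hours.
#' @return GR value(s) in (-1, 1\] for `viability <= 1`.
#' @export
viability_to_gr <- function(viability, treatment_hours, doubling_time) {
  if (any(viability <= 0))
    stop("viability must be > 0 (apply a floor upstream)", call. = FALSE)
  stopifnot(treatment_hours > 0, doubling_time > 0)
  2^(1 + log2(viability) * doubling_time / treatment_hours) - 1
}

#' Control-normalized growth rate from GR
#'
#' Inverts the GR transform to the ratio of treated to control growth
#' rate, `r_norm = log2(GR + 1)`: 1 = untreated growth, 0 = cytostasis,
#' negative = net cell loss.
#'
#' @param gr GR value(s) > -1.
#' @return normalized rate(s).
#' @export
gr_to_normalized_rate <- function(gr) {
  if (any(gr <= -1)) stop("GR must be > -1", call. = FALSE)
  log2(gr + 1)
}

#' Convert nominal to free drug concentration
#' @param dose nominal concentration (uM), >= 0.
#' @param fu fraction unbound in the relevant matrix (media or plasma),
#'   in (0, 1].
#' @return free concentration in uM.
#' @export
nominal_to_free <- function(dose, fu) {
  if (any(fu <= 0) || any(fu > 1)) stop("fu must lie in (0, 1]", call. = FALSE)
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  dose * fu
}

#' Baseline exponential growth rate from a doubling time
#' @param doubling_time doubling time (any time unit), > 0.
#' @return rate constant `ln(2)/doubling_time` in the reciprocal unit.
#' @export
baseline_rate_from_doubling <- function(doubling_time) {
  stopifnot(doubling_time > 0)
  log(2) / doubling_time
}

#' Predict xenograft tumor volumes under scaled exponential growth
#'
#' The in vivo growth rate under treatment is taken as the vehicle growth
#' rate scaled by the in vitro control-normalized growth rate at the
#' projected free exposure: `V(t) = V0 * exp(k * r_norm * t)`.
#'
#' @param initial_volume V0 in mm^3, > 0.
#' @param baseline_rate vehicle growth rate k in 1/day.
#' @param r_norm control-normalized growth rate (unitless).
#' @param times days.
#' @return volumes in mm^3 at `times`.
#' @export
predict_tumor_growth <- function(initial_volume, baseline_rate, r_norm,
                                 times) {
  stopifnot(initial_volume > 0)
  initial_volume * exp(baseline_rate * r_norm * times)
}

#' Caliper tumor volume
#' @param longer,shorter caliper measurements in mm; `longer >= shorter > 0`.
#' @return volume in mm^3, `longer * shorter^2 * 0.5`.
#' @export
caliper_volume <- function(longer, shorter) {
  if (any(shorter <= 0)) stop("measurements must be > 0", call. = FALSE)
  if (any(shorter > longer))
    stop("argument order: shorter exceeds longer", call. = FALSE)
  longer * shorter^2 * 0.5
}

#' Percent body-weight change with the euthanasia-threshold flag
#' @param current,initial body weights in g; `initial > 0`.
#' @return list with `percent` (negative for loss) and `euthanize`
#'   (TRUE at >= 20% loss).
#' @export
body_weight_change <- function(current, initial) {
  stopifnot(initial > 0)
  pct <- (current / initial - 1) * 100
  list(percent = pct, euthanize = pct <= -20 + 1e-9)
}

#' Fold change from a delta-delta-Ct value
#' @param delta_delta_ct qPCR ddCt in cycles.
#' @return relative expression fold change `2^(-ddCt)`.
#' @export
ddct_fold_change <- function(delta_delta_ct) {
  stopifnot(all(is.finite(delta_delta_ct)))
  2^(-delta_delta_ct)
}

#' Build GR / normalized-rate / Bliss-excess surfaces on free-dose axes
#'
#' Converts a combination viability matrix to the GR metric and
#' control-normalized growth rates, rescales the nominal dose axes to free
#' concentrations via the media fraction unbound, and attaches the Bliss
#' excess matrix from [synergy_analysis()] on the same grid.
#'
#' @param m a [combination_matrix()] with zero-dose margins.
#' @param constants assay constants list as from
#'   [default_assay_constants()].
#' @param smooth use the smoothed viability matrix (default TRUE).
#' @param viability_floor floor applied to viability before the log in the
#'   GR transform.
#' @return A `gr_surface`: `free_doses_a`, `free_doses_b` (uM),
#'   matrices `gr`, `normalized_rate`, `bliss_excess`, `viability`.
#' @export
build_gr_surface <- function(m, constants = default_assay_constants(),
                             smooth = TRUE, viability_floor = 1e-4) {
  syn <- synergy_analysis(m, smooth = smooth)
  v <- if (smooth) syn$smoothed_viability else m$viability
  v <- pmax(v, viability_floor)
  gr <- viability_to_gr(v, m$treatment_hours,
                        constants$doubling_time_in_vitro)
  structure(
    list(free_doses_a = nominal_to_free(m$doses_a, constants$fu_media_a),
         free_doses_b = nominal_to_free(m$doses_b, constants$fu_media_b),
         gr = gr,
         normalized_rate = gr_to_normalized_rate(gr),
         bliss_excess = syn$bliss_excess,
         viability = v,
         drug_a = m$drug_a, drug_b = m$drug_b, cell_line = m$cell_line),
    class = "gr_surface")
}
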