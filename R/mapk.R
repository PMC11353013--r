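#' Construct a MAPK signaling model variant
#'
#' Coarse-grained ODE model of RAS-RAF-MEK-ERK signaling with
#' ERK-mediated inhibitory phosphorylation of RAF (pRAF negative
#' feedback), used to explain mutant-specific synergy between a panRAF
#' inhibitor and a MEK inhibitor. Three variants are supported:
#'
#' * `BRAF_V600E` — output driven by a RAS-independent RAF monomer; no
#'   RAS/dimer/feedback states.
#' * `NRAS_Q61` — RAS-GTP loading with 10-fold reduced hydrolysis
#'   (`hyd_factor = 0.1`), RAF dimerization with 5-fold reduced dimer
#'   stability (`stab_factor = 0.2`), and active pRAF feedback.
#' * `NRAS_Q61_NO_FEEDBACK` — same with the feedback rate set to 0.
#'
#' States are fractional occupancies: RAS-GTP `R`, RAF dimers `D`,
#' feedback-phosphorylated RAF `Fp` (free RAF by conservation
#' `Fu = 1 - Fp - 2 D`), pMEK `m`, pERK `e`. Drug binding is treated at
#' rapid equilibrium: bound fractions `b_R = B/(B + kd_rafi)` and
#' `b_M = C/(C + kd_meki)`. Active RAF is `2 D (1 - b_R)` for NRAS
#' variants and `1 - b_R` for the BRAF variant. RAF phosphorylates
#' inhibitor-bound MEK at the relative rate `alpha_meki`, and
#' inhibitor-bound pMEK does not phosphorylate ERK.
#'
#' @param kind variant name.
#' @param parameters optional named list overriding entries of
#'   [default_mapk_parameters()].
#' @return A `mapk_variant` list with `kind` and `parameters`.
#' @export
mapk_variant <- function(kind = c("NRAS_Q61", "NRAS_Q61_NO_FEEDBACK",
                                  "BRAF_V600E"),
                         parameters = list()) {
  kind <- match.arg(kind)
  p <- utils::modifyList(default_mapk_parameters(), parameters)
  if (kind == "NRAS_Q61_NO_FEEDBACK") p$k_fb <- 0
  if (kind == "BRAF_V600E") { p$hyd_factor <- 1; p$stab_factor <- 1 }
  stopifnot(p$alpha_meki >= 0, p$alpha_meki <= 1,
            p$hyd_factor > 0, p$hyd_factor <= 1,
            p$stab_factor > 0, p$stab_factor <= 1)
  structure(list(kind = kind, parameters = p), class = "mapk_variant")
}

#' Default kinetic constants of the MAPK surrogate
#'
#' Rates are in 1/h, dissociation constants in uM. These defaults are
#' calibration anchors chosen (by a randomized tuning pass over the rate
#' constants) so the model reproduces the qualitative signatures of the
#' system: paradoxical pMEK increase under MEK inhibition in the NRAS Q61
#' context (abolished without feedback and reversed in the BRAF context)
#' and higher Bliss synergy on pERK in NRAS Q61 than in the other
#' variants. They are not estimates of physical rate constants. The MEK
#' and ERK activation steps run in a weakly saturating regime, which
#' keeps the monomer-driven BRAF variant close to Bliss-independent; the
#' NRAS Q61 excess then isolates the contribution of the feedback
#' reserve.
#'
#' @return named list of parameters.
#' @export
default_mapk_parameters <- function() {
  list(k_ras_act = 1, k_ras_hyd = 10, hyd_factor = 0.1,
       k_dim = 250, k_undim = 5.6, stab_factor = 0.2,
       k_fb = 300, k_fb_rev = 1,
       kd_rafi = 0.008, kd_meki = 0.016, alpha_meki = 0.3,
       k_mek_cat = 1, k_mek_ptase = 2,
       k_erk_cat = 0.8, k_erk_ptase = 2)
}

mapk_state0 <- function(variant) {
  if (variant$kind == "BRAF_V600E") c(m = 0.5, e = 0.5)
  else c(R = 0.1, D = 0.05, Fp = 0.1, m = 0.5, e = 0.5)
}

mapk_rhs <- function(t, y, parms) {
  p <- parms$p
  b_R <- parms$b_R; b_M <- parms$b_M
  if (parms$braf) {
    act <- 1 - b_R
    dm <- p$k_mek_cat * act * (1 - y["m"]) *
      (1 - (1 - p$alpha_meki) * b_M) - p$k_mek_ptase * y["m"]
    de <- p$k_erk_cat * y["m"] * (1 - b_M) * (1 - y["e"]) -
      p$k_erk_ptase * y["e"]
    return(list(c(dm, de)))
  }
  R <- y["R"]; D <- y["D"]; Fp <- y["Fp"]; m <- y["m"]; e <- y["e"]
  Fu <- 1 - Fp - 2 * D
  act <- 2 * D * (1 - b_R)
  dR <- p$k_ras_act * (1 - R) - p$k_ras_hyd * p$hyd_factor * R
  dD <- p$k_dim * p$stab_factor * R * Fu^2 - p$k_undim * D
  dFp <- p$k_fb * e * Fu - p$k_fb_rev * Fp
  dm <- p$k_mek_cat * act * (1 - m) *
    (1 - (1 - p$alpha_meki) * b_M) - p$k_mek_ptase * m
  de <- p$k_erk_cat * m * (1 - b_M) * (1 - e) - p$k_erk_ptase * e
  list(c(dR, dD, dFp, dm, de))
}

mapk_parms <- function(variant, belvarafenib, cobimetinib) {
  p <- variant$parameters
  list(p = p,
       b_R = belvarafenib / (belvarafenib + p$kd_rafi),
       b_M = cobimetinib / (cobimetinib + p$kd_meki),
       braf = variant$kind == "BRAF_V600E")
}

#' Steady state of a MAPK variant under a drug pair
#'
#' Integrates the ODE system in 4 h blocks until the relative change of
#' every state over a 4 h period falls below 0.1% (the steady-state
#' criterion), or errors after `horizon_h` simulated hours.
#'
#' @param variant a [mapk_variant()].
#' @param belvarafenib,cobimetinib doses in uM, >= 0.
#' @param y0 optional initial state (defaults to a mid-range state).
#' @param horizon_h give up after this many simulated hours.
#' @param rtol integrator relative tolerance.
#' @return A `signaling_state` list: `ras_gtp`, `raf_free`,
#'   `raf_feedback_phos`, `raf_dimer`, `pmek`, `perk`, `active_raf`
#'   (fractional, NRAS states NA for the BRAF variant).
#' @export
steady_state <- function(variant, belvarafenib = 0, cobimetinib = 0,
                         y0 = NULL, horizon_h = 1e4, rtol = 1e-8) {
  stopifnot(belvarafenib >= 0, cobimetinib >= 0)
  parms <- mapk_parms(variant, belvarafenib, cobimetinib)
  y <- if (is.null(y0)) mapk_state0(variant) else y0
  t_acc <- 0
  repeat {
    sol <- deSolve::lsoda(y, c(0, 4), mapk_rhs, parms,
                          rtol = rtol, atol = 1e-10)
    ynew <- sol[nrow(sol), -1]
    rel <- abs(ynew - y) / pmax(abs(y), 1e-9)
    t_acc <- t_acc + 4
    if (all(rel < 1e-3) && t_acc >= 8) break
    if (t_acc >= horizon_h)
      stop("steady state not reached after ", horizon_h,
           " h (max relative 4 h change ", signif(max(rel), 3), ")",
           call. = FALSE)
    y <- ynew
  }
  as_signaling_state(ynew, parms)
}

as_signaling_state <- function(y, parms) {
  if (parms$braf) {
    st <- list(ras_gtp = NA_real_, raf_free = NA_real_,
               raf_feedback_phos = NA_real_, raf_dimer = NA_real_,
               pmek = unname(y["m"]), perk = unname(y["e"]),
               active_raf = 1 - parms$b_R)
  } else {
    st <- list(ras_gtp = unname(y["R"]),
               raf_free = unname(1 - y["Fp"] - 2 * y["D"]),
               raf_feedback_phos = unname(y["Fp"]),
               raf_dimer = unname(y["D"]),
               pmek = unname(y["m"]), perk = unname(y["e"]),
               active_raf = unname(2 * y["D"] * (1 - parms$b_R)))
  }
  structure(st, class = "signaling_state")
}

#' The in silico checkerboard dose grids of the signaling model
#'
#' 10 doses per drug: 0 plus 9 log-spaced doses, cobimetinib from
#' 10^-2.75 to 10^0 uM and belvarafenib from 10^-2.25 to 10^0.5 uM.
#'
#' @return list with `belvarafenib` and `cobimetinib` dose vectors (uM).
#' @export
mapk_dose_grids <- function() {
  list(belvarafenib = c(0, 10^seq(-2.25, 0.5, length.out = 9)),
       cobimetinib = c(0, 10^seq(-2.75, 0, length.out = 9)))
}

#' Steady-state dose matrix of a MAPK variant
#'
#' Computes the steady state at every cell of the 10x10 checkerboard of
#' the two inhibitors, reports pMEK and pERK relative to the drug-free
#' steady state, and scores Bliss excess on pERK inhibition.
#'
#' @param variant a [mapk_variant()].
#' @param doses_belva,doses_cobi dose vectors (uM) including 0; default
#'   the standard grids of [mapk_dose_grids()].
#' @return list with `doses_belva`, `doses_cobi`, matrices `pmek_rel`,
#'   `perk_rel` (belvarafenib down rows), `perk_inhibition`
#'   (`1 - perk_rel`), `bliss` (output of [bliss_hsa_from_response()]),
#'   and `max_bliss_excess`.
#' @export
mapk_dose_matrix <- function(variant, doses_belva = NULL,
                             doses_cobi = NULL) {
  g <- mapk_dose_grids()
  if (is.null(doses_belva)) doses_belva <- g$belvarafenib
  if (is.null(doses_cobi)) doses_cobi <- g$cobimetinib
  base <- steady_state(variant, 0, 0)
  nb <- length(doses_belva); nc <- length(doses_cobi)
  pmek <- matrix(NA_real_, nb, nc)
  perk <- matrix(NA_real_, nb, nc)
  for (i in seq_len(nb)) for (j in seq_len(nc)) {
    st <- tryCatch(steady_state(variant, doses_belva[i], doses_cobi[j]),
                   error = function(e)
                     stop("cell (", i, ",", j, "): ", conditionMessage(e),
                          call. = FALSE))
    pmek[i, j] <- st$pmek / base$pmek
    perk[i, j] <- st$perk / base$perk
  }
  inh <- 1 - perk
  bl <- bliss_hsa_from_response(inh)
  list(doses_belva = doses_belva, doses_cobi = doses_cobi,
       pmek_rel = pmek, perk_rel = perk, perk_inhibition = inh,
       bliss = bl, max_bliss_excess = max(bl$bliss_excess))
}

#' Timecourse of pMEK/pERK after inhibitor addition
#'
#' The drug-free steady state is run for 24 h (flat by construction),
#' then the inhibitors are added (cobimetinib 0.5 uM with 0 or 0.133 uM
#' belvarafenib by default) and the system is followed for 8 h at 0.1 h
#' resolution.
#'
#' @param variant a [mapk_variant()].
#' @param cobimetinib,belvarafenib post-dose concentrations in uM.
#' @param predose_h,postdose_h phase durations in h.
#' @param dt output resolution in h.
#' @return data.frame with `time_h` (0 at drug addition; predose times
#'   negative), `pmek`, `perk`, `phase`.
#' @export
mapk_timecourse <- function(variant, cobimetinib = 0.5,
                            belvarafenib = 0, predose_h = 24,
                            postdose_h = 8, dt = 0.1) {
  base <- steady_state(variant, 0, 0)
  y0 <- if (variant$kind == "BRAF_V600E")
    c(m = base$pmek, e = base$perk)
  else
    c(R = base$ras_gtp, D = base$raf_dimer, Fp = base$raf_feedback_phos,
      m = base$pmek, e = base$perk)
  pre_t <- seq(-predose_h, 0, by = dt)
  pre <- deSolve::lsoda(y0, pre_t + predose_h, mapk_rhs,
                        mapk_parms(variant, 0, 0), rtol = 1e-8,
                        atol = 1e-10)
  post_t <- seq(0, postdose_h, by = dt)
  post <- deSolve::lsoda(pre[nrow(pre), -1], post_t, mapk_rhs,
                         mapk_parms(variant, belvarafenib, cobimetinib),
                         rtol = 1e-8, atol = 1e-10)
  rbind(
    data.frame(time_h = pre_t, pmek = pre[, "m"], perk = pre[, "e"],
               phase = "predose"),
    data.frame(time_h = post_t, pmek = post[, "m"], perk = post[, "e"],
               phase = "postdose"))
}
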