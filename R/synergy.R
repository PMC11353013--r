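#' Bliss and HSA expectation, excess, and scores for a response matrix
#'
#' Given a matrix of fractional inhibition `r` whose first row and column
#' are the single-agent margins (zero dose of the other drug), computes for
#' every cell the Bliss independence expectation
#' `rA + rB - rA*rB`, the highest-single-agent (HSA) expectation
#' `max(rA, rB)`, the excess of the observed response over each
#' expectation, and summary scores defined as the mean of the
#' `ceil(top_fraction * Ncells)` largest excess values across the matrix
#' (margins included).
#'
#' @param response matrix of fractional inhibition with single-agent
#'   margins in row 1 / column 1.
#' @param top_fraction fraction of cells pooled into each score, in (0, 1].
#' @return list with `bliss_expectation`, `hsa_expectation`,
#'   `bliss_excess`, `hsa_excess`, `bliss_score`, `hsa_score`.
#' @export
bliss_hsa_from_response <- function(response, top_fraction = 0.10) {
  if (!is.matrix(response)) response <- as.matrix(response)
  if (!(top_fraction > 0 && top_fraction <= 1))
    stop("top_fraction must lie in (0, 1]", call. = FALSE)
  ra <- response[, 1]   # drug A alone (varies down rows)
  rb <- response[1, ]   # drug B alone
  eb <- outer(ra, rb, function(x, y) x + y - x * y)
  eh <- outer(ra, rb, pmax)
  list(bliss_expectation = eb,
       hsa_expectation = eh,
       bliss_excess = response - eb,
       hsa_excess = response - eh,
       bliss_score = top_mean(response - eb, top_fraction),
       hsa_score = top_mean(response - eh, top_fraction))
}

# mean of the ceil(frac * N) largest values of x
top_mean <- function(x, frac) {
  x <- as.vector(x)
  k <- ceiling(frac * length(x))
  mean(sort(x, decreasing = TRUE)[seq_len(k)])
}

#' Synergy analysis of a drug-combination matrix
#'
#' Full checkerboard synergy workflow: smooth the viability matrix by
#' crossed log-logistic fits (optional), clip to \[0, 1\], convert to
#' fractional inhibition `r = 1 - v`, and score departure from the Bliss
#' independence and HSA null models. Positive excess means the combination
#' inhibits more than the null model predicts (synergy).
#'
#' @param m a [combination_matrix()] whose dose axes include a zero dose
#'   (the single-agent margins).
#' @param top_fraction fraction of matrix cells averaged into each score.
#' @param smooth smooth the matrix before scoring (default TRUE, matching
#'   the screen workflow); set FALSE for noiseless model output.
#' @return A `synergy_result`: `smoothed_viability`, `response`,
#'   expectation/excess matrices for both null models, and scalar
#'   `bliss_score` / `hsa_score`.
#' @export
synergy_analysis <- function(m, top_fraction = 0.10, smooth = TRUE) {
  if (m$doses_a[1] != 0 || m$doses_b[1] != 0)
    stop("margin-missing: matrix needs zero-dose row and column",
         call. = FALSE)
  sm <- if (smooth) smooth_combination_matrix(m) else m$viability
  smc <- pmin(pmax(sm, 0), 1)
  r <- 1 - smc
  bh <- bliss_hsa_from_response(r, top_fraction)
  structure(
    c(list(smoothed_viability = sm, response = r,
           doses_a = m$doses_a, doses_b = m$doses_b,
           drug_a = m$drug_a, drug_b = m$drug_b, cell_line = m$cell_line),
      bh),
    class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("<synergy_result> %s x %s (%s)\n", x$drug_a, x$drug_b,
              x$cell_line))
  cat(sprintf("  Bliss score %.4f   HSA score %.4f\n",
              x$bliss_score, x$hsa_score))
  cat(sprintf("  max Bliss excess %.4f at (%.3g, %.3g) uM\n",
              max(x$bliss_excess),
              x$doses_a[which(x$bliss_excess == max(x$bliss_excess),
                              arr.ind = TRUE)[1, 1]],
              x$doses_b[which(x$bliss_excess == max(x$bliss_excess),
                              arr.ind = TRUE)[1, 2]]))
  invisible(x)
}
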