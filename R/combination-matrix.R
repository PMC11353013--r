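#' Construct a drug-combination viability matrix
#'
#' Container for a checkerboard dose matrix of control-normalized relative
#' viability for two drugs. Dose axes are in micromolar and usually include
#' a zero dose (the single-agent margins); viability is unitless with 1 =
#' untreated control.
#'
#' @param viability numeric matrix, `length(doses_a)` rows by
#'   `length(doses_b)` columns, relative viability (typically in \[0, 1.2\]).
#' @param doses_a,doses_b strictly increasing dose vectors in uM; the first
#'   entry may be 0 (untreated margin).
#' @param drug_a,drug_b drug names (drug A varies down rows).
#' @param cell_line cell line identifier.
#' @param treatment_hours assay treatment duration in hours.
#' @param zero_tol tolerance on the (0,0) cell: when both margins include a
#'   zero dose, `viability[1, 1]` must equal 1 within this tolerance.
#'
#' @return An object of class `combination_matrix`.
#' @export
combination_matrix <- function(viability, doses_a, doses_b,
                               drug_a = "drug_a", drug_b = "drug_b",
                               cell_line = NA_character_,
                               treatment_hours = 120,
                               zero_tol = 0.25) {
  viability <- as.matrix(viability)
  doses_a <- as.numeric(doses_a)
  doses_b <- as.numeric(doses_b)
  if (nrow(viability) != length(doses_a) || ncol(viability) != length(doses_b))
    stop("viability must be |doses_a| x |doses_b|", call. = FALSE)
  if (any(diff(doses_a) <= 0) || any(diff(doses_b) <= 0))
    stop("doses must be strictly increasing", call. = FALSE)
  if (any(doses_a < 0) || any(doses_b < 0))
    stop("doses must be non-negative", call. = FALSE)
  if (any(!is.finite(viability)) || any(viability < 0))
    stop("viability values must be finite and >= 0", call. = FALSE)
  if (doses_a[1] == 0 && doses_b[1] == 0 &&
      abs(viability[1, 1] - 1) > zero_tol)
    stop("untreated (0,0) cell deviates from 1 beyond tolerance ", zero_tol,
         call. = FALSE)
  structure(
    list(viability = unname(viability),
         doses_a = doses_a, doses_b = doses_b,
         drug_a = drug_a, drug_b = drug_b,
         cell_line = cell_line,
         treatment_hours = treatment_hours),
    class = "combination_matrix")
}

#' @export
print.combination_matrix <- function(x, ...) {
  cat(sprintf("<combination_matrix> %s x %s, %d x %d doses, cell line %s\n",
              x$drug_a, x$drug_b, length(x$doses_a), length(x$doses_b),
              x$cell_line))
  cat(sprintf("  %s doses (uM): %s\n", x$drug_a,
              paste(signif(x$doses_a, 3), collapse = ", ")))
  cat(sprintf("  %s doses (uM): %s\n", x$drug_b,
              paste(signif(x$doses_b, 3), collapse = ", ")))
  cat(sprintf("  viability range: [%.3f, %.3f], treatment %g h\n",
              min(x$viability), max(x$viability), x$treatment_hours))
  invisible(x)
}

#' Transpose a combination matrix (swap the two drugs)
#' @param m a `combination_matrix`.
#' @return the matrix with drug axes swapped.
#' @export
transpose_combination <- function(m) {
  combination_matrix(t(m$viability), m$doses_b, m$doses_a,
                     drug_a = m$drug_b, drug_b = m$drug_a,
                     cell_line = m$cell_line,
                     treatment_hours = m$treatment_hours)
}
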