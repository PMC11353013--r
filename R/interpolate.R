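#' Bilinear interpolation of a dose-matrix surface at arbitrary free doses
#'
#' Looks up a value matrix defined on two dose axes at arbitrary
#' non-negative dose queries. Over the nonzero-dose grid the lookup is
#' bilinear in (log10 dose A, log10 dose B). Because a zero dose has no
#' log, queries below the smallest tested dose bridge linearly in linear
#' dose between the zero-dose margin value and the lowest-dose value.
#' Queries above the grid maximum are clamped to the boundary with a
#' warning.
#'
#' @param surface a `gr_surface`, or any list with dose axes and at least
#'   one value matrix.
#' @param dose_a,dose_b query doses (uM, >= 0); vectors are paired.
#' @param what name of the value matrix to interpolate (e.g. `"gr"`,
#'   `"normalized_rate"`, `"bliss_excess"`); ignored when `surface`
#'   carries a single `values` matrix.
#' @return interpolated value(s).
#' @export
interpolate_surface <- function(surface, dose_a, dose_b, what = "gr") {
  da <- surface$free_doses_a %||% surface$doses_a
  db <- surface$free_doses_b %||% surface$doses_b
  if (is.null(da) || is.null(db))
    stop("surface has no dose axes", call. = FALSE)
  z <- surface[[what]] %||% surface$values
  if (is.null(z)) stop("surface has no value matrix '", what, "'",
                       call. = FALSE)
  if (length(dose_a) != length(dose_b)) {
    n <- max(length(dose_a), length(dose_b))
    dose_a <- rep_len(dose_a, n); dose_b <- rep_len(dose_b, n)
  }
  if (any(dose_a < 0) || any(dose_b < 0))
    stop("query doses must be >= 0", call. = FALSE)
  vapply(seq_along(dose_a), function(i)
    interp_one(da, db, z, dose_a[i], dose_b[i]), numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

interp_one <- function(da, db, z, qa, qb) {
  has0a <- da[1] == 0; has0b <- db[1] == 0
  nza <- da[da > 0]; nzb <- db[db > 0]
  if (qa > max(nza)) {
    warning("dose_a query ", signif(qa, 3), " uM above grid; clamped",
            call. = FALSE)
    qa <- max(nza)
  }
  if (qb > max(nzb)) {
    warning("dose_b query ", signif(qb, 3), " uM above grid; clamped",
            call. = FALSE)
    qb <- max(nzb)
  }
  znz <- z[da > 0, db > 0, drop = FALSE]
  # interp2 convention: x along columns, y along rows
  core <- function(a, b)
    pracma::interp2(x = log10(nzb), y = log10(nza), Z = znz,
                    xp = log10(b), yp = log10(a), method = "linear")
  in_a <- qa >= min(nza); in_b <- qb >= min(nzb)
  if (in_a && in_b) return(core(qa, qb))
  if (!in_a && in_b) {
    # below the smallest A dose: bridge from the zero-A margin
    if (!has0a) return(core(min(nza), qb))  # no margin: clamp low
    v0 <- stats::approx(log10(nzb), z[1, db > 0], xout = log10(qb),
                        rule = 2)$y
    v1 <- core(min(nza), qb)
    t <- qa / min(nza)
    return((1 - t) * v0 + t * v1)
  }
  if (in_a && !in_b) {
    if (!has0b) return(core(qa, min(nzb)))
    v0 <- stats::approx(log10(nza), z[da > 0, 1], xout = log10(qa),
                        rule = 2)$y
    v1 <- core(qa, min(nzb))
    t <- qb / min(nzb)
    return((1 - t) * v0 + t * v1)
  }
  # both queries below the smallest tested doses: bilinear in linear dose
  # over the four corners (0,0), (amin,0), (0,bmin), (amin,bmin)
  ia <- which(da > 0)[1]; ib <- which(db > 0)[1]
  v00 <- if (has0a && has0b) z[1, 1] else z[ia, ib]
  v10 <- if (has0b) z[ia, 1] else z[ia, ib]
  v01 <- if (has0a) z[1, ib] else z[ia, ib]
  v11 <- z[ia, ib]
  ta <- qa / min(nza); tb <- qb / min(nzb)
  (1 - ta) * (1 - tb) * v00 + ta * (1 - tb) * v10 +
    (1 - ta) * tb * v01 + ta * tb * v11
}
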