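#' Read a combination viability matrix from CSV
#'
#' Two dialects are supported. Wide: first column holds the drug-A doses
#' (uM), the header row holds the drug-B doses, cells hold relative
#' viability; a dose of 0 denotes the untreated margin. Long: columns
#' `cell_line, drug_a, dose_a_uM, drug_b, dose_b_uM, viability, replicate`;
#' replicates are averaged per dose pair.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` or `"long"`.
#' @param ... passed on to [combination_matrix()] (e.g. drug names,
#'   `treatment_hours`).
#' @return A [combination_matrix()].
#' @export
read_combination_csv <- function(path, dialect = c("wide", "long"), ...) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    raw <- utils::read.csv(path, header = FALSE, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (nrow(raw) < 2 || ncol(raw) < 2)
      stop("wide matrix file needs a dose header row and column: ", path,
           call. = FALSE)
    # the corner cell is ignorable, so rectangularity is judged on the body
    widths <- apply(raw[, -1, drop = FALSE], 1,
                    function(r) sum(!is.na(r) & r != ""))
    if (length(unique(widths)) != 1)
      stop("non-rectangular wide matrix in ", path, " (row ",
           which(widths != widths[1])[1], ")", call. = FALSE)
    doses_b <- suppressWarnings(as.numeric(raw[1, -1]))
    doses_a <- suppressWarnings(as.numeric(raw[-1, 1]))
    if (any(is.na(doses_b)) || any(is.na(doses_a)))
      stop("malformed dose header in ", path, ": non-numeric dose in row 1 ",
           "or column 1", call. = FALSE)
    if (anyDuplicated(doses_a) || anyDuplicated(doses_b))
      stop("duplicate doses in wide matrix ", path, call. = FALSE)
    v <- apply(raw[-1, -1, drop = FALSE], 2, as.numeric)
    oa <- order(doses_a); ob <- order(doses_b)
    combination_matrix(v[oa, ob, drop = FALSE], doses_a[oa], doses_b[ob], ...)
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("dose_a_uM", "dose_b_uM", "viability")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("long combination CSV missing columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    agg <- stats::aggregate(viability ~ dose_a_uM + dose_b_uM, data = d,
                            FUN = mean)
    doses_a <- sort(unique(agg$dose_a_uM))
    doses_b <- sort(unique(agg$dose_b_uM))
    v <- matrix(NA_real_, length(doses_a), length(doses_b))
    v[cbind(match(agg$dose_a_uM, doses_a), match(agg$dose_b_uM, doses_b))] <-
      agg$viability
    if (any(is.na(v)))
      stop("long combination CSV does not cover the full dose grid",
           call. = FALSE)
    args <- list(...)
    if (is.null(args$drug_a) && "drug_a" %in% names(d)) args$drug_a <- d$drug_a[1]
    if (is.null(args$drug_b) && "drug_b" %in% names(d)) args$drug_b <- d$drug_b[1]
    if (is.null(args$cell_line) && "cell_line" %in% names(d))
      args$cell_line <- d$cell_line[1]
    do.call(combination_matrix, c(list(v, doses_a, doses_b), args))
  }
}

#' Write a combination matrix as wide CSV
#' @param m a [combination_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_combination_csv <- function(m, path) {
  out <- rbind(c(NA, m$doses_b), cbind(m$doses_a, m$viability))
  out[1, 1] <- 0  # placeholder corner; readers take doses from margins
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

#' Read an analysis configuration file
#'
#' YAML (or JSON) configuration holding assay constants (fraction-unbound
#' table, molecular weights, doubling times), dosing regimens, exposure and
#' prediction settings, and seeds. Seeds must be explicit; wall-clock
#' defaults are refused.
#'
#' @param path YAML or JSON file.
#' @return A named list with class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(cfg$seed) && !is.numeric(cfg$seed))
    stop("config seed must be an explicit integer", call. = FALSE)
  structure(cfg, class = c("analysis_config", "list"))
}

#' Default assay constants for the belvarafenib + cobimetinib system
#'
#' Fractions unbound in assay media (10% or 5% FBS) and plasma, molecular
#' weights, and the in vitro / in vivo doubling times used throughout the
#' translation pipeline.
#'
#' @param serum `"10%FBS"` or `"5%FBS"` assay medium.
#' @return Named list of constants: `fu_media_a/b`, `fu_plasma_a/b`,
#'   `mw_a/b` (g/mol), `doubling_time_in_vitro` (h), `treatment_hours` (h),
#'   `doubling_time_in_vivo` (days). Drug A is belvarafenib (panRAF
#'   inhibitor), drug B cobimetinib (MEK inhibitor).
#' @export
default_assay_constants <- function(serum = c("10%FBS", "5%FBS")) {
  serum <- match.arg(serum)
  fu_media <- if (serum == "10%FBS") c(a = 0.034, b = 0.196)
              else c(a = 0.068, b = 0.3)
  list(fu_media_a = unname(fu_media["a"]), fu_media_b = unname(fu_media["b"]),
       fu_plasma_a = 0.00258, fu_plasma_b = 0.052,
       mw_a = 478.93, mw_b = 531.3,
       doubling_time_in_vitro = 60, treatment_hours = 120,
       doubling_time_in_vivo = 18,
       in_vitro_to_in_vivo_free = 1)
}
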