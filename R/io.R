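# Plain-text I/O: force-curve files, kinetic traces, PMF tables, JSON
# reports. Curves are deposited as simple two-column text exports; a small
# dialect record maps vendor columns/units onto the canonical (nm, pN).

#' Column/unit dialect for force-curve text files
#'
#' @param sep_col,force_col 1-based column indices of separation and force.
#' @param sep_scale Multiplier taking the file's distance unit to nm (e.g.
#'   1000 for a file in micrometres).
#' @param force_scale Multiplier taking the file's force unit to pN.
#' @param invert_force Set `TRUE` when the export stores attractive forces
#'   as positive deflections.
#' @return A `curve_dialect` list.
#' @export
curve_dialect <- function(sep_col = 1L, force_col = 2L, sep_scale = 1,
                          force_scale = 1, invert_force = FALSE) {
  structure(list(sep_col = as.integer(sep_col),
                 force_col = as.integer(force_col),
                 sep_scale = sep_scale, force_scale = force_scale,
                 invert_force = isTRUE(invert_force)),
            class = "curve_dialect")
}

# internal: parse whitespace/comma separated numeric table, skipping header
# and comment lines; error messages carry the offending line number.
parse_numeric_table <- function(path, min_cols = 2L) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- vector("list", sum(keep))
  row_no <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(trimws(lines[i]), "[,;\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      if (row_no == 0L) next # header line before the first data row
      stop("malformed numeric row at line ", i, " of ", path, call. = FALSE)
    }
    if (length(vals) < min_cols) {
      stop("line ", i, " of ", path, " has fewer than ", min_cols,
           " numeric columns", call. = FALSE)
    }
    row_no <- row_no + 1L
    rows[[row_no]] <- vals
  }
  if (row_no == 0L) stop("no numeric data rows found in ", path, call. = FALSE)
  do.call(rbind, rows[seq_len(row_no)])
}

#' Read a force-distance curve from a text file
#'
#' Accepts whitespace-, comma- or tab-separated files with at least two
#' numeric columns; header and `#` comment lines are skipped automatically.
#' Units and column positions are taken from the `dialect`.
#'
#' @param path File path.
#' @param dialect A [curve_dialect()].
#' @param pulling_rate,temperature,label Metadata forwarded to [fd_curve()];
#'   `label` defaults to the file name.
#' @return A canonically ordered [fd_curve()].
#' @export
read_curve <- function(path, dialect = curve_dialect(),
                       pulling_rate = NA_real_, temperature = 298.15,
                       label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- parse_numeric_table(path,
                             min_cols = max(dialect$sep_col, dialect$force_col))
  sep <- tab[, dialect$sep_col] * dialect$sep_scale
  frc <- tab[, dialect$force_col] * dialect$force_scale
  if (dialect$invert_force) frc <- -frc
  fd_curve(sep, frc, pulling_rate = pulling_rate, temperature = temperature,
           label = if (is.null(label)) basename(path) else label)
}

#' Write a force-distance curve as two-column TSV
#'
#' @param curve An [fd_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fd_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("separation_nm\tforce_pN", con)
  writeLines(sprintf("%.10g\t%.10g", curve$separation, curve$force), con)
  invisible(path)
}

#' Read a kinetic coverage trace from a two-column text file
#'
#' @param path File with (time s, coverage) rows.
#' @param concentration Analyte concentration, M.
#' @param label Identifier, defaults to the file name.
#' @return A [kinetic_trace()].
#' @export
read_kinetic_trace <- function(path, concentration, label = NULL) {
  tab <- parse_numeric_table(path, min_cols = 2L)
  kinetic_trace(tab[, 1], tab[, 2], concentration,
                label = if (is.null(label)) basename(path) else label)
}

#' Read a PMF profile from a two-column text file
#'
#' @param path File with (distance nm, free energy) rows.
#' @param units `"kbt"` (default) or `"kcal_per_mol"`; the latter is
#'   converted to kBT at `temperature`.
#' @param temperature Kelvin, used only for the kcal/mol conversion.
#' @return A [pmf_profile()].
#' @export
read_pmf_profile <- function(path, units = c("kbt", "kcal_per_mol"),
                             temperature = 298.15) {
  units <- match.arg(units)
  tab <- parse_numeric_table(path, min_cols = 2L)
  e <- tab[, 2]
  if (units == "kcal_per_mol") {
    # kcal/mol -> kBT: divide by R*T in kcal/mol (R = 1.98720425e-3)
    e <- e / (1.98720425e-3 * temperature)
  }
  pmf_profile(tab[, 1], e)
}

#' Write an estimate report to JSON
#'
#' Serialises an [estimate_all()] report (or any nested list of scalars)
#' with sorted keys and a fixed float format so identical runs produce
#' byte-identical files.
#'
#' @param report An `estimate_report` (or plain list).
#' @param path Output path.
#' @param digits Significant digits to keep; `NA` (default) round-trips all
#'   fields losslessly. Command-line reports use 6.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, digits = NA) {
  x <- unclass_recursive(report)
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = if (is.na(digits)) NA else I(digits),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return A named list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# internal: strip S3 classes and order names recursively for stable JSON
unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    if (!is.null(names(x)) && all(nzchar(names(x)))) x <- x[order(names(x))]
    lapply(x, unclass_recursive)
  } else {
    x
  }
}
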