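# Domain containers: force-distance curves, screening parameters, binding
# events, work samples, kinetic traces and PMF profiles. Base-R S3 records
# with validating constructors; all energies in kBT, forces in pN,
# distances in nm.

#' Thermal energy in pN.nm
#'
#' Converts a temperature to the thermal energy `kB*T` expressed in
#' piconewton-nanometres, the natural unit for AFM work integrals
#' (`1 kBT ~ 4.1 pN.nm` at room temperature).
#'
#' @param temperature Temperature in Kelvin (> 0).
#' @return Thermal energy in pN.nm per `kBT`.
#' @examples
#' kbt_pn_nm(298.15) # ~ 4.116
#' @export
kbt_pn_nm <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a positive number of Kelvin", call. = FALSE)
  }
  1.380649e-23 * temperature / 1e-21
}

#' Force-distance curve
#'
#' A single AFM retraction trace in the canonical coordinate system:
#' tip-sample separation increases from the surface (0) into bulk, and
#' attractive (downward-deflecting) forces are negative. Points are
#' reordered by increasing separation on construction.
#'
#' @param separation Tip-sample separation distances, nm.
#' @param force Cantilever forces, pN, same length as `separation`.
#' @param pulling_rate Retraction speed, nm/s (optional metadata).
#' @param temperature Bath temperature in Kelvin (default 298.15).
#' @param label Free-text identifier.
#' @return An object of class `fd_curve` with fields `separation`, `force`,
#'   `pulling_rate`, `temperature`, `label`.
#' @export
fd_curve <- function(separation, force, pulling_rate = NA_real_,
                     temperature = 298.15, label = "") {
  separation <- as.numeric(separation)
  force <- as.numeric(force)
  if (length(separation) != length(force)) {
    stop("separation and force must have equal length", call. = FALSE)
  }
  if (length(separation) < 50L) {
    stop("a force-distance curve needs at least 50 points, got ",
         length(separation), call. = FALSE)
  }
  if (!all(is.finite(separation)) || !all(is.finite(force))) {
    stop("separation and force must be finite", call. = FALSE)
  }
  ord <- order(separation)
  separation <- separation[ord]
  force <- force[ord]
  if (any(diff(separation) <= 0)) {
    stop("separation must be strictly increasing after ordering ",
         "(duplicated distance values)", call. = FALSE)
  }
  structure(
    list(separation = separation, force = force,
         pulling_rate = pulling_rate, temperature = temperature,
         label = as.character(label)),
    class = "fd_curve"
  )
}

#' @export
print.fd_curve <- function(x, ...) {
  cat(sprintf("<fd_curve '%s': %d points, %.1f-%.1f nm, T = %.2f K>\n",
              x$label, length(x$separation), min(x$separation),
              max(x$separation), x$temperature))
  invisible(x)
}

#' @export
length.fd_curve <- function(x) length(x$separation)

#' Screening parameters
#'
#' The four thresholds controlling single-event detection, plus the
#' worm-like-chain persistence length and bath temperature.
#'
#' @param alpha_frac Fraction (0, 1) of the farthest-from-surface points
#'   treated as the bulk baseline (field name `Alpha`; typical 0.5-0.7).
#' @param lod Detection limit as a multiple of the baseline noise sigma; a
#'   binding minimum must be deeper than `-lod * sigma` (typical 3-9).
#' @param mul_base Baseline fluctuation bound, in sigma multiples, used when
#'   locating the bound state A (typical 2-4).
#' @param nls_err Acceptance tolerance for the worm-like-chain fit: the mean
#'   absolute residual must not exceed `nls_err * sigma` (typical 2-3).
#' @param persistence_length WLC persistence length, nm (default 0.37, the
#'   PEG value).
#' @param temperature Kelvin, used for the pN.nm -> kBT work conversion.
#' @return A `screening_params` object.
#' @export
screening_params <- function(alpha_frac = 0.5, lod = 5.5, mul_base = 3,
                             nls_err = 3, persistence_length = 0.37,
                             temperature = 298.15) {
  stopifnot(is.numeric(alpha_frac), is.numeric(lod), is.numeric(mul_base),
            is.numeric(nls_err), is.numeric(persistence_length),
            is.numeric(temperature))
  if (!(alpha_frac > 0 && alpha_frac < 1)) {
    stop("alpha_frac must lie in (0, 1)", call. = FALSE)
  }
  if (lod <= 0 || mul_base <= 0 || nls_err <= 0 || persistence_length <= 0 ||
      temperature <= 0) {
    stop("lod, mul_base, nls_err, persistence_length and temperature must ",
         "be positive", call. = FALSE)
  }
  structure(
    list(alpha_frac = alpha_frac, lod = lod, mul_base = mul_base,
         nls_err = nls_err, persistence_length = persistence_length,
         temperature = temperature),
    class = "screening_params"
  )
}

#' Read screening parameters from a YAML config
#'
#' @param path Path to a YAML file whose top-level keys are any of
#'   `alpha_frac`, `lod`, `mul_base`, `nls_err`, `persistence_length`,
#'   `temperature`. Missing keys take the defaults of [screening_params()].
#' @return A `screening_params` object.
#' @export
read_screening_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(screening_params))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown screening parameter(s) in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(screening_params, cfg)
}

#' Accepted single-binding event
#'
#' @param index_A Index of the bound state A (relaxed linker, near-zero
#'   force).
#' @param index_B Index of the rupture / free state B.
#' @param sigma_baseline Baseline noise SD, pN.
#' @param contour_length Fitted WLC contour length, nm.
#' @param wlc_residual Mean absolute WLC fit residual, pN.
#' @param work_kbt External pulling work from A to B, kBT (> 0).
#' @param span_nm Separation distance between states A and B, nm.
#' @param label Curve identifier the event came from.
#' @return A `binding_event` object.
#' @export
binding_event <- function(index_A, index_B, sigma_baseline, contour_length,
                          wlc_residual, work_kbt, span_nm, label = "") {
  if (!(index_A < index_B)) stop("index_A must precede index_B", call. = FALSE)
  if (!(work_kbt > 0)) stop("work must be positive", call. = FALSE)
  if (!(contour_length > span_nm)) {
    stop("contour length must exceed the A-B separation span", call. = FALSE)
  }
  structure(
    list(index_A = as.integer(index_A), index_B = as.integer(index_B),
         sigma_baseline = sigma_baseline, contour_length = contour_length,
         wlc_residual = wlc_residual, work_kbt = work_kbt,
         span_nm = span_nm, label = as.character(label)),
    class = "binding_event"
  )
}

#' Work sample
#'
#' A vector of positive pulling-work values in kBT, the input to all
#' Jarzynski-equality estimators. Non-positive values are not representable
#' (the gamma work model has support W > 0); use [as_work_sample()] to drop
#' and log them.
#'
#' @param values Numeric vector of work values, kBT, all strictly positive.
#' @return A `work_sample` object.
#' @export
work_sample <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty work sample", call. = FALSE)
  if (!all(is.finite(values))) stop("work values must be finite", call. = FALSE)
  if (any(values <= 0)) {
    stop("work values must be strictly positive; use as_work_sample() to ",
         "drop non-positive values", call. = FALSE)
  }
  structure(list(values = values), class = "work_sample")
}

#' Coerce to a work sample, dropping non-positive values
#'
#' @param x Numeric vector, `work_sample`, or list of [binding_event()]s.
#' @return A `work_sample`; a message reports how many values were dropped.
#' @export
as_work_sample <- function(x) {
  if (inherits(x, "work_sample")) return(x)
  if (is.list(x) && length(x) && inherits(x[[1]], "binding_event")) {
    x <- vapply(x, function(e) e$work_kbt, numeric(1))
  }
  x <- as.numeric(x)
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    message(sum(bad), " non-positive or non-finite work value(s) excluded ",
            "(gamma support requires W > 0)")
    x <- x[!bad]
  }
  work_sample(x)
}

# internal: plain numeric vector out of anything work-like
work_values <- function(sample) {
  if (inherits(sample, "work_sample")) sample$values else as.numeric(sample)
}

#' @export
print.work_sample <- function(x, ...) {
  cat(sprintf("<work_sample: N = %d, mean = %.3g kBT, sd = %.3g kBT>\n",
              length(x$values), mean(x$values),
              if (length(x$values) > 1) sd(x$values) else NA_real_))
  invisible(x)
}

#' Kinetic coverage trace
#'
#' One SPR sensogram expressed as fractional surface coverage versus time at
#' a fixed analyte concentration.
#'
#' @param time Times, s, non-negative and increasing.
#' @param coverage Fractional coverage `theta(t)`, dimensionless.
#' @param concentration Analyte concentration, M (> 0).
#' @param label Identifier.
#' @return A `kinetic_trace` object.
#' @export
kinetic_trace <- function(time, coverage, concentration, label = "") {
  time <- as.numeric(time); coverage <- as.numeric(coverage)
  if (length(time) != length(coverage)) {
    stop("time and coverage must have equal length", call. = FALSE)
  }
  if (!all(is.finite(time)) || !all(is.finite(coverage))) {
    stop("time and coverage must be finite", call. = FALSE)
  }
  if (any(time < 0) || any(diff(time) <= 0)) {
    stop("time must be non-negative and strictly increasing", call. = FALSE)
  }
  if (!is.finite(concentration) || concentration <= 0) {
    stop("concentration must be positive (in M)", call. = FALSE)
  }
  structure(list(time = time, coverage = coverage,
                 concentration = concentration, label = as.character(label)),
            class = "kinetic_trace")
}

#' Potential-of-mean-force profile
#'
#' Free energy along the peptide-surface separation coordinate, in kBT.
#'
#' @param grid Strictly increasing distances, nm.
#' @param energy Free energy values `dG(z)`, kBT, same length, finite.
#' @return A `pmf_profile` object.
#' @export
pmf_profile <- function(grid, energy) {
  grid <- as.numeric(grid); energy <- as.numeric(energy)
  if (length(grid) != length(energy) || length(grid) < 2L) {
    stop("grid and energy must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (!all(is.finite(energy)) || !all(is.finite(grid))) {
    stop("grid and energy must be finite", call. = FALSE)
  }
  structure(list(grid = grid, energy = energy), class = "pmf_profile")
}
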