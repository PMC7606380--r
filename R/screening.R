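# Five-step automated detection of single-peptide binding events in AFM
# retraction curves:
#   1. rupture detection via windowed-regression derivatives,
#   2. baseline alignment by linear regression on the bulk segment,
#   3. binding-minimum detection on a kernel-smoothed curve (-LOD*sigma),
#   4. bound-state (A) location within a mulBase*sigma baseline band,
#   5. worm-like-chain fit of the stretch segment,
# followed by trapezoidal integration of the external work from A to B.

# ---- rolling helpers --------------------------------------------------------

# clamped-window rolling sums: sum of x over [i-r, i+r] intersected with 1..n
rolling_sum <- function(x, r) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - r)
  hi <- pmin(n, idx + r)
  cs[hi + 1L] - cs[lo]
}

rolling_count <- function(n, r) {
  idx <- seq_len(n)
  pmin(n, idx + r) - pmax(1L, idx - r) + 1L
}

# moving-average smoothing with clamped windows (width 2*floor(w/2)+1)
smooth_ma <- function(x, width) {
  r <- max(1L, floor(width / 2))
  rolling_sum(x, r) / rolling_count(length(x), r)
}

# per-point slope of y on x from a local linear regression in [i-r, i+r]
local_slope <- function(x, y, r) {
  m <- rolling_count(length(x), r)
  sx <- rolling_sum(x, r); sy <- rolling_sum(y, r)
  sxx <- rolling_sum(x * x, r); sxy <- rolling_sum(x * y, r)
  num <- sxy - sx * sy / m
  den <- sxx - sx * sx / m
  num / pmax(den, .Machine$double.eps)
}

# indices of local maxima of d exceeding a robust significance threshold;
# the small range-scaled floor keeps rounding residue on noiseless curves
# from registering as maxima when the MAD collapses to zero
significant_maxima <- function(d) {
  thr <- median(d) + 5 * mad(d) + 1e-6 * (abs(median(d)) + diff(range(d)))
  n <- length(d)
  if (n < 3L) return(integer())
  i <- 2:(n - 1L)
  i[d[i] > thr & d[i] >= d[i - 1L] & d[i] > d[i + 1L]]
}

# ---- step 1: derivative + rupture ------------------------------------------

#' Windowed-regression derivative of a force-distance curve
#'
#' Computes the per-point slope of force versus separation from a linear
#' regression in a window `[i - r, i + r]`. The radius grows from `r_min`
#' until the number of significant derivative maxima (local maxima above
#' median + 5 MAD, a robust scale rule) is identical for two consecutive
#' radii, i.e. the discontinuity count has stopped varying.
#'
#' @param curve An [fd_curve()].
#' @param r_min,r_max Smallest and largest window radius tried.
#' @return A list with `derivative` (pN/nm, per point), `radius` (the chosen
#'   `r`), and `maxima` (indices of significant derivative maxima).
#' @export
windowed_derivative <- function(curve, r_min = 2L, r_max = 30L) {
  stopifnot(inherits(curve, "fd_curve"))
  n <- length(curve$separation)
  if (n < 2L * r_min + 1L) {
    stop("curve has ", n, " points; need at least ", 2L * r_min + 1L,
         call. = FALSE)
  }
  r_max <- min(r_max, floor((n - 1L) / 2L))
  prev_count <- -1L
  der <- NULL; mx <- integer(); r_used <- r_min
  for (r in seq.int(r_min, r_max)) {
    der <- local_slope(curve$separation, curve$force, r)
    mx <- significant_maxima(der)
    r_used <- r
    if (length(mx) == prev_count) break
    prev_count <- length(mx)
  }
  list(derivative = der, radius = r_used, maxima = mx)
}

#' Locate the rupture point (state B)
#'
#' The rupture is the significant derivative maximum farthest from the
#' surface: the tether release makes the force step back up to baseline,
#' producing a positive force-derivative spike at the largest separation
#' among the curve's discontinuities.
#'
#' @param curve An [fd_curve()].
#' @param deriv Optional precomputed [windowed_derivative()] result.
#' @return Integer index of state B, or `NA_integer_` when the curve has no
#'   significant discontinuity ("no event").
#' @export
detect_rupture <- function(curve, deriv = NULL) {
  if (is.null(deriv)) deriv <- windowed_derivative(curve)
  if (!length(deriv$maxima)) return(NA_integer_)
  max(deriv$maxima)
}

# ---- step 2: baseline alignment --------------------------------------------

#' Align the bulk baseline to zero force
#'
#' Fits a straight line to the baseline region — the `alpha_frac` fraction
#' of points farthest from the surface, restricted to points beyond the
#' rupture — and subtracts it from the entire curve, removing offset and
#' linear drift. The baseline noise level sigma is the SD of the aligned
#' baseline forces.
#'
#' @param curve An [fd_curve()].
#' @param rupture_index Index of state B from [detect_rupture()].
#' @param alpha_frac Baseline fraction in (0, 1).
#' @param margin Points skipped just after the rupture before the baseline
#'   starts.
#' @return List with `curve` (aligned [fd_curve()]) and `sigma` (pN).
#' @export
align_baseline <- function(curve, rupture_index, alpha_frac = 0.5,
                           margin = 5L) {
  stopifnot(inherits(curve, "fd_curve"))
  n <- length(curve$separation)
  start <- max(rupture_index + margin, floor(n * (1 - alpha_frac)) + 1L)
  if (n - start + 1L < 10L) {
    stop("baseline region has fewer than 10 points", call. = FALSE)
  }
  idx <- start:n
  fit <- lm(f ~ z, data = list(z = curve$separation[idx],
                               f = curve$force[idx]))
  trend <- coef(fit)[1] + coef(fit)[2] * curve$separation
  aligned <- curve
  aligned$force <- curve$force - trend
  list(curve = aligned, sigma = sd(aligned$force[idx]))
}

# ---- step 3: binding minimum -----------------------------------------------

#' Detect the binding minimum before the rupture
#'
#' Local minima are searched on a moving-average-smoothed copy of the curve
#' (kernel width equal to the derivative window radius, so the two steps
#' share one scale parameter). The minimum closest before the rupture whose
#' smoothed force is below `-lod * sigma` is accepted as the binding site;
#' when two candidate minima are equally deep the deeper raw force wins.
#'
#' @param curve Aligned [fd_curve()].
#' @param rupture_index Index of state B.
#' @param sigma Baseline noise SD, pN.
#' @param lod Detection limit in sigma multiples.
#' @param radius Smoothing kernel width (points); use the radius returned by
#'   [windowed_derivative()].
#' @return Integer index of the binding minimum, or `NA_integer_` when no
#'   minimum clears the threshold ("no binding signal").
#' @export
detect_binding_minimum <- function(curve, rupture_index, sigma, lod,
                                   radius = 5L) {
  stopifnot(inherits(curve, "fd_curve"), sigma > 0)
  sm <- smooth_ma(curve$force, radius)
  last <- rupture_index - max(1L, radius)
  if (last < 3L) return(NA_integer_)
  i <- 2:(last - 1L)
  is_min <- sm[i] <= sm[i - 1L] & sm[i] < sm[i + 1L] & sm[i] < -lod * sigma
  cand <- i[is_min]
  if (!length(cand)) return(NA_integer_)
  max(cand) # closest before the rupture
}

# ---- step 4: bound state A --------------------------------------------------

#' Locate the bound state A
#'
#' State A is the zero-force point closest before the binding site: the
#' last index before `binding_index` where the smoothed force changes
#' sign and its magnitude lies within the `mul_base * sigma` baseline
#' fluctuation band. On a stretch segment the (attractive) tether force
#' decays toward the baseline as the tip approaches the bound state, so
#' the sign change marks the relaxed-linker point; the band requirement
#' rejects sign changes inside large contact features.
#'
#' @param curve Aligned [fd_curve()].
#' @param binding_index Index from [detect_binding_minimum()].
#' @param sigma Baseline noise SD, pN.
#' @param mul_base Baseline fluctuation bound in sigma multiples.
#' @param radius Smoothing kernel width, as in [detect_binding_minimum()].
#' @return Integer index of state A, or `NA_integer_` when no qualifying
#'   zero-force point precedes the binding site.
#' @export
locate_state_A <- function(curve, binding_index, sigma, mul_base,
                           radius = 5L) {
  stopifnot(inherits(curve, "fd_curve"), sigma > 0)
  if (binding_index < 2L) return(NA_integer_)
  sm <- smooth_ma(curve$force, radius)
  bound <- mul_base * sigma
  i <- seq_len(binding_index - 1L)
  crossing <- sm[i] * sm[i + 1L] <= 0 & abs(sm[i]) <= bound
  if (!any(crossing)) return(NA_integer_)
  max(which(crossing))
}

# ---- step 5: worm-like chain -----------------------------------------------

#' Worm-like-chain force law
#'
#' Interpolated WLC restoring force at extension `gamma`:
#' `F = (kBT / lp) * (0.25 * (1 - gamma/L)^-2 + gamma/L - 0.25)`,
#' in pN for nm inputs.
#'
#' @param extension Polymer extension `gamma`, nm, in `[0, contour_length)`.
#' @param contour_length Contour length `L`, nm.
#' @param persistence_length Persistence length `lp`, nm (default 0.37).
#' @param temperature Kelvin.
#' @return Force in pN (vectorised over `extension`).
#' @examples
#' wlc_force(30, 60) # half extension: (kBT/lp) * 1.25 ~ 13.9 pN
#' @export
wlc_force <- function(extension, contour_length, persistence_length = 0.37,
                      temperature = 298.15) {
  if (any(extension < 0) || any(extension >= contour_length)) {
    stop("extension must lie in [0, contour_length)", call. = FALSE)
  }
  x <- extension / contour_length
  (kbt_pn_nm(temperature) / persistence_length) *
    (0.25 * (1 - x)^-2 + x - 0.25)
}

#' Closed-form WLC work integral
#'
#' Antiderivative of [wlc_force()] from 0 to `extension`, returned in kBT:
#' `W = (1/lp) * ((L/4) * (gamma / (L - gamma)) + gamma^2 / (2L) - gamma/4)`.
#' Used as the analytic oracle for trapezoidal work integration and to
#' invert a target work into a rupture extension.
#'
#' @inheritParams wlc_force
#' @return Work in kBT.
#' @export
wlc_work_kbt <- function(extension, contour_length,
                         persistence_length = 0.37) {
  if (any(extension < 0) || any(extension >= contour_length)) {
    stop("extension must lie in [0, contour_length)", call. = FALSE)
  }
  g <- extension; L <- contour_length
  (1 / persistence_length) * ((L / 4) * g / (L - g) + g^2 / (2 * L) - g / 4)
}

#' Fit the worm-like chain to a stretch segment
#'
#' Nonlinear least squares of the WLC force magnitude against the negated
#' curve force between states A and the binding site, with the persistence
#' length held fixed and only the contour length free. Extension is
#' measured from state A.
#'
#' @param curve Aligned [fd_curve()].
#' @param index_A,binding_index Segment bounds (state A to binding minimum).
#' @param persistence_length nm, fixed during the fit.
#' @param temperature Kelvin.
#' @return List with `contour_length` (nm), `mean_abs_residual` (pN) and
#'   `converged` (logical).
#' @export
fit_wlc <- function(curve, index_A, binding_index,
                    persistence_length = 0.37, temperature = 298.15) {
  stopifnot(inherits(curve, "fd_curve"))
  idx <- index_A:binding_index
  if (length(idx) < 10L) {
    stop("stretch segment needs at least 10 points", call. = FALSE)
  }
  g <- curve$separation[idx] - curve$separation[index_A]
  y <- -curve$force[idx] # WLC restoring-force magnitude
  gmax <- max(g)
  kblp <- kbt_pn_nm(temperature) / persistence_length
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ kblp * (0.25 * (1 - g / L)^-2 + g / L - 0.25),
      start = list(L = gmax * 1.2),
      lower = gmax * 1.001, upper = gmax * 100,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(contour_length = NA_real_, mean_abs_residual = Inf,
                converged = FALSE))
  }
  list(contour_length = unname(coef(fit)[["L"]]),
       mean_abs_residual = mean(abs(residuals(fit))),
       converged = TRUE)
}

# ---- work integration --------------------------------------------------------

#' External pulling work between two states
#'
#' Trapezoidal integral `W = -int_A^B F dD_s` on the measured points of an
#' aligned curve, converted to kBT. Attractive (negative) forces yield
#' positive work.
#'
#' @param curve Aligned [fd_curve()].
#' @param index_A,index_B State indices, `index_A < index_B`.
#' @param temperature Kelvin, for the pN.nm -> kBT conversion.
#' @return Work in kBT (may be non-positive for non-events; callers reject
#'   `W <= 0`).
#' @export
integrate_work <- function(curve, index_A, index_B, temperature = 298.15) {
  stopifnot(inherits(curve, "fd_curve"), index_A < index_B)
  idx <- index_A:index_B
  w_pn_nm <- -pracma::trapz(curve$separation[idx], curve$force[idx])
  w_pn_nm / kbt_pn_nm(temperature)
}

# ---- full screen -------------------------------------------------------------

# internal: run the five steps on one curve; returns a disposition record
screen_curve <- function(curve, params) {
  rec <- function(step, sigma = NA_real_, work = NA_real_, event = NULL) {
    list(label = curve$label, accepted = !is.null(event),
         failed_step = if (is.null(event)) step else NA_character_,
         sigma = sigma, work = work, event = event)
  }
  deriv <- tryCatch(windowed_derivative(curve), error = function(e) NULL)
  if (is.null(deriv)) return(rec("derivative"))
  b <- detect_rupture(curve, deriv)
  if (is.na(b)) return(rec("rupture"))
  al <- tryCatch(align_baseline(curve, b, params$alpha_frac),
                 error = function(e) NULL)
  if (is.null(al)) return(rec("baseline"))
  aligned <- al$curve; sigma <- al$sigma
  bind_idx <- detect_binding_minimum(aligned, b, sigma, params$lod,
                                     radius = deriv$radius)
  if (is.na(bind_idx)) return(rec("binding_minimum", sigma))
  a_idx <- locate_state_A(aligned, bind_idx, sigma, params$mul_base,
                          radius = deriv$radius)
  if (is.na(a_idx)) return(rec("state_A", sigma))
  wlc <- tryCatch(
    fit_wlc(aligned, a_idx, bind_idx, params$persistence_length,
            params$temperature),
    error = function(e) list(converged = FALSE, mean_abs_residual = Inf,
                             contour_length = NA_real_)
  )
  if (!wlc$converged || wlc$mean_abs_residual > params$nls_err * sigma) {
    return(rec("wlc_fit", sigma))
  }
  w <- integrate_work(aligned, a_idx, b, params$temperature)
  if (!is.finite(w) || w <= 0) return(rec("work", sigma, w))
  span <- aligned$separation[b] - aligned$separation[a_idx]
  ev <- tryCatch(
    binding_event(a_idx, b, sigma, wlc$contour_length,
                  wlc$mean_abs_residual, w, span, label = curve$label),
    error = function(e) NULL
  )
  if (is.null(ev)) return(rec("wlc_fit", sigma, w))
  rec(NA_character_, sigma, w, event = ev)
}

#' Screen a dataset of curves for single binding events
#'
#' Applies the five detection steps to every curve and records, per curve,
#' either the accepted [binding_event()] or the first step that failed.
#'
#' @param curves List of [fd_curve()] objects.
#' @param params A [screening_params()].
#' @return List with `events` (accepted [binding_event()]s) and `qc`, a
#'   data.frame with columns `label`, `disposition` ("accepted" or
#'   "rejected"), `failed_step`, `sigma`, `work`.
#' @export
screen_dataset <- function(curves, params = screening_params()) {
  stopifnot(is.list(curves))
  recs <- lapply(curves, screen_curve, params = params)
  qc <- data.frame(
    label = vapply(recs, `[[`, character(1), "label"),
    disposition = ifelse(vapply(recs, `[[`, logical(1), "accepted"),
                         "accepted", "rejected"),
    failed_step = vapply(recs, `[[`, character(1), "failed_step"),
    sigma = vapply(recs, `[[`, numeric(1), "sigma"),
    work = vapply(recs, `[[`, numeric(1), "work"),
    stringsAsFactors = FALSE
  )
  events <- lapply(recs[qc$disposition == "accepted"], `[[`, "event")
  list(events = events, qc = qc)
}
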