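# Langmuir-kinetics analysis of SPR coverage traces: per-trace
# (theta_eq, k_obs) fits, linear regression of k_obs on concentration to
# extract association/dissociation rates, and the standard-state
# adsorption free energy from the dissociation constant.

#' Normalise a raw SPR signal to fractional coverage
#'
#' @param signal Raw instrument response.
#' @param saturation Response at full coverage (same units).
#' @return `signal / saturation`.
#' @export
normalize_coverage <- function(signal, saturation) {
  if (!(saturation > 0)) stop("saturation must be positive", call. = FALSE)
  signal / saturation
}

#' Fit one coverage trace to the Langmuir association model
#'
#' Nonlinear least squares of `theta(t) = theta_eq * (1 - exp(-k_obs t))`
#' on the trace truncated to `[0, t_max]`, with `theta_eq` in (0, 1] and
#' `k_obs > 0`. Starting values: `theta_eq` from the maximal observed
#' coverage and `k_obs` from the reciprocal time at half saturation.
#'
#' @param trace A [kinetic_trace()].
#' @param t_max Truncation time, s (`NULL` = use the whole trace).
#' @return List with `theta_eq`, `k_obs` (1/s), `rmse`, `n`,
#'   `concentration` (M).
#' @export
fit_langmuir_trace <- function(trace, t_max = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  keep <- if (is.null(t_max)) rep(TRUE, length(trace$time))
          else trace$time <= t_max
  tt <- trace$time[keep]
  th <- trace$coverage[keep]
  if (length(tt) < 10L) {
    stop("trace has fewer than 10 points within t_max", call. = FALSE)
  }
  if (any(th < -0.05) || any(th > 1.2)) {
    stop("coverage outside [0, 1.2]; normalise the trace first",
         call. = FALSE)
  }
  if (sd(th) == 0) stop("constant trace; no kinetics to fit", call. = FALSE)
  th0 <- min(max(max(th), 1e-3), 1)
  half_idx <- which(th >= th0 / 2)
  k0 <- if (length(half_idx) && tt[half_idx[1]] > 0) 1 / tt[half_idx[1]]
        else 1 / stats::median(tt[tt > 0])
  fit <- minpack.lm::nlsLM(
    th ~ a * (1 - exp(-k * tt)),
    start = list(a = th0, k = k0),
    lower = c(1e-6, 1e-9), upper = c(1, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- coef(fit)
  list(theta_eq = unname(co[["a"]]), k_obs = unname(co[["k"]]),
       rmse = sqrt(mean(residuals(fit)^2)), n = length(tt),
       concentration = trace$concentration)
}

#' Regress observed rates on concentration
#'
#' Ordinary least squares of `k_obs = ka * C + kd`: the slope is the
#' association rate `ka` (1/(M s)) and the intercept the dissociation rate
#' `kd` (1/s).
#'
#' @param points data.frame with columns `concentration` (M) and `k_obs`
#'   (1/s); at least two distinct concentrations.
#' @return List with `ka`, `kd`, `ka_se`, `kd_se` (standard errors, `NA`
#'   with only two points).
#' @export
regress_kobs <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "k_obs") %in% names(points)))
  if (length(unique(points$concentration)) < 2L) {
    stop("need at least two distinct concentrations", call. = FALSE)
  }
  fit <- lm(k_obs ~ concentration, data = points)
  co <- suppressWarnings(summary(fit))$coefficients
  ses <- if (nrow(points) > 2L) co[, "Std. Error"] else c(NA_real_, NA_real_)
  list(ka = unname(coef(fit)[["concentration"]]),
       kd = unname(coef(fit)[["(Intercept)"]]),
       ka_se = unname(ses[2]), kd_se = unname(ses[1]))
}

#' Standard-state adsorption free energy from the dissociation constant
#'
#' `dG_ads = ln(K_D / c0)` in kBT with the standard reference concentration
#' `c0 = 1 M`; negative for sub-molar dissociation constants. The kBT-unit
#' value is temperature independent (temperature only matters when
#' converting to J/mol).
#'
#' @param kD Dissociation constant, M (> 0).
#' @param temperature Kelvin; retained for unit conversions, unused for the
#'   kBT result.
#' @return Free energy in kBT.
#' @examples
#' dg_from_kd(0.154e-6) # ~ -15.69 kBT
#' @export
dg_from_kd <- function(kD, temperature = 293.15) {
  if (!(kD > 0)) stop("kD must be positive", call. = FALSE)
  log(kD)
}

#' Full Langmuir kinetics pipeline
#'
#' For each truncation window: fits every trace with
#' [fit_langmuir_trace()], flags traces whose fit RMSE exceeds three times
#' the median RMSE (plus a 0.01 coverage floor) — the residual-ratio rule
#' that excludes concentrations outside the dilute Langmuir regime — and
#' regresses the remaining `k_obs` on concentration to obtain `ka`, `kd`,
#' `K_D = kd / ka` and `dG_ads`. Repeating over several windows guards
#' against overfitting a single time range.
#'
#' @param traces List of [kinetic_trace()] objects.
#' @param windows Numeric vector of truncation times `t_max`, s.
#' @return A `kinetics_fit` object: `per_window` data.frame (`t_max`, `ka`,
#'   `kd`, `kD`, `dg_ads`, `n_traces`), `per_trace` data.frame (per window
#'   and concentration: `theta_eq`, `k_obs`, `rmse`, `flagged`), and
#'   `average` (`mean`/`sd` across windows for `ka`, `kd`, `kD`,
#'   `dg_ads`; `sd` is `NA` with a single window).
#' @export
kinetics_pipeline <- function(traces, windows = c(300, 350, 400)) {
  stopifnot(is.list(traces), length(traces) >= 2L, length(windows) >= 1L)
  per_trace <- list()
  rows <- lapply(windows, function(w) {
    fits <- lapply(traces, fit_langmuir_trace, t_max = w)
    rmse <- vapply(fits, `[[`, numeric(1), "rmse")
    flagged <- rmse > 3 * median(rmse) + 0.01
    pt <- data.frame(
      t_max = w,
      concentration = vapply(fits, `[[`, numeric(1), "concentration"),
      theta_eq = vapply(fits, `[[`, numeric(1), "theta_eq"),
      k_obs = vapply(fits, `[[`, numeric(1), "k_obs"),
      rmse = rmse, flagged = flagged
    )
    per_trace[[length(per_trace) + 1L]] <<- pt
    use <- pt[!pt$flagged, , drop = FALSE]
    reg <- regress_kobs(use)
    kD <- reg$kd / reg$ka
    data.frame(t_max = w, ka = reg$ka, kd = reg$kd, kD = kD,
               dg_ads = dg_from_kd(kD), n_traces = nrow(use))
  })
  per_window <- do.call(rbind, rows)
  avg <- lapply(per_window[c("ka", "kd", "kD", "dg_ads")], function(x) {
    list(mean = mean(x), sd = if (length(x) > 1L) sd(x) else NA_real_)
  })
  structure(
    list(per_window = per_window, per_trace = do.call(rbind, per_trace),
         average = avg),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit>\n")
  print(x$per_window, row.names = FALSE)
  a <- x$average
  cat(sprintf("  average: ka = %.4g 1/(M s), kd = %.4g 1/s, K_D = %.4g M, dG = %.4g kBT\n",
              a$ka$mean, a$kd$mean, a$kD$mean, a$dg_ads$mean))
  invisible(x)
}
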