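# Seeded generators for every input the pipeline consumes: gamma work
# samples, force-distance curves of several morphologies with ground-truth
# annotations, Langmuir coverage traces, and PMF profiles.

#' Generate a gamma-distributed work sample
#'
#' i.i.d. draws from Gamma(shape, rate), the work law observed for peptide
#' pulling; defaults reproduce a typical experimental work distribution
#' (mean ~192 kBT, SD ~91 kBT).
#'
#' @param n Sample size.
#' @param shape,rate Gamma parameters (rate in 1/kBT).
#' @param seed Optional integer seed; fixed seeds reproduce the sample.
#' @return A [work_sample()].
#' @export
gen_work_sample <- function(n, shape = 4.42, rate = 0.023, seed = NULL) {
  work_sample(with_seed(seed, rgamma(n, shape = shape, rate = rate)))
}

# internal: invert the closed-form WLC work for a rupture extension
solve_rupture_extension <- function(work_kbt, contour_length,
                                    persistence_length) {
  upper <- 0.995 * contour_length
  wmax <- wlc_work_kbt(upper, contour_length, persistence_length)
  if (work_kbt >= wmax) {
    stop("work_target ", work_kbt, " kBT exceeds what a ", contour_length,
         " nm tether can store (", round(wmax), " kBT)", call. = FALSE)
  }
  uniroot(function(g) wlc_work_kbt(g, contour_length, persistence_length) -
            work_kbt,
          lower = 1e-6, upper = upper, tol = 1e-10)$root
}

#' Generate a synthetic force-distance curve with ground truth
#'
#' Emulates AFM retraction traces: Gaussian baseline noise, optional linear
#' drift, a repulsive contact rise at the surface, a nonspecific adhesion
#' dip, and — for `single_event` curves — a worm-like-chain stretch from
#' the bound state to a rupture step back to baseline. `double_rupture`
#' curves superpose two tethers releasing at different separations;
#' `flat` and `drift_only` curves carry no binding signal.
#'
#' @param kind One of `"single_event"`, `"flat"`, `"double_rupture"`,
#'   `"drift_only"`.
#' @param work_target Pulling work the single event must embody, kBT; the
#'   rupture extension is solved from the closed-form WLC work integral.
#'   `NULL` draws a work from Gamma(4.42, 0.023).
#' @param contour_length Tether contour length, nm (default 50, a PEG
#'   linker with unbinding separations around 50 nm).
#' @param persistence_length WLC persistence length, nm.
#' @param noise_sd Baseline force noise SD, pN (default 10).
#' @param drift_slope Linear baseline drift, pN/nm (`NULL`: 0, except
#'   0.05 for `drift_only`).
#' @param drift_intercept Baseline force offset, pN.
#' @param temperature Kelvin.
#' @param n_points,z_max Grid resolution and maximal separation, nm.
#' @param state_A_nm True bound-state separation, nm.
#' @param seed Optional integer seed.
#' @param label Curve identifier.
#' @return List with `curve` (an [fd_curve()]) and `truth`: `kind`,
#'   `index_A`, `index_B`, `work_kbt`, `rupture_nm` (all `NA` for curves
#'   without a single event).
#' @export
gen_fdc <- function(kind = c("single_event", "flat", "double_rupture",
                             "drift_only"),
                    work_target = NULL, contour_length = 50,
                    persistence_length = 0.37, noise_sd = 10,
                    drift_slope = NULL, drift_intercept = 0,
                    temperature = 298.15, n_points = 1200L, z_max = 120,
                    state_A_nm = 8, seed = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (is.null(drift_slope)) {
    drift_slope <- if (kind == "drift_only") 0.05 else 0
  }
  if (is.null(label)) label <- paste0(kind, if (!is.null(seed)) paste0("_", seed))
  with_seed(seed, {
    z <- seq(0, z_max, length.out = n_points)
    force <- rnorm(n_points, 0, noise_sd) +
      drift_intercept + drift_slope * z +
      300 * exp(-z / 0.8) # contact repulsion
    truth <- list(kind = kind, index_A = NA_integer_, index_B = NA_integer_,
                  work_kbt = NA_real_, rupture_nm = NA_real_)
    add_adhesion <- function(f) f - 40 * exp(-((z - 2.5) / 0.8)^2)
    if (kind == "single_event") {
      force <- add_adhesion(force)
      w <- if (is.null(work_target)) rgamma(1, 4.42, 0.023) else work_target
      g_r <- solve_rupture_extension(w, contour_length, persistence_length)
      i_a <- which.min(abs(z - state_A_nm))
      z_a <- z[i_a]
      stretch <- z > z_a & z < z_a + g_r
      force[stretch] <- force[stretch] -
        wlc_force(z[stretch] - z_a, contour_length, persistence_length,
                  temperature)
      i_b <- which(z >= z_a + g_r)[1]
      truth$index_A <- i_a
      truth$index_B <- i_b
      truth$work_kbt <- wlc_work_kbt(g_r, contour_length, persistence_length)
      truth$rupture_nm <- z_a + g_r
    } else if (kind == "double_rupture") {
      force <- add_adhesion(force)
      i_a <- which.min(abs(z - state_A_nm))
      z_a <- z[i_a]
      l1 <- 0.8 * contour_length; g1 <- 0.8 * l1
      l2 <- contour_length + 5;   g2 <- 0.85 * l2
      s1 <- z > z_a & z < z_a + g1
      s2 <- z > z_a & z < z_a + g2
      force[s1] <- force[s1] - wlc_force(z[s1] - z_a, l1,
                                         persistence_length, temperature)
      force[s2] <- force[s2] - wlc_force(z[s2] - z_a, l2,
                                         persistence_length, temperature)
      truth$rupture_nm <- z_a + g2
    }
    list(curve = fd_curve(z, force, temperature = temperature, label = label),
         truth = truth)
  })
}

#' Generate a composed set of synthetic curves
#'
#' @param n Number of curves.
#' @param composition Named proportions over the [gen_fdc()] kinds; counts
#'   are rounded, single events fill the remainder.
#' @param seed Integer seed; curve `i` uses seed `seed + i`.
#' @param ... Passed to [gen_fdc()] (e.g. `noise_sd`, `contour_length`).
#' @return List with `curves` (list of [fd_curve()]) and `truths`.
#' @export
gen_fdc_set <- function(n, composition = c(single_event = 0.4, flat = 0.3,
                                           double_rupture = 0.2,
                                           drift_only = 0.1),
                        seed = 1L, ...) {
  all_kinds <- c("single_event", "flat", "double_rupture", "drift_only")
  stopifnot(n >= 1L, all(names(composition) %in% all_kinds))
  full <- setNames(numeric(4), all_kinds)
  full[names(composition)] <- composition
  counts <- floor(full / sum(full) * n)
  short <- n - sum(counts)
  top <- names(which.max(full))
  counts[top] <- counts[top] + short
  kinds <- rep(names(counts), counts)
  out <- lapply(seq_len(n), function(i) {
    gen_fdc(kinds[i], seed = seed + i,
            label = sprintf("%s_%03d", kinds[i], i), ...)
  })
  list(curves = lapply(out, `[[`, "curve"),
       truths = lapply(out, `[[`, "truth"))
}

#' Generate a Langmuir kinetic trace
#'
#' Forward model `theta(t) = C/(C + K_D) * (1 - exp(-(ka C + kd) t))` with
#' `K_D = kd/ka`, plus optional Gaussian noise. Defaults reproduce a
#' sub-micromolar peptide-surface system.
#'
#' @param concentration Analyte concentration, M.
#' @param ka Association rate, 1/(M s).
#' @param kd Dissociation rate, 1/s.
#' @param t_grid Times, s.
#' @param noise_sd Gaussian coverage noise SD.
#' @param seed Optional seed.
#' @param label Identifier.
#' @return A [kinetic_trace()].
#' @export
gen_kinetic_trace <- function(concentration, ka = 10073, kd = 1.55e-3,
                              t_grid = seq(0, 600, by = 1.5), noise_sd = 0,
                              seed = NULL, label = NULL) {
  kD <- kd / ka
  theta <- concentration / (concentration + kD) *
    (1 - exp(-(ka * concentration + kd) * t_grid))
  if (noise_sd > 0) {
    theta <- theta + with_seed(seed, rnorm(length(t_grid), 0, noise_sd))
  }
  kinetic_trace(t_grid, theta, concentration,
                label = if (is.null(label))
                  sprintf("C_%.3gM", concentration) else label)
}

#' Generate a synthetic PMF profile
#'
#' @param kind `"flat"` (zero everywhere), `"square_well"` (depth `-depth`
#'   up to `well_end`), or `"smooth_well_with_plateau"` (a contact wall, a
#'   deep adsorption well, a shallow diffusive shoulder between ~1 and
#'   ~2 nm, and a flat bulk plateau — the morphology of a peptide-surface
#'   mean-force profile).
#' @param depth Well depth, kBT.
#' @param shoulder_depth Diffusive-shoulder depth, kBT.
#' @param well_end End of the square well, nm.
#' @param grid Distance grid, nm.
#' @return A [pmf_profile()].
#' @export
gen_pmf <- function(kind = c("flat", "square_well",
                             "smooth_well_with_plateau"),
                    depth = 20, shoulder_depth = 5, well_end = 1.0,
                    grid = seq(0.2, 4.2, by = 0.01)) {
  kind <- match.arg(kind)
  e <- switch(kind,
    flat = rep(0, length(grid)),
    square_well = ifelse(grid < well_end, -depth, 0),
    smooth_well_with_plateau =
      8 * exp(-(grid - grid[1]) / 0.05) -
      (depth - shoulder_depth) * plogis(-(grid - 0.9) / 0.05) -
      shoulder_depth * plogis(-(grid - 2.0) / 0.12)
  )
  pmf_profile(grid, e)
}
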