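# Jarzynski-equality free-energy estimators on samples of pulling work
# (kBT units): the exponential-mean estimator, the fluctuation-dissipation
# (stiff-spring) estimator, and the closed-form gamma-work-distribution
# estimator with maximum-likelihood fitting and Kolmogorov-Smirnov
# diagnostics.

#' Exponential-mean Jarzynski estimator
#'
#' `dG_MN = -log((1/N) * sum(exp(-W_i)))`, evaluated through a shifted
#' log-sum-exp so samples with works of hundreds of kBT do not underflow.
#' By Jensen's inequality the result never exceeds the sample mean, and it
#' is bounded above by `min(W) + log(N)`.
#'
#' @param sample A [work_sample()] (or numeric vector of works, kBT).
#' @return Free-energy estimate, kBT.
#' @examples
#' dg_mean(c(log(2), log(4))) # -log((1/2 + 1/4)/2) = 0.98083
#' @export
dg_mean <- function(sample) {
  w <- work_values(sample)
  if (!length(w)) stop("empty work sample", call. = FALSE)
  m <- min(w)
  # -log(mean(exp(-w))) = m - log(mean(exp(-(w - m))))
  m - log(mean(exp(-(w - m))))
}

#' Fluctuation-dissipation (stiff-spring) estimator
#'
#' `dG_FD = mean(W) - var(W)/2` with the unbiased (`N/(N-1)`) variance.
#' Valid when the work fluctuation is comparable to kBT; with fluctuations
#' of tens of kBT it produces large negative, nonphysical values — a
#' diagnostic this package surfaces rather than hides.
#'
#' @param sample A [work_sample()] or numeric vector, length >= 2.
#' @return Free-energy estimate, kBT.
#' @export
dg_fd <- function(sample) {
  w <- work_values(sample)
  if (length(w) < 2L) stop("FD estimator needs at least 2 works", call. = FALSE)
  mean(w) - var(w) / 2
}

#' FD estimator from summary moments
#'
#' Convenience form of [dg_fd()] on a reported mean and SD:
#' `mean - sd^2 / 2`.
#'
#' @param mean_w Sample mean of the work, kBT.
#' @param sd_w Sample SD of the work, kBT.
#' @return Free-energy estimate, kBT.
#' @examples
#' fd_from_moments(195, 96) # -4413, a nonphysical large-fluctuation value
#' @export
fd_from_moments <- function(mean_w, sd_w) {
  mean_w - sd_w^2 / 2
}

#' Closed-form gamma-distribution free energy
#'
#' For work distributed as Gamma(shape `alpha`, rate `lambda`), the
#' Jarzynski exponential average has the closed form
#' `E[exp(-W)] = (lambda / (lambda + 1))^alpha`, so
#' `dG_GA = alpha * log((lambda + 1) / lambda)`.
#'
#' @param shape Gamma shape `alpha` (> 0).
#' @param rate Gamma rate `lambda` (> 0, units 1/kBT).
#' @return Free energy, kBT.
#' @examples
#' dg_gamma(1, 1) # log(2): exponential work distribution
#' dg_gamma(5.11, 0.039) # ~16.8 kBT, a peptide-on-gold scale value
#' @export
dg_gamma <- function(shape, rate) {
  if (!(shape > 0) || !(rate > 0)) {
    stop("shape and rate must be positive", call. = FALSE)
  }
  shape * log((rate + 1) / rate)
}

#' Maximum-likelihood gamma fit of a work sample
#'
#' Maximises the gamma log-likelihood by profiling out the rate
#' (`lambda = alpha / mean(W)`) and solving the shape score equation
#' `log(alpha) - digamma(alpha) = log(mean(W)) - mean(log(W))` by Newton
#' iteration from the closed-form initialiser
#' `alpha0 = (3 - s + sqrt((s - 3)^2 + 24 s)) / (12 s)`.
#' Convergence requires a relative shape step below `1e-10` (at most 100
#' iterations). The fit carries the closed-form free energy [dg_gamma()]
#' and the Kolmogorov-Smirnov goodness-of-fit of [ks_gamma_test()].
#'
#' @param sample A [work_sample()] or positive numeric vector, `N >= 5`,
#'   not constant.
#' @return A `gamma_fit` object: `shape`, `rate`, `log_likelihood`,
#'   `dg_gamma`, `ks_statistic`, `ks_pvalue`, `n`.
#' @export
fit_gamma_mle <- function(sample) {
  w <- work_values(sample)
  if (length(w) < 5L) stop("gamma MLE needs at least 5 works", call. = FALSE)
  if (any(w <= 0)) stop("gamma support requires W > 0", call. = FALSE)
  s <- log(mean(w)) - mean(log(w))
  if (!is.finite(s) || s <= 0) {
    stop("degenerate sample (constant works); gamma fit undefined",
         call. = FALSE)
  }
  alpha <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in seq_len(100L)) {
    g <- log(alpha) - digamma(alpha) - s
    gp <- 1 / alpha - trigamma(alpha)
    step <- g / gp
    new_alpha <- alpha - step
    while (new_alpha <= 0) { # damped step; score is monotone in alpha
      step <- step / 2
      new_alpha <- alpha - step
    }
    done <- abs(new_alpha - alpha) / alpha < 1e-10
    alpha <- new_alpha
    if (done) break
  }
  rate <- alpha / mean(w)
  ks <- ks_gamma_test(w, alpha, rate)
  structure(
    list(shape = alpha, rate = rate,
         log_likelihood = sum(dgamma(w, shape = alpha, rate = rate,
                                     log = TRUE)),
         dg_gamma = dg_gamma(alpha, rate),
         ks_statistic = ks$statistic, ks_pvalue = ks$p_value,
         n = length(w)),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(paste0("<gamma_fit: N = %d, shape = %.4g, rate = %.4g, ",
                     "dG = %.4g kBT, D_KS = %.3g (p = %.3g)>\n"),
              x$n, x$shape, x$rate, x$dg_gamma, x$ks_statistic, x$ks_pvalue))
  invisible(x)
}

#' Kolmogorov-Smirnov test of a fitted gamma work distribution
#'
#' One-sample KS statistic `D = sup |F_emp - F_gamma|` with the p-value
#' from the asymptotic Kolmogorov distribution, treating the fitted
#' parameters as known. (This is anticonservative once parameters are
#' estimated from the same data; set `bootstrap > 0` for a
#' parametric-bootstrap p-value instead.)
#'
#' @param sample A [work_sample()] or numeric vector.
#' @param shape,rate Gamma parameters.
#' @param bootstrap Number of parametric-bootstrap replicates (0 = use the
#'   asymptotic p-value).
#' @param seed Optional seed for the bootstrap.
#' @return List with `statistic` (`D_KS`) and `p_value`.
#' @export
ks_gamma_test <- function(sample, shape, rate, bootstrap = 0L, seed = NULL) {
  w <- work_values(sample)
  if (!length(w)) stop("empty work sample", call. = FALSE)
  res <- suppressWarnings(
    ks.test(w, pgamma, shape = shape, rate = rate, exact = FALSE)
  )
  d <- unname(res$statistic)
  p <- res$p.value
  if (bootstrap > 0L) {
    boot <- with_seed(seed, vapply(seq_len(bootstrap), function(i) {
      x <- rgamma(length(w), shape = shape, rate = rate)
      fit <- fit_gamma_mle(x)
      fit$ks_statistic
    }, numeric(1)))
    p <- mean(boot >= d)
  }
  list(statistic = d, p_value = p)
}

#' Hazen plotting positions of a work sample
#'
#' Empirical CDF positions `(i - 0.5) / N` paired with the sorted works,
#' as used to overlay the empirical and fitted gamma CDFs.
#'
#' @param sample A [work_sample()] or numeric vector.
#' @return data.frame with columns `work` (sorted) and `cdf`.
#' @export
empirical_cdf <- function(sample) {
  w <- sort(work_values(sample))
  n <- length(w)
  data.frame(work = w, cdf = (seq_len(n) - 0.5) / n)
}

#' Probability of negative work under a Gaussian model
#'
#' `Phi(-mean/sd)`: the left-tail mass a Gaussian work model places below
#' zero. Pulling work is nonnegative by construction, so appreciable mass
#' here flags the Gaussian (FD) model as inapplicable.
#'
#' @param mean_w,sd_w Gaussian mean and SD of the work, kBT.
#' @return Probability in (0, 1).
#' @export
prob_negative_gaussian <- function(mean_w, sd_w) {
  if (!(sd_w > 0)) stop("sd must be positive", call. = FALSE)
  pnorm(-mean_w / sd_w)
}

#' Full estimator report for one work sample
#'
#' Assembles all three Jarzynski estimators plus Gaussian diagnostics and
#' the gamma MLE (when `N >= 5`) into one record.
#'
#' @param sample A [work_sample()] or positive numeric vector.
#' @return An `estimate_report`: `n_events`, `dg_mean`, `dg_fd`,
#'   `gaussian_mean`, `gaussian_sd`, `prob_negative`, `gamma_fit`.
#' @export
estimate_all <- function(sample) {
  w <- work_values(as_work_sample(sample))
  n <- length(w)
  gf <- if (n >= 5L && sd(w) > 0) fit_gamma_mle(w) else NULL
  structure(
    list(n_events = n,
         dg_mean = dg_mean(w),
         dg_fd = if (n >= 2L) dg_fd(w) else NA_real_,
         gaussian_mean = mean(w),
         gaussian_sd = if (n >= 2L) sd(w) else NA_real_,
         prob_negative = if (n >= 2L && sd(w) > 0)
           prob_negative_gaussian(mean(w), sd(w)) else NA_real_,
         gamma_fit = gf),
    class = "estimate_report"
  )
}

#' @export
print.estimate_report <- function(x, ...) {
  cat(sprintf("<estimate_report: N = %d>\n", x$n_events))
  cat(sprintf("  mean estimator  dG_MN = %.4g kBT\n", x$dg_mean))
  cat(sprintf("  FD estimator    dG_FD = %.4g kBT\n", x$dg_fd))
  if (!is.null(x$gamma_fit)) {
    cat(sprintf("  gamma estimator dG_GA = %.4g kBT (shape %.4g, rate %.4g)\n",
                x$gamma_fit$dg_gamma, x$gamma_fit$shape, x$gamma_fit$rate))
  }
  cat(sprintf("  work: mean %.4g, sd %.4g kBT; P(W < 0 | Gaussian) = %.3g\n",
              x$gaussian_mean, x$gaussian_sd, x$prob_negative))
  invisible(x)
}

#' Screening-parameter scan
#'
#' Full-factorial evaluation of the screening + estimation pipeline over a
#' grid of screening thresholds. Each cell re-screens the curves and
#' re-estimates the free energies; the attached summary gives the mean and
#' SD of the gamma estimate over cells with enough accepted events —
#' convergence of that summary across the grid is the method's internal
#' consistency check.
#'
#' @param curves List of [fd_curve()] objects.
#' @param grid Named list with any of `alpha_frac`, `lod`, `mul_base`,
#'   `nls_err`, each a numeric vector of values to scan.
#' @param base_params [screening_params()] supplying the unscanned fields.
#' @param min_events Cells with fewer accepted events than this are dropped
#'   from the convergence summary (default 5, the gamma-MLE minimum).
#' @return data.frame with one row per grid cell: the four thresholds,
#'   `n_events`, `dg_mean`, `dg_fd`, `dg_gamma`; attribute `"summary"`
#'   holds `list(dg_gamma_mean, dg_gamma_sd, n_cells)`.
#' @export
parameter_scan <- function(curves, grid, base_params = screening_params(),
                           min_events = 5L) {
  allowed <- c("alpha_frac", "lod", "mul_base", "nls_err")
  if (!length(grid) || !all(names(grid) %in% allowed)) {
    stop("grid names must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    p <- base_params
    for (nm in names(cells)) p[[nm]] <- cells[[nm]][k]
    scr <- screen_dataset(curves, p)
    n <- length(scr$events)
    rep_ <- if (n >= 1L) estimate_all(vapply(scr$events, `[[`, numeric(1),
                                             "work_kbt")) else NULL
    data.frame(
      alpha_frac = p$alpha_frac, lod = p$lod, mul_base = p$mul_base,
      nls_err = p$nls_err, n_events = n,
      dg_mean = if (is.null(rep_)) NA_real_ else rep_$dg_mean,
      dg_fd = if (is.null(rep_)) NA_real_ else rep_$dg_fd,
      dg_gamma = if (is.null(rep_) || is.null(rep_$gamma_fit)) NA_real_
                 else rep_$gamma_fit$dg_gamma
    )
  })
  out <- do.call(rbind, rows)
  ok <- out$n_events >= min_events & is.finite(out$dg_gamma)
  attr(out, "summary") <- list(
    dg_gamma_mean = if (any(ok)) mean(out$dg_gamma[ok]) else NA_real_,
    dg_gamma_sd = if (sum(ok) > 1L) sd(out$dg_gamma[ok]) else NA_real_,
    n_cells = sum(ok)
  )
  out
}

#' Subsample stability of the gamma fit
#'
#' Repeatedly refits the gamma MLE on random subsamples (without
#' replacement) and reports the spread of the recovered parameters and
#' free energy — the overfitting check for the fitted work distribution.
#'
#' @param sample A [work_sample()] or numeric vector.
#' @param fraction Subsample fraction in (0, 1]; 1 reuses the full sample.
#' @param repeats Number of refits.
#' @param seed Optional integer seed.
#' @return List of `mean`/`sd` pairs for `shape`, `rate` and `dg_gamma`
#'   (`sd` is `NA` when `repeats < 2`), plus the per-repeat table.
#' @export
subsample_stability <- function(sample, fraction = 0.9, repeats = 10L,
                                seed = NULL) {
  w <- work_values(sample)
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  m <- max(5L, floor(fraction * length(w)))
  fits <- with_seed(seed, lapply(seq_len(repeats), function(i) {
    idx <- if (fraction < 1) sample.int(length(w), m) else seq_along(w)
    fit_gamma_mle(w[idx])
  }))
  tab <- data.frame(
    shape = vapply(fits, `[[`, numeric(1), "shape"),
    rate = vapply(fits, `[[`, numeric(1), "rate"),
    dg_gamma = vapply(fits, `[[`, numeric(1), "dg_gamma")
  )
  stat <- function(x) list(mean = mean(x),
                           sd = if (repeats >= 2L) sd(x) else NA_real_)
  list(shape = stat(tab$shape), rate = stat(tab$rate),
       dg_gamma = stat(tab$dg_gamma), repeats = tab)
}

# internal: evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
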