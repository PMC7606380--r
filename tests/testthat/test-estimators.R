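test_that("exponential-mean estimator matches hand oracles and never underflows", {
  # constant samples are fixed points
  for (w in c(0.5, 5, 120)) {
    expect_equal(dg_mean(rep(w, 3)), w, tolerance = 1e-12)
  }
  # two-point hand arithmetic: -log((1/2 + 1/4) / 2)
  expect_equal(dg_mean(c(log(2), log(4))), 0.9808293, tolerance = 1e-6)
  # works of hundreds of kBT: dominated by the smallest work + log N
  expect_equal(dg_mean(c(500, 600, 700)), 500 + log(3), tolerance = 1e-6)
  expect_error(dg_mean(numeric()), "empty")
})

test_that("Jensen's inequality bounds the mean estimator by the sample mean", {
  for (s in 1:10) {
    w <- gen_work_sample(50, shape = runif(1, 1, 8),
                         rate = runif(1, 0.01, 0.5), seed = s)$values
    expect_lte(dg_mean(w), mean(w))
    expect_lte(dg_mean(w), min(w) + log(length(w)))
  }
  expect_equal(dg_mean(rep(7, 10)), mean(rep(7, 10)))
})

test_that("FD estimator uses the unbiased variance exactly as defined", {
  expect_equal(dg_fd(c(5, 5, 5, 5)), 5)
  expect_equal(dg_fd(c(1, 3)), 1) # mean 2, unbiased var 2
  expect_error(dg_fd(5), "at least 2")

  expect_equal(fd_from_moments(1, 0), 1)
  expect_equal(fd_from_moments(195, 96), -4413)
  # large-fluctuation datasets: nonphysical values at the reported scale
  expect_rel(fd_from_moments(195, 96), -4431, 0.005)
  expect_rel(fd_from_moments(268, 133), -8619, 0.005)
  expect_equal(fd_from_moments(132, 58), -1550)
})

test_that("closed-form gamma free energy matches its defining identity", {
  expect_equal(dg_gamma(1, 1), log(2))
  # large-rate limit collapses to the FD (small-fluctuation) value
  expect_rel(dg_gamma(2, 1e6), 2e-6, 1e-5)
  expect_error(dg_gamma(-1, 1), "positive")
  expect_error(dg_gamma(1, 0), "positive")
  # dG = -log E[exp(-W)] with E[exp(-W)] = (rate/(rate+1))^shape
  for (s in 1:8) {
    a <- runif(1, 0.5, 10); l <- runif(1, 0.01, 5)
    expect_equal(dg_gamma(a, l), -log((l / (l + 1))^a), tolerance = 1e-10)
  }
})

test_that("gamma MLE is consistent, satisfies the score equation, and matches
          an independent fitting package", {
  w <- gen_work_sample(1e5, shape = 4.42, rate = 0.023, seed = 42)
  fit <- fit_gamma_mle(w)
  expect_rel(fit$shape, 4.42, 0.02)
  expect_rel(fit$rate, 0.023, 0.02)

  s <- log(mean(w$values)) - mean(log(w$values))
  expect_lt(abs(log(fit$shape) - digamma(fit$shape) - s), 1e-9)
  expect_equal(fit$dg_gamma, fit$shape * log((fit$rate + 1) / fit$rate))
  expect_gte(fit$ks_statistic, 0)
  expect_lte(fit$ks_statistic, 1)

  skip_if_not_installed("fitdistrplus")
  ref <- fitdistrplus::fitdist(gen_work_sample(2000, seed = 9)$values,
                               "gamma")
  ours <- fit_gamma_mle(gen_work_sample(2000, seed = 9))
  expect_rel(ours$shape, unname(ref$estimate[["shape"]]), 0.01)
  expect_rel(ours$rate, unname(ref$estimate[["rate"]]), 0.01)

  expect_error(fit_gamma_mle(rep(1, 5)), "degenerate")
  expect_error(fit_gamma_mle(c(1, 2, 3)), "at least 5")
})

test_that("KS goodness-of-fit behaves on constructed samples", {
  # sample placed at the gamma quantiles of Hazen positions: near-perfect fit
  q <- qgamma((1:1000 - 0.5) / 1000, 4.42, 0.023)
  ks <- ks_gamma_test(q, 4.42, 0.023)
  expect_lt(ks$statistic, 0.001)
  expect_gt(ks$p_value, 0.99)

  # power: uniform works are rejected against the gamma law
  set.seed(3)
  u <- runif(500, 0, 600)
  expect_lt(ks_gamma_test(u, 4.42, 0.023)$p_value, 0.01)

  # single observation at the median
  m <- qgamma(0.5, 4.42, 0.023)
  expect_equal(ks_gamma_test(m, 4.42, 0.023)$statistic, 0.5)
  expect_error(ks_gamma_test(numeric(), 1, 1), "empty")
})

test_that("empirical CDF uses Hazen plotting positions", {
  expect_equal(empirical_cdf(c(3, 1))$cdf, c(0.25, 0.75))
  expect_equal(empirical_cdf(c(3, 1))$work, c(1, 3))
  expect_equal(empirical_cdf(5)$cdf, 0.5)
  expect_equal(empirical_cdf(c(4, 2, 8, 6))$cdf,
               c(0.125, 0.375, 0.625, 0.875))
})

test_that("Gaussian negative-work probability matches the normal tail", {
  expect_equal(prob_negative_gaussian(0, 1), 0.5)
  expect_equal(round(prob_negative_gaussian(132, 58), 3), 0.011)
  expect_equal(round(prob_negative_gaussian(268, 133), 3), 0.022)
  for (s in 1:6) {
    m <- runif(1, 10, 300); sd_ <- runif(1, 5, 150)
    p <- prob_negative_gaussian(m, sd_)
    expect_gt(p, 0); expect_lt(p, 0.5)
  }
})

test_that("the full report is internally coherent", {
  rep_ <- estimate_all(gen_work_sample(300, seed = 6))
  expect_equal(rep_$n_events, 300)
  expect_lte(rep_$dg_mean, rep_$gaussian_mean)
  expect_gt(rep_$prob_negative, 0); expect_lt(rep_$prob_negative, 0.5)
  expect_equal(rep_$dg_fd,
               rep_$gaussian_mean - rep_$gaussian_sd^2 / 2)
  expect_s3_class(rep_$gamma_fit, "gamma_fit")
  # tiny samples skip the gamma fit but keep the rest
  small <- estimate_all(c(10, 20, 30))
  expect_null(small$gamma_fit)
  expect_false(is.na(small$dg_fd))
})

test_that("parameter scans are consistent, monotone and gamma-stable", {
  fix <- single_event_curves(60, seed = 21)
  curves <- c(fix$curves, gen_fdc_set(20, composition = c(flat = 1),
                                      seed = 77, noise_sd = 4)$curves)

  # a single cell reproduces direct estimation
  tab1 <- parameter_scan(curves, list(lod = 3), test_params())
  direct <- screen_dataset(curves, test_params())
  drep <- estimate_all(vapply(direct$events, `[[`, numeric(1), "work_kbt"))
  expect_equal(tab1$n_events, length(direct$events))
  expect_equal(tab1$dg_gamma, drep$gamma_fit$dg_gamma)
  expect_equal(tab1$dg_mean, drep$dg_mean)

  tab <- parameter_scan(curves, list(lod = c(3, 5, 7, 8.5),
                                     mul_base = c(2.5, 3.5)),
                        test_params())
  # events non-increasing in the detection limit at fixed mul_base
  for (mb in unique(tab$mul_base)) {
    sub <- tab[tab$mul_base == mb, ]
    expect_true(all(diff(sub$n_events[order(sub$lod)]) <= 0))
  }
  # the gamma estimate varies less across cells than the mean estimate
  ok <- tab$n_events >= 5
  expect_lte(sd(tab$dg_gamma[ok]), sd(tab$dg_mean[ok]))
  s <- attr(tab, "summary")
  expect_equal(s$n_cells, sum(ok))
  expect_error(parameter_scan(curves, list(bogus = 1)), "grid names")
})

test_that("subsample refits are stable and degenerate cases behave", {
  w <- gen_work_sample(1e4, seed = 15)
  full <- fit_gamma_mle(w)
  ss <- subsample_stability(w, fraction = 0.9, repeats = 10, seed = 2)
  expect_lte(abs(ss$dg_gamma$mean - full$dg_gamma),
             max(ss$dg_gamma$sd, 0.05))
  expect_lte(abs(ss$shape$mean - full$shape), max(ss$shape$sd, 0.05))

  # the full sample has no subsampling noise
  s1 <- subsample_stability(w, fraction = 1, repeats = 3, seed = 1)
  expect_equal(s1$dg_gamma$sd, 0)
  expect_equal(s1$dg_gamma$mean, full$dg_gamma)

  # one repeat has no defined spread
  s2 <- subsample_stability(w, fraction = 0.9, repeats = 1, seed = 1)
  expect_true(is.na(s2$dg_gamma$sd))
})
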