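test_that("windowed derivative flags a step and ignores a straight line", {
  z <- seq(0, 100, length.out = 600)
  step_idx <- 400L
  f <- ifelse(seq_along(z) >= step_idx, 50, 0)
  d <- windowed_derivative(fd_curve(z, f))
  expect_length(d$maxima, 1L)
  expect_lte(abs(d$maxima - step_idx), d$radius + 1L)

  line <- fd_curve(z, 2 + 0.3 * z)
  dl <- windowed_derivative(line)
  expect_length(dl$maxima, 0L)

  short <- fd_curve(z[1:50], f[1:50])
  expect_error(windowed_derivative(short, r_min = 30), "at least")
})

test_that("rupture detection picks the discontinuity farthest from the surface", {
  z <- seq(0, 100, length.out = 1000)
  f <- ifelse(z < 30, -60, ifelse(z < 55, -30, 0))
  b <- detect_rupture(fd_curve(z, f))
  expect_lte(abs(z[b] - 55), 1)

  # flat noisy curve: no significant maxima, no event
  set.seed(2)
  flat <- fd_curve(z, rnorm(1000, 0, 5))
  expect_true(is.na(detect_rupture(flat)))

  # seeded single-event fixture: rupture within the window radius of truth
  for (s in 1:5) {
    g <- gen_fdc("single_event", work_target = 192, noise_sd = 4, seed = s)
    d <- windowed_derivative(g$curve)
    b <- detect_rupture(g$curve, d)
    expect_lte(abs(b - g$truth$index_B), d$radius + 2L)
  }
})

test_that("baseline alignment removes drift and recovers the noise level", {
  set.seed(7)
  z <- seq(0, 120, length.out = 1100)
  noise_sd <- 3
  f <- 4 + 0.08 * z + rnorm(1100, 0, noise_sd)
  cv <- fd_curve(z, f)
  al <- align_baseline(cv, rupture_index = 500L, alpha_frac = 0.5)
  n <- length(z)
  base <- al$curve$force[(floor(n / 2) + 1):n] # ~550 baseline points
  expect_lt(abs(mean(base)), 0.5)
  expect_rel(al$sigma, noise_sd, 0.15)

  # zero-noise flat tail
  al0 <- align_baseline(fd_curve(z, rep(0, 1100)), 500L, 0.5)
  expect_equal(al0$sigma, 0)

  # too little baseline after the rupture
  expect_error(align_baseline(cv, rupture_index = 1095L, alpha_frac = 0.5),
               "fewer than 10")
})

test_that("binding-minimum detection honours the LOD threshold", {
  set.seed(9)
  z <- seq(0, 100, length.out = 1000)
  sigma <- 2
  dip <- -8 * sigma * exp(-((z - 60) / 2)^2)
  cv <- fd_curve(z, rnorm(1000, 0, 0.5) + dip)
  rupture <- 700L
  hit <- detect_binding_minimum(cv, rupture, sigma, lod = 5.5, radius = 5L)
  expect_false(is.na(hit))
  expect_lt(abs(z[hit] - 60), 3)

  # raising the detection limit above the dip depth rejects it
  expect_true(is.na(detect_binding_minimum(cv, rupture, sigma, lod = 9,
                                           radius = 5L)))

  # all-positive curve has no binding signal
  pos <- fd_curve(z, abs(rnorm(1000, 2, 0.5)))
  expect_true(is.na(detect_binding_minimum(pos, rupture, sigma, lod = 3,
                                           radius = 5L)))
})

test_that("state A sits at the zero-force point closest to the binding site", {
  z <- seq(0, 100, length.out = 1000)
  # deterministic descent crossing zero at a known index, then a stretch
  f <- numeric(1000)
  f[1:200] <- 5
  f[201:300] <- 5 - 35 * (1:100) / 100 # crosses zero near index 215
  f[301:1000] <- -30
  cv <- fd_curve(z, f)
  cross <- which(f <= 0)[1]
  a <- locate_state_A(cv, binding_index = 600L, sigma = 2, mul_base = 3,
                      radius = 5L)
  expect_lte(abs(a - cross), 3L)

  # a vanishing band admits no zero-force point
  expect_true(is.na(locate_state_A(cv, 600L, sigma = 2, mul_base = 1e-9,
                                   radius = 5L)))

  # widening the band never moves A farther from B
  for (s in 1:6) {
    g <- gen_fdc("single_event", work_target = 192, noise_sd = 4, seed = s)
    d <- windowed_derivative(g$curve)
    b <- detect_rupture(g$curve, d)
    al <- align_baseline(g$curve, b, 0.5)
    bi <- detect_binding_minimum(al$curve, b, al$sigma, 3, d$radius)
    idx <- vapply(c(2, 3, 4), function(mb) {
      locate_state_A(al$curve, bi, al$sigma, mb, d$radius)
    }, integer(1))
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("WLC force law matches direct substitution and is monotone", {
  expect_equal(wlc_force(0, 50), 0)
  expect_equal(wlc_force(30, 60), 13.907, tolerance = 1e-3)
  g <- seq(0, 0.999 * 50, length.out = 400)
  expect_true(all(diff(wlc_force(g, 50)) > 0))
  expect_gt(wlc_force(0.999 * 50, 50), 1000)
  expect_error(wlc_force(50, 50), "extension")
  expect_error(wlc_force(-1, 50), "extension")
})

test_that("WLC fitting recovers the contour length and applies the residual rule", {
  seg <- analytic_wlc_curve(contour_length = 50, gmax = 40, n = 300)
  fit <- fit_wlc(seg, 1L, 300L)
  expect_rel(fit$contour_length, 50, 0.001)
  expect_lt(fit$mean_abs_residual, 1e-6)

  # noisy segment: accepted at nls_err = 3, rejected at 0.01
  set.seed(5)
  noisy <- seg
  sigma <- 10
  noisy$force <- noisy$force + rnorm(300, 0, sigma)
  fitn <- fit_wlc(noisy, 1L, 300L)
  expect_lte(fitn$mean_abs_residual, 3 * sigma)
  expect_gt(fitn$mean_abs_residual, 0.01 * sigma)

  # affine (non-WLC) segment: the zero-extension force mismatch stays
  g <- seq(0, 30, length.out = 200)
  lin <- fd_curve(g, -(20 + 2 * g), label = "line")
  fitl <- fit_wlc(lin, 1L, 200L)
  expect_gt(fitl$mean_abs_residual, 3 * 1) # rejected for sigma ~ 1 pN
})

test_that("work integration matches analytic oracles", {
  z <- seq(0, 100, length.out = 1000)
  # zero force -> zero work
  expect_equal(integrate_work(fd_curve(z, numeric(1000)), 1L, 1000L), 0)

  # rectangular pulse -f between the integration bounds
  f <- numeric(1000); f[300:400] <- -10
  w <- integrate_work(fd_curve(z, f), 300L, 400L)
  expect_equal(w, 10 * (z[400] - z[300]) / kbt_pn_nm(298.15),
               tolerance = 1e-12)

  # dense analytic WLC from 0 to L/2 against the closed-form integral
  crv <- analytic_wlc_curve(contour_length = 60, gmax = 30, n = 5000)
  w2 <- integrate_work(crv, 1L, 5000L)
  expect_rel(w2, wlc_work_kbt(30, 60), 0.001)
})

test_that("drift injection does not change the recovered work", {
  p <- test_params()
  for (s in c(3, 8)) {
    g0 <- gen_fdc("single_event", work_target = 150, noise_sd = 4,
                  seed = s, drift_slope = 0)
    g1 <- gen_fdc("single_event", work_target = 150, noise_sd = 4,
                  seed = s, drift_slope = 0.05, drift_intercept = 6)
    r0 <- screen_dataset(list(g0$curve), p)
    r1 <- screen_dataset(list(g1$curve), p)
    expect_length(r0$events, 1L)
    expect_length(r1$events, 1L)
    expect_rel(r1$events[[1]]$work_kbt, r0$events[[1]]$work_kbt, 0.02)
  }
})

test_that("dataset screening separates single events from confounders", {
  set_ <- gen_fdc_set(100, seed = 5, noise_sd = 4)
  res <- screen_dataset(set_$curves, test_params())
  kind <- sub("_[0-9]+$", "", res$qc$label)
  acc <- res$qc$disposition == "accepted"

  # 40 single events in the composition; boundary cases may drop a few
  expect_gte(sum(acc & kind == "single_event"), 36)
  expect_lte(sum(acc & kind != "single_event"), 2)
  expect_true(all(!is.na(res$qc$failed_step[!acc])))
  expect_length(res$events, sum(acc))

  # every accepted event satisfies the record invariants
  for (ev in res$events) {
    expect_lt(ev$index_A, ev$index_B)
    expect_gt(ev$work_kbt, 0)
    expect_gt(ev$contour_length, ev$span_nm)
  }
})

test_that("raising the detection limit never gains events", {
  set_ <- gen_fdc_set(60, seed = 5, noise_sd = 4)
  counts <- vapply(c(3, 5, 7, 9), function(lod) {
    length(screen_dataset(set_$curves,
                          screening_params(lod = lod, mul_base = 3,
                                           nls_err = 3))$events)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  # tightening the WLC tolerance never gains events either
  counts2 <- vapply(c(3, 1, 0.2), function(ne) {
    length(screen_dataset(set_$curves,
                          screening_params(lod = 3, mul_base = 3,
                                           nls_err = ne))$events)
  }, numeric(1))
  expect_true(all(diff(counts2) <= 0))
})

test_that("screening an empty set yields an empty result", {
  res <- screen_dataset(list(), test_params())
  expect_length(res$events, 0L)
  expect_equal(nrow(res$qc), 0L)
})
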