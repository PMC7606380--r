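# Shared fixtures and expectations. Screening fixtures use a low-noise
# instrument (4 pN) with LOD = 3: the binding-minimum rule |F| > LOD*sigma
# bounds the detectable work from below (~30 kBT for a 50 nm tether at
# these settings), which truncates less than 0.5% of the Gamma(4.42,
# 0.023) work law, so recovered samples are comparable to generated ones.

expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}

test_params <- function(...) {
  screening_params(lod = 3, mul_base = 3, nls_err = 3, ...)
}

# single-event curves embodying works drawn from the gamma work law
single_event_curves <- function(n, seed, noise_sd = 4, ...) {
  works <- gen_work_sample(n, seed = seed)$values
  curves <- lapply(seq_len(n), function(i) {
    gen_fdc("single_event", work_target = works[i], noise_sd = noise_sd,
            seed = seed * 1000L + i, label = sprintf("ev_%03d", i), ...)$curve
  })
  list(curves = curves, works = works)
}

# noiseless curve sampling the analytic WLC law densely on [0, gmax]
analytic_wlc_curve <- function(contour_length = 60, gmax = 30,
                               n = 5000, lp = 0.37) {
  g <- seq(0, gmax, length.out = n)
  fd_curve(g, -wlc_force(g, contour_length, lp), label = "analytic_wlc")
}
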