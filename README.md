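# afmje

Recovery of equilibrium adsorption free energies from noisy
single-molecule pulling data, for researchers doing AFM force
spectroscopy of peptide– or protein–surface interactions (and anyone
cross-checking those numbers against SPR kinetics or molecular-dynamics
mean-force profiles).

## The problem and the method

The Jarzynski equality ties the equilibrium free energy ΔG of pulling a
molecule from its bound state A to its free state B to the
nonequilibrium work W (in units of k<sub>B</sub>T):

    exp(-ΔG) = ⟨exp(-W)⟩

Its finite-sample estimators behave very differently when the work
fluctuation is large, as it is for peptide–surface unbinding:

* **Mean estimator** `dg_mean()`:
  ΔĜ = −log(Σ exp(−Wᵢ)/N). Dominated by rare small works; does not
  converge at experimental sample sizes.
* **Fluctuation–dissipation estimator** `dg_fd()`:
  ΔĜ = W̄ − σ̂²/2. Valid only for near-Gaussian work with σ ≈ k_BT;
  wildly nonphysical otherwise.
* **Gamma estimator** `fit_gamma_mle()` + `dg_gamma()`: models the work
  as Gamma(α, λ), for which the Jarzynski average is exact:

      ΔG_GA = α · ln((λ + 1)/λ)

  The maximum-likelihood fit is driven by the bulk of the sample, so the
  estimate is stable at a few hundred events.

Around the estimators the package provides the full pipeline: automated
five-step screening of retraction force–distance curves for single
binding events (rupture detection by windowed derivatives, baseline
alignment, LOD-thresholded binding minima, bound-state location,
worm-like-chain fitting) with trapezoidal work integration
(`screen_dataset()`), threshold scans and subsample stability checks
(`parameter_scan()`, `subsample_stability()`), Langmuir kinetics for SPR
coverage traces (`kinetics_pipeline()`), potential-of-mean-force
reconstruction and state-partitioned adsorption free energies
(`reconstruct_pmf()`, `dg_ads()`), and seeded generators for every input
(`gen_fdc()`, `gen_work_sample()`, `gen_kinetic_trace()`, `gen_pmf()`).
See the vignette in `vignettes/free-energy-recovery.Rmd` for the model
details and design choices.

## Worked example

Screen a mixed set of 250 synthetic retraction curves — 200 single
events embodying works drawn from Gamma(α = 4.42, λ = 0.023), plus flat
and double-rupture confounders — then estimate the free energy three
ways:

```r
library(afmje)

works <- gen_work_sample(200, seed = 501)
curves <- lapply(seq_len(200), function(i)
  gen_fdc("single_event", work_target = works$values[i], noise_sd = 4,
          seed = 501000 + i)$curve)
confound <- gen_fdc_set(50, composition = c(flat = 0.6, double_rupture = 0.4),
                        seed = 9, noise_sd = 4)$curves

scr <- screen_dataset(c(curves, confound),
                      screening_params(lod = 3, mul_base = 3, nls_err = 3))
table(scr$qc$disposition)
#> accepted rejected
#>      197       53

estimate_all(as_work_sample(scr$events))
#> <estimate_report: N = 197>
#>   mean estimator  dG_MN = 51.55 kBT
#>   FD estimator    dG_FD = -4518 kBT
#>   gamma estimator dG_GA = 16.69 kBT (shape 4.343, rate 0.02191)
#>   work: mean 198.2, sd 97.12 kBT; P(W < 0 | Gaussian) = 0.0206
```

The gamma estimate lands within 0.5% of the generating value
`dg_gamma(4.42, 0.023)` = 16.77 k<sub>B</sub>T, while the mean estimator
overshoots threefold and the FD estimator is nonphysical — the
large-fluctuation failure modes the gamma work model is there to fix.
The screen rejected all 50 confounders (each tagged with the step that
failed) and 3 boundary-case events.

A command-line wrapper over the same functions ships in `exec/afmje`:

```sh
Rscript exec/afmje simulate fdc --n 50 --seed 1 --out curves
Rscript exec/afmje screen --curves curves --out events.json --qc qc.tsv
Rscript exec/afmje estimate --events events.json --out report.json
```

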