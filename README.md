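# hdqsm — hybrid data-fidelity dipole inversion for QSM

Quantitative susceptibility mapping (QSM) reconstructs tissue magnetic
susceptibility χ (ppm) from the local magnetic field encoded in
gradient-echo MRI phase. The deconvolution is ill-posed: the Fourier-domain
dipole kernel D(k) = 1/3 − kz²/|k|² vanishes on a conical surface, so noisy
or inconsistent voxels radiate conical *streaking artifacts* through the
reconstruction. This package is for MR physicists and image-reconstruction
researchers who want a robust, linear-cost dipole inversion and a
self-contained synthetic validation bench.

## The method

`hdqsm()` estimates χ in two TV-regularized stages, both solved with ADMM
and FFT-diagonal subproblems:

1. **L1 stage** — χ₁ = argmin ‖w (F^H D F χ − φ)‖₁ + λ·TV(χ).
   The absolute-error data term ignores outlier voxels (strong noise,
   unwrapping failures) instead of spreading them as streaks.
2. **L2 stage** — χ₂ = argmin ½‖W (F^H D F χ − φ)‖₂² + λ·TV(χ),
   warm-started at the stage-1 state, with the weight attenuated by the
   stage-1 residual r = |φ − F^H D F χ₁|:  W = w·(1 − r / max r).
   The quadratic stage denoises efficiently while the discrepancy factor
   keeps it from re-fitting exactly the voxels stage 1 rejected.

A one-free-parameter heuristic ties all six stage parameters to the single
regularization weight λ (equal λ across stages, μ₁ = 10·λ, μ₂ = 1), with
iteration split i1 ∈ [10, 100] of a fixed total budget. Setting i1 = 0 or
i2 = 0 recovers the single-norm L2/L1 baselines exactly.

The ADMM inner loop runs on an FFTW-backed C++ engine; a pure-R reference
engine (`engine = "R"`) produces identical iterates and anchors the test
oracles.

## Worked example

```r
library(hdqsm)

# 48^3 phantom, SNR 100, two +/-20pi phase jumps injected into the phase
sim <- simulate_cosmos_experiment(
  phantom_spec(shape = c(48, 48, 48), snr = 100, n_jumps = 2L, seed = 3))

fit <- hdqsm(sim$phase_corrupted, sim$weight, sim$kernel_rad,
             heuristic_params(lambda = 0.18, mu_ratio = 10,
                              i_total = 100, i1 = 20),
             mask = sim$mask, truth = sim$chi)
fit
#> Hybrid data-fidelity QSM reconstruction
#>   grid: 48 x 48 x 48 voxels; mask: 33256 voxels
#>   stage 1 (L1): 20 iterations; stage 2 (L2): 80 iterations
#>   lambda = 0.18, mu1/lambda = 10
#>   final NRMSE: 14.04%

nrmse(coef(fit), sim$chi, sim$mask)     # final error, percent
#> [1] 14.03716
nrmse(coef(fit, stage = 1), sim$chi, sim$mask)  # after the L1 stage alone
#> [1] 60.16885
```

The stage-1 estimate is sub-regularized and noisy (60% NRMSE after its 20
iterations) but streak-free; the discrepancy-weighted L2 stage refines it
to 14%. A pure L2 reconstruction of the same corrupted data stays above
100% NRMSE at every λ — the jump voxels dominate it. `plot(fit)` draws the
per-iteration NRMSE trace with the stage transition marked;
`residuals(fit)` returns the field-domain misfit; `region_stats()`,
`hfen()` and `xsim()` give per-structure and global quality metrics.

A thin CLI wraps the same functions
(`exec/hdqsm simulate | reconstruct | sweep | evaluate`), exchanging
volumes as NIfTI and writing a JSON manifest per run.

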