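# nirsdot

Tomographic reconstruction and nonparametric hemodynamic response
deconvolution for functional near-infrared spectroscopy (fNIRS).

Continuous-wave fNIRS measures optical-density (OD) changes between scalp
source-detector pairs at two wavelengths. `nirsdot` turns those channel
recordings into cortical maps of oxy-/deoxyhemoglobin change and estimates
the full time course of the hemodynamic response function (HRF) at every
cortical vertex without assuming its shape — the analysis chain needed
when response timing itself is the question (motor/visual mapping,
epileptic discharges, HRF variability studies).

The chain, in the field's standard notation:

1. **Forward model.** ΔOD^λ = A^λ Δμa^λ per wavelength λ ∈ {685, 830} nm,
   with A the channels × vertices sensitivity matrix.
2. **Inverse.** A two-level hierarchical model, y_t = A x_t + e₁ with
   e₁ ~ N(0, h₁C₁) and x_t ~ N(0, h₂I); restricted maximum likelihood
   (ReML) estimates (h₁, h₂) by maximizing the free energy
   F = −(T/2)[log|Σ| + tr(Σ⁻¹S)], Σ = h₁C₁ + h₂AAᵀ, and the posterior
   mean x̂_t = h₂AᵀΣ⁻¹y_t is the L2-minimum-norm reconstruction. Both
   wavelengths share one hyperparameter pair (fusion model).
3. **Unmixing.** Δ[HbO]/Δ[HbR] from Δμa at the two wavelengths via the
   2×2 extinction-coefficient solve.
4. **Deconvolution.** Per vertex, a GLM with a finite-impulse-response
   (FIR) basis (one free coefficient per peristimulus sample, window −5
   to +30 s) plus discrete-cosine drifts (< 0.01 Hz); two-pass AR(1)
   maximum-likelihood GLS (OLS pass → Yule-Walker ρ̂ from residuals → GLS
   pass); partial F-test on the K FIR coefficients,
   F = ((N−L)/N) · β̂_hᵀΘ_h⁻¹β̂_h / (Kσ̂²) ~ F(K, N−L), Bonferroni-corrected
   over the field of view.
5. **Validation.** A simulation framework (toy anatomies, greedy montages,
   parametric sensitivity profiles, difference-of-two-gammas HRFs,
   physiological resting noise, exact SNR control) plus recovery metrics:
   normalized shape MSE and gamma-refit errors of peak latency (TTP) and
   width (FWHM).

See `vignettes/nirsdot-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Simulate a canonical-HRF dataset at 0 dB SNR on a toy anatomy, then run
the full reconstruction and deconvolution chain:

```r
library(nirsdot)

setup <- sweep_setup(seed = 1)        # anatomy + montage + sensitivity
paradigm <- generate_paradigm(seed = 1)  # 30 x 200 ms trials, ITI 2-60 s
sim <- simulate_dataset(setup$surface, setup$montage, setup$sens,
                        model_id = 1, paradigm, target_snr_db = 0, seed = 2)
result <- evaluate_dataset(sim, setup$sens)
result$map
result$metrics[, c("chromophore", "mse", "ttp1", "fwhm1", "err_ttp1")]
```

which prints

```
Deconvolution map over 156 FOV vertices (alpha = 0.05 , Bonferroni )
  HbO: 63 significant vertices (F > 1.423)
  HbR: 39 significant vertices (F > 1.423)

  chromophore    mse ttp1 fwhm1 err_ttp1
1         HbO 0.0015  5.9   5.3     0.11
2         HbR 0.0044  7.8   5.9     0.22
```

At 0 dB the F-maps localize the simulated region for both chromophores,
and refitting a difference of gammas to the deconvolved HRF at the peak
vertex recovers the simulated first-peak latency (truth: 6 s for HbO, 8 s
for HbR after the hemodynamic delay) to ~0.1-0.2 s; the shape error (MSE
between unit-normalized curves) is ~10⁻³. `run_snr_sweep()` repeats this
over models × SNR levels × replicates and `summarize_sweep()` tabulates
the error distributions.

A thin command-line front end is installed at `inst/exec/nirsdot`
(subcommands `simulate`, `reconstruct`, `deconvolve`, `evaluate`,
`pipeline`), configured by a YAML file with study-scale defaults (5 Hz,
10-minute run, 30 trials). The staged subcommands pass CSV/JSON artifacts
through a run directory, with the channel noise covariance estimated from
the initial rest period of the recording being inverted.

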