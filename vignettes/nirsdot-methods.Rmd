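---
title: "Reconstructing and deconvolving hemodynamic responses from fNIRS channel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and deconvolving hemodynamic responses from fNIRS channel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nirsdot` estimates hemodynamic response functions (HRFs) along a cortical
surface from continuous-wave functional near-infrared spectroscopy (fNIRS)
recordings. The chain has four stages: a linear forward model linking cortical
absorption changes to channel optical density (OD), a hierarchical ReML
minimum-norm tomographic inverse, spectral unmixing into oxy- and
deoxyhemoglobin (HbO/HbR), and a nonparametric finite-impulse-response (FIR)
deconvolution with AR(1) generalized least squares and partial-F inference.
A simulation framework generates SNR-controlled synthetic datasets and the
recovery metrics used to validate the chain. This vignette documents the
models, their assumptions, the tunable parameters and the numerical choices.

## Forward model and synthetic sensitivity

For each wavelength $\lambda$ the measurement model is linear,
$\Delta OD^\lambda = A^\lambda\, \Delta\mu_a^\lambda$, with $\Delta OD$ the
base-e optical-density change per channel (dimensionless), $\Delta\mu_a$ the
absorption change per cortical vertex (cm$^{-1}$), and $A^\lambda$ the
channels $\times$ vertices sensitivity matrix in cm. In practice $A$ comes
from Monte Carlo photon transport through a segmented head model; this
package replaces it with a parametric stand-in,
$$A_{cv} = g_\lambda \exp(-d_s(v)/\ell)\,\exp(-d_d(v)/\ell),$$
where $d_s, d_d$ are distances from vertex $v$ to the channel's source and
detector scalp positions and $\ell$ (`decay_scale_mm`, default 12 mm) sets
how fast sensitivity decays away from the optode pair. The product of the
two exponentials reproduces the qualitative structure of diffuse-light
sensitivity: banana-shaped profiles peaked between the optodes, heavy
overlap between neighbouring channels, and severe ill-conditioning. It is a
stand-in, not a fit to photon-transport output: absolute reconstruction
amplitudes are not interpretable, and conclusions about depth sensitivity
do not transfer. The field of view (FOV) keeps every vertex whose best
channel sensitivity reaches 10% of the matrix-wide maximum
(`fov_threshold_fraction = 0.1`); sub-threshold columns are retained in $A$.

The toy anatomy is a jittered spherical-cap patch (default 300 vertices,
sphere radius 70 mm) with a scalp shell offset 12 mm outward and a
contiguous ROI around the apex (default radius 12 mm), playing the role of
a functionally defined target such as the motor hand knob. Montages are
placed greedily on scalp vertices nearest the ROI under the standard
constraints: channel separations within 2.5--3.5 cm, optodes at least 2 cm
apart, every source measured by at least two detectors. The greedy
placement replaces mixed-integer optimal-montage solvers; the constraints
are enforced as hard checks, the optimality of coverage is not.

## Hierarchical ReML inverse

Per wavelength, channel data follow the two-level model
$y_t = A x_t + e_1$, $e_1 \sim \mathcal N(0, h_1 C_1)$,
$x_t \sim \mathcal N(0, h_2 I)$. $C_1$ is the channel noise covariance,
estimated from a resting recording (sample covariance over a 60 s window,
shrunk toward its diagonal with weight 0.1 to guarantee invertibility with
few samples). The identity source prior makes the posterior mean the
classical L2 minimum-norm estimate with data-driven regularization:
$\hat x_t = h_2 A^\top \Sigma^{-1} y_t$ with
$\Sigma = h_1 C_1 + h_2 A A^\top$.

The hyperparameters maximize the restricted likelihood (free energy) of the
temporal second-moment matrix $S = \tfrac1T \sum_t y_t y_t^\top$,
$$F(h) = -\tfrac{T}{2}\left[\log\lvert\Sigma\rvert +
\operatorname{tr}(\Sigma^{-1} S)\right] + \text{const},$$
by Fisher scoring on $\log h$ (positivity by construction), with
step-halving so $F$ never decreases; convergence is declared when the
relative change falls below $10^{-6}$ (cap 128 iterations). Initialization
uses the trace-matching values $h_1 = \operatorname{tr}(S)/\operatorname{tr}(C_1)$,
$h_2 = \operatorname{tr}(S)/\operatorname{tr}(AA^\top)$. Hyperparameters
are estimated once per run and a single linear operator is applied to all
samples.

The two wavelengths form one block-diagonal "fusion" system and share one
$(h_1, h_2)$ pair by default (`share_hyperparameters = TRUE`). This is not
merely cosmetic: the downstream 2$\times$2 unmixing into HbO/HbR assumes
both absorption maps sit on a common amplitude scale. With independent
per-wavelength hyperparameters the two minimum-norm operators shrink by
different amounts and the unmixing leaks the (3$\times$ larger) HbO
response into HbR; with a shared pair the residual scale mismatch comes
only from the wavelength gain difference and is much smaller. The
independent variant remains available for comparison.

Minimum-norm amplitude bias (overestimation at sensitivity peaks,
underestimation away from them) is a known property of the prior and is not
corrected; all shape-level validation metrics are computed on normalized
curves for this reason.

Hemoglobin conversion uses tabulated molar extinction coefficients at
685/830 nm (rounded from the standard compilation, stored base-10 and
converted to base-e), applied per vertex and sample as a 2$\times$2 solve.
The wavelength pair is fixed at 685/830 nm throughout.

## FIR deconvolution with AR(1) GLS

At each FOV vertex the reconstructed HbO or HbR series is modelled as
$$y[n] = \sum_{i=1}^{K} s[n-(i+k_0-1)]\,\beta_i +
\sum_{m=1}^{M} d_m[n]\,\beta_{K+m} + e[n],$$
a Toeplitz FIR block built from the binary stimulus vector (zero boundary
conditions) plus an orthonormal discrete-cosine drift basis keeping every
frequency strictly below 0.01 Hz ($M = 12$ for a 10-minute run at 5 Hz).
The FIR window default is $-5$ to $+30$ s ($k_0 = -25$, $K = 176$ at 5 Hz):
wide enough for pre-stimulus fluctuations and late undershoots of all
simulated shapes; the exact window is a package default, not a sharp
methodological constant.

Errors are AR(1): $\Omega_{ij} = \rho^{|i-j|}$. The estimator is the
two-pass maximum-likelihood procedure: an ordinary least-squares pass, a
lag-1 Yule--Walker estimate of $\rho$ from its residuals (clipped to
$\pm 0.99$), then one generalized pass
$\hat\beta = (X^\top\Omega^{-1}X)^{-1} X^\top \Omega^{-1} y$ with the ML
variance $\hat\sigma^2 = \tfrac1N (y - X\hat\beta)^\top \Omega^{-1}
(y - X\hat\beta)$. $\rho$ is estimated per series and not iterated further.
Numerically, $\Omega^{-1}$ is never materialized: its tridiagonal form
reduces every cross-product to three precomputed Gram pieces of $X$ plus
$O(L^2)$ per series, so thousands of vertices (or null simulations) fit
against one design in seconds; the analytic whitening filter (first sample
scaled by $\sqrt{1-\rho^2}$) gives the same estimator and serves as the
test oracle.

The FIR block is tested jointly with the partial F statistic
$$F = \frac{N-L}{N}\,
\frac{\hat\beta_h^\top \Theta_h^{-1} \hat\beta_h}{K \hat\sigma^2}
\sim F_{K,\,N-L} \text{ under } H_0,$$
$\Theta_h$ the $K\times K$ block of $(X^\top\Omega^{-1}X)^{-1}$; the
$(N-L)/N$ factor converts the ML variance to the unbiased scale. Cortical
maps are thresholded at $\alpha = 0.05$ Bonferroni-corrected by the number
of FOV vertices. Degenerate fits are handled explicitly: an exactly zero
FIR block gives $F = 0$, $p = 1$; a perfect fit with nonzero coefficients
gives $F = \infty$.

## Simulation framework

Simulated responses use the difference of two gamma lobes
$$\mathrm{HRF}(t) = (t/T_1)^{a_1} e^{-(t-T_1)/b_1} -
\gamma\,(t/T_2)^{a_2} e^{-(t-T_2)/b_2},$$
with each lobe's shape tied to its time-to-peak and width through
$a_i = 8\ln 2\, T_i^2/W_i^2$, $b_i = W_i^2/(8 \ln 2\, T_i)$, so each lobe
peaks at exactly 1 at $t = T_i$. Four reference models are packaged
(`hrf_model_table()`): canonical (6/5.2/15/9/0.1), short duration
(5/1/6/2/0.1), long duration (5/10/--/--/0) and large undershoot
(5/5.2/15/9/0.5). HbO curves are scaled to a +3 umol/L maximum; HbR curves
use the same parameters with both peak latencies delayed 2 s, sign
inverted, scaled to a $-1$ umol/L extremum. Scaling is applied to the
complete difference-of-gammas curve, after the undershoot subtraction.
Lobes are evaluated in log space because extreme shape parameters
(encountered during refitting) otherwise produce $0 \cdot \infty$.

The paradigm is rapid event-related: 30 trials of 200 ms with inter-trial
intervals drawn uniformly in 2--60 s and rescaled to fill a 600 s run at
5 Hz. ROI vertices share one HbO and one HbR time course (stimulus train
convolved with the model HRFs); all other vertices are silent. After
conversion to absorption and forward projection, resting-state noise is
added: per channel an AR(1) baseline ($\rho = 0.8$), sinusoids at cardiac
(1.1 Hz), respiratory (0.25 Hz) and Mayer-wave (0.1 Hz) frequencies with
random phases, white noise, and a shared superficial component with random
channel weights inducing spatial correlation. Oscillations can be made
quasi-periodic through a random-walk phase drift (`phase_jitter`), which is
the more realistic setting for calibration studies -- a sinusoid
phase-locked over 10 minutes is not a physiological oscillation. The
defaults are declared, not fitted to any particular instrument: no
deposited resting runs exist to fit, and passing tests therefore show
robustness to this noise family, not to every real acquisition.

A single factor $\tau$ scales the noise of all channels at both
wavelengths, preserving relative amplitudes; it is tuned so the most
ROI-sensitive 830 nm channel reaches a target SNR,
$\mathrm{SNR} = 10\log_{10}\!\left(\langle \Delta OD_{\text{evoked}}\rangle /
\tau^2 \langle \Delta OD_{\text{rest}}\rangle\right)$, with
$\langle\cdot\rangle$ the mean sum of squares. The inversion is exact, so
recomputing the SNR on a stored dataset reproduces the target to
$10^{-9}$ dB.

In the full simulation pipeline the channel covariance $C_1$ is estimated
from the first 60 s of the scaled resting recording stored with each
dataset -- the analog of estimating it from a separately acquired resting
run, as done in practice.

## Validation metrics

Recovery is scored at the vertex with maximal $|\hat\beta_i|$ at the FIR
sample nearest the simulated model's first-peak latency, among significant
vertices (all FOV vertices, flagged, when none pass -- low-SNR cells are
then reported for comparison only). Published effect-size maps
conventionally use the canonical 6 s (HbO) / 8 s (HbR) latencies and
`map_deconvolution()` keeps those as defaults, but the validation selector
must use each simulated model's own latency: a 1 s-wide response peaking at
5 s has essentially no amplitude at 6 s, and selecting there turns the
metric into a noise lottery.

The shape error is the mean squared difference after normalizing both
curves to extremum magnitude 1 with sign preserved (so HbO and HbR are
treated symmetrically and the known amplitude bias of the minimum-norm
inverse does not contaminate shape scores); the MSE covers the full FIR
window including the pre-stimulus segment. Peak parameters are recovered by
bounded nonlinear least squares (Levenberg--Marquardt) over
$(T_1, W_1, T_2, W_2, \gamma)$, initialized at the simulated truth, with
the model curve renormalized at every evaluation; for no-undershoot fits
($\gamma$ initialized at 0) only the main-lobe parameters are free. Two
numerical guards keep the fit inside the regime where the parameters mean
what they say: $\gamma \ge 0.01$ in two-lobe fits (at $\gamma = 0$ the
undershoot latency is undefined), and a smooth hinge penalty enforcing
$T_2 - T_1 \ge 0.25\,(W_1 + W_2)$. Without the latter, two nearly
coincident cancelling lobes can reproduce almost any smooth waveform --
fits occasionally drifted to $T_1 \approx T_2$, $\gamma \approx 1$
configurations whose "time to peak" no longer describes the curve's peak.
All four reference models satisfy the constraint with a wide margin, and
noiseless refits recover every tabulated parameter set to $10^{-3}$ s.

The SNR-sweep harness replicates the full chain over models $\times$ SNR
levels $\times$ seeded replicates, each replicate drawing its own toy
anatomy and noise (10 replicates emulate the 10 subject-specific anatomies
of a typical validation cohort). Study-scale defaults follow the
conditions above; the packaged acceptance script uses 10 replicates for
the canonical 0 dB cells and 5 per cell elsewhere, and 1000 null series
for calibration -- sizes chosen to keep a full run in tens of seconds on
one core while leaving Monte-Carlo error well below the bounds being
checked.

## Known limitations

* The sensitivity model is parametric; nothing is claimed about absolute
  amplitudes or depth profiles, and FOV geometry only loosely resembles
  subject-specific photon-transport output.
* Minimum-norm amplitude bias is uncorrected; metrics are shape-based.
* One AR(1) coefficient per series: higher-order serial structure (e.g.
  unmodelled coherent oscillations inside the pass band) degrades F-test
  calibration; the null studies quantify this for quasi-periodic
  physiology.
* Motion artifacts, block designs and multi-condition paradigms are
  supported structurally (stacked FIR blocks) but not validated here.
* Greedy montages are feasible, not optimal.
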