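---
title: "Time-frequency denoising of single-trial ERPs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency denoising of single-trial ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Event-related potentials (ERPs) such as the P300 are stimulus-locked
deflections of a few microvolts riding on ongoing EEG, alpha rhythm and
muscle (EMG) activity an order of magnitude larger. The classical remedy —
averaging dozens of trials — destroys exactly the trial-to-trial latency
and amplitude variability that is often the quantity of interest.
`tfdenoise` implements a single-channel, single-trial denoiser that works
in the time-frequency domain, together with the standard single-channel
baselines it is usually compared against and a benchmarking harness.

# The method

For a one-second trial $x(t)$ sampled at 250 Hz:

1. **STFT.** $x(t)$ is mapped to a complex spectrogram $X(t,f)$
   (`stft()`). The magnitude of $X$ is treated as an image: the energy
   density of an ERP trial evolves smoothly and repeats structure across
   time, which is what makes image denoisers applicable.
2. **BEMD.** Bidimensional empirical mode decomposition (`bemd()`) splits
   the magnitude image into bidimensional intrinsic mode functions
   (BIMFs) ordered from fine to coarse spatial scale, plus a residue
   carrying the trend:
   $X(t,f) = \sum_{i=1}^{N} \mathrm{BIMF}_i(t,f) + r_N(t,f)$.
   Each mode is obtained by sifting: extrema of the image are detected by
   strict 8-neighbour comparison, upper and lower envelope surfaces are
   fitted through them, and the envelope mean is subtracted until the
   normalised squared change between consecutive iterates,
   $\sum_{t,f} [h_{p-1} - h_p]^2 / h_{p-1}^2$, drops below a threshold
   (default 0.25).
3. **NLM.** Each BIMF and the residue are filtered by non-local means
   (`nlm_denoise()`): every pixel is replaced by a weighted average over
   the whole image, the weight of pixel $j$ for pixel $i$ being
   $w(i,j) = \exp(-d(i,j)/h^2)/c(i)$, where $d(i,j)$ is the
   Gaussian-weighted squared distance between the $5\times5$ patches
   around $i$ and $j$ and $c(i)$ normalises the weights to 1. Noise in a
   mode image averages out across self-similar structure, while the
   ERP's energy ridge is preserved.
4. **Recombination and inversion.** The filtered components are summed,
   negative magnitudes clipped to zero, the original phase reattached,
   and the inverse STFT (`istft()`) returns a time-domain signal of the
   input's length (`tf_denoise()` runs steps 1–4).

The approach assumes that (a) the informative signal concentrates in
low-order frequency rows and coarse modes, (b) noise dominates the fine
modes, and (c) magnitudes, not phases, carry the removable noise. None of
these is exactly true; they are the working assumptions of the method.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| STFT window | 64 samples (hann) | samples | 256 ms at 250 Hz ≈ 3.9 Hz/row; the 2–30 Hz ERP band occupies ~8 informative rows |
| STFT hop | 16 samples | samples | 75% overlap, comfortably satisfies the overlap-add inversion condition |
| BEMD modes | 5 | — | in practice the fifth mode of an ERP spectrogram is residue-like; deeper decomposition adds cost, not structure |
| Sift threshold | 0.25 | — | stopping criterion on the normalised squared change between sift iterates |
| Max sift iterations | 10 | — | bounds runtime; the threshold test divides by $h_{p-1}^2$ and cells near zero can keep the criterion large indefinitely |
| NLM patch radius | 2 (5×5) | pixels | smallest patch that captures local ridge orientation |
| NLM search | full image | — | spectrogram images here are ≤ ~33×24; quadratic cost is affordable and matches the "whole image" averaging idea |
| NLM `a` | 1 | pixels | Gaussian patch weighting SD |
| NLM `h` | 0.6·σ̂ per image | intensity | σ̂ = median(|∇F|)/0.6745 is a robust per-mode noise scale; tying `h` to it makes filtering scale-free across modes whose amplitudes differ by orders of magnitude |

All are overridable through `stft_config()`, `bemd_config()`,
`nlm_config()` and `denoise_config()`, and every CLI output records the
resolved configuration in a JSON sidecar.

# Numerical choices

- **Exact inversion.** `stft_config()` rejects window/hop pairs whose
  sliding sum of squared windows is not bounded away from zero, at
  construction time. The signal is zero-padded by one window length at
  the front (and as needed at the tail) so every sample enjoys full
  overlap; inversion is weighted overlap-add normalised by the summed
  squared window, making `istft(stft(x))` exact to machine precision.
- **Envelope surfaces.** Scattered-data "cubic spline" surface fitting is
  ill-defined; we use thin-plate-spline interpolation (the smooth
  bivariate analogue of the natural cubic spline), with the extrema set
  mirror-reflected across each image border before fitting to constrain
  the surface beyond the extrema hull. With fewer than 16 support points,
  or when the spline system is singular, the fit falls back to a
  least-squares plane (exact for planar data), and to a constant when
  even a plane is under-determined.
- **Sifting stop criterion.** The normalised-change sum divides by
  $h_{p-1}^2$; grid cells with $|h_{p-1}| < 10^{-12}$ are excluded, since
  the ratio is undefined there. The envelope mean is recomputed from the
  current iterate at every sift (standard practice); completeness of the
  decomposition is then exact by construction, and decomposing $-M$
  yields exactly the negated modes of $M$.
- **Recombination.** Summation is the default: together with exact
  inversion it makes the pipeline the identity when the NLM stage is
  disabled, a property the test suite asserts. A `mean` mode (dividing by
  the number of components, i.e. a literal "superimpose and average"
  reading) is provided for comparison; it scales the output down by
  $1/(N+1)$ and is not recommended.
- **Magnitude vs. complex filtering.** The default filters the magnitude
  image and reuses the original phase — the magnitude is the energy
  density whose self-similarity NLM exploits. A `real_imag` mode filters
  the real and imaginary planes independently instead.
- **Residue filtering.** The residue is NLM-filtered like the modes (it
  is just the coarsest component); with NLM disabled both conventions
  coincide.
- **CCA regularisation.** Both covariance blocks receive a ridge of
  10⁻⁸ × mean diagonal before the Cholesky-whitened SVD. The reported
  leading correlation is the empirical Pearson correlation of the two
  computed variates, so a set correlated with itself reports exactly 1
  regardless of the ridge; the ordered singular values are also returned.
- **FastICA.** Symmetric fixed-point iteration with the log-cosh
  contrast, eigendecomposition whitening, seeded random orthonormal
  initialisation, and a hard error (not a silent result) on
  rank-deficient input or — by default — on non-convergence. The EEMD-ICA
  denoiser relaxes the latter: the mode matrix of a single trial is not a
  set of independent sources, so a few near-Gaussian directions routinely
  keep the symmetric iteration rotating below a strict tolerance; there
  the final iterate is accepted (`on_nonconvergence = "warn"`), since
  component selection only needs the converged directions.
- **Wavelet baseline.** Daubechies-4, periodised transform on a
  power-of-two zero-padding, universal threshold
  $\sqrt{2\ln N}\,\hat\sigma$ with $\hat\sigma$ from the finest detail
  coefficients, soft thresholding of all detail levels. This is the
  standard wavelet-shrinkage stand-in for MATLAB's default
  `ddencmp`/`wdencmp` pipeline, which is not otherwise specified.

# The synthetic study

`simulate_erp()` generates the study data: 56 one-second single-channel
trials at 250 Hz (defaults). Each trial is a sum of Gaussian-windowed
components — an N1-like negativity (5 µV, peak 150 ms, SD 30 ms) and a
P300-like positivity (10 µV, peak 350 ms, SD 60 ms) — with per-trial
latency jitter (SD 20 ms) and amplitude jitter (CV 0.2), plus structured
noise: pink $1/f$ background, a 10 Hz alpha sinusoid with random phase,
and band-passed 30–120 Hz "EMG" white noise, mixed at equal relative
amplitude and rescaled per trial so that the realised SNR
$10\log_{10}(\|\mathrm{clean}\|^2/\|\mathrm{noise}\|^2)$ equals the
target (−5 dB) exactly. Everything is determined by one integer seed, and
the generator restores the caller's RNG state.

What this emulates: stimulus-locked components buried in spectrally
realistic noise, trial-to-trial variability, and an across-trial average
that is a meaningfully better reference than any single trial. What it
does **not** emulate: eye-blink and movement artifacts, non-stationary
alpha bursts, electrode drift, or volume-conduction structure across
channels. Benchmarks passing on this generator therefore demonstrate the
machinery works as specified under controlled conditions, not that the
method dominates on arbitrary clinical recordings.

# Evaluation protocol

`benchmark()` reproduces the correlation-to-reference protocol: the
reference is the across-trial mean, each method denoises each trial, and
per-trial Pearson correlations with the reference are aggregated.
Two caveats are deliberately preserved and documented:

- With `reference_policy = "all"` the trial under test contributes 1/56
  of its own reference (the published protocol); `"loo"` provides the
  unbiased leave-one-out alternative.
- EEMD-ICA selects the independent component most correlated with the
  reference — the evaluation target leaks into that method by design.
  It is implemented as described and flagged here.

Pairwise significance uses a two-sided paired t-test on Fisher
z-transformed correlations (a Wilcoxon signed-rank option is available);
the transform normalises the bounded correlation scale. Which test
produced the published significance marks is unstated, so neither is
claimed to match it.

# Problem sizes in the test suite

The suite exercises the full study at its natural size where the result
depends on it — five generator seeds × 56 trials for the
method-comparison property, all 56 trials of seed 1 for the
high-frequency-suppression property — and desk-scale instances elsewhere
(32×32 matrices for decomposition completeness, 16×16 images for the
non-local-means oracle equivalence, 250-sample signals for transform
round trips). The nested-loop NLM oracle in the test helpers is a literal
transcription of the weighting formulas, written independently of the
vectorised implementation it checks.

# Known limitations

- BEMD envelope fitting is O(n³) in the number of extrema; very large
  spectrogram images would need a faster scattered-data interpolant.
- EEMD at 100 ensemble members dominates baseline runtime (~2 s per
  trial); reduce `n_ensembles` for exploratory work.
- No EDF reader: recordings enter via the CSV contract
  (`load_csv()`/`save_csv()`); convert EDF externally.
- The denoiser assumes the informative band lies below the EMG band; for
  paradigms with high-frequency signals of interest (e.g. gamma
  responses) the defaults are inappropriate.
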