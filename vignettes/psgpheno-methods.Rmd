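---
title: "Methods: spectral, sleep, and poly-spike phenotyping of mouse polysomnography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral, sleep, and poly-spike phenotyping of mouse polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`psgpheno` quantifies three electrographic phenotypes of Angelman-syndrome
mouse models from chronic EEG/EMG recordings — a low/high-frequency shift
of EEG power, reduced light-phase REM sleep, and poly-spike episodes — and
relates them to a molecular covariate (UBE3A protein level). Because raw
recordings from such studies are rarely shared, the package pairs every
analysis stage with a synthetic polysomnography generator carrying full
ground truth, so each stage is validated by parameter recovery rather than
by eye.

# Spectral pipeline

The processing order is fixed and mirrors standard practice: artifact
exclusion first, then mean detrend, then the mains notch, then Welch
estimation on clean segments only.

**Artifact exclusion.** Published analyses typically identify artifacts
visually; an automated stand-in is used here and documented as such: a 1 s
window is flagged when any EEG channel's peak |robust z| (median/MAD over
the whole recording, per channel) exceeds `z_thresh` (default 8), and a
flag on any channel excludes the window on all channels. Parameters are
recorded in the mask for provenance. The robust scale makes the rule
invariant to amplifier gain.

**Notch filter.** An eighth-order Butterworth band-stop at 60 ± 2 Hz,
applied forward–backward (zero phase; the magnitude response is squared).
`signal` exposes no second-order-section filtering, so the design is done
in zero-pole-gain form inside the package — analog low-pass prototype,
low-pass→band-stop transform, bilinear transform, conjugate pairing into
biquads — and applied per biquad with odd-reflection padding of one second
(narrow stop bands ring for hundreds of milliseconds; short padding leaves
visible edge transients). The design was verified to reproduce the
reference band-stop magnitude response to ~1e-11, and tests assert ≥ 40 dB
attenuation at 60 Hz, < 1 % passband change at 10 Hz, zero lag, and
linearity. Stability is checked explicitly: every biquad must have poles
strictly inside the unit circle.

**Welch PSD.** 2 s periodic Hann windows, 50 % overlap, density scaling
(units²/Hz), one-sided. The frequency spacing is exactly `1/window_s`
(0.5 Hz by default). Segments are formed only inside maximal artifact-free
runs and never straddle masked samples; excluded data shrink the segment
count rather than being zero-filled, which would bias the density
downward.

**Notch-band interpolation.** PSD values on grid points in [58, 62] Hz are
replaced by a straight line fitted to the 10 grid points immediately below
58 and the 10 immediately above 62 Hz. Two readings of "a line through the
flanking points" are defensible; the default fits one least-squares line
over all 20 flanking values, and `method = "flank_means"` instead joins
the two flank mean points. Both reproduce a linear background exactly; no
claim is made about which variant any particular study used. Negative
line values are clamped to zero since a density cannot be negative.

**Band powers and the ratio.** Absolute band power is the trapezoidal area
under the PSD between band edges, which must lie on the 0.5 Hz grid. The
seven bands (δ 1–4, θ 4–8, α 8–13, β1 13–18, β2 18–25, γ1 25–50, γ2
50–100 Hz) tile 1–100 Hz with shared edges, so their powers sum *exactly*
to the 1–100 Hz total — conservation is an identity of the quadrature, not
an approximation. Relative power divides by that total. The biomarker
(α + β1 + β2)/γ2 cancels any positive scalar on the PSD, which is the
precise sense in which it is independent of absolute versus relative
normalization; the test suite asserts equality to machine precision.
Zero-power inputs (zero total, zero γ2) raise errors rather than returning
NaN tables.

**Analysis schedule.** Spectral and poly-spike statistics are computed
from six fixed one-hour windows on the second calendar day of the
recording (starting 00:00, 04:00, 08:00, 12:00, 16:00, 20:00), resolved
against the EDF start clock; a recording that does not cover all six
windows fails with the first missing window named. Partial first days are
acceptable.

# Poly-spike detection

A poly-spike episode is a cluster of three or more sharp transients on any
EEG channel. Detection operationalizes what is usually a visual call:
local extrema above `z_thresh = 6` robust z-units with half-amplitude
width in 20–70 ms; events within 30 ms merge, keeping the larger. Spikes
pooled across channels chain by single linkage with gaps ≤ 200 ms; chains
of ≥ 3 become episodes. All parameters are exposed.

One subtlety: epileptiform transients and movement artifacts overlap in
*amplitude*, so the artifact-exclusion threshold on the spike path defaults
to 20 z — well above the spike regime — and smooth high-amplitude bursts
are rejected by the width bounds instead. (An earlier amplitude-only
threshold of 12 z silently swallowed genuine spikes and was diagnosed by
injection recovery — exactly the failure mode the ground-truth sidecars
exist to catch.) Episode counts are invariant to channel order and global
amplitude scaling.

Absolute agreement with any specific study's visually scored counts cannot
be established without their raw data; the package claims
injection-recovery performance on synthetic data only (≥ 90 % sensitivity,
≤ 10 % spurious episodes at the generator's default spike amplitude of
10 z).

# Sleep staging stand-in

CNN-based scorers are deliberately not re-implemented. The stand-in keeps
the part that matters for downstream statistics — hidden-Markov-style
limits on state dynamics — and replaces the feature extractor with
something transparent: per 4 s epoch, log EMG RMS, log θ/δ and log δ
(EEG features averaged over channels; whether real scorers pool or select
channels per epoch is generally unstated, and averaging is the simplest
defensible choice). A 3-component diagonal Gaussian model supplies
emission likelihoods, decoded by a most-probable-path pass whose
transition matrix sets WAKE→REM to zero (REM is entered only through
NREM).

Two training routes exist. `fit_sleep_model()` learns the Gaussians and
transition matrix from labelled epochs; the resulting model is absolute
and can label recordings dominated by one state (an all-wake recording is
scored ≥ 95 % WAKE). The unsupervised route fits the mixture by EM
(k-means initialization) and maps components to states by physiology —
highest EMG tone is WAKE, then higher θ/δ is REM; it assumes all three
states are present and is weaker on short excerpts, where cluster
estimates are noisy. Budget and agreement computations take any
hypnogram, including externally scored CSVs.

Agreement metrics are literal one-vs-rest confusion ratios; zero
denominators yield `NA` plus a reason, never a silent 0. Epochs labelled
ARTIFACT by either scorer are excluded. Budgets resolve light/dark from
clock time (lights on 06:00 for 14 h by default; the cycle length is a
study constant, the phase is configurable because publications typically
state only the former).

# Association fits

Phenotypes are normalized by the mean of the WT-control group, making the
reference mean 1 by construction; normalization is idempotent and
scale-invariant. Linear fits are OLS with the conventional two-sided
t-test on the slope (cross-checked against a permutation null in the test
suite). The exponential decay Y = a·e^(−kX) + b is fitted by
Levenberg–Marquardt with k ≥ 0, initialized at b₀ = min(y),
a₀ = max(y) − b₀, k₀ from log-linearizing y − b₀, plus five jittered
restarts whose seed is an order-invariant digest of y, so fits do not
depend on row order. When the decay term improves nothing over the best
constant fit (k ≈ 0, a ≈ 0, or constant y), the (a, b) split is flagged
non-identifiable. Both per-mouse and per-timepoint-mean aggregations are
possible inputs; the analysis drivers fit per-mouse points, the simplest
mode consistent with one covariate row per animal. No multiple-testing
correction is applied across phenotypes; outputs say so.

# Synthetic data: what it emulates and what it does not

The generator reproduces the *statistical structure* the analysis assumes:

- **States.** A semi-Markov chain over WAKE/NREM/REM with gamma bout
  lengths (shape 2 — avoids the unrealistically short bouts an
  exponential would produce) and phase-dependent means; REM is entered
  only from NREM, with entry probability 0.40 (light) / 0.25 (dark).
  Defaults give roughly 50/40/10 % wake/NREM/REM in the light phase, in
  the range reported for laboratory mice.
- **Spectra.** Per-state shapes on a 1/(0.5 + f)^χ background (χ = 1.8):
  a δ bump in NREM, a 6.5 Hz θ peak in REM, a flatter wake spectrum. Each
  state run is white noise shaped in the frequency domain to the target
  spectrum, which controls the spectrum exactly while keeping realistic
  phase structure. EMG is white noise with RMS ordered WAKE > NREM > REM.
- **Genotype gradient.** With protein level p, EEG power in 8–25 Hz is
  multiplied by 1 + 0.4·(1 − p), power in 50–100 Hz by 1 − 0.3·(1 − p),
  and light-phase REM entry by 1 − 0.35·(1 − p). Published work does not
  report these effect sizes in generative units; the defaults were chosen
  once for comfortable recovery at n = 8 per group and are flagged as
  arbitrary. The antisense-transcript companion is generated by inverting
  protein = 0.9·e^(−2.2·ATS) + 0.08 (plus 8 % lognormal measurement
  noise), so the decay fit has a recoverable target.
- **Nuisance structure.** 60 Hz mains, 0.5–2 s movement bursts on single
  channels, and Poisson poly-spike episodes (≥ 3 Gaussian transients,
  FWHM 28–61 ms, gaps 80–150 ms, amplitude 10 z on the frontal channel).

It does **not** emulate biophysically realistic cortical dynamics,
state-transition microstructure (e.g., brief arousals), non-stationary
spectra within a state, electrode drift, or anesthesia/drug effects.
Passing tests therefore demonstrate that the *pipeline* recovers known
structure faithfully — not that any particular biological effect size is
correct, and real recordings will stage less cleanly than the generator's
well-separated states (staging accuracy near 100 % here is a property of
the synthetic separability, not a claim about field performance).

# Problem sizes

Defaults reproduce acquisition-scale conditions (5000 Hz, 48 h, three EEG
channels, 14/10 light cycle). The test and acceptance analyses run the
same code at desk scale, chosen once: spectral checks at 250–1000 Hz on
30–60 s signals; injection recovery on twenty 1 h recordings at 500 Hz;
staging on 2 h recordings at 250 Hz (features need ≤ 30 Hz content);
cohort phenotyping on 16 animals with 0.5 h of analyzed signal each —
chosen toward the 6 h/animal schedule of full studies so the smaller
high-gamma effect is adequately powered — plus full 24 h hypnograms for
sleep budgets; EDF round-trips on 10 s files.

# Known limitations

- EDF support is plain EDF with equal per-channel rates; EDF+ annotations
  are out of scope (events travel in sidecar CSVs).
- The artifact rule is amplitude-based; slow drifts or spectrally unusual
  artifacts below threshold pass through.
- The unsupervised staging route requires all three states to be present
  and misassigns clusters on recordings dominated by one state; use a
  trained model there.
- Poly-spike detection thresholds are rig-independent (robust z) but were
  validated only against the generator's stereotyped spike shape.
- Group-comparison omnibus tests (ANOVA, Kruskal–Wallis) are delegated to
  stock R routines in the analysis drivers and are not part of the
  package surface.
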