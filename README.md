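# psgpheno

EEG/EMG phenotyping of chronic mouse polysomnography recordings, built for
studies of Angelman-syndrome mouse models where the electrographic
phenotype — a shift of EEG power from high to low frequencies, reduced
light-phase REM sleep, and epileptiform poly-spikes — is read out against a
molecular covariate (UBE3A protein level, modulated by antisense
oligonucleotides targeting the *Ube3a-ATS* transcript).

The package implements the full analysis chain as reusable, tested
functions, plus a synthetic polysomnography generator that emulates the
statistical structure such studies assume, so every stage can be validated
against ground truth.

## What it computes

**Spectral phenotype.** Per EEG channel: artifact exclusion (robust-z
amplitude rule, window-wise, pooled across channels), mean detrend,
zero-phase eighth-order Butterworth band-stop at 60 ± 2 Hz, Welch PSD with
2 s Hann windows and 50 % overlap (0.5 Hz resolution) over artifact-free
segments, linear interpolation across 58–62 Hz, and integration into seven
bands: δ 1–4, θ 4–8, α 8–13, β1 13–18, β2 18–25, γ1 25–50, γ2 50–100 Hz.
Relative power is band power over total 1–100 Hz power. The headline
biomarker is the low/high-frequency power ratio

    (α + β1 + β2) / γ2  =  P(8–25 Hz) / P(50–100 Hz),

which is invariant to any positive rescaling of the PSD and therefore
identical whether computed from absolute or relative power.

**Poly-spikes.** Sharp transients (robust-z threshold, half-amplitude width
20–70 ms) pooled across EEG channels and clustered with ≤ 200 ms gaps; a
cluster of three or more spikes is an episode. Episode frequency is
reported over the six second-day analysis hours (12 AM, 4 AM, 8 AM, 12 PM,
4 PM, 8 PM, one hour each) or any window set.

**Sleep architecture.** 4 s epochs are staged WAKE/NREM/REM by a
transparent stand-in for CNN scorers: per-epoch features (log EMG RMS,
log θ/δ, log δ) under a 3-component Gaussian model, decoded with a most
probable path that forbids WAKE→REM. Budgets are split by the 14/10 h
light/dark cycle; scorer agreement uses one-vs-rest precision, recall, F1
and accuracy. Externally scored hypnogram CSVs drop in unchanged.

**Association.** Phenotypes normalized to the WT-control group mean are
regressed on protein level (OLS with a two-sided slope-zero test); protein
vs antisense-transcript level is fitted with a one-phase exponential decay
Y = a·e^(−kX) + b (Levenberg–Marquardt, k ≥ 0, multi-start).

**Synthetic data.** `sim_config()` + `simulate_recording()` /
`simulate_cohort()` generate EDF recordings with semi-Markov sleep states,
state-dependent 1/f^χ spectra, EMG tone ordered WAKE > NREM > REM, 60 Hz
mains, movement artifacts, Poisson poly-spike episodes, and a genotype
gradient: low protein raises 8–25 Hz power, lowers 50–100 Hz power, and
shrinks light-phase REM occupancy.

## Worked example

```r
library(psgpheno)
for (p in c(1, 0.1)) {
  cfg <- sim_config(sampling_rate = 500, duration_h = 0.5,
                    protein_level = p, seed = if (p == 1) 1 else 2)
  sim <- simulate_recording(cfg)
  fc  <- spectral_phenotype(sim$recording, hours = "all",
                            notch = FALSE)[["EEG FC-L"]]
  cat(sprintf("protein_level %.1f: ratio %.2f, relative high-gamma %.3f\n",
              p, fc$ratio,
              fc$bands$relative_power[fc$bands$name == "high_gamma"]))
}
#> protein_level 1.0: ratio 3.69, relative high-gamma 0.035
#> protein_level 0.1: ratio 6.47, relative high-gamma 0.031
```

The mutant-like animal (10 % of WT protein) shows the expected phenotype:
the low/high power ratio nearly doubles while relative high-gamma power
falls.

## Analysis workflow

The numbered drivers under `analysis/` run the full study on a simulated
cohort (4 groups × 4 animals graded by protein level) and write their
tables under `results/`:

1. `01_simulate_cohort.R` — EDFs + ground-truth sidecars + manifest
2. `02_spectral_phenotype.R` — band powers and power ratio per animal
3. `03_sleep_architecture.R` — light/dark budgets and scorer agreement
4. `04_polyspikes.R` — episode rates and injection recovery
5. `05_association.R` — decay and regression fits against protein level

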