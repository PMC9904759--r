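#!/usr/bin/env Rscript
# Simulate the study cohort: four treatment groups graded by UBE3A protein
# level (WT + control ASO; mutant + control, high-efficacy, or low-efficacy
# ASO), n = 4 per group. Full-length EDFs are bulky, so each animal gets a
# 30 min recording at 500 Hz for the spectral stages; 24 h hypnograms for
# the sleep stage are simulated separately in 03. EDFs and sidecars land in
# scratch/ (bulky, regenerable); the manifest is copied to results/.

library(psgpheno)

out_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)
unlink(out_dir, recursive = TRUE)

cfg <- sim_config(sampling_rate = 500, duration_h = 0.5,
                  spike_rate = 6, line_noise_amp = 20, artifact_rate = 2,
                  seed = 20240101)
groups <- data.frame(
  genotype      = c("WT", "mut", "mut", "mut"),
  treatment     = c("control", "control", "aso_high", "aso_low"),
  n             = 4,
  protein_level = c(1.0, 0.1, 0.7, 0.4)
)

manifest <- simulate_cohort(groups, cfg, out_dir)
file.copy(file.path(out_dir, "manifest.csv"), "results/manifest.csv",
          overwrite = TRUE)

cat(sprintf("simulated %d animals into %s\n", nrow(manifest), out_dir))
print(aggregate(protein_level ~ genotype + treatment, manifest, mean))
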