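#!/usr/bin/env Rscript
# Association stage: (i) one-phase exponential decay of protein level
# against antisense-transcript level across mutant animals, and (ii) linear
# regressions of WT-normalized phenotypes (band relative powers, power
# ratio, light-phase REM time) on protein level, with slope-zero tests.
# Writes results/association_fits.csv.

library(psgpheno)

manifest <- read.csv("results/manifest.csv")
bands <- read.csv("results/band_powers.csv")
budgets <- read.csv("results/sleep_budgets.csv")

## protein ~ ATS decay (mutant animals; WT protein comes from the intact allele)
mut <- manifest[manifest$genotype != "WT", ]
dec <- fit_exp_decay(mut$ATS_level, mut$protein_level)
cat(sprintf("protein = a*exp(-k*ATS)+b: a=%.3f k=%.3f b=%.3f R2=%.3f\n",
            dec$a, dec$k, dec$b, dec$r_squared))

## per-animal phenotype table (frontal channel)
fc <- bands[bands$channel == "EEG FC-L", ]
ph <- reshape(fc[, c("animal_id", "band", "relative")],
              idvar = "animal_id", timevar = "band", direction = "wide")
names(ph) <- sub("relative\\.", "", names(ph))
ph$ratio <- unique(fc[, c("animal_id", "ratio")])$ratio
rem <- budgets[budgets$state == "REM" & budgets$phase == "light",
               c("animal_id", "seconds")]
names(rem)[2] <- "rem_light_min"
rem$rem_light_min <- rem$rem_light_min / 60
ph <- merge(ph, rem)

tab <- phenotype_protein_table(manifest, ph)
fits <- NULL
for (col in setdiff(names(ph), "animal_id")) {
  fl <- fit_linear(tab$protein_level, tab[[col]])
  fits <- rbind(fits, data.frame(phenotype = col, slope = fl$a,
                                 intercept = fl$b, r_squared = fl$r_squared,
                                 p_slope = fl$p_slope, n = fl$n))
}
fits <- rbind(fits, data.frame(phenotype = "protein_vs_ATS_decay_k",
                               slope = -dec$k, intercept = dec$b,
                               r_squared = dec$r_squared, p_slope = NA,
                               n = nrow(mut)))
write.csv(fits, "results/association_fits.csv", row.names = FALSE)
cat("\nLinear fits of WT-normalized phenotypes vs protein level:\n")
print(fits, digits = 3)
cat("\n(no multiple-testing correction applied across phenotypes)\n")
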