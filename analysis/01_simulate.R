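#!/usr/bin/env Rscript
## Step 1 -- synthetic cohort.
##
## Generates the default synthetic case/control cohort (648 cases, 434
## controls, male-skewed case group, ages skewed over 60, race skewed toward
## White, group-conditional clinical feature means) and a bias-planted
## variant with a -0.30 label-rate gap against female participants. Writes a
## constitution summary to results/ and the full cohorts to scratch/ (they
## are regenerated deterministically from the seed, so they are not part of
## the deliverable tree).

suppressPackageStartupMessages(library(fairaudit))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- cohort_config()                       # seed 4765416
ch <- generate_cohort(cfg)
y <- cohort_label(ch)

summary_tab <- data.frame(
  characteristic = c("participants", "cases (PD)", "controls (HC)",
                     "male cases", "male controls", "White participants",
                     "mean age (cases)", "mean age (controls)"),
  value = c(nrow(ch), sum(y == 1), sum(y == 0),
            sum(ch$gender == 1 & y == 1), sum(ch$gender == 1 & y == 0),
            sum(ch$race == "White"),
            round(mean(ch$age[y == 1]), 2), round(mean(ch$age[y == 0]), 2))
)
write.csv(summary_tab, "results/01_cohort_constitution.csv", row.names = FALSE)
print(summary_tab, row.names = FALSE)

## group-conditional feature means realized by the generator
fs <- cfg$feature_specs
fs$realized_pd <- round(vapply(fs$name, function(n) mean(ch[[n]][y == 1]), 0), 3)
fs$realized_hc <- round(vapply(fs$name, function(n) mean(ch[[n]][y == 0]), 0), 3)
write.csv(fs, "results/01_feature_means.csv", row.names = FALSE)

write_cohort(ch, "scratch/cohort_default.csv", meta = list(seed = cfg$seed))

biased <- generate_cohort(cohort_config(bias_strength = -0.30))
gb <- group_vector(biased, default_sensitive_specs()$gender)
cat(sprintf("\nbias-planted cohort: label SPD (female minus male) = %.4f\n",
            spd(cohort_label(biased), gb)))
write_cohort(biased, "scratch/cohort_biased.csv",
             meta = list(seed = cfg$seed, bias_strength = -0.30))
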