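#!/usr/bin/env Rscript
# Step 1 -- build and calibrate the population of Purkinje models.
#
# Samples conductance multipliers for the 12 main ionic currents by Latin
# hypercube over 50-200% of baseline, paces every candidate to steady state
# at 1 Hz, computes the nine AP biomarkers on the last beat, and retains
# only candidates inside the experimental calibration windows with no
# repolarization abnormality in control at 1 Hz, 0.25 Hz or 3 Hz.
#
# This driver runs the reduced-scale profile (50 candidates, 100-beat
# pre-pacing, 25 calibration beats); the full-scale study profile
# (1000 candidates, 1000 beats, 150 beats) uses the same calls with larger
# numbers.  Writes results/population/.

library(purkinjetrials)

n_initial <- 50
prepace <- 100
calib_beats <- 25
seed <- 2024

model <- purkinje_model()
message("sampling ", n_initial, " candidates (seed ", seed, ") ...")
samples <- lhs_sample(sampling_config(n_initial, seed = seed))

message("pacing candidates to steady state at 1 Hz (", prepace, " beats) ...")
cand <- build_candidates(model, samples, prepace_beats = prepace)

message("calibrating against biomarker windows + multi-rate control runs ...")
pop <- calibrate(model, cand, extra_frequencies = c(0.25, 3),
                 n_beats = calib_beats)

print(pop)
print(table(pop$exclusions$reason))

write_population(pop, "results/population")
saveRDS(pop, "results/population/population.rds")  # reused by later steps
message("retained ", length(pop$members), "/", n_initial, " members (",
        round(100 * length(pop$members) / n_initial), "%); ",
        "study-scale run retained 530/1000 (53%)")
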