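#!/usr/bin/env Rscript
# Step 2 -- run the in-silico drug trials.
#
# Applies each reference compound of the bundled library to the frozen
# population via the IC50 pore-block model and paces 30 beats per
# concentration at the drug's tested rates (slow/1 Hz/3 Hz), starting from
# each member's cached control steady state.  The last beat is screened for
# EADs/DADs; biomarkers are computed only for normal beats.  Per-drug
# summaries (mean percent biomarker changes and abnormality incidence) are
# written under results/trials/.
#
# Study protocol used 150 drugged beats; 30 keeps this driver desk-scale.

library(purkinjetrials)

pop <- readRDS("results/population/population.rds")
model <- purkinje_model()
lib <- load_drug_library()
dir.create("results/trials", showWarnings = FALSE, recursive = TRUE)

summaries <- list()
for (drug in lib) {
  message("trial: ", drug$name, " (", length(drug$concentrations),
          " concentrations x ", length(drug$frequencies), " rates)")
  t0 <- Sys.time()
  res <- run_drug_trial(pop, drug, model, n_beats = 30)
  s <- summarize_trial(res)
  summaries[[drug$name]] <- s
  write.csv(res$detail,
            file.path("results/trials", paste0(drug$name, "_detail.csv")),
            row.names = FALSE)
  write.csv(s$table,
            file.path("results/trials", paste0(drug$name, "_summary.csv")),
            row.names = FALSE)
  message("  ", format(round(difftime(Sys.time(), t0, units = "secs"))),
          "; max EAD incidence at slow rate: ",
          round(max(s$table$incidence_pct[s$table$frequency < 1]), 1), "%")
}

all <- bind_summaries(summaries)
write.csv(all, "results/trials/all_summaries.csv", row.names = FALSE)
saveRDS(summaries, "results/trials/summaries.rds")
message("wrote per-drug summaries for ", length(summaries), " compounds")
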