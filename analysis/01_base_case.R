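#!/usr/bin/env Rscript
# Base-case cost-effectiveness of add-on dapagliflozin vs standard care for
# HFrEF: 180 monthly cycles, cohort of 1000 entering stable HF at age 66,
# 3% annual discounting, Taiwan cost/utility inputs (2020 US$).

suppressPackageStartupMessages(library(hfcea))
dir.create("results", showWarnings = FALSE)

config <- taiwan_base_config()
res <- run_model(config)
print(res)

cat("\nExpected HHF events per 1000 patients over 15 years:\n")
cat(sprintf("  standard care : %d\n", round(res$comparator$hhf_events_expected)))
cat(sprintf("  dapagliflozin : %d\n", round(res$intervention$hhf_events_expected)))
cat(sprintf("Cumulative mortality: %.1f%% vs %.1f%%\n",
            100 * res$intervention$cumulative_mortality,
            100 * res$comparator$cumulative_mortality))

# per-cycle traces for both arms, tidy format
for (arm in names(config$arms)) {
  P <- build_transition_matrix(config$arms[[arm]]$transitions, arm)
  tr <- run_cohort(P, sim_settings())
  utils::write.csv(as.data.frame(tr),
                   file.path("results", paste0("trace_", arm, ".csv")),
                   row.names = FALSE)
}

tab <- run_battery(list(config))
utils::write.csv(tab, "results/base_case.csv", row.names = FALSE)
cat("\nWrote results/base_case.csv and per-arm traces.\n")
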