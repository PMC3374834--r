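#!/usr/bin/env Rscript
# Step 3 — requirement cascade and reporting-efficiency tables.
#
# Computes the five deposition-requirement flags per trial, then the yearly
# deposition table, the restrained per-class table, outcome reporting,
# intervention efficiency, enrollment summaries and the activity/phase
# distributions.

library(ctrreport)

corpus <- read_tabular("results/corpus/corpus.csv")
cls <- readr::read_csv("results/corpus/sponsor_classes.csv",
                       show_col_types = FALSE)
corpus$sponsor_class <- cls$sponsor_class[match(corpus$nct_id, cls$nct_id)]

flags <- compute_flags(corpus)
message(sprintf(
  "cascade: %d trials -> %d completed by cutoff -> %d all requirements",
  nrow(corpus), sum(flags$completed_by_cutoff), sum(flags$all_requirements)))

out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

yearly <- yearly_requirement_table(corpus, flags)
write_table_outputs(yearly, file.path(out, "yearly_requirements"))
tot <- yearly[yearly$year_bucket == "total", ]
message(sprintf("overall completed-with-results: %s%%",
                tot$pct[tot$requirement == "overall"]))
message(sprintf("all-requirements pool: %d trials, %s%% with results",
                tot$total[tot$requirement == "all_requirements"],
                tot$pct[tot$requirement == "all_requirements"]))

restrained <- class_restrained_table(corpus, flags)
write_table_outputs(restrained, file.path(out, "class_restrained"))
message(paste(capture.output(print(restrained)), collapse = "\n"))

write_table_outputs(outcome_table(corpus), file.path(out, "outcome_reporting"))
write_table_outputs(intervention_table(corpus),
                    file.path(out, "intervention_efficiency"))
write_table_outputs(enrollment_table(corpus), file.path(out, "enrollment"))
write_table_outputs(yearly_activity(corpus), file.path(out, "yearly_activity"))
write_table_outputs(phase_distribution(corpus),
                    file.path(out, "phase_distribution"))
readr::write_csv(flags, "results/corpus/requirement_flags.csv")
message("wrote reporting tables under results/tables/")
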