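#!/usr/bin/env Rscript
# Step 1 — generate the working corpus.
#
# Draws a 20,000-trial synthetic registry from the calibrated default
# configuration (class mix, reporting rates, requirement marginals and
# enrollment scales mirroring the 2012 public-registry snapshot), writes it
# in tabular form plus the ground-truth labels, and exports a 500-record
# subsample as per-trial XML to exercise the parser in step 2.

library(ctrreport)

seed <- 20120101
out_dir <- "results/corpus"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- default_registry_config(20000)
write_registry_config(cfg, file.path(out_dir, "generator_config.yaml"))

gen <- generate_registry(cfg, seed = seed)
write_tabular(gen$corpus, file.path(out_dir, "corpus.csv"))
readr::write_csv(gen$truth, file.path(out_dir, "ground_truth.csv"))

xml_dir <- file.path(out_dir, "xml_sample")
unlink(xml_dir, recursive = TRUE)
write_corpus_xml(gen$corpus[seq_len(500), ], xml_dir)

message(sprintf("corpus: %d trials; %d completed; %d with results (%.2f%%)",
                nrow(gen$corpus),
                sum(gen$corpus$overall_status == "Completed"),
                sum(gen$corpus$has_results),
                100 * mean(gen$corpus$has_results)))
message(sprintf("wrote %s, ground truth, config, and a %d-record XML sample",
                file.path(out_dir, "corpus.csv"), 500))
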