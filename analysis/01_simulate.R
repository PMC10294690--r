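#!/usr/bin/env Rscript
# Step 1: build one round of synthetic material.
#
# Generates a five-note, 625-screen gold corpus (about 22% of screens
# carry one sign/symptom; some screens mention a negated concept that
# must stay unannotated; a few use a right/left columnar layout), then
# simulates three human raters and one machine-profile rater reading it.
# Each rater's annotations are written as one JSONL file, plus the gold
# standard as a sidecar, under results/simulated_annotations/.

suppressPackageStartupMessages(library(spanagree))

out_dir <- "results/simulated_annotations"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

catalog <- read_concept_catalog(default_catalog_path())
corpus <- generate_corpus(corpus_config(seed = 20260101), catalog)
print(corpus)

gold <- annotation_set("gold", corpus$gold_spans, screens = corpus$screens)
write_annotations(gold, corpus$screens, file.path(out_dir, "gold.jsonl"))

raters <- list(human_profile("A1", seed = 101),
               human_profile("A2", seed = 102),
               human_profile("A3", seed = 103),
               machine_profile("NN", seed = 104))
for (profile in raters) {
  set <- simulate_annotator(corpus, profile)
  path <- file.path(out_dir, paste0(profile$rater_id, ".jsonl"))
  write_annotations(set, corpus$screens, path)
  cat(sprintf("%s: %d spans (gold: %d) -> %s\n", profile$rater_id,
              nrow(set$spans), nrow(corpus$gold_spans), path))
}
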