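#!/usr/bin/env Rscript
# Step 2: score pairwise inter-rater agreement from the JSONL files.
#
# For every rater pair, agreement units are one item per span in the
# union of the two raters' annotations plus one agreeing item per screen
# neither annotated; concordance is the unadjusted percent agreement and
# Cohen's Kappa the chance-corrected version. Both the text-span task
# (did the raters mark the same offsets?) and the category-label task
# (did they also give the span the same label?) are scored.

suppressPackageStartupMessages(library(spanagree))

in_dir <- "results/simulated_annotations"
rater_ids <- c("A1", "A2", "A3", "NN")
stopifnot(file.exists(file.path(in_dir, paste0(rater_ids, ".jsonl"))))

scr <- read_screens(file.path(in_dir, "A1.jsonl"))
sets <- lapply(rater_ids, function(id) {
  read_annotations(file.path(in_dir, paste0(id, ".jsonl")), id)
})

results <- rbind(pairwise_agreement(sets, scr, "span"),
                 pairwise_agreement(sets, scr, "label"))
results$group <- ifelse(results$rater_a == "NN" | results$rater_b == "NN",
                        "human-machine", "human-human")
print(results, digits = 3)

dir.create("results", showWarnings = FALSE)
write.csv(results, "results/pairwise_agreement.csv", row.names = FALSE)
cat("\nwrote results/pairwise_agreement.csv\n")
cat(sprintf("span task: human-human mean kappa %.3f, human-machine %.3f\n",
            mean(results$kappa[results$task == "span" &
                                 results$group == "human-human"]),
            mean(results$kappa[results$task == "span" &
                                 results$group == "human-machine"])))
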