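#!/usr/bin/env Rscript
# Step 2 — five-type classification of every unit.
#
# Odor-sampling epoch rates versus the 1 s pre-ITI-end baseline, auROC +
# permutation test (p < 0.01) per cue odor, then a go/no-go preference
# test among responsive units. Writes results/classifications.csv and
# prints the type proportions and ground-truth agreement.

suppressMessages(library(gonogo))
seed <- 1L

session <- load_session("results/session")
cl <- classify_session(session, classify_config(),
                       seed = child_seed(seed, 2L))
write.csv(cl, "results/classifications.csv", row.names = FALSE,
          quote = FALSE)

summ <- classification_summary(cl)
cat(sprintf("cue-responsive: %.1f%% of %d units\n", summ$pct_responsive,
            summ$n_classified))
cat(sprintf("type proportions (I-V): %s\n",
            paste(sprintf("%.1f%%", 100 * summ$type_proportions),
                  collapse = " / ")))
resp <- cl$type_label != "V"
cat(sprintf("go / no-go preference among responsive: %.1f%% / %.1f%%\n",
            100 * sum(cl$type_label == "I") / sum(resp),
            100 * sum(cl$type_label == "II") / sum(resp)))

gt <- read.csv("results/session/ground_truth.csv",
               colClasses = c(unit_id = "character"))
cat(sprintf("ground-truth agreement: %.1f%%\n",
            100 * mean(cl$type_label == gt$type_label)))
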