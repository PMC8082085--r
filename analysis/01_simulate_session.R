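#!/usr/bin/env Rscript
# Step 1 — simulate one default-condition recording session.
#
# The generator emulates a go/no-go odor-discrimination session: 100 units
# drawn from five response archetypes (38.9/5.8/11.5/17.0/26.8%),
# log-normal baseline rates (median 0.90 Hz, IQR 0.23-3.07), sampling
# durations with medians 788/642 ms and 90% behavioral accuracy, spikes
# from inhomogeneous Poisson intensities. Writes the session (plain-text
# CSV/JSON) and its ground truth under results/session/.

suppressMessages(library(gonogo))
seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- generator_config()
gen <- generate_session(cfg, seed = seed)
write_session(gen$session, "results/session")
write_ground_truth(gen$ground_truth, "results/session")

tr <- gen$session$trials
dur <- tr$port_exit_s - tr$odor_on_s
cat("session:", gen$session$session_id, "\n")
cat(sprintf("units: %d  trials: %d  accuracy: %.1f%%\n",
            length(gen$session$units), nrow(tr),
            100 * mean(tr$outcome == "correct")))
cat(sprintf("median sampling: go %.0f ms, no-go %.0f ms\n",
            1000 * median(dur[tr$trial_type == "go"]),
            1000 * median(dur[tr$trial_type == "no-go"])))
cat(sprintf("median baseline rate: %.2f Hz\n",
            median(gen$ground_truth$baseline_hz)))
print(table(gen$ground_truth$type_label))
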