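#!/usr/bin/env Rscript
# Step 5 — population trajectory geometry.
#
# Trial-averaged, smoothed, per-unit z-scored responses for go and no-go
# conditions; joint PCA subspace; condition separation distance and
# trajectory velocity with mean + 2 SD baseline bands; per-unit weights
# (|PC1 loading|) compared across neuron types (ANOVA + Tukey).

suppressMessages(library(gonogo))

session <- load_session("results/session")
cl <- read.csv("results/classifications.csv",
               colClasses = c(unit_id = "character"))

pm <- build_population_matrix(session)
sub <- pca_subspace(pm, k = 3L)
cat(sprintf("variance explained by PC1-3: %s\n",
            paste(sprintf("%.1f%%",
                          100 * sub$explained_variance_ratio[1:3]),
                  collapse = " / ")))

traj <- data.frame(
  condition = rep(attr(pm, "conditions"), each = length(sub$bin_centers)),
  bin_center_s = rep(sub$bin_centers, 2),
  pc1 = as.numeric(sub$trajectories[1, , ]),
  pc2 = as.numeric(sub$trajectories[2, , ]),
  pc3 = as.numeric(sub$trajectories[3, , ]))
write.csv(traj, "results/trajectories.csv", row.names = FALSE,
          quote = FALSE)

dist <- trajectory_distance(pm)
vel <- trajectory_velocity(pm, condition = 1L)
geom <- rbind(
  data.frame(kind = "distance", bin_center_s = dist$bin_center,
             value = dist$value, significant = dist$significant),
  data.frame(kind = "velocity", bin_center_s = vel$bin_center,
             value = vel$value, significant = vel$significant))
write.csv(geom, "results/geometry.csv", row.names = FALSE, quote = FALSE)

first_run <- function(tr) {
  r <- rle(tr$significant)
  s <- cumsum(r$lengths) - r$lengths + 1L
  tr$bin_center[s[which(r$values & r$lengths >= 3)[1]]]
}
cat(sprintf("distance rises above baseline band at %.0f ms\n",
            1000 * first_run(dist)))
cat(sprintf("velocity peaks at %.0f ms\n",
            1000 * vel$bin_center[which.max(vel$value)]))

w <- neural_weights(sub, 1)
types <- cl$type_label[match(sub$unit_ids,
                             paste0(session$session_id, "/", cl$unit_id))]
write.csv(data.frame(unit_id = sub$unit_ids, type_label = types,
                     weight = unname(w)),
          "results/weights.csv", row.names = FALSE, quote = FALSE)
cmp <- compare_weights_by_type(w, types)
cat(sprintf("neural weights differ across types: F = %.1f, p = %.2g\n",
            cmp$f_statistic, cmp$p_value))
print(round(cmp$group_means, 3))
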