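#!/usr/bin/env Rscript
# Stage 1 - synthetic study area.
#
# Builds the ground truth for the whole analysis: a five-class land-cover
# map (urban, waterbody, cropland, other forests, target plantation tree),
# three acquisition dates of 8-band imagery with a configured red-edge
# advantage for the target tree, and 208 ground sample points at >= 20 m
# spacing split 3:1 into train/test. Everything downstream reads these
# artifacts or regenerates them from the same seed.

library(carbonscape)

seed <- 1
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- synth_truth(seed = seed)
samples <- sample_points(truth$labels,
                         c(urban = 45, waterbody = 28, cropland = 43,
                           other_forests = 53, e_ulmoides = 39),
                         min_distance = 20, seed = seed + 101)
write.csv(samples, file.path(out, "samples.csv"), row.names = FALSE)

scenes <- generate_scenes(truth)
for (d in names(scenes)) {
  write_grid(scenes[[d]], file.path(out, paste0("scene_", d)))
}
write_grid(truth$labels, file.path(out, "labels.asc"))
jsonlite::write_json(
  list(classes = truth$classes, dates = truth$dates, seed = seed,
       res_m = truth$res, dim = c(truth$nrow, truth$ncol)),
  file.path(out, "truth_meta.json"), auto_unbox = TRUE)

cat(sprintf("study area: %d x %d px at %g m, %d classes, %d dates\n",
            truth$nrow, truth$ncol, truth$res, length(truth$classes),
            length(truth$dates)))
print(table(samples$class, samples$partition))
cat("all pairwise sample distances >= 20 m:",
    min(dist(samples[, c("x", "y")])) >= 20, "\n")
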