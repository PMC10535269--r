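#!/usr/bin/env Rscript
# Stage 3 - band-combination comparison and target-species mapping.
#
# Trains one 500-tree random forest per registry model (band subsets with
# and without red-edge bands and their derived indices) on the shared
# training partition, scores them on the shared test set, and applies the
# winning model to every pixel of the selected date's scene. Accuracy is
# reported as OA, Kappa and the target class's producer/user accuracy.

library(carbonscape)

seed <- 1
out <- "results/analysis"

truth <- synth_truth(seed = seed)
samples <- read.csv(file.path(out, "samples.csv"))
samples$class <- factor(samples$class, levels = truth$classes)
best_date <- readLines(file.path(out, "best_date.txt"))
scene <- generate_scene(truth, best_date)$scene

cmp <- evaluate_combinations(scene, samples, band_combinations("models"),
                             classifier_config(seed = seed + 7))
write.csv(cmp$table, file.path(out, "model_comparison.csv"),
          row.names = FALSE)
cat("model comparison on the", best_date, "scene:\n")
print(cmp$table, digits = 4, row.names = FALSE)
cat("winner:", cmp$winner, "\n\n")

combo <- band_combinations("models")[[cmp$winner]]
map <- classify_raster(cmp$fits[[cmp$winner]], scene, combo)
write_grid(grid_raster(map$values + 0, res = map$res, xmin = map$xmin,
                       ymax = map$ymax),
           file.path(out, "class_map.asc"))
jsonlite::write_json(list(winner = cmp$winner,
                          legend = attr(map, "classes")),
                     file.path(out, "class_map_legend.json"),
                     auto_unbox = TRUE)

# full-map agreement with the generating truth
oa_px <- 100 * mean(map$values == truth$labels$values, na.rm = TRUE)
cat(sprintf("full-raster agreement with the generating truth: %.2f%%\n",
            oa_px))

# test-set confusion matrix of the winner
test <- samples$partition == "test"
ftw <- build_feature_table(scene, samples, combo)
pred <- predict(cmp$fits[[cmp$winner]], ftw$features[test, ])
cm <- confusion_matrix(as.character(samples$class[test]),
                       as.character(pred), classes = truth$classes)
write_confusion_csv(cm, file.path(out, "confusion_matrix.csv"))
s <- accuracy_summary(cm)
cat(sprintf("test-set OA %.2f%%, Kappa %.4f, target PA %.2f%%, UA %.2f%%\n",
            s$oa, s$kappa,
            s$per_class$pa[s$per_class$class == "e_ulmoides"],
            s$per_class$ua[s$per_class$class == "e_ulmoides"]))
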