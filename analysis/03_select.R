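#!/usr/bin/env Rscript
# Stage 3: random-forest descriptor selection.
#
# For each descriptor set (phenomic, classical, combined) fits a
# 100-tree accession classifier on plant-level rows with a stratified
# 70/30 split, ranks descriptors by mean minimal depth (MDM; lower =
# used earlier in the trees = more discriminating) and keeps the top 15.
# Writes MDM tables, confusion matrices and the selected descriptor
# lists under results/.

suppressPackageStartupMessages(library(phenomdiv))

seed <- 42
ds <- readRDS("results/panel/dataset.rds")
plant <- readRDS("results/phenomic_plant.rds")

res <- run_pipeline(ds, plant, config = rf_config(n_trees = 100,
                                                  train_fraction = 0.7,
                                                  top_n = 15, seed = seed))
saveRDS(res, "results/pipeline.rds")

for (ty in names(res$selection)) {
  s <- res$selection[[ty]]
  mdm <- data.frame(descriptor = names(sort(s$md$mdm)),
                    mdm = as.numeric(sort(s$md$mdm)))
  utils::write.csv(mdm, sprintf("results/mdm_%s.csv", ty), row.names = FALSE)
  utils::write.csv(as.data.frame(s$eval$oob_confusion),
                   sprintf("results/confusion_oob_%s.csv", ty))
  cat(sprintf("%s: OOB error %.3f | validation error %.3f | top 5: %s\n",
              ty, s$eval$oob_error, s$eval$valid_error,
              paste(head(s$selected, 5), collapse = ", ")))
}

gt <- ds$ground_truth
selC <- res$selection$Cla$selected
cat("Designated discriminative descriptor", gt$discriminative,
    "ranks", which(selC == gt$discriminative), "by classical MDM\n")
oc <- res$selection$Phe$eval$oob_confusion
r <- gt$redundant
cat(sprintf("Duplicate pair %s/%s mutual OOB confusion: %.2f\n",
            r[1], r[2], (oc[r[1], r[2]] + oc[r[2], r[1]]) / 2))
jsonlite::write_json(lapply(res$selection, `[[`, "selected"),
                     "results/selected_descriptors.json", pretty = TRUE)
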