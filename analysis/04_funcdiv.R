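#!/usr/bin/env Rscript
# Stage 4: functional diversity of the accessions.
#
# Treats species as functional entities and accessions (weight 1) as their
# members. For the RF-selected phenomic, classical and combined
# descriptor sets: Gower distances, a PCoA trait space (up to 4 positive
# axes), the convex hull on the first two axes (area + vertex accessions,
# the core-collection candidates), and FSpe / FOri / FIde per species.
# Writes the Table-1-shaped index table, hull summaries, coordinates and
# an ordination figure under results/.

suppressPackageStartupMessages(library(phenomdiv))

ds <- readRDS("results/panel/dataset.rds")
res <- readRDS("results/pipeline.rds")
rep <- res$report

utils::write.csv(rep$index_table, "results/fd_index_table.csv",
                 row.names = FALSE)
utils::write.csv(rep$summary, "results/hull_summary.csv", row.names = FALSE)
for (ty in names(rep$spaces)) {
  sp <- rep$spaces[[ty]]
  utils::write.csv(data.frame(accession = rownames(sp$pcoa$coords),
                              sp$pcoa$coords),
                   sprintf("results/pcoa_coords_%s.csv", ty),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sp$dist),
                   sprintf("results/gower_%s.csv", ty))
}

cat("Functional diversity indices (per descriptor type):\n")
print(rep$index_table, digits = 2)
cat("\nConvex hulls (PCo1-2):\n")
print(rep$summary, digits = 3)
for (ty in names(rep$spaces))
  cat(ty, "vertex accessions:",
      paste(rep$spaces[[ty]]$hull$vertices, collapse = ", "), "\n")

gt <- ds$ground_truth
nn <- accession_originality(rep$spaces$Com$dist)
cat("\nLowest nearest-neighbor originality (duplicate screen):\n")
print(round(sort(nn)[1:4], 4))
cat("Designated duplicates:", paste(gt$redundant, collapse = ", "), "\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dd <- do.call(rbind, lapply(names(rep$spaces), function(ty) {
    co <- rep$spaces[[ty]]$pcoa$coords
    data.frame(type = ty, accession = rownames(co),
               species = unname(gt$species_map[rownames(co)]),
               PCo1 = co[, 1], PCo2 = co[, 2])
  }))
  p <- ggplot(dd, aes(PCo1, PCo2, color = species)) +
    geom_point(size = 2) +
    facet_wrap(~type, scales = "free") +
    theme_bw() +
    labs(title = "Accession trait spaces by descriptor type")
  ggsave("results/ordination.png", p, width = 9, height = 3.2, dpi = 150)
  cat("Wrote results/ordination.png\n")
}
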