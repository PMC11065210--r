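#!/usr/bin/env Rscript
# Stage 2: extract phenomic descriptors from the rendered images.
#
# Reads every organ image back from disk, segments it (Otsu + hole fill +
# largest component), traces the outline, and runs elliptical Fourier
# analysis; one pooled morphospace per organ gives the plant-level shape
# descriptors (PC1S..., PC1L...). Seed-organ pixels are pooled per plant
# and clustered into 10 colorimetric groups (R_i/G_i/B_i/prop_i seed
# descriptors). Writes the plant-level phenomic matrix to
# results/phenomic_plant.csv.

suppressPackageStartupMessages(library(phenomdiv))

seed <- 42
ds <- readRDS("results/panel/dataset.rds")
organs <- names(ds$outlines[[1]])
suffix <- c(seed = "S", leaf = "L", pod = "P")

# trace outlines from the files rather than reusing the generator's
traced <- list()
for (acc in ds$species_map$accession) {
  sp <- ds$species_map$species[ds$species_map$accession == acc]
  traced[[acc]] <- list()
  for (org in organs) {
    files <- sort(list.files(file.path("results/panel", sp, acc, org),
                             pattern = "^plant[0-9]+\\.png$", full.names = TRUE))
    traced[[acc]][[org]] <- lapply(files, function(f)
      trace_outline(binarize(read_rgb(f))))
  }
}
ds$outlines <- traced

ph <- phenomic_from_outlines(ds, n_harmonics = 8, k_pcs = 5)
colp <- color_descriptors(ds, "seed", k = 10, from = "images",
                          level = "plant", seed = seed)
plant <- cbind_dm(ph, colp)
saveRDS(plant, "results/phenomic_plant.rds")
utils::write.csv(cbind(accession = plant$accession, species = plant$species,
                       plant$data),
                 "results/phenomic_plant.csv", row.names = FALSE)

cat("Extracted", ncol(plant$data), "phenomic descriptors (",
    ncol(ph$data), "morphospace +", ncol(colp$data), "colorimetric ) for",
    nrow(plant$data), "plants\n")
cat("Wrote results/phenomic_plant.csv\n")
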