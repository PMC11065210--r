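#!/usr/bin/env Rscript
# Stage 1: simulate the germplasm panel.
#
# Builds the default study design: 5 congeneric species with 3 accessions
# each plus one strongly displaced singleton species, 10 replicate plants
# per accession, seed + leaf organs. Two accessions of the first species
# are generated as copies of one accession (the designated duplicates) and
# the singleton species is the designated phenotypic outlier. Renders one
# organ image + mask per plant and writes the classical table and ground
# truth under results/panel/.

suppressPackageStartupMessages(library(phenomdiv))

seed <- 42
out <- "results/panel"

templates <- default_templates(5, seed = seed, organs = c("seed", "leaf"),
                               outlier = TRUE)
config <- simulation_config(templates, accessions_per_species = 3,
                            plants_per_accession = 10, image_size = 128,
                            seed = seed)
ds <- generate_dataset(config, out_dir = out)
saveRDS(ds, file.path(out, "dataset.rds"))

gt <- ds$ground_truth
n_img <- sum(vapply(ds$images, function(a) sum(lengths(a)), numeric(1)))
cat("Simulated", nrow(ds$species_map), "accessions of",
    length(unique(ds$species_map$species)), "species;",
    n_img, "organ images rendered under", out, "\n")
cat("Designated duplicates:", paste(gt$redundant, collapse = ", "),
    "| outlier:", gt$outlier,
    "| discriminative classical descriptor:", gt$discriminative, "\n")
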