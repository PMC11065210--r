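organ_suffixes <- c(seed = "S", leaf = "L", pod = "P", flower = "F")

#' Plant-level morphospace descriptors from a generated dataset
#'
#' Runs elliptical Fourier analysis on every plant outline, normalizes the
#' coefficients, builds one pooled morphospace per organ over all plants,
#' and returns the plant-level scores as a phenomic `descriptor_matrix`
#' with organ-tagged component names (PC1S, PC1L, ...).
#'
#' @param ds Dataset from [generate_dataset()].
#' @param n_harmonics Harmonics for the EFA (default 20).
#' @param k_pcs Components retained per organ (default 10).
#' @return A plant-level `descriptor_matrix` (`dtype = "phenomic"`).
#' @export
phenomic_from_outlines <- function(ds, n_harmonics = 20, k_pcs = 10) {
  organs <- names(ds$outlines[[1]])
  accs <- names(ds$outlines)
  blocks <- list(); meta <- NULL
  for (org in organs) {
    efds <- list(); rows_acc <- character(0)
    for (acc in accs) {
      for (ol in ds$outlines[[acc]][[org]]) {
        efds[[length(efds) + 1]] <- efd_normalize(efa(ol, n_harmonics))
        rows_acc <- c(rows_acc, acc)
      }
    }
    sfx <- organ_suffixes[[org]]
    ms <- morphospace(efds, k = k_pcs, organ_suffix = sfx)
    blocks[[org]] <- as.data.frame(ms$scores)
    meta <- rbind(meta, data.frame(
      name = colnames(ms$scores), dclass = "numeric", dtype = "phenomic",
      organ = org, stringsAsFactors = FALSE))
  }
  data <- do.call(cbind, unname(blocks))
  lookup <- stats::setNames(ds$species_map$species, ds$species_map$accession)
  descriptor_matrix(data, meta, accession = rows_acc,
                    species = unname(lookup[rows_acc]))
}

#' Colorimetric descriptors from a generated dataset
#'
#' Extracts k-means colorimetric groups as RGB + proportion descriptors.
#' At `level = "accession"` all of an accession's pixels are pooled (the
#' pool feeding k-means is capped at `max_pixels`); at `level = "plant"`
#' each replicate plant gets its own pixel pool, giving within-accession
#' variation for plant-level classification. With `from = "palette"`
#' pixels are drawn directly from each accession's realized palette (the
#' fast, render-free route); with `from = "images"` foreground pixels of
#' the rendered images are used.
#'
#' @param ds Dataset from [generate_dataset()].
#' @param organ Organ whose palette/images to use (suffixes the names).
#' @param k Colorimetric groups (default 10).
#' @param from `"palette"` or `"images"`.
#' @param level `"accession"` (pooled) or `"plant"`.
#' @param n_pixels Pixels per pool in palette mode.
#' @param max_pixels Pool cap in image mode (default 50000).
#' @param seed Integer seed.
#' @param n_restarts k-means++ restarts per pool (default 10).
#' @return A `descriptor_matrix` (`dtype = "phenomic"`).
#' @export
color_descriptors <- function(ds, organ = "seed", k = 10,
                              from = c("palette", "images"),
                              level = c("accession", "plant"),
                              n_pixels = 3000, max_pixels = 50000, seed = 1,
                              n_restarts = 10) {
  from <- match.arg(from)
  level <- match.arg(level)
  accs <- names(ds$palettes)
  sfx <- organ_suffixes[[organ]]
  n_plants <- ds$config$plants_per_accession

  pool_for <- function(acc, plant = NULL) {
    tag <- if (is.null(plant)) "pixels" else paste0("pixels", plant)
    if (from == "palette") {
      sample_palette_pixels(ds$palettes[[acc]], n_pixels,
                            stable_hash(seed, acc, tag))
    } else {
      ims <- ds$images[[acc]][[organ]]
      if (!is.null(plant)) ims <- ims[plant]
      pool <- do.call(rbind, lapply(ims, function(im)
        foreground_pixels(im$image, im$mask)))
      if (nrow(pool) > max_pixels) {
        set.seed(stable_hash(seed, acc, tag, "sub"))
        pool[sample.int(nrow(pool), max_pixels), , drop = FALSE]
      } else pool
    }
  }
  units <- if (level == "accession") {
    lapply(accs, function(a) list(acc = a, plant = NULL))
  } else {
    unlist(lapply(accs, function(a) lapply(seq_len(n_plants), function(i)
      list(acc = a, plant = i))), recursive = FALSE)
  }
  rows <- lapply(units, function(u) {
    px <- pool_for(u$acc, u$plant)
    cl <- kmeans_colors(px, k = k, n_restarts = n_restarts,
                        seed = stable_hash(seed, u$acc, "kmeans",
                                           if (is.null(u$plant)) 0 else u$plant))
    cluster_descriptors(cl, sfx)
  })
  data <- as.data.frame(do.call(rbind, rows))
  meta <- data.frame(name = names(data), dclass = "numeric",
                     dtype = "phenomic", organ = organ,
                     stringsAsFactors = FALSE)
  racc <- vapply(units, `[[`, "", "acc")
  lookup <- stats::setNames(ds$species_map$species, ds$species_map$accession)
  descriptor_matrix(data, meta, accession = racc,
                    species = unname(lookup[racc]))
}

#' Classical descriptor matrix of a generated dataset
#'
#' @param ds Dataset from [generate_dataset()].
#' @param level `"accession"` (plant means/modes, the classical table) or
#'   `"plant"` (raw per-plant measurements, for classification).
#' @return A `descriptor_matrix` (`dtype = "classical"`).
#' @export
classical_matrix <- function(ds, level = c("accession", "plant")) {
  level <- match.arg(level)
  tab <- if (level == "accession") ds$classical else ds$classical_plant
  cols <- setdiff(names(tab), c("accession", "species", "plant"))
  descriptor_matrix(tab[, cols, drop = FALSE],
                    ds$classical_meta[match(cols, ds$classical_meta$name), ],
                    accession = tab$accession,
                    species = tab$species,
                    levels = ds$classical_levels)
}

# broadcast an accession-level matrix to the rows of a plant-level one
broadcast_to_rows <- function(dm_acc, accession) {
  i <- match(accession, dm_acc$accession)
  if (anyNA(i)) stop("accession(s) missing from accession-level matrix")
  dm_acc$data <- dm_acc$data[i, , drop = FALSE]
  rownames(dm_acc$data) <- NULL
  dm_acc$accession <- dm_acc$accession[i]
  dm_acc$species <- dm_acc$species[i]
  dm_acc
}

#' Column-bind two descriptor matrices on identical rows
#'
#' @param a,b `descriptor_matrix` objects with the same row accessions in
#'   the same order.
#' @return A `descriptor_matrix`.
#' @export
cbind_dm <- function(a, b) {
  stopifnot(identical(a$accession, b$accession))
  descriptor_matrix(cbind(a$data, b$data), rbind(a$meta, b$meta),
                    accession = a$accession, species = a$species,
                    levels = c(a$levels, b$levels))
}

#' Run descriptor selection and functional diversity end to end
#'
#' For each descriptor set (phenomic, classical, combined): fit the
#' random-forest accession classifier on plant-level rows (the
#' accession-level classical table is broadcast to plants), rank
#' descriptors by mean minimal depth, select the top `top_n`, build the
#' accession-level selected matrix, and feed all three into
#' [fd_report()].
#'
#' Accession-level phenomic values default to the within-accession mean of
#' the plant-level descriptors; columns of `phenomic_acc` (e.g. pooled-
#' pixel colorimetric groups from [color_descriptors()]) replace or extend
#' those means for the functional-diversity matrices.
#'
#' @param ds Dataset from [generate_dataset()].
#' @param phenomic_plant Plant-level phenomic `descriptor_matrix`
#'   (e.g. [phenomic_from_outlines()], optionally [cbind_dm()]-ed with
#'   plant-level [color_descriptors()]).
#' @param phenomic_acc Optional accession-level phenomic
#'   `descriptor_matrix` overriding the aggregated plant means.
#' @param config An `rf_config`.
#' @param n_axes PCoA axis cap for the functional spaces.
#' @return List: `selection` (per type: `fit`, `md`, `eval`, `selected`),
#'   `report` (an `fd_report`), `matrices` (selected accession-level
#'   matrices per type).
#' @export
run_pipeline <- function(ds, phenomic_plant, phenomic_acc = NULL,
                         config = rf_config(), n_axes = 4) {
  cla_acc <- classical_matrix(ds)
  ph_acc <- aggregate_to_accession(phenomic_plant)
  if (!is.null(phenomic_acc)) {
    i <- match(ph_acc$accession, phenomic_acc$accession)
    if (anyNA(i)) stop("phenomic_acc must cover every accession")
    repl <- intersect(ph_acc$meta$name, phenomic_acc$meta$name)
    ph_acc$data[, repl] <- phenomic_acc$data[i, repl]
    extra <- setdiff(phenomic_acc$meta$name, repl)
    if (length(extra)) {
      ph_acc <- descriptor_matrix(
        cbind(ph_acc$data, phenomic_acc$data[i, extra, drop = FALSE]),
        rbind(ph_acc$meta,
              phenomic_acc$meta[match(extra, phenomic_acc$meta$name), ]),
        accession = ph_acc$accession, species = ph_acc$species,
        levels = ph_acc$levels)
    }
  }
  cla_plant <- if (!is.null(ds$classical_plant)) {
    cp <- classical_matrix(ds, level = "plant")
    stopifnot(identical(cp$accession, phenomic_plant$accession))
    cp
  } else broadcast_to_rows(cla_acc, phenomic_plant$accession)
  ph_plant <- phenomic_plant

  plant_sets <- list(
    Phe = ph_plant,
    Cla = cla_plant,
    Com = assemble_descriptors(ph_plant, cla_plant, ds$species_map,
                               mode = "combined"))
  acc_sets <- list(Phe = ph_acc, Cla = cla_acc,
                   Com = assemble_descriptors(ph_acc, cla_acc, ds$species_map,
                                              mode = "combined"))

  selection <- list(); selected_mats <- list()
  for (ty in names(plant_sets)) {
    enc <- encode_for_rf(plant_sets[[ty]])
    fit <- fit_forest(enc$x, enc$accession, config)
    md <- minimal_depth(fit, enc$parent)
    ev <- evaluate_forest(fit, enc$x)
    sel <- select_top(md, config$top_n)
    selection[[ty]] <- list(fit = fit, md = md, eval = ev, selected = sel)
    am <- acc_sets[[ty]]
    keep <- am$meta$name %in% sel
    selected_mats[[ty]] <- descriptor_matrix(
      am$data[, am$meta$name[keep], drop = FALSE],
      am$meta[keep, , drop = FALSE],
      accession = am$accession, species = am$species, levels = am$levels)
  }
  fe_map <- stats::setNames(ds$species_map$species, ds$species_map$accession)
  report <- fd_report(selected_mats, fe_map, n_axes = n_axes)
  list(selection = selection, report = report, matrices = selected_mats)
}
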