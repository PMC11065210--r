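#' Species template for the synthetic accession generator
#'
#' A template fixes, for one species: per-organ mean elliptical-Fourier
#' coefficients (the species' prototypical organ shapes), coefficient-space
#' noise magnitudes at the accession and plant level, an RGB Gaussian-mixture
#' color palette, and the distribution of each classical trait. Everything
#' downstream (images, classical table) is drawn from these, so the
#' ground-truth structure of the simulated germplasm panel is known by
#' construction.
#'
#' @param species_id Species label.
#' @param organs Named list; each element has `an`, `bn`, `cn`, `dn` mean
#'   coefficient vectors of equal length (the organ's mean shape).
#' @param shape_sd_accession,shape_sd_plant Nonnegative coefficient-space
#'   noise sds at accession / plant level.
#' @param palette List with `means` (`m x 3` RGB in \[0,1\]), `sds` (length
#'   m), `weights` (length m, sums to 1).
#' @param classical Named list of trait specs: numeric traits
#'   `list(class = "numeric", mean, sd)`; nominal/ordinal traits
#'   `list(class, levels, probs)` with probs summing to 1.
#' @return A `species_template` object.
#' @export
species_template <- function(species_id, organs, shape_sd_accession,
                             shape_sd_plant, palette, classical) {
  stopifnot(shape_sd_accession >= 0, shape_sd_plant >= 0,
            is.list(organs), length(organs) >= 1)
  for (o in organs)
    stopifnot(length(unique(lengths(o[c("an", "bn", "cn", "dn")]))) == 1)
  stopifnot(abs(sum(palette$weights) - 1) < 1e-9, all(palette$sds >= 0),
            nrow(palette$means) == length(palette$weights))
  for (tr in classical) {
    if (tr$class == "numeric") stopifnot(tr$sd >= 0)
    else stopifnot(tr$class %in% c("nominal", "ordinal"),
                   abs(sum(tr$probs) - 1) < 1e-9,
                   length(tr$probs) == length(tr$levels))
  }
  structure(list(species_id = species_id, organs = organs,
                 shape_sd_accession = shape_sd_accession,
                 shape_sd_plant = shape_sd_plant,
                 palette = palette, classical = classical),
            class = "species_template")
}

#' Default species templates for a simulated germplasm panel
#'
#' Builds `n_species` templates sharing a trait list but separated in shape,
#' color and classical-trait space, mirroring a panel of congeneric species
#' held in a genebank. Numeric classical traits place adjacent species means
#' 3 within-species standard deviations apart; the designated discriminative
#' trait (`days_to_flowering`) uses 6 sds. Optionally appends one strongly
#' displaced singleton "outlier" species used for specialization-recovery
#' checks.
#'
#' @param n_species Number of regular species (default 5).
#' @param seed Integer seed for the species-level draws.
#' @param organs Organ names; each gets its own base shape (supported:
#'   `"seed"`, `"leaf"`, `"pod"`).
#' @param outlier Add the displaced outlier species (default TRUE).
#' @return List of `species_template`s, the outlier (if any) last and named
#'   `"SP_OUT"`.
#' @export
default_templates <- function(n_species = 5, seed = 1,
                              organs = c("seed", "leaf"), outlier = TRUE) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  base_shapes <- list(
    seed = list(an = c(1, rep(0, 7)), bn = rep(0, 8),
                cn = rep(0, 8), dn = c(0.65, rep(0, 7))),
    leaf = list(an = c(1, rep(0, 7)), bn = rep(0, 8),
                cn = rep(0, 8), dn = c(0.45, 0.08, rep(0, 6))),
    pod  = list(an = c(1, rep(0, 7)), bn = rep(0, 8),
                cn = rep(0, 8), dn = c(0.25, 0, 0.05, rep(0, 5)))
  )
  # regular species palettes occupy a moderate shell of the RGB cube
  # (tan/brown/red/green/cream/violet seed coats); the outlier species gets
  # a saturated corner hue far from all of them
  anchors <- matrix(c(0.75, 0.55, 0.30,   # tan
                      0.45, 0.25, 0.15,   # brown
                      0.70, 0.15, 0.15,   # red
                      0.25, 0.45, 0.20,   # green
                      0.90, 0.85, 0.70,   # cream
                      0.30, 0.20, 0.45),  # violet
                    ncol = 3, byrow = TRUE)
  anchors <- 0.2 + 0.6 * anchors
  habit_levels <- c("climbing", "determinate", "indeterminate")
  color_levels <- c("black", "brown", "cream", "red", "white")
  bright_levels <- c("low", "mid", "high")
  rhs_levels <- sprintf("RHS%02d", 1:20)

  # numeric classical traits: species means 3 within-species sds apart
  # (6 for the designated discriminative trait), each trait with its own
  # species ordering so classical traits do not all encode the same
  # species axis as the shape/color signal
  # round_to mimics IBPGR field recording precision; coarse rounding ties
  # accessions within species, so only finely recorded, widely separated
  # traits can discriminate every accession. syndrome groups numeric
  # traits into two correlated blocks (a maturity syndrome and a leaf-size
  # syndrome), each with its own species ordering independent of the
  # shape/color axes.
  num_specs <- list(
    days_to_flowering = list(base = 40, sd = 3, sep = 6, round_to = 1,
                             syndrome = "maturity"),
    days_to_harvest   = list(base = 90, sd = 4, sep = 3, round_to = 5,
                             syndrome = "maturity"),
    weight_100seed    = list(base = 20, sd = 2, sep = 3, round_to = 2,
                             syndrome = "maturity"),
    pod_length        = list(base = 6.0, sd = 0.6, sep = 3, round_to = 0.5,
                             syndrome = "maturity"),
    leaf_length       = list(base = 5.0, sd = 0.5, sep = 3, round_to = 0.5,
                             syndrome = "leaf"),
    leaf_width        = list(base = 2.5, sd = 0.3, sep = 3, round_to = 0.25,
                             syndrome = "leaf"),
    leaf_ratio        = list(base = 1.8, sd = 0.15, sep = 3, round_to = 0.2,
                             syndrome = "leaf"))
  synd_perm <- list(maturity = sample(seq_len(n_species)) - 1,
                    leaf = sample(seq_len(n_species)) - 1)
  perms <- stats::setNames(lapply(num_specs, function(t)
    synd_perm[[t$syndrome]]), names(num_specs))

  mk <- function(idx, id, displace = 0) {
    orgs <- lapply(organs, function(org) {
      b <- base_shapes[[org]]
      # species-structured shape: perturb harmonics 2+ of the base shape,
      # with 1/harmonic decay so outlines stay simple; redraw until the
      # mean shape itself is a simple polygon
      for (try in 1:50) {
        pert <- function(v) {
          h <- seq_along(v)[-1]
          v + c(0, stats::rnorm(length(h), 0, 0.05 / h)) +
            c(0, displace * stats::rnorm(length(h), 0, 0.10 / h))
        }
        o <- list(an = pert(b$an), bn = pert(b$bn),
                  cn = pert(b$cn), dn = pert(b$dn))
        # the outlier species also gets a strongly different aspect ratio
        # (all y-coefficients scaled, which preserves simplicity)
        if (displace > 0) { o$cn <- o$cn * 0.45; o$dn <- o$dn * 0.45 }
        e <- structure(c(o, list(A0 = 0, C0 = 0,
                                 n_harmonics = length(o$an),
                                 normalized = FALSE)), class = "efd")
        if (is_simple_polygon(efd_reconstruct(e, 256))) break
        if (try == 50) stop("could not draw a simple mean shape")
      }
      o
    })
    names(orgs) <- organs
    anchor <- anchors[(idx %% nrow(anchors)) + 1, ]
    if (displace > 0) anchor <- c(0.9, 0.1, 0.9)
    means <- rbind(pmin(0.98, pmax(0.02, anchor + stats::rnorm(3, 0, 0.04))),
                   pmin(0.98, pmax(0.02, anchor * 0.5 + stats::rnorm(3, 0, 0.04))))
    # equal mixture weights keep the k-means centroid allocation between
    # the two coat tones stable across pixel pools
    pal <- list(means = means, sds = c(0.03, 0.03), weights = c(0.5, 0.5))
    pref <- function(levels, at, p = 0.7) {
      pr <- rep((1 - p) / (length(levels) - 1), length(levels))
      pr[at] <- p
      pr
    }
    # per-trait species position: trait-specific ordering for regular
    # species; the outlier sits 3 steps beyond the highest species on
    # every trait axis
    pos <- function(tn) if (displace > 0) n_species + 2 else perms[[tn]][idx + 1]
    cls <- lapply(names(num_specs), function(tn) {
      sp <- num_specs[[tn]]
      list(class = "numeric", mean = sp$base + sp$sep * sp$sd * pos(tn),
           sd = sp$sd, round_to = sp$round_to)
    })
    names(cls) <- names(num_specs)
    # primary seed color is the designated discriminative descriptor:
    # a near-deterministic species indicator (each regular species has its
    # own dominant coat color); other categoricals are weaker scores
    cls$seed_brightness <- list(class = "ordinal", levels = bright_levels,
                                probs = pref(bright_levels, (idx %% 3) + 1, 0.6))
    cls$vigor <- list(class = "ordinal", levels = bright_levels,
                      probs = pref(bright_levels, ((idx + 1) %% 3) + 1, 0.6))
    cls$growth_habit <- list(class = "nominal", levels = habit_levels,
                             probs = pref(habit_levels, ((idx + 2) %% 3) + 1, 0.6))
    cls$primary_seed_color <- list(class = "nominal", levels = color_levels,
                                   probs = pref(color_levels, (idx %% 5) + 1, 0.9))
    cls$secondary_seed_color <- list(class = "nominal", levels = color_levels,
                                     probs = pref(color_levels, ((idx + 2) %% 5) + 1, 0.6))
    # the designated discriminative descriptor: an RHS-chart flower color
    # code with a species-specific block of codes and high accession-level
    # diversity within the block, so it separates accessions and species
    # at once
    blk <- (idx %% 6) * 3 + 1:3
    rhs_probs <- rep(0.1 / 17, 20)
    rhs_probs[blk] <- 0.9 / 3
    cls$rhs_flower_color <- list(class = "nominal", levels = rhs_levels,
                                 probs = rhs_probs)
    species_template(id, orgs, shape_sd_accession = 0.03,
                     shape_sd_plant = 0.01, palette = pal, classical = cls)
  }
  tpl <- lapply(seq_len(n_species) - 1,
                function(i) mk(i, sprintf("SP%02d", i + 1)))
  names(tpl) <- vapply(tpl, `[[`, "", "species_id")
  if (outlier) tpl$SP_OUT <- mk(n_species, "SP_OUT", displace = 1)
  tpl
}

#' Simulation configuration
#'
#' @param species List of `species_template`s.
#' @param accessions_per_species Accessions per regular species (>= 1). A
#'   species named `"SP_OUT"` always gets a single (outlier) accession.
#' @param plants_per_accession Replicate plants (organ images) per accession
#'   (default 10, the usual plot sample in classical characterization).
#' @param image_size Rendered image side in pixels (>= 64).
#' @param seed Master seed; all per-accession streams derive from it.
#' @param n_redundant Number of accessions of the first species generated
#'   as copies of one accession (shared accession-level offsets), the
#'   designated redundant group (default 2 when the design allows it;
#'   0 disables).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(species, accessions_per_species = 3,
                              plants_per_accession = 10, image_size = 128,
                              seed = 1,
                              n_redundant = if (accessions_per_species >= 2) 2 else 0) {
  stopifnot(accessions_per_species >= 1, plants_per_accession >= 1,
            image_size >= 64, length(species) >= 1,
            n_redundant <= accessions_per_species)
  structure(list(species = species,
                 accessions_per_species = accessions_per_species,
                 plants_per_accession = plants_per_accession,
                 image_size = image_size, seed = as.integer(seed),
                 n_redundant = n_redundant),
            class = "simulation_config")
}

# deterministic string hash onto [0, 2^31 - 2]; stable across platforms so
# per-(accession, organ) streams do not shift when accessions are added
stable_hash <- function(...) {
  s <- paste(..., sep = "/")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Sample outlines for one accession and organ
#'
#' Draws one accession-level coefficient offset (sd `shape_sd_accession`)
#' and, per plant, an independent coefficient perturbation (sd
#' `shape_sd_plant`), reconstructs each perturbed coefficient set as a
#' 256-point outline, and rejects-and-resamples self-intersecting
#' reconstructions (at most 100 retries each).
#'
#' @param template A `species_template`.
#' @param organ Organ name present in the template.
#' @param n Number of outlines (plants).
#' @param accession_seed Integer stream seed for the plant-level draws of
#'   this accession x organ.
#' @param offset_seed Integer stream seed for the accession-level offset
#'   (defaults to `accession_seed`). Designated duplicate accessions share
#'   an offset stream, so they carry the same accession-level shape.
#' @return List of `n` two-column outline matrices.
#' @export
sample_outlines <- function(template, organ, n, accession_seed,
                            offset_seed = accession_seed) {
  stopifnot(inherits(template, "species_template"))
  org <- template$organs[[organ]]
  if (is.null(org)) stop("template has no organ '", organ, "'")
  nh <- length(org$an)
  hdecay <- rep(seq_len(nh), 4)       # noise shrinks as 1/harmonic
  mean_coef <- c(org$an, org$bn, org$cn, org$dn)
  recon <- function(v) {
    e <- structure(list(an = v[1:nh], bn = v[nh + 1:nh],
                        cn = v[2 * nh + 1:nh], dn = v[3 * nh + 1:nh],
                        A0 = 0, C0 = 0, n_harmonics = nh, normalized = FALSE),
                   class = "efd")
    efd_reconstruct(e, 256)
  }
  # accession-level offset; redrawn if its noise-free shape self-intersects
  set.seed(as.integer(offset_seed %% .Machine$integer.max))
  base <- NULL
  for (try in seq_len(100)) {
    offset <- stats::rnorm(4 * nh, 0, template$shape_sd_accession / hdecay)
    cand <- mean_coef + offset
    if (is_simple_polygon(recon(cand))) { base <- cand; break }
    if (template$shape_sd_accession == 0) break
  }
  if (is.null(base)) stop("degenerate template: no simple accession shape in 100 retries")
  set.seed(as.integer(accession_seed %% .Machine$integer.max))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(100)) {
      xy <- recon(base + stats::rnorm(4 * nh, 0, template$shape_sd_plant / hdecay))
      if (is_simple_polygon(xy)) { out[[i]] <- xy; ok <- TRUE; break }
    }
    if (!ok) stop("degenerate template: no simple outline in 100 retries")
  }
  out
}

#' Draw pixels from an RGB Gaussian-mixture palette
#'
#' @param palette List with `means`, `sds`, `weights` (see
#'   [species_template()]).
#' @param n Number of pixels.
#' @param seed Integer seed.
#' @return `n x 3` RGB matrix, clipped to \[0, 1\].
#' @export
sample_palette_pixels <- function(palette, n, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  comp <- sample.int(length(palette$weights), n, replace = TRUE,
                     prob = palette$weights)
  px <- palette$means[comp, , drop = FALSE] +
    matrix(stats::rnorm(3 * n, 0, palette$sds[comp]), n, 3)
  px[] <- pmin(1, pmax(0, px))
  px
}

#' Render a synthetic organ image from an outline and a palette
#'
#' Centers and scales the outline to 70% of the frame, rasterizes it, fills
#' interior pixels with palette draws (clipped to \[0,1\]) and leaves the
#' background pure white.
#'
#' @param outline Two-column (x, y) outline matrix.
#' @param palette Palette list (see [species_template()]).
#' @param image_size Image side in pixels.
#' @param seed Integer seed for the pixel draws.
#' @return List with `image` (`size x size x 3`) and `mask` (logical).
#' @export
render_organ_image <- function(outline, palette, image_size = 128, seed = 1) {
  xy <- as_outline_matrix(outline)
  if (abs(shoelace_area(xy)) < 1e-9) stop("degenerate outline: zero area")
  ctr <- colMeans(xy)
  span <- max(apply(xy, 2, function(v) diff(range(v))))
  sc <- 0.7 * image_size / span
  xy <- sweep(xy, 2, ctr) * sc
  xy <- sweep(xy, 2, c(image_size / 2, image_size / 2), `+`)
  mask <- rasterize_outline(xy, image_size, image_size)
  n_in <- sum(mask)
  if (n_in == 0) stop("degenerate outline: empty rasterization")
  px <- sample_palette_pixels(palette, n_in, seed)
  img <- array(1, dim = c(image_size, image_size, 3))
  for (c in 1:3) {
    ch <- img[, , c]
    ch[mask] <- px[, c]
    img[, , c] <- ch
  }
  list(image = img, mask = mask)
}

#' Generate a full synthetic accession dataset
#'
#' Produces, for every accession: per-organ outlines for each replicate
#' plant, an accession-specific realized palette (template palette plus an
#' accession-level mean offset), one classical-descriptor row, and the
#' ground truth (species map, designated discriminative descriptor,
#' designated redundant accession group, designated outlier accession).
#' When `out_dir` is given, writes 8-bit RGB PNGs and mask PNGs under
#' `<species>/<accession>/<organ>/<plant>.png`, the classical table as CSV,
#' and ground truth + config as JSON.
#'
#' Redundant accessions (the first `n_redundant` of the first species) get
#' zero accession-level offsets everywhere and classical values equal to
#' their species' distribution center, so their generating distributions
#' are identical. The outlier accession is the single accession of the
#' displaced `"SP_OUT"` species, when present.
#'
#' @param config A `simulation_config`.
#' @param out_dir Optional output directory.
#' @param render Render images in memory even without `out_dir` (default
#'   FALSE; outlines and palettes are always produced).
#' @return List with `outlines` (accession -> organ -> list of outlines),
#'   `palettes` (accession -> palette), `images` (if rendered),
#'   `classical` (accession-level data.frame of plant means/modes),
#'   `classical_plant` (the underlying per-plant measurements),
#'   `classical_meta`, `classical_levels`, `species_map`, `ground_truth`,
#'   `config`.
#' @export
generate_dataset <- function(config, out_dir = NULL, render = !is.null(out_dir)) {
  stopifnot(inherits(config, "simulation_config"))
  tpls <- config$species
  organs <- names(tpls[[1]]$organs)
  acc_rows <- list(); k <- 0
  for (si in seq_along(tpls)) {
    sp <- tpls[[si]]$species_id
    n_acc <- if (sp == "SP_OUT") 1 else config$accessions_per_species
    for (ai in seq_len(n_acc)) {
      k <- k + 1
      acc_rows[[k]] <- data.frame(
        accession = sprintf("ACC%03d", k), species = sp,
        redundant = (si == 1 && ai <= config$n_redundant),
        outlier = (sp == "SP_OUT"))
    }
  }
  map <- do.call(rbind, acc_rows)

  outlines <- list(); palettes <- list(); images <- list()
  cls_rows <- list()
  for (r in seq_len(nrow(map))) {
    acc <- map$accession[r]
    tpl <- tpls[[map$species[r]]]
    red <- map$redundant[r]

    # accession-level palette offset; designated duplicate accessions share
    # one offset stream (they are copies of the same accession)
    acc_tag <- if (red) "DUPLICATE" else acc
    set.seed(stable_hash(config$seed, acc_tag, "palette"))
    pal <- tpl$palette
    m <- pal$means + matrix(stats::rnorm(length(pal$means), 0, 0.08),
                            nrow(pal$means))
    m[] <- pmin(0.98, pmax(0.02, m))
    pal$means <- m
    palettes[[acc]] <- pal

    outlines[[acc]] <- list()
    if (render) images[[acc]] <- list()
    for (org in organs) {
      sd_seed <- stable_hash(config$seed, acc, org)
      ol <- sample_outlines(tpl, org, config$plants_per_accession, sd_seed,
                            offset_seed = stable_hash(config$seed, acc_tag, org))
      outlines[[acc]][[org]] <- ol
      if (render) {
        images[[acc]][[org]] <- lapply(seq_along(ol), function(i)
          render_organ_image(ol[[i]], pal, config$image_size,
                             seed = stable_hash(config$seed, acc, org, i)))
      }
    }

    # classical traits: one accession-level center per trait (shared stream
    # for duplicate accessions), measured on every replicate plant with
    # measurement noise (numerics) and recorded at field precision;
    # categorical traits are scored once per accession
    set.seed(stable_hash(config$seed, acc_tag, "classical"))
    np <- config$plants_per_accession
    centers <- lapply(tpl$classical, function(tr) {
      if (tr$class == "numeric") stats::rnorm(1, tr$mean, tr$sd)
      else sample(tr$levels, 1, prob = tr$probs)
    })
    set.seed(stable_hash(config$seed, acc, "classical-plants"))
    prow <- list(accession = rep(acc, np),
                 species = rep(map$species[r], np),
                 plant = seq_len(np))
    for (tn in names(tpl$classical)) {
      tr <- tpl$classical[[tn]]
      prow[[tn]] <- if (tr$class == "numeric") {
        v <- stats::rnorm(np, centers[[tn]], 0.5 * tr$sd)
        if (!is.null(tr$round_to)) v <- round(v / tr$round_to) * tr$round_to
        v
      } else {
        rep(centers[[tn]], np)
      }
    }
    cls_rows[[r]] <- as.data.frame(prow, stringsAsFactors = FALSE)
  }
  classical_plant <- do.call(rbind, cls_rows)
  rownames(classical_plant) <- NULL

  # accession-level classical table: plant means (numeric) / modes (categorical)
  tr0 <- tpls[[1]]$classical
  acc_rows2 <- lapply(split(classical_plant, classical_plant$accession), function(g) {
    out <- list(accession = g$accession[1], species = g$species[1])
    for (tn in names(tr0)) {
      out[[tn]] <- if (tr0[[tn]]$class == "numeric") mean(g[[tn]]) else {
        tab <- sort(table(g[[tn]]), decreasing = TRUE)
        sort(names(tab)[tab == max(tab)])[1]
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  classical <- do.call(rbind, acc_rows2[unique(classical_plant$accession)])
  rownames(classical) <- NULL
  classical_meta <- data.frame(
    name = names(tr0),
    dclass = vapply(tr0, `[[`, "", "class"),
    dtype = "classical", organ = NA_character_,
    stringsAsFactors = FALSE)
  rownames(classical_meta) <- NULL
  levels_map <- lapply(tr0, function(tr)
    if (tr$class == "numeric") NULL else tr$levels)

  gt <- list(
    species_map = stats::setNames(map$species, map$accession),
    discriminative = "rhs_flower_color",
    redundant = map$accession[map$redundant],
    outlier = if (any(map$outlier)) map$accession[map$outlier] else NULL)
  stopifnot(!(gt$outlier %in% gt$redundant))

  ds <- list(outlines = outlines, palettes = palettes,
             images = if (render) images else NULL,
             classical = classical, classical_plant = classical_plant,
             classical_meta = classical_meta,
             classical_levels = levels_map,
             species_map = map[, c("accession", "species")],
             ground_truth = gt, config = config)
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

# serialize a generated dataset: PNGs + masks, classical CSV, JSON sidecars
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (acc in names(ds$images)) {
    sp <- ds$species_map$species[ds$species_map$accession == acc]
    for (org in names(ds$images[[acc]])) {
      d <- file.path(out_dir, sp, acc, org)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(ds$images[[acc]][[org]])) {
        im <- ds$images[[acc]][[org]][[i]]
        png::writePNG(im$image, file.path(d, sprintf("plant%02d.png", i)))
        png::writePNG(im$mask * 1, file.path(d, sprintf("plant%02d_mask.png", i)))
      }
    }
  }
  utils::write.csv(ds$classical, file.path(out_dir, "classical.csv"),
                   row.names = FALSE)
  jsonlite::write_json(ds$ground_truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  cfg <- ds$config
  cfg$species <- names(cfg$species)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
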