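test_that("species_template validates its invariants", {
  org <- list(an = c(1, 0), bn = c(0, 0), cn = c(0, 0), dn = c(0.5, 0))
  pal <- list(means = matrix(0.5, 2, 3), sds = c(0.1, 0.1), weights = c(0.6, 0.4))
  cls <- list(x = list(class = "numeric", mean = 0, sd = 1))
  expect_s3_class(species_template("S", list(seed = org), 0.1, 0.1, pal, cls),
                  "species_template")
  bad_pal <- pal; bad_pal$weights <- c(0.6, 0.3)
  expect_error(species_template("S", list(seed = org), 0.1, 0.1, bad_pal, cls))
  bad_cls <- list(x = list(class = "nominal", levels = c("a", "b"),
                           probs = c(0.7, 0.2)))
  expect_error(species_template("S", list(seed = org), 0.1, 0.1, pal, bad_cls))
})

test_that("zero noise gives identical outlines; same seed reproduces", {
  tpl <- default_templates(1, seed = 3, organs = "seed", outlier = FALSE)[[1]]
  tpl$shape_sd_accession <- 0
  tpl$shape_sd_plant <- 0
  ol <- sample_outlines(tpl, "seed", 4, accession_seed = 10)
  for (i in 2:4) expect_identical(ol[[1]], ol[[i]])

  tpl2 <- default_templates(1, seed = 3, organs = "seed", outlier = FALSE)[[1]]
  a <- sample_outlines(tpl2, "seed", 3, accession_seed = 42)
  b <- sample_outlines(tpl2, "seed", 3, accession_seed = 42)
  expect_identical(a, b)
})

test_that("a circle template with zero noise reconstructs to the circle area", {
  org <- list(an = c(3, 0), bn = c(0, 0), cn = c(0, 0), dn = c(3, 0))
  pal <- list(means = matrix(0.5, 1, 3), sds = 0.02, weights = 1)
  tpl <- species_template("circle", list(seed = org), 0, 0, pal,
                          list(x = list(class = "numeric", mean = 0, sd = 1)))
  ol <- sample_outlines(tpl, "seed", 1, accession_seed = 1)[[1]]
  expect_equal(nrow(ol), 256)
  expect_equal(abs(phenomdiv:::shoelace_area(ol)), pi * 3^2, tolerance = 0.01)
})

test_that("degenerate templates exhaust the retry budget", {
  # a figure-eight first harmonic (b1 = d1 swap) self-intersects always
  org <- list(an = c(1, 0), bn = c(0, 0.9), cn = c(0, 0.9), dn = c(0, 0))
  pal <- list(means = matrix(0.5, 1, 3), sds = 0.02, weights = 1)
  tpl <- species_template("bad", list(seed = org), 0, 0.001, pal,
                          list(x = list(class = "numeric", mean = 0, sd = 1)))
  expect_error(sample_outlines(tpl, "seed", 1, accession_seed = 1), "degenerate")
})

test_that("rendering fills the mask from the palette", {
  t <- seq(0, 2 * pi, length.out = 129)[-129]
  circ <- cbind(cos(t), sin(t))
  pal1 <- list(means = matrix(c(0.3, 0.5, 0.7), 1), sds = 0, weights = 1)
  out <- render_organ_image(circ, pal1, image_size = 64, seed = 1)
  px <- foreground_pixels(out$image, out$mask)
  expect_true(all(px[, 1] == 0.3 & px[, 2] == 0.5 & px[, 3] == 0.7))
  # background is pure white
  expect_true(all(out$image[!out$mask] == 1))
  # mask equals the rasterizer's filled polygon exactly (same pixel count)
  xy <- sweep(sweep(circ, 2, colMeans(circ)) * 0.7 * 64 / 2, 2, c(32, 32), `+`)
  expect_equal(sum(out$mask), sum(rasterize_outline(xy, 64, 64)))
})

test_that("two-component palette proportions follow the weights", {
  t <- seq(0, 2 * pi, length.out = 129)[-129]
  circ <- cbind(cos(t), sin(t))
  pal <- list(means = rbind(c(0.2, 0.2, 0.2), c(0.8, 0.8, 0.8)),
              sds = c(0, 0), weights = c(0.8, 0.2))
  out <- render_organ_image(circ, pal, image_size = 160, seed = 7)
  px <- foreground_pixels(out$image, out$mask)
  expect_gt(nrow(px), 9000)              # ~1e4 interior pixels
  frac <- mean(px[, 1] < 0.5)
  expect_equal(frac, 0.8, tolerance = 0.025)
})

test_that("degenerate outlines are rejected by the renderer", {
  line <- cbind(seq(0, 1, length.out = 20), rep(0.5, 20))
  pal <- list(means = matrix(0.5, 1, 3), sds = 0, weights = 1)
  expect_error(render_organ_image(line, pal, 64, 1), "degenerate")
})

test_that("generate_dataset counts, layout and determinism", {
  ds <- small_panel(seed = 7, n_species = 2, acc = 2, plants = 3, render = TRUE)
  expect_equal(length(ds$outlines), 4)
  n_imgs <- sum(vapply(ds$images, function(a) sum(lengths(a)), numeric(1)))
  expect_equal(n_imgs, 2 * 2 * 3 * 2)     # species x accessions x plants x organs
  expect_equal(nrow(ds$classical), 4)
  expect_equal(nrow(ds$classical_plant), 12)

  # per-accession, per-organ plant counts are exact
  for (acc in names(ds$outlines))
    expect_true(all(lengths(ds$outlines[[acc]]) == 3))

  # byte-identical serialization on rerun
  d1 <- file.path(tempdir(), "panelA"); d2 <- file.path(tempdir(), "panelB")
  unlink(c(d1, d2), recursive = TRUE)
  tplA <- default_templates(2, seed = 7, organs = c("seed", "leaf"), outlier = FALSE)
  generate_dataset(simulation_config(tplA, 2, 3, seed = 7), out_dir = d1)
  tplB <- default_templates(2, seed = 7, organs = c("seed", "leaf"), outlier = FALSE)
  generate_dataset(simulation_config(tplB, 2, 3, seed = 7), out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  expect_true(any(grepl("^SP01/ACC001/seed/plant01\\.png$", f1)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(h1) == unname(h2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("ground truth designates consistent structure", {
  ds <- small_panel(seed = 5, n_species = 3, acc = 3, plants = 2, outlier = TRUE)
  gt <- ds$ground_truth
  expect_equal(length(gt$redundant), 2)
  expect_false(gt$outlier %in% gt$redundant)
  expect_true(gt$discriminative %in% ds$classical_meta$name)
  expect_equal(unname(gt$species_map[gt$outlier]), "SP_OUT")
  # duplicate accessions share their accession-level classical centers
  r <- gt$redundant
  cm <- ds$classical[match(r, ds$classical$accession), "rhs_flower_color"]
  expect_equal(cm[1], cm[2])
  expect_identical(ds$palettes[[r[1]]], ds$palettes[[r[2]]])
})

test_that("plant noise monotonically widens within-accession shape spread", {
  tpl0 <- default_templates(1, seed = 5, organs = "seed", outlier = FALSE)[[1]]
  md <- vapply(c(0.004, 0.015, 0.05), function(sdp) {
    mean(vapply(1:20, function(rep) {
      t <- tpl0
      t$shape_sd_plant <- sdp
      t$shape_sd_accession <- 0
      ol <- sample_outlines(t, "seed", 6, accession_seed = rep * 31 + 1)
      X <- do.call(rbind, lapply(ol, function(o)
        flatten_efd(efd_normalize(efa(o, 8)))))
      mean(dist(X))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(md) > 0))
})
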