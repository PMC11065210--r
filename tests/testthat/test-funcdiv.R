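test_that("gower: identical rows, the hand formula, and zero-range dropping", {
  data <- data.frame(num = c(0, 5, 10), nom = c("a", "b", "a"),
                     stringsAsFactors = FALSE)
  meta <- data.frame(name = c("num", "nom"), dclass = c("numeric", "nominal"),
                     dtype = "classical", organ = NA_character_)
  dm <- descriptor_matrix(data, meta, accession = c("A1", "A2", "A3"),
                          species = rep("S", 3))
  D <- gower_dist(dm)
  expect_equal(D["A1", "A2"], (0.5 + 1) / 2)   # |0-5|/10 and mismatch
  expect_equal(D["A1", "A3"], (1 + 0) / 2)
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  expect_equal(D, t(D))

  dup <- descriptor_matrix(data[c(1, 1, 2), ], meta,
                           accession = c("A1", "A1b", "A2"),
                           species = rep("S", 3))
  expect_equal(gower_dist(dup)["A1", "A1b"], 0)

  flat <- descriptor_matrix(
    data.frame(num = c(1, 1, 1), x = c(0, 1, 2)),
    data.frame(name = c("num", "x"), dclass = "numeric", dtype = "classical",
               organ = NA_character_),
    accession = c("A1", "A2", "A3"), species = rep("S", 3))
  expect_warning(Df <- gower_dist(flat), "zero-range")
  expect_equal(Df["A1", "A3"], 1)   # only x contributes
})

test_that("gower matches the per-cell oracle on random mixed tables", {
  for (seed in 1:6) {
    dm <- random_mixed_dm(seed)
    expect_lt(max(abs(gower_dist(dm) - gower_oracle(dm))), 1e-12)
  }
})

test_that("gower agrees with cluster::daisy on numeric-only tables", {
  skip_if_not_installed("cluster")
  set.seed(12)
  data <- as.data.frame(matrix(runif(8 * 4), 8))
  meta <- data.frame(name = names(data), dclass = "numeric",
                     dtype = "classical", organ = NA_character_)
  dm <- descriptor_matrix(data, meta, accession = paste0("A", 1:8),
                          species = rep("S", 8))
  D <- gower_dist(dm)
  Dd <- as.matrix(cluster::daisy(data, metric = "gower"))
  expect_equal(unname(D), unname(Dd), tolerance = 1e-10)
})

test_that("gower stays within [0, 1]", {
  for (seed in 7:9) {
    D <- gower_dist(random_mixed_dm(seed, n = 7))
    expect_true(all(D >= 0 & D <= 1 + 1e-12))
  }
})

test_that("pcoa recovers planar configurations up to rigid motion", {
  set.seed(13)
  pts <- matrix(runif(10), 5)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("A", 1:5), paste0("A", 1:5))
  pc <- pcoa(D, n_axes = 4)
  expect_equal(as.matrix(dist(pc$coords)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
})

test_that("pcoa of three equidistant points is an equilateral triangle", {
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(c("A", "B", "C"), c("A", "B", "C"))
  pc <- pcoa(D, n_axes = 2)
  ev <- pc$eigenvalues[pc$eigenvalues > 1e-10]
  expect_equal(length(ev), 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-8)
  d <- dist(pc$coords)
  expect_equal(as.numeric(d), rep(1, 3), tolerance = 1e-8)
})

test_that("pcoa rejects bad input", {
  D <- matrix(1, 3, 3) - diag(3)
  expect_error(pcoa(D, n_axes = 1), ">= 2")
})

test_that("hull: squares, triangles and the brute-force oracle", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  rownames(pts) <- paste0("A", 1:5)
  h <- hull_2d(pts)
  expect_equal(h$area, 1)
  expect_setequal(h$vertices, paste0("A", 1:4))

  tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
  rownames(tri) <- paste0("T", 1:3)
  expect_equal(hull_2d(tri)$area, 2)

  set.seed(14)
  for (rep in 1:3) {
    xy <- matrix(rnorm(60), 30)
    rownames(xy) <- paste0("P", 1:30)
    h <- hull_2d(xy)
    expect_setequal(h$vertices, rownames(xy)[hull_vertices_oracle(xy)])
    expect_lte(length(h$vertices), 30)
  }
})

test_that("collinear points give area zero with a warning", {
  xy <- cbind(1:5, 2 * (1:5))
  rownames(xy) <- paste0("A", 1:5)
  expect_warning(h <- hull_2d(xy), "collinear")
  expect_equal(h$area, 0)
})

fe3 <- c(A1 = "S1", A2 = "S2", A3 = "S2", A4 = "S3", A5 = "S3", A6 = "S3")

test_that("fspe: singleton farthest FE scores exactly 1", {
  set.seed(15)
  coords <- rbind(c(10, 0), c(0, 1), c(0, -1), c(-1, 0), c(-1, 1), c(0.5, 0.5))
  rownames(coords) <- names(fe3)
  s <- fspe(coords, fe3)
  expect_equal(unname(s["S1"]), 1)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(unname(max(s)), 1)
})

test_that("fspe: FE at the pooled centroid scores 0; symmetric singletons tie at 1", {
  coords <- rbind(c(-1, 0), c(1, 0), c(0, 0), c(0, 0))
  rownames(coords) <- c("L", "R", "C1", "C2")
  fe <- c(L = "left", R = "right", C1 = "center", C2 = "center")
  s <- fspe(coords, fe)
  expect_equal(unname(s[c("left", "right")]), c(1, 1))
  expect_equal(unname(s["center"]), 0)
  expect_error(fspe(coords[1, , drop = FALSE], fe), "single accession")
})

test_that("fori nearest-entity: isolated singleton scores 1, duplicates contribute 0", {
  coords <- rbind(c(10, 0), c(0, 0), c(0, 0), c(1, 0))
  rownames(coords) <- c("far", "d1", "d2", "x")
  fe <- c(far = "Sfar", d1 = "Sa", d2 = "Sb", x = "Sa")
  s <- fori(coords, fe)
  expect_equal(unname(s["Sfar"]), 1)
  # d1/d2 are identical accessions in different FEs: zero contribution
  expect_equal(unname(s["Sb"]), 0)
  expect_error(fori(coords, fe, variant = "nope"))
})

test_that("fori intra_mean flags singletons as missing", {
  coords <- rbind(c(0, 0), c(1, 0), c(5, 5))
  rownames(coords) <- c("a", "b", "c")
  fe <- c(a = "S1", b = "S1", c = "S2")
  s <- fori(coords, fe, variant = "intra_mean")
  expect_true(is.na(s["S2"]))
  expect_equal(unname(s["S1"]), 1)   # only FE with a defined value
})

test_that("fide: singleton coordinates, midpoints and the pooled-centroid identity", {
  coords <- rbind(c(-1, 0), c(1, 0), c(3, 4))
  rownames(coords) <- c("a", "b", "c")
  fe <- c(a = "S1", b = "S1", c = "S2")
  fi <- fide(coords, fe)
  expect_equal(unname(fi["S1", ]), c(0, 0))
  expect_equal(unname(fi["S2", ]), c(3, 4))

  set.seed(16)
  coords2 <- matrix(rnorm(20), 10)
  coords2 <- sweep(coords2, 2, colMeans(coords2))
  rownames(coords2) <- paste0("A", 1:10)
  fe2 <- setNames(rep(c("S1", "S2", "S3"), c(2, 3, 5)), rownames(coords2))
  fi2 <- fide(coords2, fe2)
  sizes <- table(fe2)[rownames(fi2)]
  grand <- colSums(fi2 * as.numeric(sizes)) / sum(sizes)
  expect_lt(max(abs(grand)), 1e-10)
})

test_that("fd_report: identical inputs give identical index tables", {
  dm <- random_mixed_dm(20, n = 6)
  fe <- setNames(rep(c("S1", "S2", "S3"), each = 2), dm$accession)
  rep2 <- fd_report(list(Phe = dm, Cla = dm), fe)
  it <- rep2$index_table
  expect_equal(it$FSpe_Phe, it$FSpe_Cla)
  expect_equal(it$FOri_Phe, it$FOri_Cla)
  expect_true(all(it$FSpe_Phe >= 0 & it$FSpe_Phe <= 1))
  # FSpe hits 1 exactly only when an FE holds the max-distance accession
  # alone; with paired FEs the max is merely bounded by 1
  expect_lte(max(it$FSpe_Phe), 1)
  expect_lte(max(it$FOri_Phe), 1)
  expect_equal(rep2$summary$hull_area[1], rep2$summary$hull_area[2])
  expect_lte(rep2$summary$n_vertices[1], length(dm$accession))
})

test_that("fd_report intersects differing accession sets with a warning", {
  dm1 <- random_mixed_dm(21, n = 6)
  dm2 <- random_mixed_dm(21, n = 6)
  keep <- 1:5
  dm2$data <- dm2$data[keep, ]
  dm2$accession <- dm2$accession[keep]
  dm2$species <- dm2$species[keep]
  fe <- setNames(rep(c("S1", "S2", "S3"), each = 2), dm1$accession)
  expect_warning(r <- fd_report(list(A = dm1, B = dm2), fe), "intersect")
  expect_equal(nrow(r$spaces$A$pcoa$coords), 5)
})

test_that("combined trait space beats either component when signals are independent and balanced", {
  mk <- function(latent, k, noise, seed, prefix) {
    set.seed(seed)
    n <- length(latent)
    data <- as.data.frame(sapply(seq_len(k), function(j)
      latent + rnorm(n, 0, noise)))
    names(data) <- paste0(prefix, seq_len(k))
    meta <- data.frame(name = names(data), dclass = "numeric",
                       dtype = if (prefix == "P") "phenomic" else "classical",
                       organ = NA_character_)
    descriptor_matrix(data, meta,
                      accession = paste0("A", sprintf("%02d", seq_len(n))),
                      species = rep(c("S1", "S2", "S3", "S4"),
                                    length.out = n))
  }
  wins <- vapply(1:20, function(seed) {
    set.seed(1000 + seed)
    u <- rnorm(16); v <- rnorm(16)
    phe <- mk(u, 10, 0.15, seed, "P")
    cla <- mk(v, 10, 0.15, 2000 + seed, "C")
    sm <- data.frame(accession = phe$accession, species = phe$species)
    com <- assemble_descriptors(phe, cla, sm, "combined")
    fe <- setNames(phe$species, phe$accession)
    r <- suppressWarnings(fd_report(list(Phe = phe, Cla = cla, Com = com), fe))
    h <- r$summary$hull_area
    h[3] >= max(h[1:2])
  }, logical(1))
  expect_gte(sum(wins), 18)
})
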