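circle_outline <- function(r = 5, n = 256, phase = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)] + phase
  cbind(r * cos(t), r * sin(t))
}

ellipse_outline <- function(a = 4, b = 2, n = 256) {
  t <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(a * cos(t), b * sin(t))
}

test_that("efa recovers circle and ellipse first-harmonic coefficients", {
  e <- efa(circle_outline(r = 5), 8)
  expect_equal(abs(e$an[1]), 5, tolerance = 1e-3)
  expect_equal(abs(e$dn[1]), 5, tolerance = 1e-3)
  high <- c(e$an[-1], e$bn[-1], e$cn[-1], e$dn[-1])
  expect_lt(max(abs(high)), 0.01 * 5)

  # arc-length parameterization: a1/d1 approach the semiaxes but equal the
  # oracle's values exactly
  xy <- ellipse_outline(4, 2)
  e2 <- efa(xy, 8)
  o2 <- efa_oracle(xy, 8)
  expect_equal(e2$an[1], o2$an[1], tolerance = 1e-6)
  expect_equal(e2$dn[1], o2$dn[1], tolerance = 1e-6)
  expect_equal(e2$an[1], 4, tolerance = 0.1)
  expect_equal(e2$dn[1], 2, tolerance = 0.1)
  expect_lt(abs(e2$bn[1]), 0.02)
  expect_lt(abs(e2$cn[1]), 0.02)
})

test_that("translation changes only the offset terms", {
  xy <- random_smooth_shape(11)
  e1 <- efa(xy, 10)
  e2 <- efa(sweep(xy, 2, c(3.7, -1.2), `+`), 10)
  expect_equal(e2$A0 - e1$A0, 3.7, tolerance = 1e-9)
  expect_equal(e2$C0 - e1$C0, -1.2, tolerance = 1e-9)
  expect_equal(flatten_efd(e1), flatten_efd(e2), tolerance = 1e-9)
})

test_that("efa matches the numerical-projection oracle on random smooth shapes", {
  for (seed in 1:20) {
    xy <- random_smooth_shape(seed)
    e <- efa(xy, 6)
    o <- efa_oracle(xy, 6)
    scale <- max(abs(unlist(o[c("an", "bn", "cn", "dn")])))
    expect_lt(max(abs(c(e$an - o$an, e$bn - o$bn,
                        e$cn - o$cn, e$dn - o$dn))) / scale, 1e-6)
    expect_lt(abs(e$A0 - o$A0) / scale, 1e-6)
    expect_lt(abs(e$C0 - o$C0) / scale, 1e-6)
  }
})

test_that("efa cleans repeated points and rejects degenerate outlines", {
  xy <- circle_outline(n = 64)
  dup <- xy[rep(seq_len(nrow(xy)), each = 3), ]
  expect_equal(flatten_efd(efa(dup, 4)), flatten_efd(efa(xy, 4)),
               tolerance = 1e-12)
  tiny <- matrix(c(0, 0, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  expect_error(efa(tiny, 4), "8 distinct")
})

test_that("normalization is invariant to rotation, scale and starting point", {
  for (seed in 1:8) {
    xy <- random_smooth_shape(seed)
    n <- nrow(xy)
    ref <- flatten_efd(efd_normalize(efa(xy, 10)))
    th <- 0.64713
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    xy2 <- (2.5 * xy %*% R)[c(77:n, 1:76), ]
    v2 <- flatten_efd(efd_normalize(efa(xy2, 10)))
    expect_equal(v2, ref, tolerance = 1e-6)
  }
})

test_that("normalized first harmonic is standardized; reflection is kept", {
  xy <- random_smooth_shape(3)
  en <- efd_normalize(efa(xy, 10))
  expect_equal(en$an[1], 1, tolerance = 1e-9)
  expect_equal(en$bn[1], 0, tolerance = 1e-9)
  expect_equal(en$cn[1], 0, tolerance = 1e-9)
  # mirror image: re-orient to keep positive shoelace area, then compare
  mir <- cbind(-xy[, 1], xy[, 2])
  mir <- mir[rev(seq_len(nrow(mir))), ]
  vm <- flatten_efd(efd_normalize(efa(mir, 10)))
  expect_gt(max(abs(vm - flatten_efd(en))), 1e-3)
})

test_that("degenerate first harmonic errors out", {
  e <- efa(random_smooth_shape(1), 4)
  e$an[1] <- e$bn[1] <- e$cn[1] <- e$dn[1] <- 0
  expect_error(efd_normalize(e), "degenerate")
})

test_that("reconstruction error is small and nonincreasing in harmonics", {
  xy <- random_smooth_shape(21)
  e <- efa(xy, 20)
  rec <- efd_reconstruct(e, 512)
  # mean distance from reconstructed points to the original polygon
  seg_dist <- function(p, a, b) {
    ab <- b - a
    tt <- pmin(1, pmax(0, sum((p - a) * ab) / sum(ab^2)))
    sqrt(sum((a + tt * ab - p)^2))
  }
  closed <- rbind(xy, xy[1, ])
  d <- vapply(seq_len(nrow(rec)), function(i)
    min(vapply(seq_len(nrow(xy)), function(j)
      seg_dist(rec[i, ], closed[j, ], closed[j + 1, ]), numeric(1))),
    numeric(1))
  expect_lt(mean(d), 0.01)   # shape has unit-order radius

  # truncation error vs the 20-harmonic curve at common parameter values is
  # nonincreasing in harmonics (tail energy of the Fourier series)
  ref <- efd_reconstruct(e, 256)
  rms <- vapply(c(1, 2, 4, 8, 16), function(h) {
    eh <- e
    keep <- seq_len(h)
    eh$an <- e$an[keep]; eh$bn <- e$bn[keep]
    eh$cn <- e$cn[keep]; eh$dn <- e$dn[keep]
    eh$n_harmonics <- h
    sqrt(mean((efd_reconstruct(eh, 256) - ref)^2))
  }, numeric(1))
  expect_true(all(diff(rms) <= 1e-9))
})

test_that("one-harmonic reconstruction is an ellipse", {
  e <- efa(random_smooth_shape(5), 1)
  pts <- efd_reconstruct(e, 128)
  # algebraic check: centered points satisfy a quadratic form with unit RHS
  pc <- sweep(pts, 2, c(e$A0, e$C0))
  M <- cbind(pc[, 1]^2, pc[, 1] * pc[, 2], pc[, 2]^2)
  coefs <- qr.solve(M, rep(1, nrow(M)))
  expect_lt(max(abs(M %*% coefs - 1)), 1e-8)
})

test_that("outline measures: squares, rotated rectangles, isoperimetry", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  m <- outline_measures(sq)
  expect_equal(m$area, 1)
  expect_equal(m$perimeter, 4)
  expect_equal(m$length, 1, tolerance = 1e-9)
  expect_equal(m$width, 1, tolerance = 1e-9)

  # 4 x 2 rectangle rotated 30 degrees, sampled densely along the sides
  s <- seq(0, 1, length.out = 50)[-50]
  side <- function(p, q) cbind(p[1] + s * (q[1] - p[1]), p[2] + s * (q[2] - p[2]))
  rect <- rbind(side(c(0, 0), c(4, 0)), side(c(4, 0), c(4, 2)),
                side(c(4, 2), c(0, 2)), side(c(0, 2), c(0, 0)))
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mr <- outline_measures(rect %*% R)
  expect_equal(mr$length, 4, tolerance = 0.04)
  expect_equal(mr$width, 2, tolerance = 0.02)

  for (seed in 1:5) {
    mm <- outline_measures(random_smooth_shape(seed))
    expect_gte(mm$perimeter^2, 4 * pi * mm$area - 1e-9)
  }
})

test_that("morphospace behaves on degenerate, separated and full-rank input", {
  base <- efd_normalize(efa(random_smooth_shape(2), 8))
  same <- morphospace(list(base, base, base, base), k = 3)
  expect_lt(max(abs(same$scores)), 1e-10)

  # two families differing in one underlying shape feature
  fam <- lapply(1:12, function(i) {
    r <- 1 + 0.25 * (i > 6)
    t <- seq(0, 2 * pi, length.out = 129)[-129]
    xy <- cbind((1 + 0.2 * r * cos(3 * t)) * cos(t),
                (1 + 0.2 * r * cos(3 * t)) * sin(t))
    efd_normalize(efa(xy, 8))
  })
  ms <- morphospace(fam, k = 4)
  g1 <- ms$scores[1:6, 1]; g2 <- ms$scores[7:12, 1]
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))
  expect_true(all(diff(ms$explained) <= 1e-12))
  expect_lte(sum(ms$explained), 1 + 1e-9)
  expect_lt(max(abs(colMeans(ms$scores))), 1e-8)

  # full-rank scores reproduce pairwise coefficient distances
  efds <- lapply(1:6, function(i) efd_normalize(efa(random_smooth_shape(i), 5)))
  msf <- morphospace(efds, k = 20)
  X <- do.call(rbind, lapply(efds, flatten_efd))
  expect_equal(as.matrix(dist(msf$scores)), as.matrix(dist(X)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("morphospace rejects too-few or unnormalized input", {
  e <- efd_normalize(efa(random_smooth_shape(1), 6))
  expect_error(morphospace(list(e, e), k = 2), "at least 3")
  raw <- efa(random_smooth_shape(1), 6)
  expect_error(morphospace(list(raw, raw, raw), k = 2), "normalized")
})
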