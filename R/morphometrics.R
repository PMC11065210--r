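#' Elliptical Fourier analysis of a closed outline
#'
#' Decomposes a closed outline into elliptical Fourier harmonics in the
#' Kuhl-Giardina convention: for arc-length parameter `t` over one traversal
#' of the contour, `x(t) = A0 + sum_n a_n cos(2 pi n t / T) + b_n sin(...)`
#' and likewise `y(t)` with coefficients `c_n`, `d_n`. Coefficients are
#' computed exactly for the piecewise-linear contour (closed-form segment
#' integrals), not by sampling.
#'
#' @param outline A two-column matrix of (x, y) outline points, ordered along
#'   the contour; the polygon is closed implicitly (do not repeat the first
#'   point). Repeated consecutive points are dropped.
#' @param n_harmonics Number of harmonics to compute (>= 1).
#' @return An object of class `efd`: list with `an`, `bn`, `cn`, `dn`
#'   (length `n_harmonics`), `A0`, `C0`, `n_harmonics`, `normalized`.
#' @seealso [efd_normalize()], [efd_reconstruct()], [morphospace()]
#' @export
efa <- function(outline, n_harmonics = 20) {
  stopifnot(n_harmonics >= 1)
  xy <- as_outline_matrix(outline)
  # drop zero-length segments (repeated consecutive points, incl. wraparound)
  keep <- c(TRUE, rowSums(abs(diff(xy)))[seq_len(nrow(xy) - 1)] > 0)
  xy <- xy[keep, , drop = FALSE]
  if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 8) stop("outline has fewer than 8 distinct points after cleaning")

  p <- rbind(xy, xy[1, , drop = FALSE])
  dxy <- diff(p)
  dt <- sqrt(rowSums(dxy^2))
  tt <- c(0, cumsum(dt))
  Tt <- tt[length(tt)]
  phi <- 2 * pi * tt / Tt                  # parameter angle at segment ends
  n <- seq_len(n_harmonics)

  # outer(segment, harmonic) increments of cos/sin at segment endpoints
  dcos <- cos(outer(phi[-1], n)) - cos(outer(phi[-length(phi)], n))
  dsin <- sin(outer(phi[-1], n)) - sin(outer(phi[-length(phi)], n))
  fac <- Tt / (2 * pi^2 * n^2)
  vx <- dxy[, 1] / dt
  vy <- dxy[, 2] / dt
  an <- fac * colSums(vx * dcos)
  bn <- fac * colSums(vx * dsin)
  cn <- fac * colSums(vy * dcos)
  dn <- fac * colSums(vy * dsin)

  # offsets: x is piecewise linear in t, so the integral is the trapezoid sum
  A0 <- sum(dt * (p[-1, 1] + p[-nrow(p), 1]) / 2) / Tt
  C0 <- sum(dt * (p[-1, 2] + p[-nrow(p), 2]) / 2) / Tt

  structure(list(an = an, bn = bn, cn = cn, dn = dn, A0 = A0, C0 = C0,
                 n_harmonics = n_harmonics, normalized = FALSE),
            class = "efd")
}

#' Normalize elliptical Fourier coefficients
#'
#' Standardizes size, in-plane rotation and starting-point phase using the
#' first-harmonic ellipse: the parameter origin is moved to the semi-major
#' axis, the shape is rotated so the semi-major axis lies along +x, and all
#' coefficients are divided by the semi-major magnitude. After normalization
#' `a1 = 1` and `b1 = c1 = 0` (to rounding), and the offset is dropped.
#' Reflection is deliberately not removed: mirror-image outlines (e.g.
#' left/right leaflet chirality) keep distinct coefficient vectors.
#'
#' The half-period ambiguity of the phase is resolved deterministically by
#' comparing the two candidate coefficient vectors and keeping the
#' lexicographically larger, which is invariant to the input's rotation,
#' scale and starting point.
#'
#' @param efd An unnormalized `efd` object from [efa()].
#' @return A normalized `efd` object (`normalized = TRUE`, `A0 = C0 = 0`).
#' @export
efd_normalize <- function(efd) {
  stopifnot(inherits(efd, "efd"))
  if (isTRUE(efd$normalized)) return(efd)
  a1 <- efd$an[1]; b1 <- efd$bn[1]; c1 <- efd$cn[1]; d1 <- efd$dn[1]
  if (sqrt(a1^2 + b1^2 + c1^2 + d1^2) < 1e-12)
    stop("degenerate first harmonic; cannot normalize")

  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  # ensure theta points at the semi-MAJOR axis of the first-harmonic ellipse
  mag2 <- function(th) {
    (a1 * cos(th) + b1 * sin(th))^2 + (c1 * cos(th) + d1 * sin(th))^2
  }
  if (mag2(theta) < mag2(theta + pi / 2)) theta <- theta + pi / 2

  cand <- lapply(c(theta, theta + pi), function(th) apply_phase_rotation(efd, th))
  v1 <- flatten_efd(cand[[1]]); v2 <- flatten_efd(cand[[2]])
  dif <- which(abs(v1 - v2) > 1e-9)
  pick <- if (length(dif) == 0 || v1[dif[1]] >= v2[dif[1]]) 1L else 2L
  cand[[pick]]
}

# shift the parameter origin by theta, rotate space onto the semi-major axis
# and rescale; returns a fully normalized efd
apply_phase_rotation <- function(efd, theta) {
  n <- seq_len(efd$n_harmonics)
  cn_ <- cos(n * theta); sn_ <- sin(n * theta)
  an <- efd$an * cn_ + efd$bn * sn_
  bn <- -efd$an * sn_ + efd$bn * cn_
  cn <- efd$cn * cn_ + efd$dn * sn_
  dn <- -efd$cn * sn_ + efd$dn * cn_
  psi <- atan2(cn[1], an[1])
  E <- sqrt(an[1]^2 + cn[1]^2)
  an2 <- (cos(psi) * an + sin(psi) * cn) / E
  cn2 <- (-sin(psi) * an + cos(psi) * cn) / E
  bn2 <- (cos(psi) * bn + sin(psi) * dn) / E
  dn2 <- (-sin(psi) * bn + cos(psi) * dn) / E
  structure(list(an = an2, bn = bn2, cn = cn2, dn = dn2, A0 = 0, C0 = 0,
                 n_harmonics = efd$n_harmonics, normalized = TRUE),
            class = "efd")
}

#' Flatten an efd object into a plain coefficient vector
#'
#' Order is a1..aN, b1..bN, c1..cN, d1..dN.
#' @param efd An `efd` object.
#' @return Numeric vector of length `4 * n_harmonics`.
#' @export
flatten_efd <- function(efd) {
  c(efd$an, efd$bn, efd$cn, efd$dn)
}

#' Reconstruct an outline from elliptical Fourier coefficients
#'
#' Evaluates the finite harmonic series at uniform parameter steps.
#'
#' @param efd An `efd` object.
#' @param n_points Number of points to evaluate (>= 16).
#' @return A two-column (x, y) matrix; the polygon closes implicitly.
#' @export
efd_reconstruct <- function(efd, n_points = 256) {
  stopifnot(inherits(efd, "efd"), n_points >= 16)
  t <- seq(0, 2 * pi, length.out = n_points + 1)[seq_len(n_points)]
  n <- seq_len(efd$n_harmonics)
  ct <- cos(outer(t, n)); st <- sin(outer(t, n))
  x <- efd$A0 + ct %*% efd$an + st %*% efd$bn
  y <- efd$C0 + ct %*% efd$cn + st %*% efd$dn
  cbind(x = as.numeric(x), y = as.numeric(y))
}

#' Classical morphometric measures of an outline
#'
#' Area by the shoelace formula, perimeter by segment sum, and length/width
#' as the extents of the outline points along and across the first principal
#' axis of the point cloud.
#'
#' @param outline A two-column (x, y) matrix (closed implicitly).
#' @return A list with `length`, `width`, `area`, `perimeter`.
#' @export
outline_measures <- function(outline) {
  xy <- as_outline_matrix(outline)
  area <- abs(shoelace_area(xy))
  p <- rbind(xy, xy[1, , drop = FALSE])
  perimeter <- sum(sqrt(rowSums(diff(p)^2)))
  ev <- eigen(stats::cov(xy), symmetric = TRUE)$vectors
  proj <- xy %*% ev
  ext <- apply(proj, 2, function(v) diff(range(v)))
  list(length = max(ext), width = min(ext), area = area, perimeter = perimeter)
}

#' Morphospace: PCA over normalized elliptical Fourier coefficients
#'
#' Flattens each normalized coefficient set into a vector and performs a
#' centered PCA. Component signs are fixed deterministically (the
#' largest-magnitude loading of each component is made positive) so
#' descriptor tables reproduce across runs. Components are named
#' `PC1<suffix>`, `PC2<suffix>`, ... matching the organ-tagged descriptor
#' convention (suffix "S" for seed, "L" for leaf, "P" for pod).
#'
#' @param efds List of normalized `efd` objects with equal `n_harmonics`.
#' @param k Maximum number of components to retain (default 10).
#' @param organ_suffix Suffix appended to component names (e.g. `"S"`).
#' @return A list of class `morphospace`: `scores` (outlines x components),
#'   `loadings`, `explained` (variance fractions), `center`.
#' @export
morphospace <- function(efds, k = 10, organ_suffix = "") {
  if (length(efds) < 3) stop("morphospace needs at least 3 outlines")
  if (!all(vapply(efds, function(e) inherits(e, "efd") && isTRUE(e$normalized), logical(1))))
    stop("all efds must be normalized (see efd_normalize)")
  nh <- unique(vapply(efds, function(e) e$n_harmonics, numeric(1)))
  if (length(nh) != 1) stop("all efds must share n_harmonics")

  X <- do.call(rbind, lapply(efds, flatten_efd))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  rank <- sum(pc$sdev > 1e-10)
  r <- max(1L, min(k, rank, ncol(pc$x)))
  scores <- pc$x[, seq_len(r), drop = FALSE]
  loadings <- pc$rotation[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  nm <- paste0("PC", seq_len(r), organ_suffix)
  colnames(scores) <- nm
  colnames(loadings) <- nm
  explained <- if (tot > 0) pc$sdev[seq_len(r)]^2 / tot else rep(0, r)
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, center = pc$center),
            class = "morphospace")
}

# ---- internal geometry helpers ----

as_outline_matrix <- function(outline) {
  xy <- as.matrix(outline)
  if (ncol(xy) != 2) stop("outline must have two columns (x, y)")
  storage.mode(xy) <- "double"
  if (anyNA(xy) || any(!is.finite(xy))) stop("outline contains non-finite points")
  xy
}

# signed area; positive for counterclockwise orientation in a y-up frame
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# TRUE if the closed polygon has no self-intersection between non-adjacent edges
is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  p <- rbind(xy, xy[1, , drop = FALSE])
  a <- p[-nrow(p), , drop = FALSE]
  b <- p[-1, , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    if (i == 1) j <- j[j != n]           # edge n is adjacent to edge 1
    if (length(j) == 0) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
    d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}
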