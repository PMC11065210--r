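#' Gower distance over a mixed-type descriptor matrix
#'
#' Per-descriptor dissimilarities: numeric, absolute difference divided by
#' the column range; ordinal, Podani rank treatment (ranks with ties
#' correction, normalized by the tie-corrected rank range); nominal, 0/1
#' mismatch. Per-pair distance is the mean over descriptors where both
#' values are present. Zero-range numeric descriptors are dropped with a
#' warning. Values lie in \[0, 1\].
#'
#' @param dm A `descriptor_matrix` (one row per accession).
#' @return Symmetric distance matrix with zero diagonal, labelled by
#'   accession.
#' @export
gower_dist <- function(dm) {
  n <- nrow(dm$data)
  if (n < 2) stop("need at least 2 accessions")
  D <- matrix(0, n, n)
  W <- matrix(0, n, n)               # descriptors contributing per pair
  for (j in seq_len(ncol(dm$data))) {
    col <- dm$data[[j]]
    dcl <- dm$meta$dclass[j]
    if (dcl == "numeric") {
      rng <- diff(range(col, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) {
        warning("zero-range numeric descriptor dropped: ", dm$meta$name[j])
        next
      }
      dj <- abs(outer(col, col, `-`)) / rng
    } else if (dcl == "ordinal") {
      r <- rank(match(col, dm$levels[[dm$meta$name[j]]]),
                na.last = "keep")     # ties -> midranks (Podani)
      tie <- table(r)
      t_of <- function(x) as.numeric(tie[as.character(x)])
      rmin <- min(r, na.rm = TRUE); rmax <- max(r, na.rm = TRUE)
      denom <- rmax - rmin - (t_of(rmax) - 1) / 2 - (t_of(rmin) - 1) / 2
      raw <- abs(outer(r, r, `-`)) -
        (outer(t_of(r), t_of(r), `+`) - 2) / 2
      dj <- if (denom <= 0) matrix(0, n, n) else pmax(raw, 0) / denom
      dj[outer(r, r, `==`)] <- 0
    } else {
      dj <- 1 * outer(col, col, `!=`)
    }
    ok <- !is.na(dj)
    dj[!ok] <- 0
    D <- D + dj
    W <- W + ok
  }
  if (all(W[upper.tri(W)] == 0)) stop("no usable descriptors")
  D <- D / pmax(W, 1)
  diag(D) <- 0
  dimnames(D) <- list(dm$accession, dm$accession)
  D
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling: double-centering of `-D^2 / 2` and
#' eigendecomposition. Axes with eigenvalue above `1e-10` are retained, up
#' to `n_axes`; negative eigenvalues (non-Euclidean distances) are dropped
#' without correction. Axis signs are fixed deterministically (largest-
#' magnitude coordinate positive).
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal.
#' @param n_axes Maximum axes to retain (>= 2, default 4).
#' @return List of class `pcoa`: `coords` (rows x axes, named PCo1...),
#'   `eigenvalues` (all, nonincreasing), `positive` (retained count).
#' @export
pcoa <- function(D, n_axes = 4) {
  if (n_axes < 2) stop("n_axes must be >= 2")
  D <- as.matrix(D)
  stopifnot(isSymmetric(unname(D), tol = 1e-8), all(D >= -1e-12),
            all(abs(diag(D)) < 1e-12))
  n <- nrow(D)
  cs <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1, eig = TRUE))
  eig <- cs$eig
  keep <- min(n_axes, sum(eig > 1e-10))
  if (keep < 1) stop("no positive eigenvalues: degenerate distance matrix")
  coords <- cs$points[, seq_len(keep), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  rownames(coords) <- rownames(D)
  structure(list(coords = coords, eigenvalues = eig, positive = keep),
            class = "pcoa")
}

#' 2-D convex hull of a trait space
#'
#' Convex hull of the accession cloud on a chosen axis pair; its area (by
#' the shoelace formula) summarizes the spread of phenotypic variation and
#' its vertices are the extreme ("vertex") accessions — natural candidates
#' for a core collection. Collinear clouds return area 0 and the extreme
#' pair, with a warning.
#'
#' @param coords Coordinate matrix with accession rownames.
#' @param axes Length-2 integer vector of axis columns (default `c(1, 2)`).
#' @return List: `area`, `vertices` (accession ids in hull order),
#'   `vertex_idx`.
#' @export
hull_2d <- function(coords, axes = c(1, 2)) {
  xy <- coords[, axes, drop = FALSE]
  if (nrow(xy) < 3) stop("need at least 3 points")
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(idx) < 3) {
    warning("all points collinear; hull area is 0")
    proj <- xy[, 1] + xy[, 2] * 0   # chull already returned the extremes
    return(list(area = 0, vertices = rownames(xy)[idx], vertex_idx = idx))
  }
  area <- abs(shoelace_area(xy[idx, , drop = FALSE]))
  if (area < 1e-12) warning("all points collinear; hull area is 0")
  list(area = area, vertices = rownames(xy)[idx], vertex_idx = idx)
}

check_fe_map <- function(coords, fe_map) {
  stopifnot(!is.null(rownames(coords)))
  fe <- fe_map[rownames(coords)]
  if (anyNA(fe)) stop("accession(s) missing from the FE map: ",
                      paste(rownames(coords)[is.na(fe)], collapse = ", "))
  fe
}

#' Functional specialization (FSpe) per functional entity
#'
#' Distance of each accession to the pooled centroid of all accessions;
#' each FE (species) scores the mean over its accessions, normalized by the
#' maximum per-accession distance. Scores lie in \[0, 1\] and an FE holding
#' only the single farthest accession scores exactly 1.
#'
#' @param coords PCoA coordinate matrix (accession rownames).
#' @param fe_map Named vector: accession -> FE (species) label.
#' @return Named numeric vector, one score per FE.
#' @export
fspe <- function(coords, fe_map) {
  if (nrow(coords) < 2) stop("FSpe undefined for a single accession")
  fe <- check_fe_map(coords, fe_map)
  ctr <- colMeans(coords)
  d <- sqrt(rowSums(sweep(coords, 2, ctr)^2))
  if (max(d) == 0) return(stats::setNames(rep(0, length(unique(fe))), unique(fe)))
  s <- tapply(d / max(d), fe, mean)
  stats::setNames(as.numeric(s), names(s))[unique(fe)]
}

#' Functional originality (FOri) per functional entity
#'
#' Default `nearest_entity` variant: per accession, the distance to the
#' nearest accession of a *different* FE; each FE scores the mean over its
#' accessions, normalized by the maximum such distance over all accessions
#' (so the most isolated FE can score exactly 1, and singleton FEs are
#' well-defined). The `intra_mean` variant scores the mean pairwise
#' distance within the FE (normalized by the maximum FE score); it is
#' undefined (NA) for singleton FEs.
#'
#' @param coords PCoA coordinate matrix (accession rownames).
#' @param fe_map Named vector: accession -> FE label.
#' @param variant `"nearest_entity"` (default) or `"intra_mean"`.
#' @return Named numeric vector, one score per FE (NA possible under
#'   `intra_mean`).
#' @export
fori <- function(coords, fe_map, variant = c("nearest_entity", "intra_mean")) {
  variant <- match.arg(variant)
  fe <- check_fe_map(coords, fe_map)
  if (length(unique(fe)) < 2) stop("FOri needs at least 2 FEs")
  D <- as.matrix(stats::dist(coords))
  if (variant == "nearest_entity") {
    dmin <- vapply(seq_len(nrow(D)), function(i) {
      other <- fe != fe[i]
      min(D[i, other])
    }, numeric(1))
    mx <- max(dmin)
    s <- if (mx == 0) tapply(dmin, fe, mean) else tapply(dmin / mx, fe, mean)
    stats::setNames(as.numeric(s), names(s))[unique(fe)]
  } else {
    fes <- unique(fe)
    raw <- vapply(fes, function(f) {
      i <- which(fe == f)
      if (length(i) < 2) return(NA_real_)
      mean(D[i, i][upper.tri(D[i, i])])
    }, numeric(1))
    mx <- max(raw, na.rm = TRUE)
    s <- if (is.finite(mx) && mx > 0) raw / mx else raw
    stats::setNames(s, fes)
  }
}

#' Functional identity (FIde): FE centroid coordinates
#'
#' Per-axis unweighted mean of each FE's accession coordinates (every
#' accession has weight 1).
#'
#' @param coords PCoA coordinate matrix (accession rownames).
#' @param fe_map Named vector: accession -> FE label.
#' @return Matrix FE x axes.
#' @export
fide <- function(coords, fe_map) {
  fe <- check_fe_map(coords, fe_map)
  fes <- unique(fe)
  out <- t(vapply(fes, function(f)
    colMeans(coords[fe == f, , drop = FALSE]), numeric(ncol(coords))))
  rownames(out) <- fes
  colnames(out) <- colnames(coords)
  out
}

#' Per-accession originality (nearest-neighbor distance)
#'
#' Distance of each accession to its nearest other accession, regardless
#' of FE. Near-zero values flag putatively redundant (duplicated)
#' accessions. Prefer passing the full Gower distance matrix: screening in
#' a truncated ordination can spuriously collapse accessions whose
#' differences live on the dropped axes.
#'
#' @param x Either a square symmetric distance matrix (zero diagonal) with
#'   accession dimnames, or a PCoA coordinate matrix (accession rownames).
#' @return Named numeric vector.
#' @export
accession_originality <- function(x) {
  x <- as.matrix(x)
  is_dist <- nrow(x) == ncol(x) && all(abs(diag(x)) < 1e-12) &&
    isSymmetric(unname(x), tol = 1e-8)
  D <- if (is_dist) x else as.matrix(stats::dist(x))
  diag(D) <- Inf
  apply(D, 1, min)
}

#' Functional-diversity report across descriptor types
#'
#' For each descriptor-type matrix (phenomic, classical, combined):
#' Gower distances, PCoA trait space (default 4-axis cap), 2-D convex hull
#' on the first two axes, and per-FE FSpe/FOri/FIde. Accession sets are
#' intersected across types (with a warning) if they differ. The index
#' table mirrors the field's usual layout: FE rows, FSpe and FOri columns
#' per descriptor type, plus per-FE accession counts.
#'
#' @param matrices Named list of `descriptor_matrix` objects, e.g.
#'   `list(Phe = ..., Cla = ..., Com = ...)`, one row per accession.
#' @param fe_map Named vector: accession -> FE label.
#' @param n_axes PCoA axis cap (default 4).
#' @param fori_variant Passed to [fori()].
#' @return List of class `fd_report`: `index_table` (data.frame),
#'   `spaces` (per type: `pcoa`, `hull`, `fide`), `summary` (area and
#'   vertex-count comparison).
#' @export
fd_report <- function(matrices, fe_map, n_axes = 4,
                      fori_variant = "nearest_entity") {
  stopifnot(length(matrices) >= 1, !is.null(names(matrices)))
  accs <- Reduce(intersect, lapply(matrices, `[[`, "accession"))
  if (any(vapply(matrices, function(m) length(m$accession), 0) > length(accs)))
    warning("accession sets differ across descriptor types; intersecting")
  spaces <- list(); idx <- NULL
  for (ty in names(matrices)) {
    dm <- matrices[[ty]]
    keep <- dm$accession %in% accs
    dm$data <- dm$data[keep, , drop = FALSE]
    dm$accession <- dm$accession[keep]
    dm$species <- dm$species[keep]
    D <- gower_dist(dm)
    pc <- pcoa(D, n_axes = n_axes)
    hl <- hull_2d(pc$coords)
    sp_fspe <- fspe(pc$coords, fe_map)
    sp_fori <- fori(pc$coords, fe_map, variant = fori_variant)
    spaces[[ty]] <- list(dist = D, pcoa = pc, hull = hl,
                         fide = fide(pc$coords, fe_map),
                         fspe = sp_fspe, fori = sp_fori)
    fes <- names(sp_fspe)
    part <- data.frame(FE = fes,
                       n = as.integer(table(fe_map[accs])[fes]),
                       FSpe = as.numeric(sp_fspe),
                       FOri = as.numeric(sp_fori[fes]))
    names(part)[3:4] <- paste0(c("FSpe_", "FOri_"), ty)
    idx <- if (is.null(idx)) part else merge(idx, part, by = c("FE", "n"))
  }
  idx <- idx[order(idx$FE), , drop = FALSE]
  rownames(idx) <- NULL
  summary <- data.frame(
    type = names(matrices),
    hull_area = vapply(spaces, function(s) s$hull$area, numeric(1)),
    n_vertices = vapply(spaces, function(s) length(s$hull$vertices), numeric(1)),
    n_axes = vapply(spaces, function(s) s$pcoa$positive, numeric(1)))
  rownames(summary) <- NULL
  structure(list(index_table = idx, spaces = spaces, summary = summary),
            class = "fd_report")
}
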