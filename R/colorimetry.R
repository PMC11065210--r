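#' RGB color histogram on a fixed regular grid
#'
#' Bins pixels into a `bins_per_channel^3` regular grid over the RGB cube
#' and normalizes counts to proportions. Empty bins are retained with
#' proportion zero so histograms from the same configuration share a grid
#' and are directly comparable (e.g. with [emd()]).
#'
#' @param pixels `N x 3` matrix of RGB values in \[0, 1\].
#' @param bins_per_channel Bins per channel (default 4, i.e. 64 bins).
#' @return A `color_histogram`: list with `centers` (`B x 3` bin centers),
#'   `proportions` (length `B`, sums to 1), `bins_per_channel`.
#' @export
color_histogram <- function(pixels, bins_per_channel = 4) {
  px <- as.matrix(pixels)
  stopifnot(nrow(px) >= 1, ncol(px) == 3, bins_per_channel >= 1)
  B <- as.integer(bins_per_channel)
  ix <- pmin(floor(px * B), B - 1)                # per-channel bin, 0-based
  flat <- ix[, 1] * B^2 + ix[, 2] * B + ix[, 3] + 1
  counts <- tabulate(flat, nbins = B^3)
  g <- (seq_len(B) - 0.5) / B
  centers <- as.matrix(expand.grid(B3 = g, G2 = g, R1 = g))[, 3:1, drop = FALSE]
  colnames(centers) <- c("R", "G", "B")
  structure(list(centers = centers, proportions = counts / sum(counts),
                 bins_per_channel = B),
            class = "color_histogram")
}

#' Earth mover's distance between two color histograms
#'
#' Exact optimal-transport cost between the two bin-proportion vectors with
#' Euclidean RGB distance between bin centers as the ground metric, solved
#' with a transportation simplex (northwest-corner start, Bland's entering
#' rule for guaranteed termination). Symmetric, zero iff the proportions
#' are identical, and a true metric because the ground distance is.
#'
#' @param h1,h2 `color_histogram` objects on the same grid.
#' @return Nonnegative scalar transport cost.
#' @export
emd <- function(h1, h2) {
  stopifnot(inherits(h1, "color_histogram"), inherits(h2, "color_histogram"))
  if (h1$bins_per_channel != h2$bins_per_channel ||
      !isTRUE(all.equal(h1$centers, h2$centers, tolerance = 1e-12)))
    stop("histograms are on different grids")
  s <- h1$proportions; d <- h2$proportions
  is <- which(s > 0); id <- which(d > 0)
  cost <- as.matrix(stats::dist(rbind(h1$centers[is, , drop = FALSE],
                                      h2$centers[id, , drop = FALSE])))
  cost <- cost[seq_along(is), length(is) + seq_along(id), drop = FALSE]
  transport_simplex(s[is], d[id], cost)$cost
}

# Exact solver for the balanced transportation problem min sum(C * X),
# rowSums(X) = supply, colSums(X) = demand. Maintains a spanning-tree basis
# of m + n - 1 cells (zero flows allowed); duals by tree traversal; Bland's
# smallest-index entering rule ensures finite termination under degeneracy.
transport_simplex <- function(supply, demand, cost, tol = 1e-12) {
  m <- length(supply); n <- length(demand)
  stopifnot(nrow(cost) == m, ncol(cost) == n,
            abs(sum(supply) - sum(demand)) < 1e-9)
  if (m == 1 || n == 1) {
    X <- if (m == 1) matrix(demand, 1) else matrix(supply, ncol = 1)
    return(list(cost = sum(cost * X), plan = X))
  }
  # northwest-corner initial basis: exactly m + n - 1 basic cells
  X <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  i <- 1L; j <- 1L
  s <- supply; d <- demand
  repeat {
    q <- min(s[i], d[j])
    X[i, j] <- q; basis[i, j] <- TRUE
    s[i] <- s[i] - q; d[j] <- d[j] - q
    if (i == m && j == n) break
    if (s[i] <= d[j] && i < m) i <- i + 1L else j <- j + 1L
  }

  maxit <- 100000L
  for (it in seq_len(maxit)) {
    uv <- transport_duals(basis, cost)
    red <- cost - outer(uv$u, uv$v, `+`)
    red[basis] <- 0
    neg <- which(red < -tol)
    if (length(neg) == 0) break
    enter <- neg[1]                                   # Bland: smallest index
    ei <- ((enter - 1) %% m) + 1
    ej <- ((enter - 1) %/% m) + 1
    cyc <- transport_cycle(basis, ei, ej)             # cells alternating +,-
    minus <- cyc[seq(2, nrow(cyc), by = 2), , drop = FALSE]
    flows <- X[minus]
    theta <- min(flows)
    leave <- minus[which.min(flows), , drop = FALSE]  # first minimizer
    sgn <- rep(c(1, -1), length.out = nrow(cyc))
    X[cyc] <- X[cyc] + sgn * theta
    basis[ei, ej] <- TRUE
    basis[leave] <- FALSE
    X[leave] <- 0
    if (it == maxit) stop("transport simplex failed to converge")
  }
  list(cost = sum(cost * X), plan = X)
}

# dual variables u (rows), v (cols) from c_ij = u_i + v_j on the basis tree
transport_duals <- function(basis, cost) {
  m <- nrow(basis); n <- ncol(basis)
  u <- rep(NA_real_, m); v <- rep(NA_real_, n)
  u[1] <- 0
  queue <- c(1L)                 # node ids: rows 1..m, cols m+1..m+n
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    if (nd <= m) {
      js <- which(basis[nd, ] & is.na(v))
      v[js] <- cost[nd, js] - u[nd]
      queue <- c(queue, m + js)
    } else {
      j <- nd - m
      is_ <- which(basis[, j] & is.na(u))
      u[is_] <- cost[is_, j] - v[j]
      queue <- c(queue, is_)
    }
  }
  list(u = u, v = v)
}

# unique alternating cycle created by adding cell (ei, ej) to the basis
# tree; returned as a 2-column (i, j) matrix starting at the entering cell,
# alternating +, -, +, - ...
transport_cycle <- function(basis, ei, ej) {
  m <- nrow(basis); n <- ncol(basis)
  # path in the basis tree from row node ei to col node ej (BFS)
  adj <- which(basis, arr.ind = TRUE)
  target <- m + ej
  prev <- rep(NA_integer_, m + n)
  seen <- rep(FALSE, m + n)
  seen[ei] <- TRUE
  queue <- c(ei)
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    if (nd == target) break
    nbr <- if (nd <= m) m + adj[adj[, 1] == nd, 2] else adj[adj[, 2] == nd - m, 1]
    nbr <- nbr[!seen[nbr]]
    seen[nbr] <- TRUE
    prev[nbr] <- nd
    queue <- c(queue, nbr)
  }
  path <- target
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  # path nodes alternate row, col, row, ... from ei to col ej
  cells <- matrix(c(ei, ej), 1, 2)
  for (k in seq_len(length(path) - 1)) {
    a <- path[k]; b <- path[k + 1]
    cell <- if (a <= m) c(a, b - m) else c(b, a - m)
    cells <- rbind(cells, cell)
  }
  unname(cells)
}

#' K-means color clustering of foreground pixels
#'
#' Partitions an organ's pixel pool into `k` colorimetric groups with
#' Lloyd's algorithm, restarted from `n_restarts` k-means++ seedings; the
#' best (lowest within-cluster sum of squares) fit is kept. Centroids are
#' sorted by luminance `(R + G + B) / 3`, descending, before naming, so
#' colorimetric group `i` is comparable across accessions.
#'
#' @param pixels `N x 3` RGB matrix in \[0, 1\], `N >= k`.
#' @param k Number of colorimetric groups (default 10).
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @return A `color_clusters`: list with `centroids` (`k x 3`),
#'   `proportions` (length `k`, sums to 1), `k`, `totss_path` (objective of
#'   each restart's converged fit).
#' @export
kmeans_colors <- function(pixels, k = 10, seed = 1, n_restarts = 10) {
  px <- unname(as.matrix(pixels))
  if (nrow(px) < k) stop("need at least k pixels (N = ", nrow(px), ", k = ", k, ")")
  set.seed(as.integer(seed %% .Machine$integer.max))
  best <- NULL
  objs <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    ctr <- kmeanspp_init(px, k)
    fit <- suppressWarnings(
      stats::kmeans(px, centers = ctr, iter.max = 100, algorithm = "Lloyd"))
    objs[r] <- fit$tot.withinss
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  lum <- rowMeans(best$centers)
  ord <- order(lum, decreasing = TRUE)
  centroids <- best$centers[ord, , drop = FALSE]
  colnames(centroids) <- c("R", "G", "B")
  rownames(centroids) <- NULL
  prop <- as.numeric(table(factor(best$cluster, levels = ord))) / length(best$cluster)
  structure(list(centroids = centroids, proportions = prop, k = k,
                 totss_path = objs),
            class = "color_clusters")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center; duplicates avoided when possible
kmeanspp_init <- function(px, k) {
  n <- nrow(px)
  centers <- matrix(NA_real_, k, ncol(px))
  centers[1, ] <- px[sample.int(n, 1), ]
  d2 <- rowSums((px - matrix(centers[1, ], n, ncol(px), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- px[sample.int(n, 1, prob = p), ]
    d2j <- rowSums((px - matrix(centers[j + 1, ], n, ncol(px), byrow = TRUE))^2)
    d2 <- pmin(d2, d2j)
  }
  # Lloyd in stats::kmeans requires distinct centers
  if (anyDuplicated(centers)) {
    dup <- which(duplicated(centers))
    jit <- matrix(stats::runif(length(dup) * ncol(px), -1e-6, 1e-6), length(dup))
    centers[dup, ] <- pmin(1, pmax(0, centers[dup, , drop = FALSE] + jit))
  }
  centers
}

#' Flatten color clusters into a named phenomic descriptor row
#'
#' Produces the `4k` descriptors `R_i`, `G_i`, `B_i`, `prop_i` for
#' `i = 1..k`, each suffixed by the organ tag ("S" seed, "F" flower, "P"
#' pod), e.g. `R_10S` = red value of seed colorimetric group 10.
#'
#' @param clusters A `color_clusters` object.
#' @param organ Organ suffix letter (e.g. `"S"`).
#' @return Named numeric vector of length `4k`.
#' @export
cluster_descriptors <- function(clusters, organ) {
  stopifnot(inherits(clusters, "color_clusters"))
  k <- clusters$k
  vals <- as.numeric(t(cbind(clusters$centroids, clusters$proportions)))
  nm <- as.vector(vapply(seq_len(k), function(i)
    paste0(c("R_", "G_", "B_", "prop_"), i, organ), character(4)))
  stats::setNames(vals, nm)
}
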