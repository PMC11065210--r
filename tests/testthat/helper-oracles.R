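# Independent oracles used across the test suite. Each one deliberately
# takes a different computational route than the package implementation.

# Elliptical Fourier coefficients by direct numerical projection: resample
# the outline densely by arc length and integrate x(t) * cos/sin with the
# trapezoid rule (the implementation instead uses closed-form segment
# integrals of the derivative).
efa_oracle <- function(outline, n_harmonics, m = 2^14) {
  p <- rbind(outline, outline[1, , drop = FALSE])
  dt <- sqrt(rowSums(diff(p)^2))
  tt <- c(0, cumsum(dt))
  Tt <- tt[length(tt)]
  tg <- seq(0, Tt, length.out = m + 1)
  xg <- stats::approx(tt, p[, 1], xout = tg)$y
  yg <- stats::approx(tt, p[, 2], xout = tg)$y
  trap <- function(f) (sum(f) - (f[1] + f[length(f)]) / 2) * (Tt / m)
  res <- list(an = numeric(n_harmonics), bn = numeric(n_harmonics),
              cn = numeric(n_harmonics), dn = numeric(n_harmonics))
  for (n in seq_len(n_harmonics)) {
    cn_ <- cos(2 * pi * n * tg / Tt); sn_ <- sin(2 * pi * n * tg / Tt)
    res$an[n] <- 2 / Tt * trap(xg * cn_)
    res$bn[n] <- 2 / Tt * trap(xg * sn_)
    res$cn[n] <- 2 / Tt * trap(yg * cn_)
    res$dn[n] <- 2 / Tt * trap(yg * sn_)
  }
  res$A0 <- trap(xg) / Tt
  res$C0 <- trap(yg) / Tt
  res
}

# a smooth random closed shape (positive radius Fourier series in polar form)
random_smooth_shape <- function(seed, n_points = 256) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n_points + 1)[seq_len(n_points)]
  r <- 1
  for (k in 1:4) {
    r <- r + stats::runif(1, 0, 0.12 / k) * cos(k * th + stats::runif(1, 0, 2 * pi))
  }
  cbind(r * cos(th), r * sin(th))
}

# earth mover's distance as an explicit linear program (boot::simplex)
emd_lp_oracle <- function(h1, h2) {
  s <- h1$proportions; d <- h2$proportions
  is <- which(s > 0); id <- which(d > 0)
  m <- length(is); n <- length(id)
  cost <- as.matrix(stats::dist(rbind(h1$centers[is, , drop = FALSE],
                                      h2$centers[id, , drop = FALSE])))
  cost <- cost[seq_len(m), m + seq_len(n), drop = FALSE]
  # variables x_ij in row-major blocks; equality constraints on both margins
  # (one redundant constraint dropped)
  nv <- m * n
  A3 <- matrix(0, m + n - 1, nv)
  b3 <- numeric(m + n - 1)
  for (i in seq_len(m)) {
    A3[i, (i - 1) * n + seq_len(n)] <- 1
    b3[i] <- s[is[i]]
  }
  if (n > 1) {
    for (j in seq_len(n - 1)) {
      A3[m + j, (seq_len(m) - 1) * n + j] <- 1
      b3[m + j] <- d[id[j]]
    }
  }
  fit <- boot::simplex(a = as.numeric(t(cost)), A3 = A3, b3 = b3, maxi = FALSE)
  fit$value
}

# 2-D convex hull vertices by brute force: a point is a vertex iff it is
# not contained in any triangle formed by three other points
hull_vertices_oracle <- function(xy) {
  n <- nrow(xy)
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 >= -1e-12 & s2 >= -1e-12 & s3 >= -1e-12) |
      (s1 <= 1e-12 & s2 <= 1e-12 & s3 <= 1e-12)
  }
  vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    combs <- utils::combn(others, 3)
    for (k in seq_len(ncol(combs))) {
      if (in_triangle(xy[i, ], xy[combs[1, k], ], xy[combs[2, k], ],
                      xy[combs[3, k], ])) return(FALSE)
    }
    TRUE
  }, logical(1))
}

# Gower distance computed cell by cell with scalar loops (Podani ordinal)
gower_oracle <- function(dm) {
  n <- nrow(dm$data)
  ord_info <- list()
  for (j in seq_len(ncol(dm$data))) {
    if (dm$meta$dclass[j] == "ordinal") {
      r <- rank(match(dm$data[[j]], dm$levels[[dm$meta$name[j]]]),
                na.last = "keep")
      tie <- table(r)
      ord_info[[j]] <- list(r = r, tie = tie)
    }
  }
  D <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    num <- 0; den <- 0
    for (j in seq_len(ncol(dm$data))) {
      va <- dm$data[[j]][a]; vb <- dm$data[[j]][b]
      if (is.na(va) || is.na(vb)) next
      dcl <- dm$meta$dclass[j]
      if (dcl == "numeric") {
        rng <- diff(range(dm$data[[j]], na.rm = TRUE))
        if (rng == 0) next
        num <- num + abs(va - vb) / rng
      } else if (dcl == "ordinal") {
        oi <- ord_info[[j]]
        ra <- oi$r[a]; rb <- oi$r[b]
        if (ra == rb) { den <- den + 1; next }
        Ta <- as.numeric(oi$tie[as.character(ra)])
        Tb <- as.numeric(oi$tie[as.character(rb)])
        rmin <- min(oi$r, na.rm = TRUE); rmax <- max(oi$r, na.rm = TRUE)
        Tmin <- as.numeric(oi$tie[as.character(rmin)])
        Tmax <- as.numeric(oi$tie[as.character(rmax)])
        dd <- rmax - rmin - (Tmax - 1) / 2 - (Tmin - 1) / 2
        if (dd > 0)
          num <- num + max(0, (abs(ra - rb) - (Ta - 1) / 2 - (Tb - 1) / 2)) / dd
      } else {
        num <- num + as.numeric(va != vb)
      }
      den <- den + 1
    }
    D[a, b] <- D[b, a] <- if (den > 0) num / den else 0
  }
  dimnames(D) <- list(dm$accession, dm$accession)
  D
}

# small hand-built descriptor matrix with mixed classes
random_mixed_dm <- function(seed, n = 5) {
  set.seed(seed)
  data <- data.frame(
    x1 = stats::rnorm(n),
    x2 = stats::runif(n, 0, 10),
    o1 = sample(c("low", "mid", "high"), n, replace = TRUE),
    n1 = sample(c("red", "blue"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  meta <- data.frame(
    name = c("x1", "x2", "o1", "n1"),
    dclass = c("numeric", "numeric", "ordinal", "nominal"),
    dtype = "classical", organ = NA_character_, stringsAsFactors = FALSE)
  descriptor_matrix(data, meta, accession = paste0("A", seq_len(n)),
                    species = rep("S1", n),
                    levels = list(o1 = c("low", "mid", "high")))
}

# tiny deterministic image: a dark disk on a white background
disk_image <- function(size = 64, r = 20, value = c(0.2, 0.2, 0.2)) {
  img <- array(1, dim = c(size, size, 3))
  ctr <- (size + 1) / 2
  for (row in seq_len(size)) for (col in seq_len(size)) {
    if ((row - ctr)^2 + (col - ctr)^2 <= r^2)
      img[row, col, ] <- value
  }
  img
}

# default small simulated panel shared by several tests
small_panel <- function(seed = 7, n_species = 2, acc = 2, plants = 3,
                        outlier = FALSE, render = FALSE) {
  tpl <- default_templates(n_species, seed = seed, organs = c("seed", "leaf"),
                           outlier = outlier)
  cfg <- simulation_config(tpl, accessions_per_species = acc,
                           plants_per_accession = plants, seed = seed)
  generate_dataset(cfg, render = render)
}
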