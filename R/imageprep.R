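#' Read an RGB image from disk
#'
#' Reads PNG or TIFF into a height x width x 3 array in \[0, 1\]. Grayscale
#' images are expanded to three identical channels; alpha is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array `height x width x 3` in \[0, 1\].
#' @export
read_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required for TIFF input")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Linear white balance against a color reference card
#'
#' Applies per-channel gains `g_c = target_c / observed_c` computed from a
#' neutral card patch, then clips to \[0, 1\]. Standardizes images taken
#' under somewhat different lighting before colorimetry.
#'
#' @param image `h x w x 3` array in \[0, 1\].
#' @param card_patch_means Observed per-channel means of the card patch.
#' @param card_patch_targets Reference per-channel values for that patch.
#' @return Corrected image, same shape, clipped to \[0, 1\].
#' @export
white_balance <- function(image, card_patch_means, card_patch_targets) {
  stopifnot(length(card_patch_means) == 3, length(card_patch_targets) == 3)
  if (any(card_patch_means <= 0.01))
    stop("unusable card: observed channel mean <= 0.01")
  g <- card_patch_targets / card_patch_means
  out <- image
  for (c in 1:3) out[, , c] <- pmin(1, pmax(0, image[, , c] * g[c]))
  out
}

#' Segment the organ from a white background
#'
#' Otsu thresholding on luminance `(R + G + B) / 3` (256-level histogram),
#' with the darker side taken as foreground (white-background convention),
#' followed by hole filling and retention of the largest connected
#' component.
#'
#' @param image `h x w x 3` array in \[0, 1\].
#' @return Logical `h x w` matrix marking the organ.
#' @export
binarize <- function(image) {
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  if (diff(range(lum)) < 1e-9) stop("no foreground: image is uniform")
  thr <- EBImage::otsu(EBImage::Image(lum), range = c(0, 1), levels = 256)
  fg <- lum < thr
  if (!any(fg)) stop("no foreground below the Otsu threshold")
  fg <- EBImage::fillHull(EBImage::Image(fg * 1))
  lab <- EBImage::bwlabel(fg)
  counts <- tabulate(as.integer(EBImage::imageData(lab)))
  biggest <- which.max(counts)
  matrix(as.integer(EBImage::imageData(lab)) == biggest, nrow = nrow(lum))
}

#' Trace the outline of a binary mask
#'
#' Extracts the boundary of the mask's single foreground region as a closed
#' polygon by contouring the mask at the 0.5 level on a zero-padded raster
#' (the "crack" boundary between foreground and background pixels). Pixel
#' centers sit at integer coordinates, x = column and y = row, origin at the
#' top-left. The returned polygon is oriented so its shoelace signed area is
#' positive.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Two-column (x, y) matrix, >= 8 points, closed implicitly.
#' @export
trace_outline <- function(mask) {
  m <- (mask > 0) * 1
  if (sum(m) == 0) stop("mask has no foreground pixels")
  if (any(m[1, ] > 0) || any(m[nrow(m), ] > 0) || any(m[, 1] > 0) || any(m[, ncol(m)] > 0))
    warning("foreground touches the image border; outline is clipped")
  pad <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  # contourLines works on z[x, y]; feed rows as x so x=row first, then swap
  cl <- grDevices::contourLines(x = 0:(nrow(pad) - 1), y = 0:(ncol(pad) - 1),
                                z = pad, levels = 0.5)
  if (length(cl) == 0) stop("no contour found")
  # keep the longest contour (largest component's outer boundary)
  lens <- vapply(cl, function(cc) {
    xy <- cbind(cc$y, cc$x)
    sum(sqrt(rowSums(diff(rbind(xy, xy[1, ]))^2)))
  }, numeric(1))
  best <- cl[[which.max(lens)]]
  xy <- cbind(x = best$y, y = best$x)   # x = column, y = row
  if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 8) stop("outline has fewer than 8 points")
  # positive shoelace orientation
  if (shoelace_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  xy
}

#' Extract foreground RGB pixels under a mask
#'
#' @param image `h x w x 3` array in \[0, 1\].
#' @param mask Logical `h x w` matrix.
#' @return `N x 3` matrix of RGB triples where the mask is TRUE, row-major
#'   (reading order: along rows, then down).
#' @export
foreground_pixels <- function(image, mask) {
  stopifnot(dim(image)[1] == nrow(mask), dim(image)[2] == ncol(mask))
  if (!any(mask)) stop("empty mask")
  # row-major order: transpose so pixels are read along each row in turn
  idx <- which(t(mask))
  px <- cbind(as.numeric(t(image[, , 1]))[idx],
              as.numeric(t(image[, , 2]))[idx],
              as.numeric(t(image[, , 3]))[idx])
  colnames(px) <- c("R", "G", "B")
  px
}

#' Rasterize a closed polygon to a binary mask
#'
#' Even-odd scanline fill: a pixel center (integer x, y) is foreground when
#' a horizontal ray crosses the polygon an odd number of times. Used for
#' outline/mask round-trip checks and synthetic image rendering.
#'
#' @param outline Two-column (x, y) matrix (pixel coordinates, closed
#'   implicitly).
#' @param height,width Raster dimensions in pixels.
#' @return Logical `height x width` matrix.
#' @export
rasterize_outline <- function(outline, height, width) {
  xy <- as_outline_matrix(outline)
  p <- rbind(xy, xy[1, , drop = FALSE])
  mask <- matrix(FALSE, height, width)
  x1 <- p[-nrow(p), 1]; y1 <- p[-nrow(p), 2]
  x2 <- p[-1, 1]; y2 <- p[-1, 2]
  for (row in seq_len(height)) {
    yr <- row
    crosses <- ((y1 <= yr) & (y2 > yr)) | ((y2 <= yr) & (y1 > yr))
    if (!any(crosses)) next
    xs <- x1[crosses] + (yr - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (x2[crosses] - x1[crosses])
    xs <- sort(xs)
    for (i in seq(1, length(xs) - 1, by = 2)) {
      lo <- ceiling(xs[i]); hi <- floor(xs[i + 1])
      if (hi >= lo) {
        lo <- max(1, lo); hi <- min(width, hi)
        if (hi >= lo) mask[row, lo:hi] <- TRUE
      }
    }
  }
  mask
}
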