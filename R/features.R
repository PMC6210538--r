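#' Convert an image to grayscale luminance
#'
#' Color frames are reduced to luminance with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B) before gradient computation.  Grayscale
#' matrices pass through unchanged; an alpha channel, if present, is ignored.
#'
#' @param image A numeric matrix (grayscale) or a rows x cols x channels
#'   array with intensities in `[0, 1]`.
#' @return A numeric matrix of luminance values.
#' @export
as_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L) {
    nch <- dim(image)[3L]
    if (nch == 1L) return(image[, , 1L])
    return(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L])
  }
  stop("image must be a matrix or a rows x cols x channels array")
}

#' Read a PNG video frame
#'
#' @param path Path to a PNG file.
#' @return Grayscale intensity matrix in `[0, 1]`.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("frame not found: ", path)
  as_grayscale(png::readPNG(path))
}

#' Write a grayscale frame to PNG
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @export
write_frame <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
}

#' Construct a HOG level object
#'
#' A single level of a feature pyramid: a rows x cols x bins grid of
#' orientation-histogram cells together with the geometry needed to map cell
#' coordinates back to original-image pixels.
#'
#' @param cells Numeric array, rows x cols x bins.
#' @param cell_size_px Pixels per cell side at this level's resolution.
#' @param scale Level scale relative to the original image (level 0 has
#'   scale 1).
#' @param bins Number of unsigned orientation bins.
#' @param normalize Normalization scheme used (`"cell"`, `"block4"`, `"none"`).
#' @return An object of class `hog_level`.
#' @export
hog_level <- function(cells, cell_size_px, scale = 1, bins = dim(cells)[3L],
                      normalize = "none") {
  stopifnot(is.array(cells), length(dim(cells)) == 3L)
  if (cell_size_px < 1L) stop("cell_size_px must be a positive integer")
  if (scale <= 0) stop("scale must be positive")
  structure(list(cells = cells, cell_size_px = as.integer(cell_size_px),
                 scale = scale, bins = as.integer(bins), normalize = normalize),
            class = "hog_level")
}

#' @export
print.hog_level <- function(x, ...) {
  d <- dim(x$cells)
  cat(sprintf("<hog_level> %d x %d cells, %d bins, cell %d px, scale %.4f\n",
              d[1L], d[2L], d[3L], x$cell_size_px, x$scale))
  invisible(x)
}

# Gradients by central differences with clamped (replicated) borders.
# Orientation is unsigned, folded into [0, pi).
hog_gradients <- function(img, bins) {
  h <- nrow(img); w <- ncol(img)
  xr <- c(pmin(seq_len(w) + 1L, w))
  xl <- c(pmax(seq_len(w) - 1L, 1L))
  yd <- c(pmin(seq_len(h) + 1L, h))
  yu <- c(pmax(seq_len(h) - 1L, 1L))
  gx <- img[, xr, drop = FALSE] - img[, xl, drop = FALSE]
  gy <- img[yd, , drop = FALSE] - img[yu, , drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx) %% pi
  bin <- floor(ori / (pi / bins)) %% bins  # folds ori == pi back to bin 0
  list(mag = mag, bin = bin)
}

#' Normalize raw HOG cell histograms
#'
#' The default `"cell"` scheme divides each cell histogram by its own L2
#' norm, zeroing cells whose gradient energy falls below `tau`; this map is
#' a projection (applying it twice equals applying it once) and keeps every
#' entry in `[0, 1]`.  The `"block4"` alternative normalizes each cell by the
#' energy of every 2 x 2 cell block containing it and averages the results
#' back into the cell (classical block normalization); it is bounded in
#' `[0, 1]` but not idempotent.
#'
#' @param raw Numeric array rows x cols x bins of unnormalized histograms.
#' @param scheme `"cell"`, `"block4"` or `"none"`.
#' @param tau Energy threshold below which a cell is zeroed (`"cell"`) or
#'   the divisor floor (`"block4"`).
#' @return Array of the same shape.
#' @export
hog_normalize <- function(raw, scheme = c("cell", "block4", "none"),
                          tau = 1e-6) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(raw)
  d <- dim(raw)
  if (scheme == "cell") {
    nrm <- sqrt(apply(raw^2, c(1L, 2L), sum))
    div <- ifelse(nrm < tau, Inf, nrm)  # below-threshold cells -> 0
    return(raw / array(rep(div, d[3L]), d))
  }
  # block4: energy of each cell, then 2x2 block norms anchored at (r, c)
  en <- apply(raw^2, c(1L, 2L), sum)
  out <- array(0, d)
  cnt <- matrix(0, d[1L], d[2L])
  acc <- array(0, d)
  for (dr in 0:1) {
    for (dc in 0:1) {
      # block anchored so that the current cell participates with offset (dr, dc)
      r0 <- seq_len(d[1L]) - dr
      c0 <- seq_len(d[2L]) - dc
      ok_r <- r0 >= 1L & r0 + 1L <= d[1L]
      ok_c <- c0 >= 1L & c0 + 1L <= d[2L]
      if (!any(ok_r) || !any(ok_c)) next
      rr <- which(ok_r); cc <- which(ok_c)
      bn <- sqrt(en[r0[rr], c0[cc], drop = FALSE] +
                 en[r0[rr] + 1L, c0[cc], drop = FALSE] +
                 en[r0[rr], c0[cc] + 1L, drop = FALSE] +
                 en[r0[rr] + 1L, c0[cc] + 1L, drop = FALSE])
      bn <- pmax(bn, tau)
      acc[rr, cc, ] <- acc[rr, cc, , drop = FALSE] +
        raw[rr, cc, , drop = FALSE] / array(rep(bn, d[3L]), c(length(rr), length(cc), d[3L]))
      cnt[rr, cc] <- cnt[rr, cc] + 1
    }
  }
  cnt[cnt == 0] <- 1
  out <- acc / array(rep(cnt, d[3L]), d)
  out
}

#' Compute a HOG feature map for one image
#'
#' Gradients are taken by central differences (replicated borders) on the
#' luminance image; each pixel votes its full gradient magnitude into the
#' unsigned orientation bin containing its gradient direction, and votes are
#' accumulated over non-overlapping square cells.  Pixels beyond the last
#' complete cell row/column are ignored.
#'
#' @param image Grayscale matrix or color array, finite intensities.
#' @param cell_size_px Cell side in pixels (default 8).
#' @param bins Number of unsigned orientation bins (default 9).
#' @param normalize Normalization scheme, see [hog_normalize()].
#' @return A [hog_level()] at scale 1.
#' @export
compute_hog <- function(image, cell_size_px = 8L, bins = 9L,
                        normalize = c("cell", "block4", "none")) {
  normalize <- match.arg(normalize)
  img <- as_grayscale(image)
  cs <- as.integer(cell_size_px)
  if (cs < 1L) stop("cell_size_px must be a positive integer")
  if (bins < 1L) stop("bins must be a positive integer")
  if (nrow(img) < cs || ncol(img) < cs)
    stop(sprintf("image (%d x %d) smaller than one %d px cell",
                 nrow(img), ncol(img), cs))
  if (!all(is.finite(img))) stop("image intensities must be finite")
  g <- hog_gradients(img, bins)
  rows <- nrow(img) %/% cs
  cols <- ncol(img) %/% cs
  h <- rows * cs; w <- cols * cs
  mag <- g$mag[seq_len(h), seq_len(w), drop = FALSE]
  bin <- g$bin[seq_len(h), seq_len(w), drop = FALSE]
  cr <- (row(mag) - 1L) %/% cs          # 0-based cell row
  cc <- (col(mag) - 1L) %/% cs          # 0-based cell col
  idx <- cr + rows * cc + rows * cols * bin + 1
  raw <- numeric(rows * cols * bins)
  acc <- rowsum(as.vector(mag), group = as.vector(idx))
  raw[as.integer(rownames(acc))] <- acc[, 1L]
  raw <- array(raw, c(rows, cols, bins))
  hog_level(hog_normalize(raw, normalize), cs, scale = 1, bins = bins,
            normalize = normalize)
}

#' Bilinear image resize
#'
#' @param image Grayscale matrix.
#' @param scale Scale factor (> 0); output dims are `floor(dim * scale)`.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(image, scale) {
  if (scale <= 0) stop("scale must be positive")
  h <- nrow(image); w <- ncol(image)
  nh <- max(1L, floor(h * scale)); nw <- max(1L, floor(w * scale))
  if (nh == h && nw == w && isTRUE(all.equal(scale, 1))) return(image)
  # map output pixel centers back into input coordinates (0-based)
  sy <- ((seq_len(nh) - 0.5) / scale) - 0.5
  sx <- ((seq_len(nw) - 0.5) / scale) - 0.5
  sy <- pmin(pmax(sy, 0), h - 1); sx <- pmin(pmax(sx, 0), w - 1)
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- sy - y0; fx <- sx - x0
  A <- image[y0 + 1, x0 + 1, drop = FALSE]
  B <- image[y0 + 1, x1 + 1, drop = FALSE]
  C <- image[y1 + 1, x0 + 1, drop = FALSE]
  D <- image[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, nh, nw); wx <- matrix(fx, nh, nw, byrow = TRUE)
  A * (1 - wy) * (1 - wx) + B * (1 - wy) * wx + C * wy * (1 - wx) + D * wy * wx
}

#' Build a multi-scale HOG pyramid
#'
#' Level `k` is computed on the image resized by `2^(-k / interval)`; levels
#' are added while both resized sides stay at or above `min_level_px`.
#' Level 0 is identical to [compute_hog()] on the original image.
#'
#' @inheritParams compute_hog
#' @param interval Number of pyramid levels per octave (default 2).
#' @param min_level_px Minimum image side, in pixels, for a level to be kept.
#' @param max_scale Scale of the finest level (default 1; values above 1
#'   prepend an upsampled bottom octave so small subjects are detected on a
#'   finer placement grid).
#' @return An object of class `hog_pyramid`: a list with `levels` (ordered,
#'   scales strictly decreasing) and the feature settings.  With the default
#'   `max_scale = 1` level 0 is identical to [compute_hog()] on the original
#'   image.
#' @export
build_pyramid <- function(image, cell_size_px = 8L, bins = 9L, interval = 2L,
                          min_level_px = 40L,
                          normalize = c("cell", "block4", "none"),
                          max_scale = 1) {
  normalize <- match.arg(normalize)
  if (interval < 1L) stop("interval must be a positive integer")
  if (max_scale <= 0) stop("max_scale must be positive")
  img <- as_grayscale(image)
  if (min(dim(img)) < min_level_px)
    stop("image smaller than min_level_px in at least one dimension")
  levels <- list()
  k <- 0L
  repeat {
    s <- max_scale * 2^(-k / interval)
    if (floor(min(dim(img)) * s) < min_level_px && k > 0L) break
    scaled <- if (abs(s - 1) < 1e-12) img else resize_bilinear(img, s)
    if (min(dim(scaled)) < cell_size_px) break
    lev <- compute_hog(scaled, cell_size_px, bins, normalize)
    lev$scale <- s
    levels[[k + 1L]] <- lev
    k <- k + 1L
  }
  structure(list(levels = levels, interval = as.integer(interval),
                 cell_size_px = as.integer(cell_size_px), bins = as.integer(bins),
                 normalize = normalize, image_dim = dim(img)),
            class = "hog_pyramid")
}

#' @export
print.hog_pyramid <- function(x, ...) {
  cat(sprintf("<hog_pyramid> %d levels, interval %d, cell %d px\n",
              length(x$levels), x$interval, x$cell_size_px))
  invisible(x)
}

#' Map a part placement to its original-image joint estimate
#'
#' The joint estimate is the center of the detected `patch_cells` x
#' `patch_cells` cell patch, expressed in 0-based pixel coordinates of the
#' original image.
#'
#' @param l Cell coordinate `c(x, y)` (0-based, x = column) at a level.
#' @param cell_size_px,scale Level geometry.
#' @param patch_cells Patch side in cells (part templates use 5).
#' @return Pixel coordinate `c(x, y)`.
#' @export
cell_center_px <- function(l, cell_size_px, scale = 1, patch_cells = 5L) {
  (l + patch_cells / 2) * cell_size_px / scale - 0.5
}

#' Map an original-image pixel coordinate to the nearest patch anchor cell
#'
#' Inverse of [cell_center_px()] up to rounding: the returned anchor cell is
#' the one whose patch center lies closest to the pixel.
#'
#' @param px Pixel coordinate `c(x, y)` (0-based) in the original image.
#' @inheritParams cell_center_px
#' @return Integer cell coordinate `c(x, y)` (0-based, unclamped).
#' @export
px_to_cell <- function(px, cell_size_px, scale = 1, patch_cells = 5L) {
  as.integer(round((px + 0.5) * scale / cell_size_px - patch_cells / 2))
}
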