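#' Image grid container
#'
#' An `image_grid` is the unit every stage of the pipeline consumes: a 2-D
#' raster of non-negative intensities together with its physical scale
#' (micrometres per pixel) and the direction of electrophoretic migration.
#' Comet tails extend along the migration axis; internally all analysis is
#' performed with migration pointing toward increasing column index
#' (direction `"right"`), and [normalize_migration()] re-orients any other
#' declared direction.
#'
#' @param pixels Numeric matrix of intensities, all finite and `>= 0`.
#'   Rows index the vertical image coordinate, columns the horizontal one.
#' @param scale Physical scale in micrometres per pixel (`> 0`). Defaults to
#'   1 um/px, the acquisition resolution of single-focal-plane well imaging
#'   this package targets.
#' @param migration One of `"right"`, `"left"`, `"up"`, `"down"`: the
#'   direction DNA migrates (the direction tails point).
#'
#' @return An object of class `image_grid`: a list with elements `pixels`,
#'   `scale` and `migration`.
#' @examples
#' g <- image_grid(matrix(0, 32, 32))
#' dim(g$pixels)
#' @export
image_grid <- function(pixels, scale = 1, migration = "right") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (length(pixels) == 0L) stop("image_grid: empty pixel raster")
  if (!all(is.finite(pixels))) stop("image_grid: intensities must be finite")
  if (any(pixels < 0)) stop("image_grid: intensities must be >= 0")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("image_grid: scale must be a single positive number (um/px)")
  migration <- match.arg(migration, c("right", "left", "up", "down"))
  structure(list(pixels = pixels, scale = scale, migration = migration),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px, %.3g um/px, migration %s\n",
              nrow(x$pixels), ncol(x$pixels), x$scale, x$migration))
  cat(sprintf("  intensity range [%.4g, %.4g], total %.6g\n",
              min(x$pixels), max(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Re-orient an image so migration points toward increasing columns
#'
#' All detection and quantification code assumes tails extend to the right.
#' This rotates/flips the raster so the declared migration direction becomes
#' `"right"`; the physical scale is unchanged.
#'
#' @param grid An [image_grid()].
#' @return An `image_grid` with `migration == "right"`.
#' @export
normalize_migration <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  p <- grid$pixels
  p <- switch(grid$migration,
    right = p,
    left  = p[, rev(seq_len(ncol(p))), drop = FALSE],
    down  = t(p),                                   # tails downward -> rightward
    up    = t(p)[, rev(seq_len(nrow(p))), drop = FALSE]
  )
  image_grid(p, scale = grid$scale, migration = "right")
}

#' Read a grayscale TIFF or PNG as an image grid
#'
#' 8- and 16-bit integer images are read at their native integer levels
#' (0..255 or 0..65535); multi-channel images are averaged to one channel.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @inheritParams image_grid
#' @return An [image_grid()].
#' @export
read_image_grid <- function(path, scale = 1, migration = "right") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    a <- png::readPNG(path)
    # png::readPNG always rescales to [0,1]; restore integer levels
    a <- a * 65535
    if (max(a) <= 255 * 257 && all(abs(a / 257 - round(a / 257)) < 1e-6)) a <- a / 257
  } else {
    stop("read_image_grid: unsupported extension '", ext, "' (use TIFF or PNG)")
  }
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
  image_grid(a, scale = scale, migration = migration)
}

#' Write an image grid as a grayscale 16-bit TIFF
#'
#' @param grid An [image_grid()].
#' @param path Output path ending in `.tif`/`.tiff`.
#' @param max_level Intensity ceiling mapped to full scale (default 65535,
#'   i.e. intensities are written as 16-bit levels verbatim).
#' @return `path`, invisibly.
#' @export
write_image_grid <- function(grid, path, max_level = 65535) {
  stopifnot(inherits(grid, "image_grid"))
  m <- pmin(pmax(grid$pixels / max_level, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

# ---- windowed statistics -----------------------------------------------
# Exact clipped-window sums via summed-area tables. The scanning window for
# the pixel at (i, j) covers rows [i - floor(h/2), i + floor(h/2)] and
# columns [j - floor(w/2), j + floor(w/2)], intersected with the image; even
# window dimensions therefore behave as the next odd size (a window must be
# centred on its pixel).

integral_image <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))  # s[i+1, j+1] = sum m[1..i, 1..j]
}

window_sum <- function(m, h, w) {
  nr <- nrow(m); nc <- ncol(m)
  hr <- h %/% 2L; hc <- w %/% 2L
  s <- integral_image(m)
  r1 <- pmax(seq_len(nr) - hr, 1L); r2 <- pmin(seq_len(nr) + hr, nr)
  c1 <- pmax(seq_len(nc) - hc, 1L); c2 <- pmin(seq_len(nc) + hc, nc)
  s[r2 + 1L, c2 + 1L, drop = FALSE] - s[r1, c2 + 1L, drop = FALSE] -
    s[r2 + 1L, c1, drop = FALSE] + s[r1, c1, drop = FALSE]
}

window_count <- function(nr, nc, h, w) {
  hr <- h %/% 2L; hc <- w %/% 2L
  rext <- pmin(seq_len(nr) + hr, nr) - pmax(seq_len(nr) - hr, 1L) + 1L
  cext <- pmin(seq_len(nc) + hc, nc) - pmax(seq_len(nc) - hc, 1L) + 1L
  outer(rext, cext)
}

# Normalized k x k box convolution with zero padding (conserves total
# intensity exactly for mass >= floor(k/2) px from every edge).
box_smooth <- function(m, k) {
  if (k <= 1L) return(m)
  window_sum(m, k, k) / (k * k)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
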