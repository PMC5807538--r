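#' Detection parameters
#'
#' The scanning box is the local neighbourhood over which adaptive-threshold
#' statistics are computed; its default 220 x 180 px (at 1 um/px) is sized
#' to hold a heavily damaged comet without overlapping its neighbours.
#'
#' @param box_rows,box_cols Scanning-box height and width in px. Even sizes
#'   behave as the next odd size, since the box is centred on each pixel.
#' @param threshold_k Multiplier of the local standard deviation: a pixel is
#'   foreground when it exceeds `local mean + threshold_k * local sd`.
#' @param min_seed_area Minimum connected-component area (px^2) kept as a
#'   candidate; biological size limits are the classifier's job, this only
#'   drops specks.
#' @param presmooth_sigma Optional Gaussian pre-smoothing of the image before
#'   thresholding (px, 0 = off). Candidate features are always computed on
#'   the raw image.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(box_rows = 180, box_cols = 220, threshold_k = 2,
                             min_seed_area = 40, presmooth_sigma = 0) {
  stopifnot(box_rows >= 1, box_cols >= 1, min_seed_area >= 1,
            presmooth_sigma >= 0)
  structure(list(box_rows = as.integer(box_rows),
                 box_cols = as.integer(box_cols),
                 threshold_k = threshold_k,
                 min_seed_area = min_seed_area,
                 presmooth_sigma = presmooth_sigma),
            class = "detection_config")
}

as_pixels <- function(image) {
  if (inherits(image, "image_grid")) image$pixels else as.matrix(image)
}

#' Scanning-box adaptive threshold
#'
#' Partitions foreground from background with a dense scanning box: the
#' pixel at `(i, j)` is foreground iff its intensity strictly exceeds
#' `mean + threshold_k * sd` of the box centred on it (clipped at image
#' edges; sample sd, n-1 denominator). Because the statistics are local, a
#' smooth illumination gradient does not produce foreground, and adding a
#' constant to the whole image leaves the mask unchanged.
#'
#' @param image An [image_grid()] or numeric matrix.
#' @param config A [detection_config()].
#' @return A logical matrix of the image's shape; `TRUE` = foreground. A
#'   constant image yields an all-`FALSE` mask.
#' @export
adaptive_threshold <- function(image, config = detection_config()) {
  p <- as_pixels(image)
  if (config$presmooth_sigma > 0)
    p_stat <- gauss_smooth(p, config$presmooth_sigma)
  else
    p_stat <- p
  h <- min(config$box_rows, nrow(p)); w <- min(config$box_cols, ncol(p))
  n <- window_count(nrow(p), ncol(p), h, w)
  s1 <- window_sum(p_stat, h, w)
  s2 <- window_sum(p_stat * p_stat, h, w)
  m <- s1 / n
  v <- (s2 - n * m * m) / pmax(n - 1, 1)
  sdv <- sqrt(pmax(v, 0))
  p_stat > m + config$threshold_k * sdv
}

gauss_smooth <- function(p, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad <- function(m, n) rbind(matrix(0, n, ncol(m)), m, matrix(0, n, ncol(m)))
  conv1 <- function(m) {  # along rows, zero padding
    out <- matrix(0, nrow(m), ncol(m))
    for (d in -r:r) {
      src <- pmin(pmax(seq_len(nrow(m)) + d, 1L), nrow(m))
      valid <- seq_len(nrow(m)) + d >= 1L & seq_len(nrow(m)) + d <= nrow(m)
      out <- out + k[d + r + 1] * (m[src, , drop = FALSE] * valid)
    }
    out
  }
  t(conv1(t(conv1(p))))
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find over the
# label adjacency graph.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]            # down-right diagonal
  c1 <- lab[-nr, -1]; d1 <- lab[-1, -nc]          # down-left diagonal
  pairs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
                 cbind(c1[c1 > 0 & d1 > 0 & c1 != d1],
                       d1[c1 > 0 & d1 > 0 & c1 != d1]))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, 0L)
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Extract candidate objects from a foreground mask
#'
#' 8-connected components of the mask with at least `min_seed_area` pixels
#' become candidate objects, ordered row-major by bounding-box origin.
#' Photometric features are computed from the raw image intensities on the
#' component's pixels; geometry (axes, orientation) comes from the
#' intensity-weighted second moments with the standard 1/12 unit-pixel
#' spread added, so even one-pixel-wide objects have a positive minor axis.
#' All public coordinates are 0-based; bounding boxes are half-open
#' `(row_min, col_min, row_max, col_max)`.
#'
#' @param image An [image_grid()] or numeric matrix (raw intensities).
#' @param mask Logical matrix from [adaptive_threshold()] (same shape).
#' @param config A [detection_config()].
#' @return A list of `candidate_object`s, each with fields `object_id`,
#'   `bbox`, `mask` (logical raster over the bbox), `area`, `centroid`
#'   (intensity-weighted, 0-based `(row, col)`), `major_axis`, `minor_axis`,
#'   `orientation` (degrees in (-90, 90] from the migration axis),
#'   `mean_intensity` and `symmetry` (see [symmetry_score()]).
#' @export
extract_candidates <- function(image, mask, config = detection_config()) {
  p <- as_pixels(image)
  stopifnot(identical(dim(p), dim(mask)))
  if (!any(mask)) return(list())
  lab <- label_components(mask)
  nlab <- max(lab)
  idx_by_lab <- split(which(lab > 0), lab[lab > 0])
  out <- list()
  for (k in seq_len(nlab)) {
    idx <- idx_by_lab[[as.character(k)]]
    if (length(idx) < config$min_seed_area) next
    r <- (idx - 1L) %% nrow(p) + 1L
    cc <- (idx - 1L) %/% nrow(p) + 1L
    rmin <- min(r); rmax <- max(r); cmin <- min(cc); cmax <- max(cc)
    w <- p[idx]
    tw <- sum(w)
    if (tw <= 0) { w <- rep(1, length(idx)); tw <- length(idx) }
    cen_r <- sum(w * r) / tw; cen_c <- sum(w * cc) / tw
    mrr <- sum(w * (r - cen_r)^2) / tw + 1 / 12
    mcc <- sum(w * (cc - cen_c)^2) / tw + 1 / 12
    mrc <- sum(w * (r - cen_r) * (cc - cen_c)) / tw
    tr <- mrr + mcc; dt <- sqrt(((mrr - mcc) / 2)^2 + mrc^2)
    l1 <- tr / 2 + dt; l2 <- max(tr / 2 - dt, 0)
    theta <- 0.5 * atan2(2 * mrc, mcc - mrr) * 180 / pi  # from the col axis
    if (theta <= -90) theta <- theta + 180
    if (theta > 90) theta <- theta - 180
    cmask <- matrix(FALSE, rmax - rmin + 1L, cmax - cmin + 1L)
    cmask[cbind(r - rmin + 1L, cc - cmin + 1L)] <- TRUE
    cand <- structure(list(
      object_id = NA_integer_,
      bbox = c(row_min = rmin - 1L, col_min = cmin - 1L,
               row_max = rmax, col_max = cmax),
      mask = cmask,
      area = length(idx),
      centroid = c(row = cen_r - 1, col = cen_c - 1),
      major_axis = 4 * sqrt(l1),
      minor_axis = 4 * sqrt(l2),
      orientation = theta,
      mean_intensity = mean(p[idx]),
      symmetry = NA_real_,
      label = k
    ), class = "candidate_object")
    cand$symmetry <- symmetry_score(cand, p)
    out[[length(out) + 1L]] <- cand
  }
  if (length(out) == 0) return(out)
  ord <- order(vapply(out, function(o) o$bbox[["row_min"]], 0),
               vapply(out, function(o) o$bbox[["col_min"]], 0))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$object_id <- i
  out
}

# Raw-image patch of a candidate, zero outside its mask (1-based indexing).
candidate_patch <- function(candidate, pixels) {
  b <- candidate$bbox
  patch <- pixels[(b[["row_min"]] + 1L):b[["row_max"]],
                  (b[["col_min"]] + 1L):b[["col_max"]], drop = FALSE]
  patch[!candidate$mask] <- 0
  patch
}
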