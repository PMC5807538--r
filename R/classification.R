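#' Classifier limits
#'
#' The classifier answers five plausibility questions about each candidate
#' object — too small? too big? aligned with electrophoresis? comet-shaped?
#' symmetric about the migration axis? — and accepts the object only if all
#' pass. Defaults assume 1 um/px: nucleus cross-sections of 10-25 um bound
#' plausible head areas from below, and the analysis box bounds any comet
#' from above.
#'
#' @param min_area,max_area Accepted area range, px^2.
#' @param max_orientation_dev Largest allowed angle (degrees) between the
#'   object's major axis and the migration axis; only enforced for objects
#'   with aspect ratio above `max_aspect` (a near-circular undamaged comet
#'   has no meaningful orientation).
#' @param min_symmetry Minimum [symmetry_score()].
#' @param min_shape_score Minimum [shape_score()].
#' @param max_aspect Aspect ratio at or below which the orientation rule is
#'   waived.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(min_area = 200, max_area = 39600,
                              max_orientation_dev = 30, min_symmetry = 0.6,
                              min_shape_score = 0.5, max_aspect = 1.2) {
  stopifnot(min_area < max_area, max_orientation_dev > 0,
            max_orientation_dev <= 90,
            min_symmetry >= 0, min_symmetry <= 1,
            min_shape_score >= 0, min_shape_score <= 1, max_aspect >= 1)
  structure(list(min_area = min_area, max_area = max_area,
                 max_orientation_dev = max_orientation_dev,
                 min_symmetry = min_symmetry,
                 min_shape_score = min_shape_score,
                 max_aspect = max_aspect),
            class = "classifier_config")
}

#' Mirror-symmetry score about the migration axis
#'
#' A comet should look the same above and below a line drawn through its
#' centre parallel to the migration axis. The score is the Pearson
#' correlation between the object's intensity patch and its reflection
#' about the row through the intensity centroid, mapped to `[0, 1]` via
#' `(r + 1) / 2`. Degenerate patches (a single row, or zero variance)
#' score 1 by convention, so undamaged uniform discs are never rejected as
#' asymmetric.
#'
#' @param candidate A `candidate_object` from [extract_candidates()].
#' @param image The image (or its pixel matrix) the candidate came from.
#' @return A score in `[0, 1]`.
#' @export
symmetry_score <- function(candidate, image) {
  p <- as_pixels(image)
  patch <- candidate_patch(candidate, p)
  nr <- nrow(patch)
  if (nr <= 1L) return(1)
  w <- sum(patch)
  cen_r <- if (w > 0) sum(patch * row(patch)) / w else (nr + 1) / 2
  src <- round(2 * cen_r) - seq_len(nr)
  refl <- matrix(0, nr, ncol(patch))
  ok <- src >= 1L & src <= nr
  refl[ok, ] <- patch[src[ok], , drop = FALSE]
  if (stats::sd(patch) == 0 || stats::sd(refl) == 0) return(1)
  (stats::cor(as.vector(patch), as.vector(refl)) + 1) / 2
}

#' Comet-shape plausibility score
#'
#' Composite score in `[0, 1]`: the geometric mean of (a) the roundness of
#' the leading (head-side) third of the mask, measured as its solidity
#' (pixel area over rasterized convex-hull area), and (b) the
#' monotone-decay fraction of the axial intensity profile after its peak
#' (share of adjacent column pairs that are non-increasing, with a 5%-of-peak
#' tolerance). A single round head with a decaying tail scores near 1; rings
#' score low on roundness, and side-by-side merged cells produce a bimodal
#' profile that breaks monotone decay.
#'
#' @inheritParams symmetry_score
#' @return A score in `[0, 1]`.
#' @export
shape_score <- function(candidate, image) {
  p <- as_pixels(image)
  patch <- candidate_patch(candidate, p)
  msk <- candidate$mask
  nc <- ncol(msk)
  lead_cols <- seq_len(max(1L, ceiling(nc / 3)))
  sub <- msk[, lead_cols, drop = FALSE]
  roundness <- mask_solidity(sub)
  prof <- colSums(patch)
  peak <- which.max(prof)
  if (peak >= length(prof)) {
    decay <- 1
  } else {
    after <- prof[peak:length(prof)]
    tol <- 0.05 * prof[peak]
    decay <- mean(diff(after) <= tol)
  }
  sqrt(max(roundness, 0) * max(decay, 0))
}

# Solidity of a logical mask: area / area of the rasterized convex hull of
# the pixel centres. Degenerate (collinear) masks score 1.
mask_solidity <- function(msk) {
  idx <- which(msk)
  if (length(idx) < 3L) return(1)
  r <- (idx - 1L) %% nrow(msk) + 1L
  cc <- (idx - 1L) %/% nrow(msk) + 1L
  pts <- unique(cbind(r, cc))
  if (nrow(pts) < 3L) return(1)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  if (length(h) < 3L) return(1)  # collinear
  hull <- pts[h, , drop = FALSE]
  grid_r <- rep(seq(min(r), max(r)), times = max(cc) - min(cc) + 1L)
  grid_c <- rep(seq(min(cc), max(cc)), each = max(r) - min(r) + 1L)
  inside <- pracma::inpolygon(grid_c, grid_r, hull[, 2], hull[, 1],
                              boundary = TRUE)
  hull_area <- sum(inside)
  if (hull_area <= 0) return(1)
  min(1, length(idx) / hull_area)
}

#' Classify a candidate object as comet or non-target
#'
#' Evaluates all five rules (no short-circuiting) so the reason set is a
#' complete diagnostic: `TOO_SMALL`, `TOO_BIG`, `BAD_ORIENTATION` (major
#' axis deviates from the electrophoresis direction by more than the limit,
#' only for elongated objects), `BAD_SHAPE` and `ASYMMETRIC`. The object is
#' accepted iff no rule fires. All rules are geometric or
#' correlation-based, so classification is invariant to rescaling image
#' intensities by a positive constant.
#'
#' @inheritParams symmetry_score
#' @param config A [classifier_config()].
#' @return A list of class `comet_classification` with `accepted` (flag),
#'   `reasons` (character vector, empty iff accepted), and the computed
#'   `shape` and `symmetry` scores.
#' @export
classify <- function(candidate, image, config = classifier_config()) {
  reasons <- character(0)
  if (candidate$area < config$min_area) reasons <- c(reasons, "TOO_SMALL")
  if (candidate$area > config$max_area) reasons <- c(reasons, "TOO_BIG")
  aspect <- candidate$major_axis / candidate$minor_axis
  if (abs(candidate$orientation) > config$max_orientation_dev &&
      aspect > config$max_aspect)
    reasons <- c(reasons, "BAD_ORIENTATION")
  shp <- shape_score(candidate, image)
  if (shp < config$min_shape_score) reasons <- c(reasons, "BAD_SHAPE")
  sym <- if (is.na(candidate$symmetry))
    symmetry_score(candidate, image) else candidate$symmetry
  if (sym < config$min_symmetry) reasons <- c(reasons, "ASYMMETRIC")
  structure(list(accepted = length(reasons) == 0L, reasons = reasons,
                 shape = shp, symmetry = sym),
            class = "comet_classification")
}

#' @export
print.comet_classification <- function(x, ...) {
  cat(if (x$accepted) "accepted comet" else
        paste("rejected:", paste(x$reasons, collapse = ", ")),
      sprintf("(shape %.2f, symmetry %.2f)\n", x$shape, x$symmetry))
  invisible(x)
}
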