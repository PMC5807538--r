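#' Fit a bilinear background surface around a comet
#'
#' Non-specific background fluorescence varies smoothly across a well. A
#' bilinear surface `a + b*row + c*col + d*row*col` is least-squares fitted
#' to the non-object pixels of the analysis box; its residual standard
#' deviation is kept as the local noise floor used to threshold the axial
#' profile.
#'
#' @param image An [image_grid()] or numeric matrix.
#' @param box Analysis box as 0-based half-open
#'   `(row_min, col_min, row_max, col_max)`.
#' @param object_mask Logical matrix over the box (`TRUE` = pixel belongs to
#'   some detected object and is excluded from the fit).
#' @return A list of class `background_surface`: `coefficients`
#'   (`intercept, row, col, row:col`, in box-relative 0-based coordinates),
#'   `residual_sd`, `box`.
#' @export
fit_background <- function(image, box, object_mask) {
  p <- as_pixels(image)
  rows <- (box[[1]] + 1L):box[[3]]; cols <- (box[[2]] + 1L):box[[4]]
  patch <- p[rows, cols, drop = FALSE]
  stopifnot(identical(dim(object_mask), dim(patch)))
  bg <- !object_mask
  if (sum(bg) < 10L)
    stop("fit_background: fewer than 10 background pixels in the box; ",
         "enlarge the box or lower the detection threshold")
  rr <- row(patch)[bg] - 1; cc <- col(patch)[bg] - 1
  X <- cbind(1, rr, cc, rr * cc)
  fit <- stats::lm.fit(X, patch[bg])
  n <- sum(bg)
  sigma <- sqrt(sum(fit$residuals^2) / max(n - 4L, 1L))
  structure(list(coefficients = stats::setNames(fit$coefficients,
                                                c("intercept", "row", "col", "row:col")),
                 residual_sd = sigma, box = box),
            class = "background_surface")
}

# Evaluate a background surface over its box (box-relative coordinates).
eval_background <- function(surface) {
  box <- surface$box
  nr <- box[[3]] - box[[1]]; nc <- box[[4]] - box[[2]]
  rr <- matrix(0:(nr - 1), nr, nc)
  cc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  b <- surface$coefficients
  b[[1]] + b[[2]] * rr + b[[3]] * cc + b[[4]] * rr * cc
}

#' Subtract a fitted background surface from an image patch
#'
#' The surface is evaluated at every pixel of the box and subtracted;
#' negative results are clamped to zero so downstream intensity sums (and
#' hence percent tail DNA) stay non-negative.
#'
#' @param patch Numeric matrix over the surface's box.
#' @param surface A `background_surface` from [fit_background()].
#' @return Corrected patch, same shape, all values `>= 0`.
#' @export
subtract_background <- function(patch, surface) {
  s <- eval_background(surface)
  stopifnot(identical(dim(patch), dim(s)))
  pmax(patch - s, 0)
}

#' Axial intensity profile
#'
#' Sums corrected intensities along lines perpendicular to the migration
#' axis: `profile[i]` is the total intensity at axial position `i`. The
#' profile conserves total intensity exactly (`sum(profile) == sum(patch)`).
#'
#' @param patch Corrected (background-subtracted) numeric matrix in the
#'   canonical frame (migration toward increasing columns).
#' @return Numeric vector of length `ncol(patch)`.
#' @export
axial_profile <- function(patch) {
  stopifnot(length(patch) > 0)
  .colSums(patch, nrow(patch), ncol(patch))
}

#' Place the head-start, head-end and tail-end markers on a profile
#'
#' The three axial markers bound the comet: the first and last positions
#' whose profile exceeds a signal threshold delimit the object, and the
#' head/tail dividing line is placed by mirroring the leading rise about
#' the profile peak — the head is modelled as symmetric about its peak, so
#' its trailing edge sits as far beyond the peak as its leading edge sits
#' before it (clipped to the tail end). When several adjacent positions tie
#' for the maximum (a flat-topped head), the peak is the midpoint of the
#' earliest tied run: a rectangular head of width `w` then yields
#' `head_end = head_start + w - 1`, covering the whole head.
#'
#' The signal threshold combines a noise term with a `peak_frac`-of-peak
#' floor. Because negative corrected intensities are clamped to zero before
#' profiling, a pure-noise line of `line_width` pixels does not sum to zero
#' but to `line_width * sd * phi(0)` on average; the noise term is that
#' baseline plus a multiple of the standard deviation of the clamped sum,
#' `sd * sqrt(line_width * (1/2 - 1/(2*pi)))`. The multiple is `noise_k`
#' sigma corrected for multiplicity: the first/last-above-threshold markers
#' test every profile position at once, so the per-position quantile is
#' sharpened to keep the familywise false-signal rate at the `noise_k`-sigma
#' level across the whole profile (a single stray noise column would
#' otherwise drag `head_start` or `tail_end` far from the comet).
#'
#' @param profile Axial profile from [axial_profile()].
#' @param noise_floor Per-pixel background residual sd (from
#'   [fit_background()]).
#' @param line_width Number of pixels summed into each profile value.
#' @param noise_k,peak_frac Threshold constants (defaults 3 and 0.01).
#' @return Integer vector `(head_start, head_end, tail_end)`, 1-based
#'   indices into `profile`, with `head_start <= head_end <= tail_end`.
#'   Errors with a "no signal" message when nothing exceeds the threshold.
#' @export
locate_markers <- function(profile, noise_floor, line_width = 1,
                           noise_k = 3, peak_frac = 0.01) {
  clamp_bias <- line_width * noise_floor / sqrt(2 * pi)
  clamp_sd <- noise_floor * sqrt(line_width * (0.5 - 1 / (2 * pi)))
  z <- stats::qnorm(1 - stats::pnorm(-noise_k) / max(length(profile), 1L))
  tt <- max(clamp_bias + z * clamp_sd, peak_frac * max(profile))
  above <- which(profile > tt)
  if (length(above) == 0L)
    stop("locate_markers: no signal above threshold ", format(tt))
  hs <- above[1L]; te <- above[length(above)]
  seg <- profile[hs:te]
  tied <- which(seg == max(seg))
  run <- tied[cumsum(c(1L, diff(tied) != 1L)) == 1L]  # earliest tied run
  # mirror the leading rise about the (possibly half-integer) midpoint of
  # the peak run: 2 * mid - hs = run_first + run_last - hs
  he <- min(hs - 2L + run[1L] + run[length(run)], te)
  he <- max(he, hs)
  c(head_start = hs, head_end = he, tail_end = te)
}

#' Damage metrics from a corrected patch and its markers
#'
#' The tail is the half-open axial interval `(head_end, tail_end]`; the
#' whole comet is `[head_start, tail_end]`. Percent tail DNA is the tail's
#' share of total corrected intensity; tail length is the head-edge to
#' tail-tip distance in micrometres; tail moment is the exact identity
#' `tail_length * percent_tail / 100`; tail area counts corrected-positive
#' pixels in the tail interval. Measurements with percent tail DNA above
#' 80 are flagged `saturated` — beyond that level tails become too dim and
#' diffuse for the head/tail boundary to be trusted — but are reported,
#' not censored.
#'
#' @param patch Corrected patch (canonical frame).
#' @param markers Marker triple from [locate_markers()].
#' @param scale Micrometres per pixel.
#' @param olive Also report the Olive moment (centroid-distance form)?
#' @return A list of class `comet_measurement`.
#' @export
measure <- function(patch, markers, scale = 1, olive = FALSE) {
  hs <- markers[[1]]; he <- markers[[2]]; te <- markers[[3]]
  stopifnot(hs <= he, he <= te, te <= ncol(patch))
  prof <- axial_profile(patch)
  tail_idx <- if (te > he) (he + 1L):te else integer(0)
  tail_intensity <- sum(prof[tail_idx])
  total_intensity <- sum(prof[hs:te])
  ptd <- 100 * tail_intensity / total_intensity
  tail_length <- (te - he) * scale
  tail_area <- if (length(tail_idx))
    sum(patch[, tail_idx, drop = FALSE] > 0) else 0L
  out <- list(head_start = hs - 1L, head_end = he - 1L, tail_end = te - 1L,
              percent_tail_dna = ptd,
              tail_length_um = tail_length,
              tail_moment = tail_length * ptd / 100,
              tail_area_px2 = tail_area,
              tail_intensity = tail_intensity,
              total_intensity = total_intensity,
              saturated = ptd > 80)
  if (olive) {
    head_idx <- hs:he
    cen_head <- sum(prof[head_idx] * head_idx) / max(sum(prof[head_idx]), .Machine$double.eps)
    cen_tail <- if (length(tail_idx) && tail_intensity > 0)
      sum(prof[tail_idx] * tail_idx) / tail_intensity else cen_head
    out$olive_moment <- abs(cen_tail - cen_head) * scale * ptd / 100
  }
  structure(out, class = "comet_measurement")
}

#' @export
print.comet_measurement <- function(x, ...) {
  cat(sprintf("comet: %.1f%% tail DNA, tail %.1f um, moment %.2f%s\n",
              x$percent_tail_dna, x$tail_length_um, x$tail_moment,
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles the per-stage parameter blocks used by [analyze_image()] and the
#' plate pipeline. Any element can be overridden from a YAML config file
#' (see [load_config()]).
#'
#' @param detection A [detection_config()].
#' @param classifier A [classifier_config()].
#' @param box_pad Padding (px) added around a candidate's bounding box to
#'   form the local analysis box used for the background fit.
#' @param bg_guard Radius (px) by which the detection mask is dilated before
#'   the background fit, so the soft sub-threshold fringe around each object
#'   does not contaminate the background surface or inflate the noise floor.
#' @param profile_pad Padding (px) around the bounding box delimiting the
#'   profiled region (kept tighter than `box_pad` so residual noise columns
#'   beyond the comet do not enter the profile).
#' @param noise_k,peak_frac Marker threshold constants, see
#'   [locate_markers()].
#' @param olive_moment Also report the Olive moment column?
#' @param scale Micrometres per pixel of the input images.
#' @param migration Declared migration direction of the input images.
#' @return A nested list of class `analysis_config`.
#' @export
analysis_config <- function(detection = detection_config(),
                            classifier = classifier_config(),
                            box_pad = 24, profile_pad = 10, bg_guard = 10,
                            noise_k = 3, peak_frac = 0.01,
                            olive_moment = FALSE,
                            scale = 1, migration = "right") {
  structure(list(detection = detection, classifier = classifier,
                 box_pad = box_pad, profile_pad = profile_pad,
                 bg_guard = bg_guard,
                 noise_k = noise_k, peak_frac = peak_frac,
                 olive_moment = olive_moment,
                 scale = scale, migration = migration),
            class = "analysis_config")
}

#' Run the full single-image pipeline: detect, classify, quantify
#'
#' Re-orients the image to the canonical frame, thresholds it, extracts
#' candidates, classifies each, and measures every accepted comet: a local
#' analysis box is drawn around the candidate, a bilinear background
#' surface is fitted to its non-object pixels and subtracted, pixels of
#' other detected objects are zeroed, and the markers and damage metrics
#' are computed on the axial profile. Per-object failures ("no signal", too
#' little background) become rejection reasons rather than aborting the
#' image. Output is deterministic: identical inputs give identical results.
#'
#' @param image An [image_grid()] (or numeric matrix, assumed canonical).
#' @param config An [analysis_config()].
#' @return A list of class `comet_analysis`: `table`, a data frame with one
#'   row per candidate (features, acceptance, reasons, markers in 0-based
#'   box-frame coordinates, and damage metrics; metric columns are `NA` for
#'   rejected objects), and `objects`, the per-candidate detail list
#'   (candidate, classification, measurement or NULL).
#' @export
analyze_image <- function(image, config = analysis_config()) {
  if (!inherits(image, "image_grid"))
    image <- image_grid(image, scale = config$scale,
                        migration = config$migration)
  grid <- normalize_migration(image)
  p <- grid$pixels
  mask <- adaptive_threshold(p, config$detection)
  cands <- extract_candidates(p, mask, config$detection)
  guard <- if (config$bg_guard > 0)
    EBImage::dilate(mask * 1,
                    EBImage::makeBrush(2 * config$bg_guard + 1, "disc")) > 0
  else mask
  # background must come from pixels surrounding the comets: besides the
  # dilated detection mask, exclude every candidate's migration corridor
  # (its row band, from just ahead of the head to one scanning-box width
  # downstream), where faint sub-threshold tails may lie
  for (cand in cands) {
    bb <- cand$bbox
    rr <- max(bb[["row_min"]] + 1L - config$bg_guard, 1L):
          min(bb[["row_max"]] + config$bg_guard, nrow(p))
    cc <- max(bb[["col_min"]] + 1L - config$bg_guard, 1L):
          min(bb[["col_min"]] + config$detection$box_cols, ncol(p))
    guard[rr, cc] <- TRUE
  }
  objects <- vector("list", length(cands))
  rows <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    cand <- cands[[i]]
    cls <- classify(cand, p, config$classifier)
    meas <- NULL
    reasons <- cls$reasons
    if (cls$accepted) {
      res <- tryCatch(quantify_candidate(p, mask, guard, cand, grid$scale,
                                         config),
                      error = function(e) e)
      if (inherits(res, "error")) {
        reasons <- c(reasons, "NO_SIGNAL")
      } else meas <- res
    }
    accepted <- length(reasons) == 0L
    objects[[i]] <- list(candidate = cand,
                         classification = cls,
                         reasons = reasons,
                         measurement = meas)
    rows[[i]] <- data.frame(
      object_id = cand$object_id,
      centroid_row = cand$centroid[["row"]],
      centroid_col = cand$centroid[["col"]],
      area_px2 = cand$area,
      major_axis = cand$major_axis, minor_axis = cand$minor_axis,
      orientation_deg = cand$orientation,
      shape_score = cls$shape, symmetry_score = cls$symmetry,
      accepted = accepted,
      reasons = paste(reasons, collapse = ";"),
      head_start = if (accepted) meas$head_start else NA_integer_,
      head_end = if (accepted) meas$head_end else NA_integer_,
      tail_end = if (accepted) meas$tail_end else NA_integer_,
      percent_tail_dna = if (accepted) meas$percent_tail_dna else NA_real_,
      tail_length_um = if (accepted) meas$tail_length_um else NA_real_,
      tail_moment = if (accepted) meas$tail_moment else NA_real_,
      tail_area_px2 = if (accepted) meas$tail_area_px2 else NA_integer_,
      tail_intensity = if (accepted) meas$tail_intensity else NA_real_,
      total_intensity = if (accepted) meas$total_intensity else NA_real_,
      saturated = if (accepted) meas$saturated else NA)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else empty_comet_table()
  structure(list(table = tab, objects = objects,
                 image_dim = dim(p)), class = "comet_analysis")
}

empty_comet_table <- function() {
  data.frame(object_id = integer(), centroid_row = numeric(),
             centroid_col = numeric(), area_px2 = integer(),
             major_axis = numeric(), minor_axis = numeric(),
             orientation_deg = numeric(), shape_score = numeric(),
             symmetry_score = numeric(), accepted = logical(),
             reasons = character(), head_start = integer(),
             head_end = integer(), tail_end = integer(),
             percent_tail_dna = numeric(), tail_length_um = numeric(),
             tail_moment = numeric(), tail_area_px2 = integer(),
             tail_intensity = numeric(), total_intensity = numeric(),
             saturated = logical())
}

#' @export
print.comet_analysis <- function(x, ...) {
  n <- nrow(x$table)
  acc <- sum(x$table$accepted)
  cat(sprintf("<comet_analysis> %d candidates, %d accepted\n", n, acc))
  if (acc > 0)
    cat(sprintf("  %% tail DNA: mean %.1f, range [%.1f, %.1f]; %d saturated\n",
                mean(x$table$percent_tail_dna[x$table$accepted]),
                min(x$table$percent_tail_dna[x$table$accepted]),
                max(x$table$percent_tail_dna[x$table$accepted]),
                sum(x$table$saturated[x$table$accepted])))
  invisible(x)
}

# Background-correct and measure one accepted candidate. Internal.
quantify_candidate <- function(p, mask, guard, cand, scale, config) {
  b <- cand$bbox
  nr <- nrow(p); nc <- ncol(p)
  bh <- b[["row_max"]] - b[["row_min"]]; bw <- b[["col_max"]] - b[["col_min"]]
  # the analysis box is at least the configured scanning-box size: it must
  # capture the full tail of a heavily damaged comet even when the faint
  # tail end fell below the detection threshold. Rows are centred on the
  # candidate; columns start just ahead of the leading (head) edge so the
  # spare width lies on the tail side.
  box_h <- max(config$detection$box_rows, bh + 2 * config$box_pad)
  box_w <- max(config$detection$box_cols, bw + 2 * config$box_pad)
  r1 <- b[["row_min"]] - (box_h - bh) %/% 2
  c1 <- b[["col_min"]] - config$box_pad
  r1 <- min(max(r1, 0), max(nr - box_h, 0))
  c1 <- min(max(c1, 0), max(nc - box_w, 0))
  box <- c(r1, c1, min(r1 + box_h, nr), min(c1 + box_w, nc))
  rows <- (box[1] + 1L):box[3]; cols <- (box[2] + 1L):box[4]
  obj <- mask[rows, cols, drop = FALSE]
  orr0 <- (b[["row_min"]] + 1L):b[["row_max"]] - box[1]
  surf <- fit_background(p, box, guard[rows, cols, drop = FALSE])
  patch <- p[rows, cols, drop = FALSE]
  corrected <- subtract_background(patch, surf)
  orr <- orr0
  # profile over the candidate's rows (plus padding) but the full axial
  # extent of the box: sub-threshold tail columns — including tail pieces
  # the threshold split into separate small components — are still
  # measured, while row-neighbouring comets stay outside the band
  pr <- c(max(orr[1] - config$profile_pad, 1),
          min(orr[length(orr)] + config$profile_pad, length(rows)))
  pc <- c(1L, length(cols))
  sub <- corrected[pr[1]:pr[2], pc[1]:pc[2], drop = FALSE]
  prof <- axial_profile(sub)
  mk <- locate_markers(prof, noise_floor = surf$residual_sd,
                       line_width = nrow(sub),
                       noise_k = config$noise_k, peak_frac = config$peak_frac)
  m <- measure(sub, mk, scale = scale, olive = config$olive_moment)
  # report markers in whole-image 0-based axial coordinates
  off <- box[2] + (pc[1] - 1L)
  m$head_start <- m$head_start + off
  m$head_end <- m$head_end + off
  m$tail_end <- m$tail_end + off
  m
}
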