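#' Parametric description of one simulated comet
#'
#' A simulated comet is a circular head disc plus a half-ellipse tail of
#' chosen grey values, the classical construction used to validate automated
#' comet scoring: because the figure is drawn from known regions, its
#' percent tail DNA, tail length and tail moment are known analytically
#' before any image processing happens.
#'
#' Geometry (in the canonical frame, migration toward increasing columns):
#' the head is the disc of radius `head_radius` around `head_center`; the
#' tail occupies the half-ellipse with semi-axes `tail_extent` (along
#' migration) and `tail_semi_minor` (perpendicular), centred on the head's
#' trailing edge, restricted to columns strictly beyond that edge. Pixels
#' claimed by the head keep `head_grey`, so head and tail masks are
#' exclusive and the ground-truth region sums are exact.
#'
#' @param head_center `(row, col)` of the head centre, px.
#' @param head_radius Head disc radius, px (> 0).
#' @param head_grey Head intensity level, in `[1, max_level]`.
#' @param tail_semi_minor Tail half-width perpendicular to migration, px (>= 0).
#' @param tail_extent Tail length beyond the head edge along migration, px (>= 0).
#' @param tail_grey Tail intensity level, in `[0, head_grey]` (tails are never
#'   brighter than heads).
#' @param max_level Intensity ceiling (default 255); levels are abstract and
#'   may be non-integer — bit depth is an I/O concern only.
#' @return An object of class `comet_spec`.
#' @seealso [spec_for_target()], [render_comet()], [render_well()]
#' @export
comet_spec <- function(head_center, head_radius, head_grey,
                       tail_semi_minor = head_radius, tail_extent = 0,
                       tail_grey = 0, max_level = 255) {
  stopifnot(length(head_center) == 2L, head_radius > 0,
            tail_semi_minor >= 0, tail_extent >= 0)
  if (head_grey < 1 || head_grey > max_level)
    stop("comet_spec: head_grey must lie in [1, max_level]")
  if (tail_grey < 0 || tail_grey > head_grey)
    stop("comet_spec: tail_grey must lie in [0, head_grey]")
  structure(list(head_center = as.numeric(head_center),
                 head_radius = head_radius, head_grey = head_grey,
                 tail_semi_minor = tail_semi_minor, tail_extent = tail_extent,
                 tail_grey = tail_grey, max_level = max_level),
            class = "comet_spec")
}

# Exclusive head/tail pixel masks of a spec on a rows x cols canvas.
# Returned as integer index vectors into the canvas matrix.
comet_masks <- function(spec, canvas) {
  nr <- canvas[1]; nc <- canvas[2]
  r0 <- spec$head_center[1]; c0 <- spec$head_center[2]
  R <- spec$head_radius; b <- spec$tail_semi_minor; E <- spec$tail_extent
  edge <- c0 + R
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  head <- (rr - r0)^2 + (cc - c0)^2 <= R^2
  if (E > 0 && b >= 0) {
    inside <- if (b > 0) ((cc - edge) / E)^2 + ((rr - r0) / b)^2 <= 1
              else ((cc - edge) / E)^2 <= 1 & rr == round(r0)
    tail <- inside & cc > edge & !head
  } else {
    tail <- matrix(FALSE, nr, nc)
  }
  list(head = which(head), tail = which(tail))
}

# Pixel areas of the head disc and tail half-ellipse for a given geometry,
# independent of placement (computed on a minimal private canvas).
region_areas <- function(head_radius, tail_semi_minor, tail_extent) {
  R <- ceiling(head_radius); b <- ceiling(tail_semi_minor); E <- ceiling(tail_extent)
  half <- max(R, b) + 2L
  sp <- comet_spec(head_center = c(half + 1L, R + 2L), head_radius = head_radius,
                   head_grey = 1, tail_semi_minor = tail_semi_minor,
                   tail_extent = tail_extent, tail_grey = 0)
  m <- comet_masks(sp, c(2L * half + 1L, R + E + R + 4L))
  c(head = length(m$head), tail = length(m$tail))
}

#' Analytically known metrics of a simulated comet
#'
#' Ground truth is defined on the pre-smoothing region masks: percent tail
#' DNA is `100 * S_tail / (S_head + S_tail)` with `S_head = head_grey *
#' head_area` and `S_tail = tail_grey * tail_area`; tail length is
#' `tail_extent * scale` (head edge to tail tip); tail moment is the exact
#' identity `tail_length * percent_tail / 100`.
#'
#' @param spec A [comet_spec()].
#' @param scale Micrometres per pixel.
#' @return A list with `true_percent_tail_dna`, `true_tail_length_um`,
#'   `true_tail_moment`, and the region pixel areas and sums.
#' @export
ground_truth <- function(spec, scale = 1) {
  a <- region_areas(spec$head_radius, spec$tail_semi_minor, spec$tail_extent)
  s_head <- spec$head_grey * a[["head"]]
  s_tail <- spec$tail_grey * a[["tail"]]
  ptd <- 100 * s_tail / (s_head + s_tail)
  tl <- spec$tail_extent * scale
  list(true_percent_tail_dna = ptd,
       true_tail_length_um = tl,
       true_tail_moment = tl * ptd / 100,
       head_area_px2 = a[["head"]], tail_area_px2 = a[["tail"]],
       head_sum = s_head, tail_sum = s_tail)
}

#' Solve a comet geometry for a requested percent tail DNA
#'
#' Inverts the ground-truth identity: given a target percent tail DNA,
#' chooses a tail length and tail grey value so that the rendered spec's
#' true percent tail DNA equals the target (grey levels are continuous, so
#' the match is exact up to floating point).
#'
#' When `tail_extent` is given explicitly in `geometry` it is held fixed
#' and only `tail_grey` is solved (an error is raised if the tail would
#' have to be brighter than the head). Otherwise the solver picks the tail
#' envelope the way real comets behave — damage fills and then lengthens
#' the tail while the head/tail boundary stays resolvable — by keeping
#' `tail_grey` inside a band of the head grey: at least
#' `min_tail_grey_frac` of `head_grey` (so even faint tails stay above the
#' profile signal threshold) and at most `max_tail_grey_frac` (a tail as
#' bright as its head no longer looks like a comet, and its profile would
#' rival the head peak). The tail area follows the target within those
#' constraints, capped at `tail_area_ref`.
#'
#' @param target_percent_tail Requested percent tail DNA, in `[0, 95]`.
#' @param geometry Named list of geometry defaults: `head_radius`,
#'   `tail_semi_minor`, `head_grey`, `max_level`, optional fixed
#'   `tail_extent`, `max_tail_extent`, `tail_area_ref`,
#'   `min_tail_grey_frac`, `max_tail_grey_frac`.
#' @param head_center Placement of the head centre; the default leaves a
#'   wide clear surround, as on a real well image.
#' @return A [comet_spec()] whose [ground_truth()] percent tail DNA is
#'   within 0.5 points of (in practice, equal to) the target. Errors when
#'   the target is unreachable under `max_tail_extent` (e.g. very high
#'   damage with a small cap): the required tail would be brighter than
#'   the head.
#' @export
spec_for_target <- function(target_percent_tail,
                            geometry = list(),
                            head_center = NULL) {
  g <- utils::modifyList(list(head_radius = 12, tail_semi_minor = 12,
                              tail_extent = NULL, head_grey = 200,
                              max_level = 255, max_tail_extent = 400,
                              tail_area_ref = 1700,
                              min_tail_grey_frac = 0.02,
                              max_tail_grey_frac = 0.75),
                         geometry)
  p <- target_percent_tail
  if (!is.finite(p) || p < 0 || p > 95)
    stop("spec_for_target: target must lie in [0, 95] percent")
  if (is.null(head_center))
    head_center <- c(max(g$head_radius, g$tail_semi_minor) + 64,
                     g$head_radius + 64)
  if (p == 0)
    return(comet_spec(head_center, g$head_radius, g$head_grey,
                      g$tail_semi_minor, tail_extent = 0, tail_grey = 0,
                      max_level = g$max_level))
  odds <- p / (100 - p)
  area_of <- function(E) region_areas(g$head_radius, g$tail_semi_minor, E)
  a_head <- region_areas(g$head_radius, g$tail_semi_minor, 1)[["head"]]
  solve_grey <- function(E) {
    a <- area_of(E)
    if (a[["tail"]] == 0) return(NULL)
    odds * g$head_grey * a[["head"]] / a[["tail"]]
  }
  if (!is.null(g$tail_extent)) {
    E <- g$tail_extent
    tg <- solve_grey(E)
    if (is.null(tg) || tg > g$head_grey)
      stop(sprintf(paste0("spec_for_target: %g%% tail DNA is unreachable ",
                          "with the fixed tail_extent %g px (the tail ",
                          "would need to be brighter than the head)"), p, E))
    return(comet_spec(head_center, g$head_radius, g$head_grey,
                      g$tail_semi_minor, tail_extent = E, tail_grey = tg,
                      max_level = g$max_level))
  }
  # wanted tail area: track the target so faint tails stay detectable,
  # cap at the reference envelope, and enlarge when the grey ceiling binds
  a_want <- min(g$tail_area_ref, odds * a_head / g$min_tail_grey_frac)
  a_want <- max(a_want, odds * a_head / g$max_tail_grey_frac)
  E <- max(1, floor(a_want / (pi / 2 * max(g$tail_semi_minor, 1))) - 2)
  while (E <= g$max_tail_extent && area_of(E)[["tail"]] < a_want)
    E <- E + 1
  E <- min(E, g$max_tail_extent)
  tg <- solve_grey(E)
  if (is.null(tg) || tg > g$head_grey)
    stop(sprintf(paste0("spec_for_target: %g%% tail DNA is unreachable with ",
                        "head_radius %g and max_tail_extent %g px (the tail ",
                        "would need to be brighter than the head); raise ",
                        "max_tail_extent or shrink the head"),
                 p, g$head_radius, g$max_tail_extent))
  comet_spec(head_center, g$head_radius, g$head_grey, g$tail_semi_minor,
             tail_extent = E, tail_grey = tg, max_level = g$max_level)
}

#' Render one simulated comet and its ground truth
#'
#' Draws the head disc and tail half-ellipse at their grey values and blurs
#' the drawing with a normalized `smoothing_window` x `smoothing_window` box
#' filter to give the simulated comet a realistic soft appearance
#' (`smoothing_window = 1` leaves the raw drawing untouched). Ground truth
#' is computed from the pre-smoothing region masks; the normalized filter
#' conserves total intensity (to within boundary effects, which the margin
#' requirement keeps below 0.1%).
#'
#' @param spec A [comet_spec()].
#' @param canvas `(rows, cols)` of the output raster.
#' @param smoothing_window Odd box-filter width in px (default 15).
#' @param scale Micrometres per pixel of the output grid.
#' @return A list: `image` (an [image_grid()], migration `"right"`),
#'   `truth` (see [ground_truth()]).
#' @export
render_comet <- function(spec, canvas = NULL, smoothing_window = 15, scale = 1) {
  margin <- 8
  r0 <- spec$head_center[1]; c0 <- spec$head_center[2]
  R <- spec$head_radius; b <- spec$tail_semi_minor; E <- spec$tail_extent
  if (is.null(canvas))
    canvas <- c(ceiling(r0 + max(R, b) + 64),
                ceiling(c0 + R + E + 64))
  ext_r <- c(r0 - max(R, if (E > 0) b else 0), r0 + max(R, if (E > 0) b else 0))
  ext_c <- c(c0 - R, c0 + R + E)
  if (ext_r[1] < 1 + margin || ext_c[1] < 1 + margin ||
      ext_r[2] > canvas[1] - margin || ext_c[2] > canvas[2] - margin)
    stop(sprintf(paste0("render_comet: comet spans rows [%.0f, %.0f], cols ",
                        "[%.0f, %.0f] but must keep a %d px margin inside a ",
                        "%d x %d canvas (so the smoothing filter is never ",
                        "truncated over the object)"),
                 ext_r[1], ext_r[2], ext_c[1], ext_c[2], margin,
                 canvas[1], canvas[2]))
  raw <- matrix(0, canvas[1], canvas[2])
  m <- comet_masks(spec, canvas)
  raw[m$head] <- spec$head_grey
  raw[m$tail] <- spec$tail_grey
  img <- pmax(box_smooth(raw, as.integer(smoothing_window)), 0)
  list(image = image_grid(img, scale = scale, migration = "right"),
       truth = ground_truth(spec, scale = scale))
}

#' Render a synthetic well image: a grid of comets over background and noise
#'
#' Comets are laid out row-major on a regular grid (one per node), the raw
#' drawing is box-smoothed, and a background plane plus zero-mean Gaussian
#' noise (clamped at zero) is added afterwards. With a fixed `rng_seed` the
#' output raster is bit-identical across calls. Explicit `positions`
#' override the grid and allow deliberately overlapping placements, in which
#' case a warning lists the colliding comet indices (overlapping objects are
#' meant to be rejected downstream as multi-cell loading).
#'
#' @param specs List of [comet_spec()]s; their `head_center` is replaced by
#'   the layout position.
#' @param grid_pitch Centre-to-centre spacing in px, a scalar or
#'   `(row_pitch, col_pitch)`. Must be at least twice the largest comet
#'   bounding extent for overlap-free placement.
#' @param layout `(rows, cols)` of the comet grid; default near-square.
#' @param positions Optional n x 2 matrix of `(row, col)` head centres,
#'   overriding the grid layout.
#' @param background `(base, gradient_row, gradient_col)`: plane
#'   `base + gr * row + gc * col` added to the whole canvas.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   levels); 0 disables noise.
#' @param smoothing_window Box-filter width applied to the comet drawing.
#' @param rng_seed Integer seed for the noise; required when `noise_sd > 0`.
#' @param scale Micrometres per pixel.
#' @return A list: `image` (an [image_grid()]) and `truth`, a data frame
#'   with one row per comet: `comet_id`, `row_px`, `col_px`,
#'   `true_percent_tail_dna`, `true_tail_length_um`, `true_tail_moment`.
#' @export
render_well <- function(specs, grid_pitch = 150, layout = NULL,
                        positions = NULL,
                        background = c(10, 0, 0), noise_sd = 0,
                        smoothing_window = 15, rng_seed = 1, scale = 1) {
  n <- length(specs)
  margin <- 8
  pitch <- if (length(grid_pitch) == 1L) c(grid_pitch, grid_pitch) else grid_pitch
  ext_r <- vapply(specs, function(s)
    2 * max(s$head_radius, if (s$tail_extent > 0) s$tail_semi_minor else 0) + 1,
    0)
  ext_c <- vapply(specs, function(s) 2 * s$head_radius + s$tail_extent + 1, 0)
  if (is.null(positions)) {
    if (n == 0) {
      canvas <- c(round(2 * margin + pitch[1]), round(2 * margin + pitch[2]))
      positions <- matrix(numeric(0), 0, 2)
    } else {
      if (is.null(layout)) {
        lc <- ceiling(sqrt(n)); lr <- ceiling(n / lc); layout <- c(lr, lc)
      }
      if (any(pitch < 2 * c(max(ext_r), max(ext_c))))
        warning(sprintf("render_well: grid pitch (%g, %g) px is below twice the largest comet extent (%g, %g); comets may overlap",
                        pitch[1], pitch[2], max(ext_r), max(ext_c)))
      ij <- cbind(rep(seq_len(layout[1]), each = layout[2]),
                  rep(seq_len(layout[2]), times = layout[1]))[seq_len(n), , drop = FALSE]
      # offset so every comet keeps the smoothing margin
      off_r <- margin + max(ext_r) / 2
      off_c <- margin + vapply(specs, function(s) s$head_radius, 0)
      positions <- cbind(off_r + (ij[, 1] - 0.5) * pitch[1],
                         max(off_c) + 1 + (ij[, 2] - 1) * pitch[2])
      canvas <- c(ceiling(2 * margin + layout[1] * pitch[1] + max(ext_r)),
                  ceiling(2 * margin + layout[2] * pitch[2] + max(ext_c)))
    }
  } else {
    positions <- as.matrix(positions)
    stopifnot(nrow(positions) == n, ncol(positions) == 2L)
    canvas <- c(ceiling(max(positions[, 1] + ext_r / 2) + margin + max(ext_r)),
                ceiling(max(positions[, 2] + ext_c) + margin))
  }
  placed <- vector("list", n)
  raw <- matrix(0, canvas[1], canvas[2])
  for (i in seq_len(n)) {
    s <- specs[[i]]
    s$head_center <- positions[i, ]
    placed[[i]] <- s
    m <- comet_masks(s, canvas)
    raw[m$head] <- pmax(raw[m$head], s$head_grey)
    raw[m$tail] <- pmax(raw[m$tail], s$tail_grey)
  }
  # overlap check on bounding boxes
  if (n >= 2) {
    bb <- t(vapply(seq_len(n), function(i) {
      s <- placed[[i]]
      c(positions[i, 1] - ext_r[i] / 2, positions[i, 1] + ext_r[i] / 2,
        positions[i, 2] - s$head_radius, positions[i, 2] + s$head_radius + s$tail_extent)
    }, numeric(4)))
    coll <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (bb[i, 1] <= bb[j, 2] && bb[j, 1] <= bb[i, 2] &&
          bb[i, 3] <= bb[j, 4] && bb[j, 3] <= bb[i, 4])
        coll[[length(coll) + 1L]] <- c(i, j)
    if (length(coll))
      warning("render_well: overlapping comets at indices ",
              paste(vapply(coll, function(p) paste(p, collapse = "-"), ""),
                    collapse = ", "))
  }
  img <- box_smooth(raw, as.integer(smoothing_window))
  rr <- matrix(seq_len(canvas[1]), canvas[1], canvas[2])
  cc <- matrix(seq_len(canvas[2]), canvas[1], canvas[2], byrow = TRUE)
  img <- img + background[1] + background[2] * rr + background[3] * cc
  if (noise_sd > 0)
    img <- img + with_seed(rng_seed,
                           matrix(stats::rnorm(length(img), 0, noise_sd),
                                  canvas[1], canvas[2]))
  img <- pmax(img, 0)
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    gt <- ground_truth(placed[[i]], scale = scale)
    data.frame(comet_id = i,
               row_px = positions[i, 1], col_px = positions[i, 2],
               true_percent_tail_dna = gt$true_percent_tail_dna,
               true_tail_length_um = gt$true_tail_length_um,
               true_tail_moment = gt$true_tail_moment)
  }))
  if (is.null(truth))
    truth <- data.frame(comet_id = integer(), row_px = numeric(),
                        col_px = numeric(), true_percent_tail_dna = numeric(),
                        true_tail_length_um = numeric(),
                        true_tail_moment = numeric())
  list(image = image_grid(img, scale = scale, migration = "right"),
       truth = truth)
}

#' Simulate a full well at requested damage levels
#'
#' Convenience wrapper: builds one [spec_for_target()] per requested percent
#' tail DNA and renders them with [render_well()].
#'
#' @param targets Numeric vector of target percent tail DNA values, each in
#'   `[0, 95]`.
#' @param geometry Geometry defaults passed to [spec_for_target()].
#' @inheritParams render_well
#' @return As [render_well()]; `truth` gains a `target_percent_tail` column.
#' @export
simulate_well <- function(targets, geometry = list(), grid_pitch = NULL,
                          layout = NULL, background = c(10, 0, 0),
                          noise_sd = 0, smoothing_window = 15, rng_seed = 1,
                          scale = 1) {
  specs <- lapply(targets, spec_for_target, geometry = geometry)
  if (is.null(grid_pitch)) {
    ext_r <- max(vapply(specs, function(s)
      2 * max(s$head_radius, s$tail_semi_minor) + 1, 0))
    ext_c <- max(vapply(specs, function(s)
      2 * s$head_radius + s$tail_extent + 1, 0))
    grid_pitch <- c(2 * ext_r + 4, 2 * ext_c + 4)
  }
  w <- render_well(specs, grid_pitch = grid_pitch, layout = layout,
                   background = background, noise_sd = noise_sd,
                   smoothing_window = smoothing_window, rng_seed = rng_seed,
                   scale = scale)
  w$truth$target_percent_tail <- targets
  w
}
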