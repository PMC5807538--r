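#' Stitch a grid of image tiles into one mosaic
#'
#' Well imagers capture several tiles per well which are combined into a
#' single representation. Tiles are abutted on a regular grid in row-major
#' order — no registration or blending — so the mosaic dimensions are the
#' tile dimensions times the grid dimensions.
#'
#' @param tiles List of [image_grid()]s or numeric matrices, row-major.
#' @param grid `(rows, cols)` of the tile grid; `rows * cols` must equal
#'   `length(tiles)` and all tiles must share one shape.
#' @return An [image_grid()] (scale and migration taken from the first tile
#'   when tiles are `image_grid`s).
#' @export
stitch_tiles <- function(tiles, grid) {
  stopifnot(length(grid) == 2L)
  if (length(tiles) != grid[1] * grid[2])
    stop(sprintf("stitch_tiles: %d tiles supplied but grid %dx%d needs %d",
                 length(tiles), grid[1], grid[2], grid[1] * grid[2]))
  mats <- lapply(tiles, as_pixels)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), TRUE)))
    stop("stitch_tiles: all tiles must have identical dimensions")
  out <- matrix(0, d[1] * grid[1], d[2] * grid[2])
  k <- 1L
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) {
    out[(i - 1) * d[1] + seq_len(d[1]), (j - 1) * d[2] + seq_len(d[2])] <- mats[[k]]
    k <- k + 1L
  }
  first <- tiles[[1]]
  if (inherits(first, "image_grid"))
    image_grid(out, scale = first$scale, migration = first$migration)
  else image_grid(out)
}

#' Per-well summary statistics of percent tail DNA
#'
#' Mean, sample standard deviation (n-1 denominator) and the Student-t 95%
#' confidence interval of the mean, the standard presentation for per-well
#' comet damage. With fewer than two comets the record is emitted but
#' flagged and its interval is undefined.
#'
#' @param values Numeric vector of per-comet percent tail DNA.
#' @param alpha Significance level for the `1 - alpha` CI (default 0.05).
#' @return A list: `n`, `mean`, `sd`, `ci_lower`, `ci_upper`, `flagged`.
#' @export
summarize_well <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L)
    return(list(n = n, mean = if (n) mean(values) else NA_real_,
                sd = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                flagged = TRUE))
  m <- mean(values); s <- stats::sd(values)
  half <- stats::qt(1 - alpha / 2, df = n - 1) * s / sqrt(n)
  list(n = n, mean = m, sd = s, ci_lower = m - half, ci_upper = m + half,
       flagged = FALSE)
}

#' Pooled-variance Student's t-test between treatment groups
#'
#' Unpaired Student's t-test with pooled variance (the classical "Student's
#' t-test"; Welch's correction is available behind `welch = TRUE`).
#' One-sided tests take the alternative that the treated mean exceeds the
#' control mean — the direction a DNA-damaging compound is screened for.
#' Two groups that are identical and constant have no variance to test
#' against; by convention they return `t = 0, p = 1`, flagged.
#'
#' @param treated,control Numeric vectors, each of length `>= 2`.
#' @param sidedness `"two"` or `"one"`.
#' @param welch Use Welch's unequal-variance form instead of pooling?
#' @return A list: `t`, `p`, `df`, `sidedness`, `flagged`.
#' @export
compare_groups <- function(treated, control, sidedness = c("two", "one"),
                           welch = FALSE) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(treated) >= 2L, length(control) >= 2L)
  alt <- if (sidedness == "one") "greater" else "two.sided"
  res <- tryCatch(
    stats::t.test(treated, control, alternative = alt, var.equal = !welch),
    error = function(e) e)
  if (inherits(res, "error"))
    return(list(t = 0, p = 1, df = NA_real_, sidedness = sidedness,
                flagged = TRUE))
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), sidedness = sidedness, flagged = FALSE)
}

#' Inter-assay coefficient of variation
#'
#' `100 * sd / mean` over the per-assay means of a positive control, the
#' standard reproducibility figure for the assay.
#'
#' @param replicate_means Numeric vector of per-assay mean percent tail DNA
#'   values, length `>= 2`.
#' @return CV in percent.
#' @export
assay_cv <- function(replicate_means) {
  if (length(replicate_means) < 2L)
    stop("assay_cv: need at least 2 replicate means")
  m <- mean(replicate_means)
  if (m == 0) stop("assay_cv: mean is zero, CV undefined")
  100 * stats::sd(replicate_means) / m
}

#' Regress measured against true percent tail DNA
#'
#' Ordinary least squares of the pipeline's measurements on the analytically
#' known values of simulated comets; the r-squared of this line is the
#' standard validation figure for automated comet scoring.
#'
#' @param truth,measured Equal-length numeric vectors (`>= 3` points;
#'   `truth` must not be constant).
#' @return A list: `r_squared`, `slope`, `intercept`, `n`.
#' @export
validate_linearity <- function(truth, measured) {
  stopifnot(length(truth) == length(measured))
  if (length(truth) < 3L)
    stop("validate_linearity: need at least 3 points")
  if (stats::sd(truth) == 0)
    stop("validate_linearity: truth values are constant, r-squared undefined")
  fit <- stats::lm(measured ~ truth)
  s <- summary(fit)
  list(r_squared = s$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(truth))
}

#' Is a well on the plate periphery?
#'
#' Peripheral wells are rows A/H and columns 1/12 of a 96-well plate — the
#' outermost ring, which shows the largest deviation from the plate mean
#' (the edge effect).
#'
#' @param well_id Character vector of labels like `"A1"`, `"H12"`.
#' @return Logical vector.
#' @export
is_peripheral_well <- function(well_id) {
  rowl <- toupper(substr(well_id, 1, 1))
  coln <- suppressWarnings(as.integer(substring(well_id, 2)))
  rowl %in% c("A", "H") | coln %in% c(1L, 12L)
}

#' Load an analysis configuration from YAML
#'
#' Reads the `detection:`, `classifier:`, `quantification:` and top-level
#' keys of a YAML file and merges them over the package defaults.
#'
#' @param path Path to a YAML file (may also contain pipeline keys such as
#'   `images`, `well_map`, `out_dir`, `tiles`, `stats` used by
#'   [run_pipeline()]).
#' @return A list: `analysis` (an [analysis_config()]) and `pipeline` (the
#'   remaining keys).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  y <- yaml::read_yaml(path)
  det <- do.call(detection_config,
                 utils::modifyList(list(), y$detection %||% list()))
  cls <- do.call(classifier_config,
                 utils::modifyList(list(), y$classifier %||% list()))
  qargs <- y$quantification %||% list()
  top <- y[intersect(names(y), c("scale", "migration"))]
  ana <- do.call(analysis_config,
                 c(list(detection = det, classifier = cls), qargs, top))
  pipe <- y[setdiff(names(y), c("detection", "classifier", "quantification",
                                "scale", "migration"))]
  list(analysis = ana, pipeline = pipe)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the plate pipeline from a config file
#'
#' End-to-end driver: resolves the image files, optionally stitches tile
#' grids per well, analyzes every well image, and writes `comets.csv` (one
#' row per candidate with features, reasons and damage metrics),
#' `wells.csv` (per-well n / mean / sd / 95% CI and peripheral flag) and
#' `plate_report.json` (totals, rejection tally by reason, saturated count,
#' edge report, and pooled-t comparisons of each group against the control
#' group when `stats$control_group` is set). Reruns on identical inputs
#' produce byte-identical CSV bodies.
#'
#' Config keys (YAML): `images` (glob or directory), `well_map` (CSV with
#' columns `file,well,group`), `out_dir`, optional `tiles: [rows, cols]`
#' (files of one well stitched in lexicographic row-major order), `scale`,
#' `migration`, `stats: {control_group, sidedness}`, plus the `detection:`,
#' `classifier:` and `quantification:` blocks.
#'
#' @param config_path Path to the YAML config.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the report and the two tables.
#' @export
run_pipeline <- function(config_path, quiet = FALSE) {
  cfg <- load_config(config_path)
  pipe <- cfg$pipeline
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) if (file.exists(p) || grepl("^/", p)) p else file.path(base, p)
  say <- function(...) if (!quiet) message(sprintf(...))
  spec <- pipe$images %||% stop("run_pipeline: config lacks 'images'")
  spec <- resolve(spec)
  files <- if (dir.exists(spec))
    list.files(spec, pattern = "\\.(tif|tiff|png)$", full.names = TRUE)
  else Sys.glob(spec)
  files <- sort(files)
  if (length(files) == 0L)
    stop("run_pipeline: no inputs matched '", spec, "'")
  wm_path <- resolve(pipe$well_map %||% stop("run_pipeline: config lacks 'well_map'"))
  if (!file.exists(wm_path)) stop("run_pipeline: well map not found: ", wm_path)
  wm <- utils::read.csv(wm_path, stringsAsFactors = FALSE)
  if (!all(c("file", "well") %in% names(wm)))
    stop("run_pipeline: well map needs 'file' and 'well' columns")
  if (is.null(wm$group)) wm$group <- ""
  out_dir <- resolve(pipe$out_dir %||% ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ana <- cfg$analysis
  missing <- setdiff(wm$file, basename(files))
  if (length(missing))
    stop("run_pipeline: well map references missing files: ",
         paste(missing, collapse = ", "))
  wm <- wm[order(wm$well, wm$file), , drop = FALSE]
  per_well <- split(wm, wm$well)
  tiles <- pipe$tiles
  comet_rows <- list()
  n_images <- 0L
  for (well in names(per_well)) {
    entry <- per_well[[well]]
    paths <- files[match(entry$file, basename(files))]
    if (!is.null(tiles)) {
      tl <- lapply(paths, read_image_grid, scale = ana$scale,
                   migration = ana$migration)
      img <- stitch_tiles(tl, unlist(tiles))
      n_images <- n_images + length(paths)
    } else {
      if (length(paths) != 1L)
        stop("run_pipeline: well ", well, " maps to ", length(paths),
             " files but no 'tiles' grid is configured")
      img <- read_image_grid(paths[1], scale = ana$scale,
                             migration = ana$migration)
      n_images <- n_images + 1L
    }
    res <- analyze_image(img, ana)
    tab <- res$table
    if (nrow(tab)) {
      tab <- cbind(data.frame(well = well, group = entry$group[1],
                              image_id = if (!is.null(tiles)) well
                                         else basename(paths[1])),
                   tab)
      comet_rows[[well]] <- tab
    }
    say("well %s: %d candidates, %d accepted", well, nrow(res$table),
        sum(res$table$accepted))
  }
  comets <- if (length(comet_rows)) do.call(rbind, comet_rows) else
    cbind(data.frame(well = character(), group = character(),
                     image_id = character()), empty_comet_table())
  rownames(comets) <- NULL
  # per-well summaries
  wrec <- lapply(names(per_well), function(well) {
    vals <- comets$percent_tail_dna[comets$well == well & comets$accepted]
    s <- summarize_well(vals)
    data.frame(well = well, group = per_well[[well]]$group[1],
               n_comets = s$n, mean_ptd = s$mean, sd_ptd = s$sd,
               ci_lower = s$ci_lower, ci_upper = s$ci_upper,
               flagged = s$flagged,
               is_peripheral = is_peripheral_well(well))
  })
  wells <- do.call(rbind, wrec)
  rownames(wells) <- NULL
  acc <- comets[comets$accepted, , drop = FALSE]
  plate_mean <- if (nrow(acc)) mean(acc$percent_tail_dna) else NA_real_
  dev <- abs(wells$mean_ptd - plate_mean)
  edge_report <- list(
    peripheral_max_dev = if (any(wells$is_peripheral, na.rm = TRUE))
      max(dev[wells$is_peripheral], na.rm = TRUE) else NA_real_,
    internal_max_dev = if (any(!wells$is_peripheral, na.rm = TRUE))
      max(dev[!wells$is_peripheral], na.rm = TRUE) else NA_real_)
  # group comparisons against the control
  comparisons <- list()
  stats_cfg <- pipe$stats %||% list()
  ctrl <- stats_cfg$control_group
  if (!is.null(ctrl)) {
    if (!ctrl %in% comets$group)
      stop("run_pipeline: control group '", ctrl, "' not present")
    sided <- stats_cfg$sidedness %||% "one"
    ctrl_vals <- acc$percent_tail_dna[acc$group == ctrl]
    for (g in setdiff(unique(acc$group), ctrl)) {
      tv <- acc$percent_tail_dna[acc$group == g]
      if (length(tv) >= 2L && length(ctrl_vals) >= 2L) {
        ct <- compare_groups(tv, ctrl_vals, sidedness = sided)
        comparisons[[length(comparisons) + 1L]] <-
          list(group = g, control = ctrl, t = ct$t, p = ct$p, df = ct$df,
               sidedness = sided)
      }
    }
  }
  reasons <- unlist(strsplit(comets$reasons[!comets$accepted], ";"))
  report <- list(
    n_images = n_images, n_wells = length(per_well),
    candidates = nrow(comets), accepted = sum(comets$accepted),
    rejected_by_reason = as.list(table(reasons)),
    saturated = sum(comets$saturated, na.rm = TRUE),
    plate_mean_ptd = plate_mean,
    edge_report = edge_report,
    comparisons = comparisons)
  write_csv_plain(comets, file.path(out_dir, "comets.csv"))
  write_csv_plain(wells, file.path(out_dir, "wells.csv"))
  jsonlite::write_json(report, file.path(out_dir, "plate_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote %s", file.path(out_dir, c("comets.csv", "wells.csv",
                                       "plate_report.json"))[1])
  invisible(list(report = report, comets = comets, wells = wells,
                 out_dir = out_dir))
}

# Deterministic CSV writer: fixed 15-significant-digit formatting so that
# identical inputs give byte-identical bodies across platforms.
write_csv_plain <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.15g", x)
    out[is.na(x)] <- "NA"
    out
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
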