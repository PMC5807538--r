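# Independent oracle implementations and shared fixtures, deliberately
# written as naive loops so they share no code path with the package.

# Per-pixel scanning-box adaptive threshold (clipped window, sample sd).
naive_adaptive_threshold <- function(img, box_rows, box_cols, k) {
  nr <- nrow(img); nc <- ncol(img)
  hr <- box_rows %/% 2; hc <- box_cols %/% 2
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rs <- max(i - hr, 1):min(i + hr, nr)
    cs <- max(j - hc, 1):min(j + hc, nc)
    v <- img[rs, cs]
    s <- if (length(v) > 1) stats::sd(v) else 0
    out[i, j] <- img[i, j] > mean(v) + k * s
  }
  out
}

# Direct loop convolution with a normalized k x k box, zero padding.
naive_box_smooth <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  h <- k %/% 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rs <- max(i - h, 1):min(i + h, nr)
    cs <- max(j - h, 1):min(j + h, nc)
    out[i, j] <- sum(img[rs, cs]) / (k * k)
  }
  out
}

# Draw a filled disc onto a matrix.
draw_disc <- function(img, r0, c0, radius, level) {
  rr <- row(img); cc <- col(img)
  img[(rr - r0)^2 + (cc - c0)^2 <= radius^2] <- level
  img
}

# A lone candidate built from a fixed-level mask (classification fixtures
# care about object geometry, not thresholding).
single_candidate <- function(img, thr = 0) {
  cfg <- detection_config(min_seed_area = 1)
  cands <- extract_candidates(img, img > thr, cfg)
  stopifnot(length(cands) >= 1)
  cands[[1]]
}

# Match accepted measurements to ground-truth rows by nearest centroid.
match_truth <- function(table, truth) {
  acc <- table[table$accepted, , drop = FALSE]
  idx <- vapply(seq_len(nrow(truth)), function(i) {
    which.min((acc$centroid_row - truth$row_px[i])^2 +
                (acc$centroid_col - truth$col_px[i])^2)
  }, 0L)
  acc[idx, , drop = FALSE]
}
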