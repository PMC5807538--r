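test_that("background fit recovers constants and planes exactly", {
  img <- matrix(13.5, 60, 60)
  msk <- matrix(FALSE, 40, 40); msk[10:20, 10:20] <- TRUE
  s <- fit_background(img, c(0, 0, 40, 40), msk)
  expect_equal(unname(s$coefficients), c(13.5, 0, 0, 0), tolerance = 1e-10)
  expect_equal(s$residual_sd, 0, tolerance = 1e-9)
  # exact bilinear surface with an object hole
  rr <- matrix(0:(49), 50, 50); cc <- t(rr)
  img2 <- 2 + 0.1 * rr + 0.3 * cc
  hole <- matrix(FALSE, 50, 50); hole[20:32, 15:30] <- TRUE
  s2 <- fit_background(img2, c(0, 0, 50, 50), hole)
  expect_equal(unname(s2$coefficients), c(2, 0.1, 0.3, 0), tolerance = 1e-7)
})

test_that("noisy plane fit agrees with a direct normal-equations solve", {
  set.seed(91)
  rr <- matrix(0:39, 40, 40); cc <- t(rr)
  img <- 5 + 0.2 * rr + 0.05 * cc + matrix(rnorm(1600, 0, 2), 40, 40)
  msk <- matrix(FALSE, 40, 40); msk[15:25, 15:25] <- TRUE
  s <- fit_background(img, c(0, 0, 40, 40), msk)
  bg <- !msk
  X <- cbind(1, rr[bg], cc[bg], rr[bg] * cc[bg])
  beta <- solve(t(X) %*% X, t(X) %*% img[bg])
  expect_equal(unname(s$coefficients), as.vector(beta), tolerance = 1e-8)
  # coefficients near the generating plane
  se <- sqrt(diag(solve(t(X) %*% X))) * s$residual_sd
  expect_true(all(abs(s$coefficients - c(5, 0.2, 0.05, 0)) < 3.5 * se))
})

test_that("background fit refuses boxes with too few background pixels", {
  img <- matrix(1, 10, 10)
  msk <- matrix(TRUE, 6, 6); msk[1, 1:4] <- FALSE  # 4 background px
  expect_error(fit_background(img, c(0, 0, 6, 6), msk), "10 background")
})

test_that("background subtraction is exact, clamped, and matches a loop", {
  rr <- matrix(0:19, 20, 20); cc <- t(rr)
  surf <- structure(list(coefficients = c(intercept = 4, row = 0.5,
                                          col = -0.1, `row:col` = 0.02),
                         residual_sd = 0, box = c(0, 0, 20, 20)),
                    class = "background_surface")
  plane <- 4 + 0.5 * rr - 0.1 * cc + 0.02 * rr * cc
  expect_equal(subtract_background(plane, surf), matrix(0, 20, 20))
  disc <- draw_disc(matrix(0, 20, 20), 10, 10, 5, 30)
  expect_equal(subtract_background(plane + disc, surf), disc)
  set.seed(7)
  noisy <- matrix(runif(400, 0, 10), 20, 20)
  got <- subtract_background(noisy, surf)
  ora <- noisy
  for (i in 1:20) for (j in 1:20) ora[i, j] <- max(noisy[i, j] - plane[i, j], 0)
  expect_equal(got, ora)
})

test_that("axial profile conserves intensity and handles point masses", {
  expect_equal(axial_profile(matrix(0, 5, 8)), rep(0, 8))
  m <- matrix(0, 6, 10); m[3, 7] <- 4.5
  expect_equal(axial_profile(m), c(rep(0, 6), 4.5, 0, 0, 0))
  set.seed(3)
  patch <- matrix(runif(600), 20, 30)
  expect_identical(sum(axial_profile(patch)), sum(patch))
})

test_that("markers follow the mirror rule on a rectangular head and shelf", {
  prof <- c(rep(0, 4), rep(100, 10), rep(8, 26), rep(0, 10))
  mk <- locate_markers(prof, noise_floor = 0)
  # brute-force scan oracle: T = 1% of peak; head plateau mirrored about
  # its midpoint; shelf assigned to the tail
  tt <- 0.01 * max(prof)
  above <- which(prof > tt)
  hs <- min(above); te <- max(above)
  plateau <- which(prof == max(prof))
  he <- min(min(plateau) + max(plateau) - hs, te)  # mirror about plateau mid
  expect_identical(unname(mk), c(5L, 14L, 40L))
  expect_identical(as.integer(mk[["head_end"]]), as.integer(he))
  expect_error(locate_markers(rep(0, 30), noise_floor = 0), "no signal")
})

test_that("a symmetric unimodal profile yields an empty tail", {
  chord <- function(c0, R, x) 2 * floor(sqrt(pmax(R^2 - (x - c0)^2, 0))) + 1
  prof <- ifelse(abs(seq_len(41) - 21) <= 9, chord(21, 9, seq_len(41)) * 50, 0)
  mk <- locate_markers(prof, noise_floor = 0)
  patch <- matrix(prof, nrow = 1, ncol = 41, byrow = TRUE)
  m <- measure(patch, mk)
  expect_equal(m$percent_tail_dna, 0)
  expect_equal(m$tail_length_um, 0)
  expect_equal(m$tail_moment, 0)
})

test_that("measurement recovers known region sums and exact identities", {
  # hand-built 20x30 patch: head block sums 700, tail block sums 300
  patch <- matrix(0, 20, 30)
  patch[6:15, 3:9] <- 10     # head: 700
  patch[6:15, 10:24] <- 2    # tail: 300
  mk <- c(head_start = 3L, head_end = 9L, tail_end = 24L)
  m <- measure(patch, mk, scale = 1)
  expect_equal(m$percent_tail_dna, 30)
  expect_equal(m$tail_length_um, 15)
  expect_equal(m$tail_moment, 15 * 30 / 100)
  expect_equal(m$tail_area_px2, sum(patch[, 10:24] > 0))
  expect_false(m$saturated)
  # degenerate empty tail interval
  m0 <- measure(patch, c(head_start = 3L, head_end = 24L, tail_end = 24L))
  expect_equal(m0$percent_tail_dna, 0)
  expect_equal(m0$tail_length_um, 0)
  # identity to machine precision for arbitrary markers
  set.seed(17)
  rpatch <- matrix(runif(300, 0, 5), 10, 30)
  mr <- measure(rpatch, c(head_start = 2L, head_end = 11L, tail_end = 28L),
                scale = 1.7)
  expect_identical(mr$tail_moment,
                   mr$tail_length_um * mr$percent_tail_dna / 100)
})

test_that("full image analysis is deterministic and total on wells", {
  w <- simulate_well(c(0, 25, 55), noise_sd = 1.5,
                     background = c(8, 0.003, 0.001), rng_seed = 13)
  a <- analyze_image(w$image)
  b <- analyze_image(w$image)
  expect_identical(a$table, b$table)
  expect_equal(sum(a$table$accepted), 3)
  acc <- a$table[a$table$accepted, ]
  expect_true(all(acc$head_start <= acc$head_end))
  expect_true(all(acc$head_end <= acc$tail_end))
  expect_true(all(acc$percent_tail_dna >= 0 & acc$percent_tail_dna <= 100))
  # background-only image: nothing accepted
  empty <- render_well(list(), background = c(12, 0, 0), noise_sd = 0)
  expect_equal(nrow(analyze_image(empty$image)$table), 0)
})

test_that("measured percent tail DNA is non-decreasing in tail grey", {
  greys <- seq(10, 140, by = 26)
  meas <- vapply(greys, function(g) {
    sp <- comet_spec(c(76, 76), 12, 200, 12, tail_extent = 60, tail_grey = g)
    rc <- render_comet(sp, smoothing_window = 15)
    res <- analyze_image(image_grid(rc$image$pixels + 10))
    res$table$percent_tail_dna[res$table$accepted][1]
  }, 0)
  expect_true(all(diff(meas) > -1e-9))
})
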