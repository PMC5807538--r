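test_that("tile stitching abuts blocks row-major and validates its input", {
  tile <- matrix(runif(12), 3, 4)
  expect_equal(stitch_tiles(list(tile), c(1, 1))$pixels, tile)
  tiles <- lapply(0:15, function(v) matrix(v, 5, 6))
  mos <- stitch_tiles(tiles, c(4, 4))$pixels
  expect_identical(dim(mos), c(20L, 24L))
  k <- 1
  for (i in 1:4) for (j in 1:4) {
    expect_true(all(mos[(i - 1) * 5 + 1:5, (j - 1) * 6 + 1:6] == k - 1))
    k <- k + 1
  }
  expect_error(stitch_tiles(tiles, c(4, 5)), "16 tiles")
  bad <- tiles; bad[[3]] <- matrix(0, 4, 6)
  expect_error(stitch_tiles(bad, c(4, 4)), "identical dimensions")
})

test_that("stitching then analyzing matches analyzing the mosaic", {
  w <- simulate_well(c(10, 40, 70), noise_sd = 1, background = c(10, 0, 0),
                     rng_seed = 21)
  img <- w$image$pixels
  nr <- nrow(img); nc <- ncol(img)
  nr2 <- nr - nr %% 2; nc2 <- nc - nc %% 2
  img <- img[1:nr2, 1:nc2]
  tiles <- list(img[1:(nr2 / 2), 1:(nc2 / 2)], img[1:(nr2 / 2), (nc2 / 2 + 1):nc2],
                img[(nr2 / 2 + 1):nr2, 1:(nc2 / 2)],
                img[(nr2 / 2 + 1):nr2, (nc2 / 2 + 1):nc2])
  mos <- stitch_tiles(tiles, c(2, 2))
  expect_identical(mos$pixels, img)
  expect_identical(analyze_image(mos)$table,
                   analyze_image(image_grid(img))$table)
})

test_that("well summaries match closed-form Student-t intervals", {
  s <- summarize_well(c(40, 40, 40, 40))
  expect_equal(s$mean, 40); expect_equal(s$sd, 0)
  expect_equal(c(s$ci_lower, s$ci_upper), c(40, 40))
  s2 <- summarize_well(c(10, 20, 30))
  half <- qt(0.975, df = 2) * 10 / sqrt(3)
  expect_equal(s2$mean, 20, tolerance = 1e-12)
  expect_equal(s2$sd, 10, tolerance = 1e-12)
  expect_equal(s2$ci_lower, 20 - half, tolerance = 1e-10)
  expect_equal(s2$ci_upper, 20 + half, tolerance = 1e-10)
  expect_false(s2$flagged)
  s1 <- summarize_well(55)
  expect_true(s1$flagged)
  expect_true(is.na(s1$ci_lower))
})

test_that("group comparison reproduces the pooled-variance formula", {
  treated <- c(60, 62, 58, 61); control <- c(10, 12, 11, 9)
  got <- compare_groups(treated, control, sidedness = "one")
  sp2 <- ((3 * var(treated)) + (3 * var(control))) / 6
  t_hand <- (mean(treated) - mean(control)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(got$t, t_hand, tolerance = 1e-10)
  expect_lt(got$p, 1e-4)
  expect_equal(got$p, pt(t_hand, df = 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # swapped roles: one-sided p flips past 0.5
  expect_gte(compare_groups(control, treated, sidedness = "one")$p, 0.5)
  # identical constant groups: convention t = 0, p = 1, flagged
  z <- compare_groups(c(5, 5, 5), c(5, 5, 5))
  expect_equal(z$t, 0); expect_equal(z$p, 1); expect_true(z$flagged)
  # identical non-degenerate groups: t = 0, two-sided p = 1
  y <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(y$t, 0); expect_equal(y$p, 1)
})

test_that("assay CV matches its definition and guards degenerate input", {
  expect_equal(assay_cv(c(50, 50, 50)), 0)
  expect_equal(assay_cv(c(40, 50, 60)), 100 * 10 / 50)
  expect_error(assay_cv(42), "at least 2")
  expect_error(assay_cv(c(-3, 3)), "mean is zero")
})

test_that("linearity regression matches closed-form least squares", {
  x <- c(0, 10, 20, 40, 80)
  f <- suppressWarnings(validate_linearity(x, x))
  expect_equal(f$r_squared, 1); expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  f2 <- suppressWarnings(validate_linearity(x, 2 * x + 5))
  expect_equal(f2$r_squared, 1); expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 5, tolerance = 1e-10)
  set.seed(8)
  y <- 0.9 * x + rnorm(5)
  f3 <- validate_linearity(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(f3$intercept, f3$slope), as.vector(beta), tolerance = 1e-10)
  resid <- y - X %*% beta
  expect_equal(f3$r_squared, 1 - sum(resid^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_error(validate_linearity(rep(3, 4), 1:4), "constant")
})

test_that("peripheral wells are rows A/H and columns 1/12", {
  expect_true(all(is_peripheral_well(c("A5", "H3", "B1", "C12"))))
  expect_false(any(is_peripheral_well(c("B2", "D7", "G11"))))
})

test_that("the plate pipeline runs end to end, deterministically", {
  dir <- withr::local_tempdir()
  img_dir <- file.path(dir, "imgs"); dir.create(img_dir)
  for (i in 1:2) {
    w <- simulate_well(c(5, 30, 60) + (i - 1) * 5, noise_sd = 1,
                       background = c(10, 0, 0), rng_seed = 30 + i)
    write_image_grid(w$image, file.path(img_dir, sprintf("well%d.tif", i)),
                     max_level = 255)
  }
  write.csv(data.frame(file = c("well1.tif", "well2.tif"),
                       well = c("B2", "B3"),
                       group = c("control", "treated")),
            file.path(dir, "map.csv"), row.names = FALSE)
  cfg <- list(images = img_dir, well_map = file.path(dir, "map.csv"),
              out_dir = file.path(dir, "out"),
              stats = list(control_group = "control", sidedness = "one"))
  yaml::write_yaml(cfg, file.path(dir, "cfg.yaml"))
  res <- run_pipeline(file.path(dir, "cfg.yaml"), quiet = TRUE)
  expect_true(file.exists(file.path(dir, "out", "comets.csv")))
  expect_true(file.exists(file.path(dir, "out", "wells.csv")))
  expect_true(file.exists(file.path(dir, "out", "plate_report.json")))
  comets <- read.csv(file.path(dir, "out", "comets.csv"))
  expect_equal(sum(comets$accepted == "TRUE" | comets$accepted == TRUE),
               res$report$accepted)
  expect_gte(res$report$accepted, 6)  # 6 comets; noise may add fragments
  wells <- read.csv(file.path(dir, "out", "wells.csv"))
  expect_identical(sort(wells$well), c("B2", "B3"))
  expect_length(res$report$comparisons, 1)
  # byte-identical rerun
  body1 <- readBin(file.path(dir, "out", "comets.csv"), "raw", 1e6)
  run_pipeline(file.path(dir, "cfg.yaml"), quiet = TRUE)
  body2 <- readBin(file.path(dir, "out", "comets.csv"), "raw", 1e6)
  expect_identical(body1, body2)
  # empty image directory fails fast
  cfg2 <- cfg; cfg2$images <- file.path(dir, "none")
  yaml::write_yaml(cfg2, file.path(dir, "cfg2.yaml"))
  expect_error(run_pipeline(file.path(dir, "cfg2.yaml"), quiet = TRUE),
               "no inputs")
})

test_that("an edge-offset plate shows larger peripheral deviation", {
  # peripheral wells rendered with +5 points of damage
  mk_vals <- function(base) base + c(-0.6, 0.2, 0.5, -0.1)
  wells <- list(A1 = mk_vals(45), H12 = mk_vals(45.5),
                B2 = mk_vals(40), C3 = mk_vals(40.3),
                D4 = mk_vals(39.8), E6 = mk_vals(40.1))
  means <- vapply(wells, function(v) summarize_well(v)$mean, 0)
  periph <- is_peripheral_well(names(wells))
  plate_mean <- mean(unlist(wells))
  dev <- abs(means - plate_mean)
  expect_gt(max(dev[periph]), max(dev[!periph]))
})
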