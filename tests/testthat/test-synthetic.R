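test_that("ground truth identities hold exactly for generated specs", {
  targets <- c(0, 5, 17.5, 30, 42, 55, 63, 80, 92)
  for (p in targets) {
    sp <- spec_for_target(p)
    gt <- ground_truth(sp)
    expect_equal(gt$true_tail_moment,
                 gt$true_tail_length_um * gt$true_percent_tail_dna / 100)
    expect_lte(abs(gt$true_percent_tail_dna - p), 0.5)
    expect_lte(sp$tail_grey, sp$head_grey)
  }
  expect_identical(spec_for_target(0)$tail_extent, 0)
  expect_identical(ground_truth(spec_for_target(0))$true_percent_tail_dna, 0)
})

test_that("target solving matches a brute-force pixel-sum oracle", {
  # the fixed-geometry case: head radius 12, tail semi-minor 12, tail 30 px
  sp <- spec_for_target(30, geometry = list(head_radius = 12,
                                            tail_semi_minor = 12,
                                            tail_extent = 30))
  expect_equal(sp$tail_extent, 30)
  canvas <- c(151, 201)
  sp$head_center <- c(75, 60)
  m <- cometscore:::comet_masks(sp, canvas)
  s_head <- length(m$head) * sp$head_grey
  s_tail <- length(m$tail) * sp$tail_grey
  expect_equal(100 * s_tail / (s_head + s_tail), 30, tolerance = 1e-12)
  # equal region sums at 50%: tail_grey * area_tail == head_grey * area_head
  sp50 <- spec_for_target(50, geometry = list(tail_extent = 30))
  a <- cometscore:::region_areas(12, 12, 30)
  expect_equal(sp50$tail_grey * a[["tail"]], sp50$head_grey * a[["head"]])
})

test_that("unreachable targets raise an infeasibility error", {
  expect_error(spec_for_target(95, geometry = list(max_tail_extent = 60)),
               "unreachable")
  expect_error(spec_for_target(80, geometry = list(tail_extent = 10)),
               "unreachable")
  expect_error(spec_for_target(99), "\\[0, 95\\]")
})

test_that("rendering with a unit window reproduces the raw drawing", {
  sp <- spec_for_target(40)
  rc <- render_comet(sp, smoothing_window = 1)
  canvas <- dim(rc$image$pixels)
  m <- cometscore:::comet_masks(sp, canvas)
  raw <- matrix(0, canvas[1], canvas[2])
  raw[m$head] <- sp$head_grey
  raw[m$tail] <- sp$tail_grey
  expect_equal(rc$image$pixels, raw)
})

test_that("box smoothing conserves total intensity and matches a loop oracle", {
  sp <- spec_for_target(35)
  raw <- render_comet(sp, smoothing_window = 1)$image$pixels
  sm <- render_comet(sp, smoothing_window = 15)$image$pixels
  expect_lt(abs(sum(sm) - sum(raw)) / sum(raw), 0.001)
  # oracle equality on a small random field
  set.seed(201)
  f <- matrix(runif(30 * 22, 0, 10), 30, 22)
  expect_equal(cometscore:::box_smooth(f, 5), naive_box_smooth(f, 5),
               tolerance = 1e-9)
})

test_that("true percent tail DNA increases strictly with tail grey", {
  vals <- vapply(seq(5, 200, by = 15), function(g) {
    sp <- comet_spec(c(50, 30), 12, 200, 12, tail_extent = 40, tail_grey = g)
    ground_truth(sp)$true_percent_tail_dna
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("a spec violating the smoothing margin is rejected", {
  sp <- comet_spec(c(10, 10), 8, 200)  # 2 px from the border
  expect_error(render_comet(sp, canvas = c(40, 40)), "margin")
})

test_that("well rendering is reproducible and honest about overlaps", {
  specs <- lapply(c(0, 20, 45, 65, 80), spec_for_target)
  a <- render_well(specs, grid_pitch = c(60, 320), noise_sd = 3, rng_seed = 7)
  b <- render_well(specs, grid_pitch = c(60, 320), noise_sd = 3, rng_seed = 7)
  expect_identical(a$image$pixels, b$image$pixels)
  d <- render_well(specs, grid_pitch = c(60, 320), noise_sd = 3, rng_seed = 8)
  expect_false(identical(a$image$pixels, d$image$pixels))
  # background-only well: flat value everywhere
  e <- render_well(list(), background = c(7, 0, 0), noise_sd = 0)
  expect_true(all(e$image$pixels == 7))
  # deliberate overlap -> warning naming the colliding pair
  s2 <- lapply(c(0, 0), spec_for_target)
  expect_warning(
    render_well(s2, positions = rbind(c(100, 100), c(100, 112)),
                noise_sd = 0, rng_seed = 1),
    "overlap.*1-2")
})

test_that("all intensities from the generator are finite and non-negative", {
  w <- simulate_well(c(0, 30, 60), noise_sd = 5,
                     background = c(2, 0.01, -0.001), rng_seed = 3)
  expect_true(all(is.finite(w$image$pixels)))
  expect_true(all(w$image$pixels >= 0))
  expect_equal(w$truth$true_tail_moment,
               w$truth$true_tail_length_um * w$truth$true_percent_tail_dna / 100)
})
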