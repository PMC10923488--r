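test_that("fixation rendering is linear in duration and respects the kernel support", {
  shape <- c(64L, 64L)
  # empty input yields the zero map, not an error
  empty <- render_from_fixations(fix_df(numeric(0), numeric(0), numeric(0)),
                                 shape, radius = 10)
  expect_true(all(empty$grid == 0))
  expect_identical(empty$stage, "raw")

  # a single centred fixation: argmax at the fixation pixel, support within
  # the kernel radius, radially symmetric
  one <- render_from_fixations(fix_df(32, 32, 1000), shape, radius = 10)
  g <- unclass(one$grid)
  expect_equal(which(g == max(g), arr.ind = TRUE)[1, ], c(row = 33, col = 33))
  nz <- which(g > 0, arr.ind = TRUE)
  expect_true(all(sqrt((nz[, 1] - 33)^2 + (nz[, 2] - 33)^2) <= 10))
  expect_equal(g[33 + 5, 33], g[33 - 5, 33])
  expect_equal(g[33, 33 + 5], g[33 + 5, 33])

  # linearity: durations 200 + 300 at one pixel equal 500/200 of a single
  # 200 ms fixation (direct-summation oracle)
  two <- render_from_fixations(fix_df(c(20, 20), c(40, 40), c(200, 300)),
                               shape, radius = 10)
  base <- render_from_fixations(fix_df(20, 40, 200), shape, radius = 10)
  expect_equal(unclass(two$grid), unclass(base$grid) * (500 / 200))

  # total mass proportional to summed duration when no kernel is clipped
  m1 <- render_from_fixations(fix_df(30, 30, 400), shape, radius = 10)
  m2 <- render_from_fixations(fix_df(c(30, 45), c(30, 20), c(400, 800)),
                              shape, radius = 10)
  expect_equal(sum(m2$grid) / sum(m1$grid), 3, tolerance = 1e-12)

  expect_error(render_from_fixations(fix_df(64, 10, 100), shape, radius = 10),
               "outside grid")
  expect_error(render_from_fixations(fix_df(10, 10, 0), shape, radius = 10),
               "positive")
})

test_that("averaging is the elementwise mean and validates its inputs", {
  m <- amap(matrix(c(1, 2, 3, 4), 2))
  expect_equal(unclass(average_maps(list(m, m, m))$grid), unclass(m$grid))
  zero <- amap(matrix(0, 2, 2))
  expect_equal(unclass(average_maps(list(m, zero))$grid), unclass(m$grid) / 2)

  g1 <- matrix(c(1, 0, 2, 5), 2); g2 <- matrix(c(3, 3, 0, 1), 2)
  g3 <- matrix(c(2, 6, 4, 0), 2)
  got <- average_maps(list(amap(g1), amap(g2), amap(g3)))
  expect_equal(unclass(got$grid), (g1 + g2 + g3) / 3)
  expect_identical(got$participant_id, "GROUP_AVG")

  expect_error(average_maps(list()), "empty")
  expect_error(average_maps(list(amap(g1), amap(matrix(0, 3, 3)))), "shapes")
  expect_error(average_maps(list(amap(g1, image = "A"),
                                 amap(g2, image = "B"))), "images")
})

test_that("common attention pools all participant-image maps of one group", {
  g <- matrix(1:4, 2)
  maps <- list(amap(g, "P1", image = "A"), amap(g, "P1", image = "B"),
               amap(g, "P2", image = "A"), amap(g, "P2", image = "B"))
  com <- common_attention(maps)
  expect_equal(unclass(com$grid), g + 0)  # identical inputs -> that map
  expect_identical(com$image_id, "COMMON")

  grids <- list(matrix(c(4, 0, 2, 2), 2), matrix(c(0, 8, 0, 0), 2),
                matrix(c(1, 1, 1, 1), 2), matrix(c(3, 3, 5, 1), 2))
  maps2 <- Map(function(gr, p, im) amap(gr, p, image = im), grids,
               c("P1", "P1", "P2", "P2"), c("A", "B", "A", "B"))
  expect_equal(unclass(common_attention(maps2)$grid),
               Reduce(`+`, grids) / 4)
  # k = 1 passthrough
  expect_equal(unclass(common_attention(maps2[1])$grid), grids[[1]])
  expect_error(common_attention(list(amap(g), amap(g, group = "nonclinician"))),
               "single group")
})

test_that("common-attention subtraction clips at zero and checks groups", {
  m <- amap(matrix(c(5, 1, 3, 2), 2))
  sub <- subtract_common(m, m)
  expect_true(all(sub$grid == 0))
  expect_identical(sub$stage, "common_subtracted")

  zero <- amap(matrix(0, 2, 2))
  expect_true(all(subtract_common(zero, m)$grid == 0))

  com <- amap(matrix(c(2, 2, 2, 2), 2), "GROUP_AVG", image = "COMMON")
  got <- subtract_common(m, com)
  expect_equal(unclass(got$grid), matrix(c(3, 0, 1, 0), 2))

  expect_error(subtract_common(m, amap(matrix(1, 2, 2),
                                       group = "nonclinician")),
               "group mismatch")
})

test_that("averaging and subtracting commute when nothing clips", {
  set.seed(42)
  for (rep in 1:10) {
    common_g <- matrix(runif(36, 0, 0.5), 6)
    maps <- lapply(1:4, function(i)
      amap(common_g + matrix(runif(36), 6), paste0("P", i)))
    com <- amap(common_g, "GROUP_AVG", image = "COMMON")
    a <- subtract_common(average_maps(maps), com)
    b <- average_maps(lapply(maps, subtract_common, common = com))
    expect_equal(unclass(a$grid), unclass(b$grid), tolerance = 1e-12)
  }
})

test_that("box smoothing shrinks at edges, preserves the max, and is exact on a 3x3 window", {
  m <- amap(matrix(runif(25), 5))
  expect_equal(unclass(smooth_map(m, 1)$grid), unclass(m$grid))
  const <- amap(matrix(2, 5, 5))
  expect_equal(unclass(smooth_map(const, 3)$grid), matrix(2, 5, 5))

  g <- matrix(1:9, 3, byrow = TRUE)
  sm <- smooth_map(amap(g), 3)
  # direct window means with shrink-to-valid edges
  win <- function(i, j) {
    rr <- max(1, i - 1):min(3, i + 1); cc <- max(1, j - 1):min(3, j + 1)
    mean(g[rr, cc])
  }
  raw <- outer(1:3, 1:3, Vectorize(win))
  expect_equal(unclass(sm$grid), raw * (max(g) / max(raw)), tolerance = 1e-12)
  expect_equal(max(sm$grid), max(g))
  expect_error(smooth_map(m, 4), "odd")
})

test_that("noise thresholding keeps original values and is monotone in the cutoff", {
  g <- matrix(1:9, 3)
  m <- amap(g, stage = "smoothed")
  expect_equal(unclass(apply_noise_threshold(m, threshold_spec("absolute", 0))$grid),
               g + 0)
  expect_true(all(apply_noise_threshold(
    m, threshold_spec("absolute", 10))$grid == 0))
  t5 <- apply_noise_threshold(m, threshold_spec("absolute", 5))
  expect_equal(sum(t5$grid > 0), 5L)   # counting oracle: values 5..9 survive
  expect_equal(sort(unclass(t5$grid)[t5$grid > 0]), 5:9)
  expect_identical(t5$stage, "thresholded_low")

  # monotone coverage in the absolute cutoff
  counts <- vapply(seq(0, 10, by = 0.5), function(t)
    sum(apply_noise_threshold(m, threshold_spec("absolute", t))$grid > 0),
    numeric(1))
  expect_true(all(diff(counts) <= 0))

  # fraction-of-max resolves against the map maximum
  fm <- apply_noise_threshold(m, threshold_spec("fraction_of_max", 0.5))
  expect_equal(sum(fm$grid > 0), sum(g >= 4.5))

  expect_error(
    apply_noise_threshold(m, threshold_spec("coverage_fraction", 0.1)),
    "face_mask")
  mk <- full_mask(3, 3)
  cv <- apply_noise_threshold(m, threshold_spec("coverage_fraction", 4 / 9),
                              mask = mk, level = "high")
  expect_equal(sum(cv$grid > 0), 4L)
  expect_identical(cv$stage, "thresholded_high")
})

test_that("stages only move forward", {
  m <- amap(matrix(1:4, 2), stage = "smoothed")
  expect_error(subtract_common(m, amap(matrix(0, 2, 2), "GROUP_AVG",
                                       image = "COMMON")),
               "backwards")
  expect_error(threshold_spec("coverage_fraction", 1.5), "<= 1")
})
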