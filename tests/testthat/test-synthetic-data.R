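test_that("layout generation is deterministic, seed-sensitive, and geometrically sane", {
  l1 <- generate_layout(5)
  l2 <- generate_layout(5)
  expect_identical(l1, l2)
  expect_identical(l1$shape, c(720L, 720L))
  l3 <- generate_layout(6)
  expect_false(identical(l1$landmarks, l3$landmarks))

  # landmarks inside the face mask; mask area within 20-80% of the frame
  frac <- l1$mask$area / prod(l1$shape)
  expect_gt(frac, 0.2); expect_lt(frac, 0.8)
  for (lm in l1$landmarks) {
    expect_true(l1$mask$mask[round(lm["y"]) + 1, round(lm["x"]) + 1])
  }
  # study image set: 10 affected + 6 unaffected
  expect_equal(sum(l1$images$affected), 10)
  expect_equal(nrow(l1$images), 16)
  expect_setequal(names(l1$feature_regions),
                  l1$images$image_id[l1$images$affected])
})

test_that("cohorts are reproducible and participant substreams are stable under growth", {
  layout <- generate_layout(2, c(120L, 120L), 2L, 1L)
  c1 <- generate_cohort(layout, 3L, 3L, seed = 9, radius = 5, render = FALSE)
  c2 <- generate_cohort(layout, 3L, 3L, seed = 9, radius = 5, render = FALSE)
  expect_identical(c1, c2)
  # adding participants never perturbs existing ones
  c3 <- generate_cohort(layout, 5L, 3L, seed = 9, radius = 5, render = FALSE)
  keep <- c3$fixations$participant_id %in% unique(c1$fixations$participant_id)
  grown <- c3$fixations[keep, ]
  rownames(grown) <- NULL
  expect_identical(grown, c1$fixations)

  # conservation: every participant sees every image once
  expect_equal(nrow(c1$responses), 6 * nrow(layout$images))
  expect_false(anyDuplicated(paste(c1$responses$participant_id,
                                   c1$responses$image_id)) > 0)
  # fixation invariants: inside frame, inside the viewing window
  fx <- c1$fixations
  expect_true(all(fx$x >= 0 & fx$x < 120 & fx$y >= 0 & fx$y < 120))
  expect_true(all(fx$duration_ms > 0))
  expect_true(all(fx$onset_ms + fx$duration_ms <= 7000))

  # accuracy 1 -> all responses correct
  prof <- gaze_profile(c(left_eye = 0.5, mouth = 0.5), accuracy = 1)
  call <- generate_cohort(layout, 2L, 2L, prof, prof, seed = 1,
                          radius = 5, render = FALSE)
  expect_true(all(call$responses$response_affected ==
                  call$responses$truth_affected))
})

test_that("empirical fixation mixtures converge to the profile weights", {
  layout <- generate_layout(1, c(240L, 240L), 1L, 0L)
  w <- c(left_eye = 0.2, right_eye = 0.2, nose = 0.2, mouth = 0.2,
         feature = 0.2)
  prof <- gaze_profile(w, sigma_frac = 0.01, n_fixations = 50,
                       idiosyncrasy = 0, accuracy = 1)
  co <- generate_cohort(layout, 100L, 1L, prof, prof, seed = 4,
                        radius = 6, render = FALSE)
  fx <- co$fixations[co$fixations$group == "clinician", ]
  expect_gt(nrow(fx), 4000)
  cen <- rbind(do.call(rbind, layout$landmarks),
               feature = layout$feature_regions[[1]]$center)
  nearest <- apply(as.matrix(fx[, c("x", "y")]), 1, function(p)
    which.min((cen[, 1] - p[1])^2 + (cen[, 2] - p[2])^2))
  obs <- tabulate(nearest, nbins = nrow(cen))
  expected <- c(0.2, 0.2, 0.2, 0.2, 0, 0, 0, 0, 0.2)
  keep <- expected > 0
  p <- suppressWarnings(stats::chisq.test(obs[keep],
                                          p = expected[keep]))$p.value
  expect_gt(p, 0.01)
  expect_equal(sum(obs[!keep]), 0)
})

test_that("response accuracy converges to the profile accuracy", {
  layout <- generate_layout(3, c(100L, 100L), 3L, 2L)
  prof <- gaze_profile(c(left_eye = 0.5, nose = 0.25, feature = 0.25),
                       accuracy = 0.769)
  co <- generate_cohort(layout, 40L, 1L, prof, prof, seed = 8,
                        radius = 5, render = FALSE)
  r <- co$responses[co$responses$group == "clinician", ]
  phat <- mean(r$response_affected == r$truth_affected)
  n <- nrow(r)
  ci <- 0.769 + c(-1, 1) * 3 * sqrt(0.769 * 0.231 / n)
  expect_gt(phat, ci[1]); expect_lt(phat, ci[2])
})

test_that("identical group profiles make the group-average maps converge as n grows", {
  prof <- default_profiles()$clinician
  iou_at_n <- function(n, seed) {
    layout <- generate_layout(seed, c(160L, 160L), 2L, 0L)
    co <- generate_cohort(layout, n, n, prof, prof, seed = seed, radius = 6)
    grp <- vapply(co$maps, function(m) m$group, character(1))
    iid_of <- vapply(co$maps, function(m) m$image_id, character(1))
    mean(vapply(layout$images$image_id, function(iid) {
      avg <- function(g) Reduce(`+`, lapply(
        co$maps[grp == g & iid_of == iid],
        function(m) unclass(m$grid))) / n
      map_iou(coverage_threshold(avg("clinician"), layout$mask, 0.07),
              coverage_threshold(avg("nonclinician"), layout$mask, 0.07))
    }, numeric(1)))
  }
  small <- mean(vapply(1:3, function(s) iou_at_n(3L, s), numeric(1)))
  large <- mean(vapply(1:3, function(s) iou_at_n(20L, s), numeric(1)))
  expect_gt(large, small)
  expect_gt(large, 0.25)
})

test_that("the toy study bundles coherent ground truth and concentrated saliency", {
  study <- generate_toy_study(seed = 11, n_affected = 2L, n_unaffected = 1L,
                              n_clin = 2L, n_nonclin = 2L)
  expect_equal(length(study$cohort$maps), 4 * 3)
  expect_equal(sort(unique(study$cohort$responses$participant_id)),
               c("C01", "C02", "N01", "N02"))
  expect_setequal(study$bundle$labels,
                  c(names(study$layout$feature_regions), "unaffected"))

  # occlusion saliency concentrates its mass inside the known feature region
  iid <- names(study$layout$feature_regions)[1]
  s <- occlusion_saliency(study$bundle$images[[iid]],
                          study$bundle$classifiers[[1]],
                          study$bundle$truth[[iid]], image_id = iid)
  fr <- study$layout$feature_regions[[iid]]
  H <- study$layout$shape[1]; W <- study$layout$shape[2]
  x <- matrix(rep(0:(W - 1), each = H), H, W)
  y <- matrix(rep(0:(H - 1), times = W), H, W)
  inreg <- (x - fr$center[1])^2 + (y - fr$center[2])^2 <= fr$radius^2
  g <- unclass(s$grid)
  expect_gte(sum(g[inreg]) / sum(g), 0.8)

  # the ensemble classifiers rank the true label first on each image
  for (iid2 in names(study$bundle$images)) {
    p <- study$bundle$classifiers[[2]]$predict(study$bundle$images[[iid2]])
    expect_equal(names(which.max(p)), unname(study$bundle$truth[[iid2]]))
  }
})
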