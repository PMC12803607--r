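test_that("ROI detection finds planted geometry exactly", {
  # uniform near-white image -> no tissue
  blank <- array(245L, dim = c(40, 40, 3))
  expect_equal(sum(detect_roi(blank)), 0)

  # one 10x10 coloured square on white -> ROI of exactly 100 pixels
  img <- array(250L, dim = c(50, 50, 3))
  img[21:30, 21:30, 1] <- 180L
  img[21:30, 21:30, 2] <- 60L
  img[21:30, 21:30, 3] <- 70L
  roi <- detect_roi(img)
  expect_equal(sum(roi), 100)
  expect_true(all(roi[21:30, 21:30]))

  expect_error(detect_roi(img, background_distance_threshold = 0), "> 0")
})

test_that("ROI covers essentially all truth tissue on a generated slide", {
  s <- add_artifacts(small_slide(seed = 31), 3, 1, seed = 32)
  roi <- detect_roi(s$pixels)
  truth_tissue <- s$truth_mask != 0
  expect_gte(mean(roi[truth_tissue]), 0.99)
})

test_that("classifier training reproduces means, priors, pooled covariance", {
  # two extreme classes: means recovered exactly
  ext <- data.frame(
    r = c(rep(0, 10), rep(255, 10)),
    g = c(rep(0, 10), rep(255, 10)),
    b = c(rep(0, 10), rep(255, 10)),
    label = rep(c("background", "muscle"), each = 10)
  )
  clf <- train_classifier(pixel_training_set(ext))
  expect_equal(unname(clf$class_means$background), c(0, 0, 0))
  expect_equal(unname(clf$class_means$muscle), c(255, 255, 255))

  # equal priors with 3 classes
  s <- small_slide(seed = 41)
  clf3 <- train_classifier(sample_training_pixels(s, 50, seed = 42), "equal")
  expect_equal(unname(clf3$priors), rep(1 / 3, 3))
  expect_equal(sum(clf3$priors), 1, tolerance = 1e-12)

  # pooled covariance equals the hand formula on a small toy set
  toy <- withr::with_seed(99, data.frame(
    r = sample(0:20, 30, replace = TRUE),
    g = sample(0:20, 30, replace = TRUE),
    b = sample(0:20, 30, replace = TRUE),
    label = rep(c("background", "muscle", "fibrosis"), each = 10)
  ))
  clf_toy <- train_classifier(pixel_training_set(toy))
  X <- as.matrix(toy[, 1:3])
  pooled <- matrix(0, 3, 3)
  for (k in unique(toy$label)) {
    Xi <- X[toy$label == k, , drop = FALSE]
    d <- sweep(Xi, 2, colMeans(Xi))
    pooled <- pooled + t(d) %*% d
  }
  pooled <- pooled / (nrow(X) - 3)
  expect_equal(unname(clf_toy$shared_covariance), unname(pooled),
               tolerance = 1e-10)
})

test_that("midpoint ties go to the earlier class in the fixed order", {
  tr <- data.frame(
    r = c(rep(0, 20), rep(200, 20), rep(100, 20)),
    g = c(rep(0, 20), rep(200, 20), rep(250, 20)),
    b = c(rep(0, 20), rep(200, 20), rep(250, 20)),
    label = rep(c("background", "muscle", "fibrosis"), each = 20)
  )
  clf <- train_classifier(pixel_training_set(tr))
  clf$shared_covariance <- diag(25, 3)  # isotropic: midpoint is a true tie
  mid <- array(100L, dim = c(1, 1, 3))  # midpoint of background and muscle
  roi <- matrix(TRUE, 1, 1)
  lab <- classify_pixels(mid, roi, clf)
  expect_equal(lab[1, 1], 0)  # background < muscle in the class order
})

test_that("classification is near-perfect on well-separated palettes", {
  s <- small_slide(cvf = 35, area = 0.4, seed = 51)
  clf <- trained_clf(s, seed = 52)
  roi <- detect_roi(s$pixels)
  lab <- classify_pixels(s$pixels, roi, clf)
  acc <- mean(lab[roi] == s$truth_mask[roi])
  expect_gte(acc, 0.99)

  # resubstitution on the training pixels themselves
  tr <- sample_training_pixels(s, 300, seed = 53)
  X <- as.matrix(tr$samples[, c("r", "g", "b")])
  codes <- c(background = 0L, muscle = 1L, fibrosis = 2L)
  pred <- fibrosurv:::discriminant_argmax(X, clf)
  expect_gte(mean(pred == codes[tr$samples$label]), 0.99)
})

test_that("classify_pixels validates shapes and class coverage", {
  s <- small_slide(seed = 61)
  clf <- trained_clf(s)
  expect_error(classify_pixels(s$pixels, matrix(TRUE, 2, 2), clf),
               "dimensions differ")
  clf2 <- clf
  clf2$classes <- clf$classes[1:2]
  expect_error(classify_pixels(s$pixels, detect_roi(s$pixels), clf2),
               "canonical classes")
})

test_that("postprocess removes sub-element speckle and small components", {
  # a single isolated tissue pixel disappears under radius-1 opening
  lab <- matrix(0L, 21, 21)
  lab[11, 11] <- 1L
  out <- postprocess(lab, min_fragment_area_px = 0, opening_radius_px = 1)
  expect_equal(sum(out), 0)

  # area threshold boundary: area-1 removed, exact area retained
  lab2 <- matrix(0L, 30, 30)
  lab2[5:8, 5:8] <- 1L    # 16 px component
  lab2[20:22, 20:24] <- 1L  # 15 px component
  out2 <- postprocess(lab2, min_fragment_area_px = 16, opening_radius_px = 0)
  expect_equal(sum(out2[5:8, 5:8] == 1), 16)
  expect_equal(sum(out2[20:22, 20:24] == 1), 0)
})

test_that("postprocess is idempotent on classified slides", {
  for (seed in c(71, 72)) {
    s <- add_artifacts(small_slide(cvf = 25, seed = seed), 4, 2,
                       seed = seed + 1)
    clf <- trained_clf(s, seed = seed + 2)
    lab <- classify_pixels(s$pixels, detect_roi(s$pixels), clf)
    p1 <- postprocess(lab, 50, 1)
    p2 <- postprocess(p1, 50, 1)
    expect_identical(p1, p2)
  }
})

test_that("areas convert pixel counts to mm2 and partition the image", {
  lab <- matrix(0L, 100, 50)
  lab[1:20, 1:50] <- 2L  # 1000 fibrosis px
  seg <- compute_areas(lab, resolution_um_per_px = 10)
  expect_equal(seg$areas$mm2[seg$areas$class == "fibrosis"], 0.1)
  expect_equal(sum(seg$areas$pixels), 100 * 50)

  empty <- compute_areas(matrix(0L, 5, 5), 4)
  expect_equal(empty$areas$mm2[empty$areas$class != "background"], c(0, 0))
})

test_that("the CVF formula excludes background and guards empty tissue", {
  expect_equal(compute_cvf(0, 10), 0)
  expect_equal(compute_cvf(10, 0), 100)
  expect_equal(compute_cvf(32, 68), 32)
  expect_error(compute_cvf(0, 0), "no tissue")
  expect_error(compute_cvf(-1, 5), ">= 0")
})

test_that("quality filter excludes small fragments with recorded reasons", {
  mk <- function(px_fib, px_mus, id) {
    lab <- matrix(0L, 200, 200)
    if (px_mus > 0) lab[seq_len(px_mus)] <- 1L
    if (px_fib > 0) lab[px_mus + seq_len(px_fib)] <- 2L
    compute_areas(lab, resolution_um_per_px = 10, fragment_id = id)
  }
  # 19000 px * 100 um2 = 1.9 mm2 < 2.0 -> excluded
  frags <- list(mk(9000, 10000, "f1"), mk(10000, 15000, "f2"))
  qf <- quality_filter(frags, min_tissue_mm2 = 2.0)
  expect_length(qf$retained, 1)
  expect_equal(qf$exclusions$fragment_id, "f1")
  expect_match(qf$exclusions$reason, "below minimum")

  qf2 <- quality_filter(frags, min_tissue_mm2 = 0.25)
  expect_length(qf2$retained, 2)
  expect_equal(nrow(qf2$exclusions), 0)

  # zero retained fragments: patient CVF undefined
  expect_error(aggregate_patient("P1", list()), "no retained fragments")
})

test_that("patient aggregation pools areas, not per-fragment CVFs", {
  mk <- function(fib_mm2, mus_mm2, id) {
    # 10 um/px -> 1 px = 1e-4 mm2
    lab <- matrix(0L, 400, 400)
    lab[seq_len(mus_mm2 * 1e4)] <- 1L
    lab[mus_mm2 * 1e4 + seq_len(fib_mm2 * 1e4)] <- 2L
    compute_areas(lab, 10, fragment_id = id)
  }
  f13 <- mk(1, 3, "a"); f62 <- mk(6, 2, "b")
  pc <- aggregate_patient("P1", list(f13, f62))
  expect_equal(pc$cvf_percent, 100 * 7 / 12, tolerance = 1e-9)
  # pooling, not averaging: mean of per-fragment CVFs would be 50
  expect_false(isTRUE(all.equal(pc$cvf_percent, 50)))

  single <- aggregate_patient("P2", list(f13))
  expect_equal(single$cvf_percent, 25)

  swapped <- aggregate_patient("P1", list(f62, f13))
  expect_equal(swapped$cvf_percent, pc$cvf_percent)

  expect_equal(pc$qc_flag, "ok")
  tiny <- aggregate_patient("P3", list(mk(0.2, 0.6, "c")))
  expect_equal(tiny$qc_flag, "insufficient_tissue")
})

test_that("pure-background margin leaves measured CVF unchanged", {
  s <- small_slide(cvf = 30, area = 0.3, seed = 81)
  clf <- trained_clf(s, seed = 82)
  seg <- quantify_slide(s, clf)
  cvf1 <- compute_cvf(class_mm2_test(seg, "fibrosis"),
                      class_mm2_test(seg, "muscle"))

  pad <- 30
  d <- dim(s$pixels)
  big <- s
  withr::with_seed(83, {
    big$pixels <- array(0L, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, 3))
    for (ch in 1:3) {
      plane <- matrix(as.integer(pmin(pmax(round(
        rnorm((d[1] + 2 * pad) * (d[2] + 2 * pad), 245, 4)), 0), 255)),
        d[1] + 2 * pad, d[2] + 2 * pad)
      plane[pad + seq_len(d[1]), pad + seq_len(d[2])] <- s$pixels[, , ch]
      big$pixels[, , ch] <- plane
    }
    big$truth_mask <- matrix(0L, d[1] + 2 * pad, d[2] + 2 * pad)
    big$truth_mask[pad + seq_len(d[1]), pad + seq_len(d[2])] <- s$truth_mask
  })
  seg2 <- quantify_slide(big, clf)
  cvf2 <- compute_cvf(class_mm2_test(seg2, "fibrosis"),
                      class_mm2_test(seg2, "muscle"))
  expect_lt(abs(cvf2 - cvf1), 0.1)
})
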