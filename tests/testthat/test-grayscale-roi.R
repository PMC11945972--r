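test_that("histogram counts pixels per gray level", {
  expect_equal(compute_histogram(matrix(0, 2, 2)),
               c(4L, rep(0L, 255)))
  h <- compute_histogram(matrix(c(10, 10, 200), 1))
  expect_equal(h[11], 2L)
  expect_equal(h[201], 1L)
  expect_equal(sum(h), 3L)

  # a sharp synthetic eye has a spike at the pupil gray
  sc <- render_scene(scene_params(seed = 11, noise_std = 0,
                                  boundary_roughness = 0, n_glints = 0))
  h <- compute_histogram(sc$image)
  expect_equal(sum(h), 640L * 480L)
  expect_gt(h[21], 5000)  # pupil gray 20 occupies the pupil's full area
})

test_that("valley threshold lands between the two modes of a bimodal histogram", {
  counts <- integer(256)
  counts[16:26] <- round(4000 / 11)     # grays 15-25
  counts[141:161] <- round(36000 / 21)  # grays 140-160
  T <- histogram_valley_threshold(counts, smooth_window = 5)
  expect_gt(T, 25)
  expect_lt(T, 140)

  # brute-force oracle: smooth independently and verify T is the first gray
  # level attaining the minimum smoothed count between the two modes
  sm <- sapply(1:256, function(g)
    mean(counts[max(1, g - 2):min(256, g + 2)]))
  between <- 27:140                    # grays 26..139, strictly between modes
  inter_min <- min(sm[between])
  expect_equal(sm[T + 1L], inter_min)
  expect_equal(T, between[which(sm[between] == inter_min)][1L] - 1L)
})

test_that("unimodal histograms have no valley and trigger the fallback", {
  counts <- integer(256)
  counts[101:121] <- 500
  expect_error(histogram_valley_threshold(counts), class = "noValleyFound")
  # fallback picks the smallest gray reaching 5% cumulative mass
  # (5% of 21 * 500 = 525, so the first bin alone is not enough)
  expect_equal(pupilloc:::fallback_threshold(counts), 101L)
})

test_that("valley threshold separates pupil from iris on a sharp scene", {
  sc <- render_scene(scene_params(seed = 21))
  T <- histogram_valley_threshold(compute_histogram(sc$image))
  expect_gte(T, 20)   # every pre-blur pupil gray is below the threshold
  expect_lt(T, 90)    # the iris gray stays above it
})

test_that("binarization is inclusive at the threshold", {
  expect_true(all(binarize(matrix(sample(0:255, 20), 4, 5), 255)))
  expect_false(any(binarize(matrix(c(1, 5, 9), 1), 0)))
  expect_equal(as.vector(binarize(matrix(c(10, 50, 90), 1), 50)),
               c(TRUE, TRUE, FALSE))
})

test_that("integral projection counts foreground per row and column", {
  m <- matrix(FALSE, 10, 10)
  m[3:5, 4:8] <- TRUE   # rows 2-4, cols 3-7 in 0-based terms
  p <- integral_projection(m)
  expect_equal(p$row_counts, c(0L, 0L, 5L, 5L, 5L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(p$col_counts, c(0L, 0L, 0L, 3L, 3L, 3L, 3L, 3L, 0L, 0L))
  expect_equal(integral_projection(matrix(FALSE, 3, 3))$row_counts, c(0L, 0L, 0L))

  # conservation: both profiles count the same pixel set
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(runif(300) < runif(1), 15, 20)
    p <- integral_projection(m)
    expect_identical(sum(p$row_counts), sum(p$col_counts))
    expect_identical(sum(p$row_counts), sum(m))
  }
})

test_that("main interval of a profile uses the fractional cut", {
  expect_equal(profile_main_interval(c(0, 0, 5, 5, 5, 0, 0, 0, 0, 0), 0.15),
               c(lo = 2L, hi = 4L))
  expect_equal(profile_main_interval(c(1, 0, 0, 10, 10, 0, 1), 0.15),
               c(lo = 3L, hi = 4L))
  expect_error(profile_main_interval(rep(0, 8)), class = "emptyProfile")
})

test_that("rectangle expansion moves each side by the long-side margin, clamped", {
  img <- matrix(0, 100, 200)
  expect_equal(unclass(expand_rect(pl_rect(30, 40, 60, 70), img)),
               unclass(pl_rect(20, 30, 70, 80)), ignore_attr = TRUE)
  expect_equal(unclass(expand_rect(pl_rect(0, 0, 20, 20), img)),
               unclass(pl_rect(0, 0, 30, 30)), ignore_attr = TRUE)
  img40 <- matrix(0, 40, 40)
  expect_equal(unclass(expand_rect(pl_rect(10, 10, 20, 20), img40)),
               unclass(pl_rect(8, 8, 22, 22)), ignore_attr = TRUE)
  # monotonicity: the expansion always contains its input
  set.seed(8)
  for (i in 1:20) {
    r <- pl_rect(sample(0:80, 1), sample(0:30, 1), sample(90:200, 1), sample(40:100, 1))
    e <- expand_rect(r, img)
    expect_true(e["x0"] <= r["x0"] && e["y0"] <= r["y0"] &&
                e["x1"] >= r["x1"] && e["y1"] >= r["y1"])
  }
})

test_that("mask foreground count equals the cumulative histogram at the threshold", {
  set.seed(13)
  img <- matrix(sample(0:255, 80 * 60, replace = TRUE), 60, 80)
  h <- compute_histogram(img)
  for (T in c(0, 17, 128, 255))
    expect_identical(sum(binarize(img, T)), sum(h[seq_len(T + 1)]))
})

test_that("rough ROI contains the pupil on sharp and blurred scenes", {
  sc <- render_scene(scene_params(seed = 31))
  roi <- extract_rough_roi(sc$image)
  tr <- sc$truth
  # the full pupil disc fits in the rectangle
  expect_lte(roi$rect[["x0"]], tr$x0 - tr$a)
  expect_gte(roi$rect[["x1"]], tr$x0 + tr$a)
  expect_lte(roi$rect[["y0"]], tr$y0 - tr$a)
  expect_gte(roi$rect[["y1"]], tr$y0 + tr$a)

  sc6 <- render_scene(scene_params(seed = 31, blur_sigma = 6))
  roi6 <- extract_rough_roi(sc6$image)
  expect_true(roi6$rect[["x0"]] <= sc6$truth$x0 && sc6$truth$x0 < roi6$rect[["x1"]])
  expect_true(roi6$rect[["y0"]] <= sc6$truth$y0 && sc6$truth$y0 < roi6$rect[["y1"]])

  expect_error(extract_rough_roi(matrix(128, 50, 50)), class = "noPupilCandidate")
})

test_that("true center lies inside the ROI on at least 99% of random scenes", {
  set.seed(77)
  n <- 100; hits <- 0L
  for (i in 1:n) {
    sigma <- runif(1, 0, 8)   # beyond the generator's defocus ceiling
    a <- runif(1, 48, 58); b <- a * runif(1, 0.9, 1)
    p <- scene_params(
      pupil_center = c(320 + runif(1, -50, 50), 240 + runif(1, -40, 40)),
      pupil_axes = c(a, b), pupil_angle = runif(1, 0, pi),
      iris_radius = a + runif(1, 50, 65), n_glints = sample(1:2, 1),
      eyebrow = runif(1) < 0.8, blur_sigma = sigma)
    sc <- render_scene(p)
    roi <- tryCatch(extract_rough_roi(sc$image), pupilloc_error = function(e) NULL)
    if (!is.null(roi) &&
        roi$rect[["x0"]] <= sc$truth$x0 && sc$truth$x0 < roi$rect[["x1"]] &&
        roi$rect[["y0"]] <= sc$truth$y0 && sc$truth$y0 < roi$rect[["y1"]])
      hits <- hits + 1L
  }
  expect_gte(hits / n, 0.99)
})

test_that("thresholded foreground keeps the pupil support under blur", {
  # fixed scene, sharp vs sigma = 4: the low-gray mode survives blurring
  for (sigma in c(0, 4)) {
    p <- scene_params(seed = 55, blur_sigma = sigma, n_glints = 0)
    sc <- render_scene(p)
    support <- render_scene(scene_params(seed = 55, blur_sigma = 0, n_glints = 0,
                                         noise_std = 0))$image <= 20
    roi <- extract_rough_roi(sc$image)
    fg <- binarize(sc$image, roi$threshold)
    expect_gte(sum(fg & support) / sum(support), 0.90)
  }
})
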