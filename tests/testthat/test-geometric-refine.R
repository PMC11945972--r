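test_that("opening removes specks, preserves bulk, and is idempotent", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_false(any(morphological_open(m, 1)))

  sq <- matrix(FALSE, 31, 31); sq[6:26, 6:26] <- TRUE
  opened <- morphological_open(sq, 1)
  expect_gte(sum(opened), 0.95 * sum(sq))
  expect_true(all(opened <= sq))   # anti-extensive

  set.seed(4)
  rnd <- matrix(runif(40 * 40) < 0.45, 40, 40)
  once <- morphological_open(rnd, 1)
  expect_identical(morphological_open(once, 1), once)
  expect_true(all(once <= rnd))
})

test_that("component extraction uses 8-connectivity with deterministic labels", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_length(connected_components(m), 1L)

  m2 <- matrix(FALSE, 9, 9); m2[1:2, 1:2] <- TRUE; m2[6:7, 6:7] <- TRUE
  comps <- connected_components(m2)
  expect_length(comps, 2L)
  # raster-scan labeling: the top-left blob comes first
  expect_equal(comps[[1]]$label, 1L)
  expect_true(all(comps[[1]]$xs <= 1))

  board <- matrix(FALSE, 4, 4)
  board[(row(board) + col(board)) %% 2 == 0] <- TRUE
  expect_length(connected_components(board), 1L)
})

test_that("labeling partition matches a brute-force flood fill on random masks", {
  set.seed(17)
  for (i in 1:15) {
    m <- matrix(runif(30 * 25) < runif(1, 0.2, 0.6), 25, 30)
    comps <- connected_components(m)
    lab <- oracle_components(m)
    expect_length(comps, max(lab))
    for (r in comps) {
      ids <- unique(lab[cbind(r$ys + 1L, r$xs + 1L)])
      expect_length(ids, 1L)                        # one oracle component
      expect_equal(r$area, sum(lab == ids))         # fully covered
    }
  }
})

test_that("hole filling closes enclosed holes only, and is idempotent", {
  outer <- rasterize_ellipse(20, 20, 15, 15)
  inner <- rasterize_ellipse(20, 20, 6, 6)
  key <- function(p) paste(p$xs, p$ys)
  ann <- pupil_region(outer$xs[!key(outer) %in% key(inner)],
                      outer$ys[!key(outer) %in% key(inner)],
                      dim = c(41L, 41L))
  filled <- fill_holes(ann)
  expect_equal(filled$area, length(outer$xs))
  expect_equal(filled$area - ann$area, length(inner$xs))

  # a concavity open to the frame border stays open
  cshape <- matrix(FALSE, 10, 10)
  cshape[2:9, 2:4] <- TRUE; cshape[2:3, 2:9] <- TRUE; cshape[8:9, 2:9] <- TRUE
  reg <- connected_components(cshape)[[1]]
  expect_equal(fill_holes(reg)$area, reg$area)

  expect_equal(fill_holes(filled)$area, filled$area)  # idempotent
})

test_that("inertia ratio matches covariance eigenvalues and analytic limits", {
  d <- disc_region(20)
  expect_gte(inertia_ratio(d), 0.98)

  e <- ellipse_region(40, 20)
  expect_lt(abs(inertia_ratio(e) - 0.25), 0.02)

  line <- pupil_region(xs = 0:49, ys = rep(3L, 50))
  expect_equal(inertia_ratio(line), 0)

  tiny <- pupil_region(xs = c(0, 1), ys = c(0, 0))
  expect_equal(inertia_ratio(tiny), 0)   # below the 5-px floor

  set.seed(31)
  for (i in 1:25) {
    r <- random_region()
    ev <- oracle_cov_eigen(r)
    expected <- if (r$area < 5L || ev[2] <= 0) 0 else ev[1] / ev[2]
    expect_equal(inertia_ratio(r), expected, tolerance = 1e-9)
  }
})

test_that("ellipse fit error is small for ellipses, large for bars and squares", {
  expect_lte(ellipse_fit_error(disc_region(20)), 0.08)

  sq <- connected_components(matrix(TRUE, 30, 30))[[1]]
  expect_gt(ellipse_fit_error(sq), 0.1)

  # fixed point: refitting a region that is its own fitted ellipse
  e <- ellipse_region(30, 18, theta = 0.5)
  expect_lte(ellipse_fit_error(e), 0.05)
})

test_that("shape index blends uniformity and ellipticity as designed", {
  expect_gte(pupil_shape_index(disc_region(20))$w, 0.95)

  s <- pupil_shape_index(ellipse_region(40, 20))
  expect_lt(abs(s$w - 0.55), 0.05)   # 0.6*0.25 + 0.4*(~1)

  line <- pupil_region(xs = 0:49, ys = rep(0L, 50))
  expect_lte(pupil_shape_index(line)$w, 0.4)

  # custom weights shift the blend
  cfg <- pupil_config(lambda1 = 1, lambda2 = 0)
  expect_lt(abs(pupil_shape_index(ellipse_region(40, 20), cfg)$w - 0.25), 0.02)
})

test_that("shape index stays in [0, 1] and is exactly translation invariant", {
  set.seed(41)
  for (i in 1:20) {
    r <- random_region()
    s <- pupil_shape_index(r)
    expect_gte(s$w, 0)
    expect_lte(s$w, 1)
    shifted <- pupil_region(r$xs + 137L, r$ys + 212L)
    st <- pupil_shape_index(shifted)
    expect_identical(st$inertia_ratio, s$inertia_ratio)
    expect_identical(st$w, s$w)
  }
})

test_that("shape index is robust to rotation and penalizes elongation monotonically", {
  base <- pupil_shape_index(ellipse_region(36, 18))$w
  rot <- pupil_shape_index(ellipse_region(36, 18, theta = pi / 6))$w
  expect_lte(abs(base - rot), 0.05)

  # fixed area ~ pi*24^2, aspect ratios 1, 2, 4
  firsts <- sapply(list(c(24, 24), c(34, 17), c(48, 12)), function(ab)
    pupil_shape_index(ellipse_region(ab[1], ab[2]))$inertia_ratio)
  expect_true(all(diff(firsts) < 0))
})

test_that("selection picks the disc over distractors and errors without candidates", {
  cfg <- pupil_config()
  d <- disc_region(20, dim = c(60L, 60L))
  line <- pupil_region(xs = 0:49, ys = rep(55L, 50), dim = c(60L, 60L))
  sel <- select_pupil_region(list(line, d), cfg)
  expect_identical(sel$region, d)
  expect_equal(nrow(sel$table), 2L)
  expect_equal(sum(sel$table$selected), 1L)

  expect_error(select_pupil_region(list(), cfg), class = "noCandidateRegions")
  tiny <- pupil_region(xs = 0:3, ys = rep(0L, 4))
  expect_error(select_pupil_region(list(tiny), cfg), class = "noCandidateRegions")
})

test_that("shape-index screening wins on at least 99% of candidate draws", {
  res <- screening_results(n_draws = 200, seed = 1234)
  expect_gte(mean(res$w_wins), 0.99)
})
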