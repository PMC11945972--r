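## Fixture builders and independent oracles shared across the test files.

# --- region fixtures --------------------------------------------------------

disc_region <- function(r, cx = r + 2, cy = r + 2, dim = NULL) {
  px <- rasterize_ellipse(cx, cy, r, r)
  pupil_region(px$xs, px$ys, dim = dim)
}

ellipse_region <- function(a, b, theta = 0, cx = a + 2, cy = a + 2, dim = NULL) {
  px <- rasterize_ellipse(cx, cy, a, b, theta)
  pupil_region(px$xs, px$ys, dim = dim)
}

# Irregular random-walk blob: what pixel noise looks like after an opening —
# straggly, not disc-like. Optionally lightly dilated (rounder variant).
random_blob <- function(n_steps = 25, cx = 0, cy = 0, dilate = FALSE) {
  x <- cx; y <- cy
  xs <- integer(n_steps); ys <- integer(n_steps)
  for (i in seq_len(n_steps)) {
    xs[i] <- x; ys[i] <- y
    stp <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    x <- x + stp[1]; y <- y + stp[2]
  }
  keep <- !duplicated(cbind(xs, ys))
  xs <- xs[keep]; ys <- ys[keep]
  if (dilate) {
    d <- expand.grid(dx = -1:1, dy = -1:1)
    all <- cbind(rep(xs, each = 9) + d$dx, rep(ys, each = 9) + d$dy)
    all <- all[!duplicated(all), , drop = FALSE]
    xs <- all[, 1]; ys <- all[, 2]
  }
  list(xs = xs, ys = ys)
}

# One screening draw: a pupil ellipse, an eyebrow-bar fragment, and 2-4
# noise specks, all in a 220x220 candidate frame. Returns the regions plus
# the index of the true pupil.
candidate_draw <- function() {
  dim <- c(220L, 220L)
  a <- runif(1, 48, 58); b <- a * runif(1, 0.9, 1)
  pupil <- ellipse_region(a, b, theta = runif(1, 0, pi),
                          cx = runif(1, 90, 130), cy = runif(1, 90, 130),
                          dim = dim)
  bar_w <- round(runif(1, 90, 150)); bar_h <- round(runif(1, 10, 16))
  bx <- sample(0:(220 - bar_w), 1)
  g <- expand.grid(x = bx:(bx + bar_w - 1L), y = 2:(1 + bar_h))
  bar <- pupil_region(g$x, g$y, dim = dim)
  regions <- list(pupil, bar)
  for (k in seq_len(sample(2:4, 1))) {
    bl <- random_blob(n_steps = sample(20:40, 1),
                      cx = sample(10:200, 1), cy = sample(10:200, 1),
                      dilate = runif(1) < 0.5)
    regions <- c(regions, list(pupil_region(bl$xs - min(bl$xs),
                                            bl$ys - min(bl$ys), dim = dim)))
  }
  ord <- sample(seq_along(regions))
  list(regions = regions[ord], true_index = which(ord == 1L))
}

# --- independent oracles ----------------------------------------------------

# Covariance eigenvalues via base eigen() on the explicitly formed matrix.
oracle_cov_eigen <- function(region) {
  xs <- region$xs; ys <- region$ys; n <- length(xs)
  S <- matrix(c(sum((xs - mean(xs))^2), sum((xs - mean(xs)) * (ys - mean(ys))),
                sum((xs - mean(xs)) * (ys - mean(ys))), sum((ys - mean(ys))^2)),
              2, 2) / n
  sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
}

# Brute-force flood fill (8-connectivity) for cross-checking the labeler.
oracle_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w); cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      y <- (p - 1L) %% h + 1L; x <- (p - 1L) %/% h + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
            mask[yy, xx] && lab[yy, xx] == 0L) {
          lab[yy, xx] <- cur
          queue <- c(queue, (xx - 1L) * h + yy)
        }
      }
    }
  }
  lab
}

# Random test regions for the oracle-equivalence checks: translated discs,
# ellipses and blobs of varied size.
random_region <- function() {
  kind <- sample(1:3, 1)
  off_x <- sample(0:500, 1); off_y <- sample(0:500, 1)
  if (kind == 1L) {
    disc_region(runif(1, 4, 30), cx = off_x + 40, cy = off_y + 40)
  } else if (kind == 2L) {
    a <- runif(1, 8, 40)
    ellipse_region(a, a * runif(1, 0.3, 1), theta = runif(1, 0, pi),
                   cx = off_x + 50, cy = off_y + 50)
  } else {
    bl <- random_blob(n_steps = sample(10:60, 1), cx = off_x, cy = off_y,
                      dilate = runif(1) < 0.5)
    pupil_region(bl$xs - min(bl$xs), bl$ys - min(bl$ys))
  }
}

# --- memoized synthetic benchmarks (shared by several test files) -----------

.bench_cache <- new.env(parent = emptyenv())

# In-memory defocus sweep: n_per_level scenes at z in {0, 5, 10, 15, 20},
# located with the default configuration.
blur_sweep_records <- function(master_seed = 42, n_per_level = 20) {
  key <- paste0("sweep_", master_seed, "_", n_per_level)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  levels <- c(0, 5, 10, 15, 20)
  rows <- list(); idx <- 0L
  for (z in levels) {
    for (i in seq_len(n_per_level)) {
      idx <- idx + 1L
      sc <- random_scene(pupilloc:::derive_seed(master_seed, idx), z_cm = z)
      ft <- locate_pupil(sc$image)
      err <- if (ft$status == "ok")
        localization_error(c(ft$xc, ft$yc), c(sc$truth$x0, sc$truth$y0))
      else NA_real_
      rows[[idx]] <- data.frame(
        z_cm = z, status = ft$status, error = err,
        correct = !is.na(err) && is_correct(err, 640, 480),
        radius = ft$radius, r_true = sqrt(sc$truth$a * sc$truth$b))
    }
  }
  .bench_cache[[key]] <- do.call(rbind, rows)
  .bench_cache[[key]]
}

sharp_set_records <- function(master_seed = 7, n = 50) {
  key <- paste0("sharp_", master_seed, "_", n)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  rows <- lapply(seq_len(n), function(i) {
    sc <- random_scene(pupilloc:::derive_seed(master_seed, i), z_cm = 0)
    ft <- locate_pupil(sc$image)
    err <- if (ft$status == "ok")
      localization_error(c(ft$xc, ft$yc), c(sc$truth$x0, sc$truth$y0))
    else NA_real_
    data.frame(status = ft$status, error = err,
               correct = !is.na(err) && is_correct(err, 640, 480))
  })
  .bench_cache[[key]] <- do.call(rbind, rows)
  .bench_cache[[key]]
}

# Screening experiment shared by the refinement properties and acceptance:
# over n draws, how often does each criterion pick the true pupil?
screening_results <- function(n_draws = 200, seed = 1234) {
  key <- paste0("screen_", n_draws, "_", seed)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  set.seed(seed)
  cfg <- pupil_config()
  w_wins <- logical(n_draws); ir_wins <- logical(n_draws)
  for (i in seq_len(n_draws)) {
    d <- candidate_draw()
    eligible <- vapply(d$regions, function(r) r$area >= cfg$min_area, logical(1))
    sel <- select_pupil_region(d$regions, cfg)
    w_wins[i] <- identical(sel$region, d$regions[[d$true_index]])
    irs <- vapply(d$regions, inertia_ratio, numeric(1))
    irs[!eligible] <- -1
    ir_wins[i] <- which.max(irs) == d$true_index
  }
  .bench_cache[[key]] <- list(w_wins = w_wins, ir_wins = ir_wins)
  .bench_cache[[key]]
}
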