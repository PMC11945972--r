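## Stage 2: refine the rough pupil region with geometric constraints.
##
## The dark mask inside the ROI is cleaned by a morphological opening,
## partitioned into 8-connected components, hole-filled (glints punch
## near-saturated holes into the pupil), and each candidate is scored with
## the pupil shape index
##     w = lambda1 * (I_minor / I_major) + lambda2 / (1 + fitting_error),
## a weighted blend of the region's inertia ratio (shape uniformity) and the
## inverse of its ellipse-fitting error (ellipticity / boundary smoothness).
## The candidate with the largest w wins.

#' Connected region of a binary mask
#'
#' A region stores its member pixels as 0-based `(x, y)` coordinates in the
#' frame of the mask it was extracted from, together with the frame
#' dimensions. Created by [connected_components()]; the constructor is
#' exported for building test fixtures.
#'
#' @param xs,ys Integer pixel coordinates (0-based; `x` = column, `y` = row).
#' @param dim Frame dimensions `c(H, W)`; defaults to the pixel bounding box.
#' @param label Integer region id.
#' @return An object of class `pupil_region`.
#' @examples
#' r <- pupil_region(xs = c(0, 1, 0, 1), ys = c(0, 0, 1, 1))
#' r$area
#' @export
pupil_region <- function(xs, ys, dim = NULL, label = 1L) {
  stopifnot(length(xs) == length(ys), length(xs) >= 1L)
  xs <- as.integer(xs); ys <- as.integer(ys)
  if (is.null(dim)) dim <- c(max(ys) + 1L, max(xs) + 1L)
  structure(list(label = as.integer(label), xs = xs, ys = ys,
                 area = length(xs), dim = as.integer(dim)),
            class = "pupil_region")
}

#' @export
print.pupil_region <- function(x, ...) {
  cat(sprintf("<pupil_region #%d> area %d px, frame %d x %d, centroid (%.2f, %.2f)\n",
              x$label, x$area, x$dim[2], x$dim[1], mean(x$xs), mean(x$ys)))
  invisible(x)
}

region_mask <- function(region) {
  m <- matrix(FALSE, region$dim[1], region$dim[2])
  m[cbind(region$ys + 1L, region$xs + 1L)] <- TRUE
  m
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with a disc-shaped structuring element;
#' removes foreground noise smaller than the element without growing the
#' object. Radius 1 uses a 3x3 element; radius 0 is the identity.
#'
#' @param mask Logical matrix.
#' @param radius Structuring-element radius in pixels.
#' @return Logical matrix; always a subset of the input (anti-extensive).
#' @export
morphological_open <- function(mask, radius = 1L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (radius < 1L) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::opening(mask * 1, brush) > 0.5
}

# -- 8-connected component labeling (run-length union-find) ------------------
# EBImage's labeling is 4-connected; the method requires 8-connectivity, so
# runs of foreground pixels in consecutive rows are unioned whenever they
# overlap or touch diagonally (column ranges within +/- 1).

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' 8-connected components of a binary mask
#'
#' Partitions the foreground into maximal 8-connected regions. Labels are
#' assigned in raster-scan order of each region's first pixel, so the output
#' is deterministic.
#'
#' @param mask Logical matrix.
#' @return List of [pupil_region()] objects (possibly empty).
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' length(connected_components(m))  # diagonal pixels join under 8-connectivity
#' @export
connected_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (y in seq_len(h)) {
    v <- mask[y, ]
    d <- diff(c(FALSE, v, FALSE))
    s <- which(d == 1L); e <- which(d == -1L) - 1L
    if (length(s)) {
      run_row <- c(run_row, rep.int(y, length(s)))
      run_s <- c(run_s, s); run_e <- c(run_e, e)
    }
  }
  nr <- length(run_s)
  if (nr == 0L) return(list())
  parent <- seq_len(nr)
  row_start <- match(seq_len(h), run_row)           # first run index per row
  for (i in seq_len(nr)) {
    y <- run_row[i]
    if (y == 1L) next
    j <- row_start[y - 1L]
    if (is.na(j)) next
    while (j <= nr && run_row[j] == y - 1L) {
      # 8-connectivity: touching diagonally counts, hence the +/- 1 slack
      if (run_s[j] <= run_e[i] + 1L && run_e[j] >= run_s[i] - 1L) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      j <- j + 1L
    }
  }
  roots <- vapply(seq_len(nr), function(i) uf_find(parent, i), integer(1))
  labels <- match(roots, unique(roots))             # raster order of first run
  out <- vector("list", max(labels))
  for (lab in seq_along(out)) {
    idx <- which(labels == lab)
    xs <- unlist(lapply(idx, function(i) run_s[i]:run_e[i]), use.names = FALSE)
    ys <- rep.int(run_row[idx], run_e[idx] - run_s[idx] + 1L)
    out[[lab]] <- pupil_region(xs - 1L, ys - 1L, dim = c(h, w), label = lab)
  }
  out
}

#' Fill enclosed holes of a region
#'
#' Adds every background pixel that cannot be reached from the frame border
#' through 4-connected background moves — the dual of 8-connected
#' foreground. Glint reflections inside the pupil become such holes after
#' thresholding and are removed here. Extensive and idempotent.
#'
#' @param region A [pupil_region()].
#' @param roi Optional [pl_rect()] giving the frame; defaults to the
#'   region's stored frame dimensions.
#' @return The filled `pupil_region`.
#' @export
fill_holes <- function(region, roi = NULL) {
  stopifnot(inherits(region, "pupil_region"))
  dim <- if (is.null(roi)) region$dim else c(rect_height(roi), rect_width(roi))
  m <- matrix(FALSE, dim[1], dim[2])
  m[cbind(region$ys + 1L, region$xs + 1L)] <- TRUE
  f <- EBImage::fillHull(m * 1) > 0.5
  idx <- which(f, arr.ind = TRUE)
  pupil_region(idx[, 2L] - 1L, idx[, 1L] - 1L, dim = dim, label = region$label)
}

# Second central moments of the pixel-center coordinates (population
# normalization) and the eigenvalues of the 2x2 covariance matrix.
# Coordinates are shifted by their integer minimum first, so the statistics
# are bit-identical under translation (and better conditioned).
region_covariance_eigen <- function(region) {
  ox <- min(region$xs); oy <- min(region$ys)
  xs <- region$xs - ox; ys <- region$ys - oy
  mx <- mean(xs); my <- mean(ys)
  sxx <- mean(xs * xs) - mx * mx
  syy <- mean(ys * ys) - my * my
  sxy <- mean(xs * ys) - mx * my
  tr2 <- (sxx + syy) / 2
  det_part <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  list(centroid = c(mx + ox, my + oy),
       lambda_major = tr2 + det_part, lambda_minor = max(tr2 - det_part, 0),
       # principal-axis angle, measured from +x toward +y
       theta = 0.5 * atan2(2 * sxy, sxx - syy))
}

#' Inertia ratio of a region
#'
#' Ratio of the secondary to the main moment of inertia, computed as
#' `lambda_min / lambda_max` of the region's second-central-moment matrix:
#' 1 for a disc, about `b^2 / a^2` for an ellipse with semi-axes `a >= b`,
#' 0 for a line. Regions with fewer than 5 pixels or a degenerate major
#' axis score 0 so that specks can never win the screening.
#'
#' @param region A [pupil_region()].
#' @return A value in \[0, 1\].
#' @export
inertia_ratio <- function(region) {
  stopifnot(inherits(region, "pupil_region"))
  if (region$area < 5L) return(0)
  ev <- region_covariance_eigen(region)
  if (ev$lambda_major <= 0) return(0)
  ev$lambda_minor / ev$lambda_major
}

#' Rasterize an ellipse on the pixel grid
#'
#' Returns the 0-based coordinates of every pixel whose center lies inside
#' the ellipse. Used internally by [ellipse_fit_error()] and handy for
#' building region fixtures.
#'
#' @param cx,cy Ellipse center.
#' @param a,b Semi-axes (px).
#' @param theta Rotation (radians, from +x toward +y).
#' @return List with integer vectors `xs` and `ys`.
#' @examples
#' length(rasterize_ellipse(0, 0, 20, 20)$xs) / (pi * 20^2)  # close to 1
#' @export
rasterize_ellipse <- function(cx, cy, a, b, theta = 0) {
  ext_x <- abs(a * cos(theta)) + abs(b * sin(theta))
  ext_y <- abs(a * sin(theta)) + abs(b * cos(theta))
  gx <- floor(cx - ext_x):ceiling(cx + ext_x)
  gy <- floor(cy - ext_y):ceiling(cy + ext_y)
  dx <- outer(rep(1, length(gy)), gx - cx)
  dy <- outer(gy - cy, rep(1, length(gx)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / max(b, 1e-9)
  inside <- which(u * u + v * v <= 1, arr.ind = TRUE)
  list(xs = gx[inside[, 2L]], ys = gy[inside[, 1L]])
}

#' Ellipse-fitting error of a region
#'
#' Fits the moment-equivalent ellipse (center at the centroid, axes along
#' the principal directions, semi-axes `2 * sqrt(eigenvalue)` — exact for a
#' uniform ellipse) and reports the area of the symmetric difference between
#' the region and the rasterized ellipse, normalized by the region area.
#' Near 0 for elliptical regions regardless of blur-diffused boundaries;
#' grows for bars, squares and ragged blobs. Degenerate regions (fewer than
#' 5 pixels, or a vanishing minor axis) return `Inf`.
#'
#' @param region A [pupil_region()].
#' @return A non-negative number (possibly `Inf`).
#' @export
ellipse_fit_error <- function(region) {
  stopifnot(inherits(region, "pupil_region"))
  if (region$area < 5L) return(Inf)
  ev <- region_covariance_eigen(region)
  if (ev$lambda_minor <= 0) return(Inf)
  a <- 2 * sqrt(ev$lambda_major); b <- 2 * sqrt(ev$lambda_minor)
  ell <- rasterize_ellipse(ev$centroid[1], ev$centroid[2], a, b, ev$theta)
  # set comparison on packed integer keys; coordinates can be negative
  off_x <- min(region$xs, ell$xs); off_y <- min(region$ys, ell$ys)
  span <- max(region$ys, ell$ys) - off_y + 2L
  key_r <- (region$xs - off_x) * span + (region$ys - off_y)
  key_e <- (ell$xs - off_x) * span + (ell$ys - off_y)
  sym_diff <- length(setdiff(key_r, key_e)) + length(setdiff(key_e, key_r))
  sym_diff / region$area
}

#' Pupil shape index
#'
#' The screening score
#' `w = lambda1 * inertia_ratio + lambda2 / (1 + fitting_error)`,
#' with `lambda1 + lambda2 = 1` so that `w` lies in \[0, 1\]. The first term
#' rewards uniform (near-circular) mass distributions, the second rewards
#' elliptical, smooth-boundary regions; the default weights 0.6/0.4
#' prioritize uniformity so a slightly occluded or noisy pupil still ranks
#' first.
#'
#' @param region A [pupil_region()].
#' @param cfg A [pupil_config()] supplying `lambda1`/`lambda2`.
#' @return A list of class `shape_score` with `inertia_ratio`,
#'   `fitting_error` and `w`.
#' @examples
#' disc <- do.call(pupil_region, rasterize_ellipse(25, 25, 20, 20))
#' pupil_shape_index(disc)$w
#' @export
pupil_shape_index <- function(region, cfg = pupil_config()) {
  ir <- inertia_ratio(region)
  fe <- ellipse_fit_error(region)
  ell_term <- if (is.infinite(fe)) 0 else 1 / (1 + fe)
  structure(list(inertia_ratio = ir, fitting_error = fe,
                 w = cfg$lambda1 * ir + cfg$lambda2 * ell_term),
            class = "shape_score")
}

#' @export
print.shape_score <- function(x, ...) {
  cat(sprintf("<shape_score> w = %.4f (inertia ratio %.4f, fit error %.4f)\n",
              x$w, x$inertia_ratio, x$fitting_error))
  invisible(x)
}

#' Select the pupil region among candidates
#'
#' Scores every candidate with [pupil_shape_index()] and returns the one
#' with the largest index. Regions below `cfg$min_area` are excluded. Exact
#' ties are broken by larger area, then by smaller centroid distance to the
#' frame center — a deterministic order for reproducibility.
#'
#' @param regions List of [pupil_region()] candidates.
#' @param cfg A [pupil_config()].
#' @param center Optional `c(x, y)` frame center used by the final
#'   tie-break; defaults to the center of the first region's frame.
#' @return List with `region` (the winner), `score` (its `shape_score`) and
#'   `table` (a data frame of all candidate scores, for debugging).
#' @section Errors: signals `noCandidateRegions` when no region passes the
#'   area floor.
#' @export
select_pupil_region <- function(regions, cfg = pupil_config(), center = NULL) {
  regions <- Filter(function(r) r$area >= cfg$min_area, regions)
  if (length(regions) == 0L)
    pl_stop("noCandidateRegions", "no connected component reaches min_area")
  if (is.null(center)) center <- c(regions[[1L]]$dim[2L], regions[[1L]]$dim[1L]) / 2
  scores <- lapply(regions, pupil_shape_index, cfg = cfg)
  tab <- data.frame(
    label = vapply(regions, `[[`, integer(1), "label"),
    area = vapply(regions, `[[`, integer(1), "area"),
    inertia_ratio = vapply(scores, `[[`, numeric(1), "inertia_ratio"),
    fitting_error = vapply(scores, `[[`, numeric(1), "fitting_error"),
    w = vapply(scores, `[[`, numeric(1), "w")
  )
  dist <- vapply(regions, function(r)
    sqrt((mean(r$xs) - center[1])^2 + (mean(r$ys) - center[2])^2), numeric(1))
  best <- order(-tab$w, -tab$area, dist)[1L]
  tab$selected <- seq_len(nrow(tab)) == best
  list(region = regions[[best]], score = scores[[best]], table = tab)
}
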