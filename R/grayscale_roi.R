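## Stage 1: rough pupil region from grayscale constraints.
##
## In near-infrared periocular images the pupil is the darkest structure, so
## its pixels sit in the lowest-gray spike of the histogram. The stage
## thresholds at the valley after that spike, projects the dark mask onto the
## two axes, takes the main interval of each projection and expands the
## resulting rectangle.

#' Gray-level histogram
#'
#' @param img Grayscale image matrix (see [read_eye_image()]).
#' @return Integer vector of length 256; element `g + 1` counts the pixels
#'   with intensity `g`.
#' @examples
#' compute_histogram(matrix(c(10, 10, 200), 1))[c(11, 201)]
#' @export
compute_histogram <- function(img) {
  check_gray_image(img)
  tabulate(as.integer(round(img)) + 1L, nbins = 256L)
}

# Centered moving average with shrinking windows at the ends.
smooth_counts <- function(counts, window) {
  h <- (window - 1L) %/% 2L
  n <- length(counts)
  if (h == 0L) return(as.numeric(counts))
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Significant peaks of a smoothed histogram: first index of every
# local-maximum plateau whose height reaches min_count.
find_peaks <- function(sm, min_count) {
  n <- length(sm)
  r <- rle(sm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_peak <- logical(k)
  for (i in seq_len(k)) {
    left_ok  <- i == 1L || r$values[i] > r$values[i - 1L]
    right_ok <- i == k  || r$values[i] > r$values[i + 1L]
    is_peak[i] <- left_ok && right_ok && r$values[i] >= min_count
  }
  starts[is_peak]   # 1-based indices into sm
}

#' Histogram-valley segmentation threshold
#'
#' Finds the dark-side segmentation threshold as the valley that follows the
#' lowest-gray significant peak of the smoothed histogram. The histogram is
#' smoothed with a centered moving average; a peak is significant when its
#' smoothed count reaches `min_peak_frac` of the total pixel count. The
#' threshold is the smallest gray level attaining the minimum smoothed count
#' strictly between the lowest significant peak and the next significant peak.
#'
#' @param hist Length-256 histogram from [compute_histogram()].
#' @param smooth_window Odd moving-average width (gray levels).
#' @param min_peak_frac Significance fraction of the total pixel count.
#' @return A gray level `T` in \[0, 255\]. Pixels with intensity `<= T` form
#'   the dark (pupil-candidate) class.
#' @section Errors: signals a condition of class `noValleyFound` when the
#'   smoothed histogram has fewer than two significant peaks, i.e. no second
#'   mode to delimit a valley.
#' @examples
#' h <- integer(256); h[16:26] <- 400; h[141:161] <- 1800
#' histogram_valley_threshold(h)
#' @export
histogram_valley_threshold <- function(hist, smooth_window = 5L,
                                       min_peak_frac = 0.001) {
  stopifnot(length(hist) == 256L, smooth_window >= 1L)
  total <- sum(hist)
  if (total == 0) pl_stop("emptyImage", "empty histogram")
  sm <- smooth_counts(hist, smooth_window)
  peaks <- find_peaks(sm, min_count = min_peak_frac * total)
  if (length(peaks) < 2L)
    pl_stop("noValleyFound",
            "histogram has no second significant mode; no valley to threshold at")
  p1 <- peaks[1L]
  p2 <- peaks[2L]
  span <- (p1 + 1L):(p2 - 1L)
  if (length(span) == 0L)
    pl_stop("noValleyFound", "adjacent peaks leave no valley")
  t_idx <- span[which.min(sm[span])]   # which.min takes the first minimum
  t_idx - 1L                           # back to 0-based gray level
}

# Fallback threshold: the pupil occupies a small dark fraction of the frame,
# so take the smallest gray level where the cumulative histogram reaches
# `frac` of all pixels.
fallback_threshold <- function(hist, frac = 0.05) {
  cum <- cumsum(hist)
  unname(which(cum >= frac * cum[256L])[1L] - 1L)
}

#' Binarize an image at a gray threshold
#'
#' @param img Grayscale image matrix.
#' @param threshold Gray level `T`; the comparison is inclusive.
#' @return Logical `H x W` matrix, `TRUE` where `img <= T` (the dark class).
#' @examples
#' binarize(matrix(c(10, 50, 90), 1), 50)
#' @export
binarize <- function(img, threshold) {
  check_gray_image(img)
  stopifnot(threshold >= 0, threshold <= 255)
  img <= threshold
}

#' Gray integral projection of a binary mask
#'
#' Accumulates the number of dark-class pixels along each row and each
#' column, yielding the two 1-D profiles whose main intervals bound the
#' pupil's extent.
#'
#' @param mask Logical `H x W` matrix.
#' @return List with `row_counts` (length H) and `col_counts` (length W).
#' @examples
#' m <- matrix(FALSE, 10, 10); m[3:5, 4:8] <- TRUE
#' integral_projection(m)$row_counts
#' @export
integral_projection <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask), length(mask) > 0L)
  list(row_counts = as.integer(rowSums(mask)),
       col_counts = as.integer(colSums(mask)))
}

#' Main interval of a projection profile
#'
#' @param profile Non-negative counts.
#' @param frac Cut fraction of the profile maximum.
#' @return Integer vector `c(lo, hi)`: the first and last 0-based indices
#'   whose count reaches `frac * max(profile)`.
#' @section Errors: signals `emptyProfile` when the profile is all zero.
#' @examples
#' profile_main_interval(c(0, 0, 5, 5, 5, 0), 0.15)
#' @export
profile_main_interval <- function(profile, frac = 0.15) {
  stopifnot(length(profile) >= 1L, frac > 0, frac < 1)
  m <- max(profile)
  if (m == 0) pl_stop("emptyProfile", "projection profile is identically zero")
  idx <- which(profile >= frac * m)
  c(lo = idx[1L] - 1L, hi = idx[length(idx)] - 1L)
}

#' Expand a rectangle by the image-proportional margin
#'
#' Each side of the rectangle is moved outward by
#' `floor(max(H, W) / divisor)` pixels and clamped to the image bounds; the
#' default divisor of 20 guards against an undersized rough region when
#' glints sit on the pupil boundary.
#'
#' @param rect A [pl_rect()].
#' @param img Image matrix providing the bounds.
#' @param divisor Expansion divisor of the long side.
#' @return The expanded `pl_rect`.
#' @examples
#' expand_rect(pl_rect(30, 40, 60, 70), matrix(0, 100, 200))
#' @export
expand_rect <- function(rect, img, divisor = 20L) {
  h <- nrow(img); w <- ncol(img)
  margin <- max(h, w) %/% as.integer(divisor)
  pl_rect(max(0L, rect["x0"] - margin), max(0L, rect["y0"] - margin),
          min(w, rect["x1"] + margin), min(h, rect["y1"] + margin))
}

#' Rough pupil region from grayscale constraints
#'
#' Composes the grayscale stage: histogram, valley threshold (with the
#' 5%-cumulative fallback when the histogram is unimodal), binarization,
#' integral projection, main-interval extraction in both axes, and
#' rectangle expansion.
#'
#' @param img Grayscale image matrix.
#' @param cfg A [pupil_config()].
#' @return A list with elements `rect` (the expanded ROI, a [pl_rect()]),
#'   `mask` (the binary dark mask cropped to `rect`), `threshold` (the gray
#'   level used) and `fallback` (`TRUE` when the valley rule failed and the
#'   cumulative fallback produced the threshold).
#' @section Errors: signals `noPupilCandidate` when no usable dark region
#'   exists (all-background mask, or a dark class covering more than
#'   `cfg$max_foreground_frac` of the frame, as on a uniform image).
#' @examples
#' scene <- render_scene(scene_params(seed = 1))
#' roi <- extract_rough_roi(scene$image, pupil_config())
#' roi$rect
#' @export
extract_rough_roi <- function(img, cfg = pupil_config()) {
  check_gray_image(img)
  hist <- compute_histogram(img)
  fallback <- FALSE
  threshold <- tryCatch(
    histogram_valley_threshold(hist, cfg$smooth_window, cfg$min_peak_frac),
    noValleyFound = function(e) {
      pl_log("warning", paste0("valley detection failed (", conditionMessage(e),
                               "); using cumulative fallback threshold"))
      fallback <<- TRUE
      fallback_threshold(hist)
    })
  mask <- binarize(img, threshold)
  n_fg <- sum(mask)
  if (n_fg == 0L || n_fg > cfg$max_foreground_frac * length(mask))
    pl_stop("noPupilCandidate",
            "dark class is empty or covers most of the frame; no pupil candidate")
  proj <- integral_projection(mask)
  rows <- tryCatch(profile_main_interval(proj$row_counts, cfg$projection_frac),
                   emptyProfile = function(e) pl_stop("noPupilCandidate", conditionMessage(e)))
  cols <- tryCatch(profile_main_interval(proj$col_counts, cfg$projection_frac),
                   emptyProfile = function(e) pl_stop("noPupilCandidate", conditionMessage(e)))
  rect <- pl_rect(cols["lo"], rows["lo"], cols["hi"] + 1L, rows["hi"] + 1L)
  rect <- expand_rect(rect, img, cfg$expand_divisor)
  crop <- mask[(rect["y0"] + 1L):rect["y1"], (rect["x0"] + 1L):rect["x1"], drop = FALSE]
  list(rect = rect, mask = crop, threshold = threshold, fallback = fallback)
}
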