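## Stage 3: pupil center and size from geometric moments.
##
## The selected region is treated as a binary density (member pixels weigh
## 1), so M00 is the area, and the centroid M10/M00, M01/M00 is the pupil
## center. A single pass over the member pixels suffices: the cost is
## proportional to the region area.

#' Geometric moments of a region
#'
#' Computes the zero- and first-order moments `Mij = sum x^i y^j f(x, y)`
#' with the binary convention `f = 1` on member pixels. The attribute
#' `"ops"` records the number of pixel visits (one per member pixel),
#' documenting the linear-time contract of the moment stage.
#'
#' @param region A [pupil_region()].
#' @return List with `M00`, `M10`, `M01` and a `frame` tag (`"local"`).
#' @examples
#' region_moments(pupil_region(xs = c(0, 1, 0, 1), ys = c(0, 0, 1, 1)))
#' @export
region_moments <- function(region) {
  stopifnot(inherits(region, "pupil_region"))
  if (region$area < 1L) pl_stop("emptyRegion", "region has no pixels")
  m <- list(M00 = as.numeric(region$area),
            M10 = sum(as.numeric(region$xs)),
            M01 = sum(as.numeric(region$ys)),
            frame = "local")
  attr(m, "ops") <- region$area
  m
}

#' Pupil center from moments
#'
#' `xc = x0 + M10 / M00`, `yc = y0 + M01 / M00`: the first-order moments
#' over the zero-order moment, shifted by the ROI origin into full-image
#' coordinates.
#'
#' @param m Moments from [region_moments()].
#' @param roi_offset `c(x0, y0)` origin of the region's frame in the full
#'   image (0-based).
#' @return Named numeric `c(xc, yc)`, sub-pixel, full-image frame.
#' @export
pupil_center <- function(m, roi_offset = c(0, 0)) {
  if (m$M00 <= 0) pl_stop("zeroMass", "M00 = 0: no mass to locate")
  c(xc = roi_offset[1] + m$M10 / m$M00,
    yc = roi_offset[2] + m$M01 / m$M00)
}

#' Equivalent-circle pupil radius from the zero-order moment
#'
#' @param m Moments from [region_moments()].
#' @return `sqrt(M00 / pi)` in pixels; for elliptical pupils this is the
#'   radius of the circle with the same area.
#' @export
pupil_radius <- function(m) {
  if (m$M00 <= 0) pl_stop("zeroMass", "M00 = 0: no mass to size")
  sqrt(m$M00 / pi)
}

#' Locate the pupil center in a grayscale eye image
#'
#' Runs the full double-constraint pipeline: grayscale rough-region
#' extraction ([extract_rough_roi()]), geometric refinement (opening,
#' 8-connected components, hole filling, shape-index screening), and
#' moment-based localization. Recoverable failures (no dark mode, no
#' candidate region) yield `status = "no_pupil_found"` rather than an error.
#'
#' @param img Grayscale image matrix (see [read_eye_image()]) or a file
#'   path, which is read with [read_eye_image()].
#' @param cfg A [pupil_config()].
#' @return An object of class `pupil_result`: a list with `status`
#'   (`"ok"` or `"no_pupil_found"`), sub-pixel center `xc`, `yc`
#'   (full-image 0-based pixel coordinates), equivalent-circle `radius`,
#'   shape index `w`, the candidate diagnostics (`inertia_ratio`,
#'   `fitting_error`, `n_candidates`), the grayscale-stage `threshold` and
#'   `roi`, and the image dimensions.
#' @examples
#' scene <- render_scene(scene_params(seed = 3, blur_sigma = 2))
#' fit <- locate_pupil(scene$image)
#' fit
#' coef(fit)
#' @seealso [run_benchmark()] for batch evaluation against ground truth.
#' @export
locate_pupil <- function(img, cfg = pupil_config()) {
  if (is.character(img)) img <- read_eye_image(img)
  check_gray_image(img)
  empty <- structure(
    list(status = "no_pupil_found", xc = NA_real_, yc = NA_real_,
         radius = NA_real_, w = NA_real_, inertia_ratio = NA_real_,
         fitting_error = NA_real_, n_candidates = 0L,
         threshold = NA_integer_, roi = NULL, dim = dim(img)),
    class = "pupil_result")
  tryCatch({
    roi <- extract_rough_roi(img, cfg)
    opened <- morphological_open(roi$mask, cfg$opening_radius)
    regions <- connected_components(opened)
    regions <- lapply(regions, fill_holes)
    sel <- select_pupil_region(regions, cfg,
                               center = c(ncol(opened), nrow(opened)) / 2)
    m <- region_moments(sel$region)
    ctr <- pupil_center(m, roi_offset = c(roi$rect[["x0"]], roi$rect[["y0"]]))
    structure(
      list(status = "ok", xc = unname(ctr["xc"]), yc = unname(ctr["yc"]),
           radius = pupil_radius(m), w = sel$score$w,
           inertia_ratio = sel$score$inertia_ratio,
           fitting_error = sel$score$fitting_error,
           n_candidates = nrow(sel$table),
           threshold = roi$threshold, roi = roi$rect, dim = dim(img)),
      class = "pupil_result")
  },
  noPupilCandidate = function(e) { pl_log("warning", conditionMessage(e)); empty },
  noValleyFound = function(e) { pl_log("warning", conditionMessage(e)); empty },
  noCandidateRegions = function(e) { pl_log("warning", conditionMessage(e)); empty })
}

#' @export
print.pupil_result <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("Pupil located at (%.3f, %.3f), radius %.2f px\n",
                x$xc, x$yc, x$radius))
    cat(sprintf("  shape index w = %.4f (inertia ratio %.4f, fit error %.4f)\n",
                x$w, x$inertia_ratio, x$fitting_error))
    cat(sprintf("  threshold %d, %d candidate region(s) in ROI [%d, %d) x [%d, %d)\n",
                x$threshold, x$n_candidates,
                x$roi[["x0"]], x$roi[["x1"]], x$roi[["y0"]], x$roi[["y1"]]))
  } else {
    cat("No pupil found (status:", x$status, ")\n")
  }
  invisible(x)
}

#' @export
coef.pupil_result <- function(object, ...) {
  c(xc = object$xc, yc = object$yc, radius = object$radius)
}

#' @export
as.data.frame.pupil_result <- function(x, ..., filename = NA_character_) {
  data.frame(filename = filename, status = x$status,
             xc = x$xc, yc = x$yc, radius = x$radius, w = x$w)
}

#' Plot a localization result over its image
#'
#' Draws the image with a cross at the located center and a circle of the
#' reported equivalent radius.
#'
#' @param x A `pupil_result`.
#' @param img The image the result was computed from.
#' @param ... Passed to [graphics::rasterImage()] (unused).
#' @return `x`, invisibly.
#' @export
plot.pupil_result <- function(x, img, ...) {
  check_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  graphics::plot(NA, xlim = c(0, w), ylim = c(h, 0), asp = 1,
                 xlab = "x (px)", ylab = "y (px)")
  graphics::rasterImage(img / 255, 0, h, w, 0, interpolate = FALSE)
  if (x$status == "ok") {
    graphics::points(x$xc, x$yc, pch = 3, col = "green", cex = 2, lwd = 2)
    th <- seq(0, 2 * pi, length.out = 181)
    graphics::lines(x$xc + x$radius * cos(th), x$yc + x$radius * sin(th),
                    col = "red", lwd = 2)
  }
  invisible(x)
}
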