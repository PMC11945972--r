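## Ground-truthed synthetic near-infrared periocular scenes.
##
## Emulates a defocus image series: a dark elliptical pupil (slightly rough
## boundary — real pupils are not perfect circles), a mid-gray iris disc, a
## bright lens-shaped sclera opening on skin, near-saturated corneal glints,
## an optional dark eyebrow bar, Gaussian defocus blur, and sensor noise.
## The true pupil centroid is recorded from the pre-blur rasterized pupil
## support, so (the blur kernel being symmetric) localization errors are
## attributable to the algorithm, not to the ground truth.

#' Map a defocus distance to a Gaussian blur sigma
#'
#' Linear surrogate for the defocus point-spread: `sigma = sigma_max * |z| /
#' z_max`, with `sigma_max = 6` px at the largest defocus `z_max = 20` cm.
#'
#' @param z_cm Defocus distance in cm, `|z_cm| <= z_max`.
#' @param sigma_max Blur sigma at full defocus (px).
#' @param z_max Largest supported defocus (cm).
#' @return Blur sigma in pixels.
#' @examples
#' defocus_to_sigma(10)  # 3 px
#' @export
defocus_to_sigma <- function(z_cm, sigma_max = 6, z_max = 20) {
  if (abs(z_cm) > z_max)
    pl_stop("invalidParams", sprintf("|z| = %g cm exceeds z_max = %g cm",
                                     abs(z_cm), z_max))
  sigma_max * abs(z_cm) / z_max
}

#' Synthetic scene parameters
#'
#' Defaults describe a typical 640x480 near-eye infrared frame: pupil
#' semi-axes (50, 45) px, palette pupil 20 / iris 90 / skin 160 / sclera
#' 200, two glints, an eyebrow distractor, 3% boundary roughness and sensor
#' noise with standard deviation 3 gray levels. The palette ordering
#' (pupil < iris < sclera) guarantees by construction that the pupil is the
#' lowest-gray mode the grayscale stage relies on.
#'
#' @param width,height Image size (px).
#' @param pupil_center `c(x, y)` in 0-based pixel coordinates.
#' @param pupil_axes Semi-axes `c(a, b)` (px).
#' @param iris_offset Decentration `c(dx, dy)` of the iris center relative
#'   to the pupil center (real pupils sit slightly off the iris axis); the
#'   eye opening and eyebrow are anchored to the iris center.
#' @param pupil_angle Rotation of the pupil ellipse (radians).
#' @param pupil_gray,iris_gray,sclera_gray,skin_gray Palette intensities.
#' @param iris_radius Iris disc radius (px), concentric with the pupil.
#' @param n_glints Number of corneal glints.
#' @param glint_radius_range `c(min, max)` glint radius (px).
#' @param glint_gray Glint intensity (near-saturated).
#' @param eyebrow Render the dark eyebrow bar above the eye opening?
#' @param eyebrow_gray Eyebrow intensity; between pupil and iris so it
#'   genuinely competes in thresholding.
#' @param boundary_roughness Fractional radial perturbation amplitude of the
#'   pupil boundary.
#' @param blur_sigma Gaussian defocus blur sigma (px); see
#'   [defocus_to_sigma()].
#' @param noise_std Additive Gaussian noise standard deviation (gray
#'   levels), applied after blur.
#' @param defocus_z_cm Optional defocus tag stored with the ground truth.
#' @param seed Optional RNG seed making the rendering reproducible.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(width = 640L, height = 480L,
                         pupil_center = c(320, 240),
                         pupil_axes = c(50, 45),
                         pupil_angle = 0,
                         iris_offset = c(0, 0),
                         pupil_gray = 20, iris_gray = 90,
                         sclera_gray = 200, skin_gray = 160,
                         iris_radius = 110,
                         n_glints = 2L,
                         glint_radius_range = c(2, 4),
                         glint_gray = 250,
                         eyebrow = TRUE,
                         eyebrow_gray = 50,
                         boundary_roughness = 0.03,
                         blur_sigma = 0,
                         noise_std = 3,
                         defocus_z_cm = NA_real_,
                         seed = NULL) {
  p <- as.list(environment())
  class(p) <- "scene_params"
  validate_scene_params(p)
}

validate_scene_params <- function(p) {
  if (!(p$pupil_gray < p$iris_gray && p$iris_gray < p$sclera_gray))
    pl_stop("invalidParams", "palette must satisfy pupil < iris < sclera")
  a_max <- max(p$pupil_axes) * (1 + p$boundary_roughness) +
    sqrt(sum(p$iris_offset^2))
  if (a_max >= p$iris_radius)
    pl_stop("invalidParams", "pupil ellipse must fit inside the iris disc")
  cx <- p$pupil_center[1] + p$iris_offset[1]
  cy <- p$pupil_center[2] + p$iris_offset[2]
  if (cx - p$iris_radius < 0 || cx + p$iris_radius >= p$width ||
      cy - p$iris_radius < 0 || cy + p$iris_radius >= p$height)
    pl_stop("invalidParams", "iris disc must lie inside the image")
  if (p$blur_sigma < 0 || p$noise_std < 0 || p$boundary_roughness < 0)
    pl_stop("invalidParams", "blur_sigma, noise_std, boundary_roughness must be >= 0")
  p
}

#' Render a synthetic eye scene
#'
#' Paints the scene layers (skin, sclera lens, iris, rough-boundary pupil,
#' eyebrow, glints), applies Gaussian defocus blur, adds sensor noise and
#' clamps to \[0, 255\]. Fully reproducible when `p$seed` is set.
#'
#' @param p A [scene_params()] object.
#' @return List with `image` (grayscale matrix) and `truth` (list with the
#'   pre-blur pupil centroid `x0`, `y0`, the axes, angle, `blur_sigma` and
#'   `defocus_z_cm`).
#' @examples
#' scene <- render_scene(scene_params(seed = 1, blur_sigma = 3))
#' scene$truth$x0
#' @export
render_scene <- function(p) {
  stopifnot(inherits(p, "scene_params"))
  if (!is.null(p$seed)) set.seed(p$seed)
  h <- as.integer(p$height); w <- as.integer(p$width)
  cx <- p$pupil_center[1]; cy <- p$pupil_center[2]
  icx <- cx + p$iris_offset[1]; icy <- cy + p$iris_offset[2]
  X <- matrix(rep(0:(w - 1L), each = h), h, w)
  Y <- matrix(rep(0:(h - 1L), w), h, w)
  img <- matrix(p$skin_gray, h, w)

  # sclera: lens-shaped eye opening (intersection of two circles)
  wl <- 1.9 * p$iris_radius            # half-width of the opening
  hl <- 1.3 * p$iris_radius            # half-height
  R <- (wl^2 + hl^2) / (2 * hl)
  d2a <- (X - icx)^2 + (Y - (icy + (R - hl)))^2
  d2b <- (X - icx)^2 + (Y - (icy - (R - hl)))^2
  img[d2a <= R^2 & d2b <= R^2] <- p$sclera_gray

  # eyebrow distractor: dark bar above the eye opening
  if (isTRUE(p$eyebrow)) {
    off <- stats::runif(1, -30, 30)
    ex0 <- max(0, round(icx - 100 + off)); ex1 <- min(w - 1, round(icx + 100 + off))
    ey1 <- round(icy - hl - 25); ey0 <- ey1 - 20
    if (ey0 < 0) { ey0 <- 0; ey1 <- max(ey1, 5) }
    if (ex1 > ex0 && ey1 > ey0)
      img[(ey0 + 1):(ey1 + 1), (ex0 + 1):(ex1 + 1)] <- p$eyebrow_gray
  }

  # iris disc (pupil sits slightly off its center when iris_offset != 0)
  d2 <- (X - icx)^2 + (Y - icy)^2
  img[d2 <= p$iris_radius^2] <- p$iris_gray

  # pupil ellipse with radial boundary roughness
  a <- p$pupil_axes[1]; b <- p$pupil_axes[2]; th <- p$pupil_angle
  U <- ((X - cx) * cos(th) + (Y - cy) * sin(th)) / a
  V <- (-(X - cx) * sin(th) + (Y - cy) * cos(th)) / b
  rho <- sqrt(U^2 + V^2)
  if (p$boundary_roughness > 0) {
    amp <- stats::runif(3); amp <- amp / max(sum(amp), 1e-9)
    phase <- stats::runif(3, 0, 2 * pi)
    phi <- atan2(V, U)
    eps <- p$boundary_roughness *
      (amp[1] * cos(2 * phi + phase[1]) + amp[2] * cos(3 * phi + phase[2]) +
         amp[3] * cos(5 * phi + phase[3]))
  } else {
    eps <- 0
  }
  pupil_mask <- rho <= 1 + eps
  img[pupil_mask] <- p$pupil_gray

  # ground truth: centroid of the pre-blur pupil support
  truth <- list(
    x0 = mean(X[pupil_mask]), y0 = mean(Y[pupil_mask]),
    a = a, b = b, angle = th,
    blur_sigma = p$blur_sigma, defocus_z_cm = p$defocus_z_cm)

  # corneal glints: near-saturated discs overlapping pupil/iris
  if (p$n_glints > 0L) {
    for (k in seq_len(p$n_glints)) {
      gr <- stats::runif(1, p$glint_radius_range[1], p$glint_radius_range[2])
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 1.1 * a)
      gx <- cx + rad * cos(ang); gy <- cy + rad * sin(ang)
      img[(X - gx)^2 + (Y - gy)^2 <= gr^2] <- p$glint_gray
    }
  }

  if (p$blur_sigma > 0)
    img <- EBImage::gblur(img / 255, sigma = p$blur_sigma) * 255
  if (p$noise_std > 0)
    img <- img + stats::rnorm(length(img), 0, p$noise_std)
  img <- round(img)
  img[img < 0] <- 0; img[img > 255] <- 255

  list(image = img, truth = truth, params = p)
}

# Deterministic per-image seed derivation (kept below 2^31).
derive_seed <- function(master, index) {
  (as.numeric(master) %% 65011 * 33013 + index * 9973 + 1) %% 2147483647
}

#' Draw a randomized scene from a per-image seed
#'
#' Used by [generate_dataset()] and by tests to re-derive a scene from its
#' manifest seed. Scene randomization: center jitter of +/- 50 (x) and
#' +/- 40 (y) px around the frame center, pupil semi-major axis
#' U\[48, 58\] px with axis ratio U\[0.90, 1\], random orientation, iris
#' radius `a` + U\[50, 65\] px with a pupil decentration of up to 4 px,
#' 1-2 glints, eyebrow present with probability 0.8.
#'
#' @param seed Per-image RNG seed.
#' @param z_cm Defocus distance (cm) mapped through [defocus_to_sigma()].
#' @param sigma_max,z_max Defocus model parameters.
#' @param noise_std Sensor noise standard deviation.
#' @return As [render_scene()].
#' @export
random_scene <- function(seed, z_cm = 0, sigma_max = 6, z_max = 20,
                         noise_std = 3) {
  set.seed(seed)
  a <- stats::runif(1, 48, 58)
  b <- a * stats::runif(1, 0.90, 1)
  dec <- stats::runif(1, 0, 4); dang <- stats::runif(1, 0, 2 * pi)
  p <- scene_params(
    pupil_center = c(320 + stats::runif(1, -50, 50),
                     240 + stats::runif(1, -40, 40)),
    pupil_axes = c(a, b),
    pupil_angle = stats::runif(1, 0, pi),
    iris_offset = dec * c(cos(dang), sin(dang)),
    iris_radius = a + stats::runif(1, 50, 65),
    n_glints = sample(1:2, 1),
    eyebrow = stats::runif(1) < 0.8,
    blur_sigma = defocus_to_sigma(z_cm, sigma_max, z_max),
    noise_std = noise_std,
    defocus_z_cm = z_cm,
    seed = NULL)                       # continue the stream seeded above
  render_scene(p)
}

#' Generate a ground-truthed synthetic defocus dataset
#'
#' Writes `n` randomized scenes per blur level as 8-bit PNGs plus a
#' ground-truth manifest CSV (`filename, x0, y0, a, b, angle_rad,
#' blur_sigma, defocus_z_cm, seed`). Per-image seeds are derived
#' deterministically from the master seed, so the dataset is fully
#' reproducible and any scene can be re-rendered from its manifest row.
#'
#' @param n Images per blur level.
#' @param blur_levels Defocus distances in cm (see [defocus_to_sigma()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param sigma_max,z_max,noise_std Passed to [random_scene()].
#' @return The manifest as a data frame, invisibly; also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @examples
#' \donttest{
#' man <- generate_dataset(2, blur_levels = c(0, 20), out_dir = tempfile(),
#'                         seed = 42)
#' nrow(man)
#' }
#' @export
generate_dataset <- function(n, blur_levels = c(0, 5, 10, 15, 20),
                             out_dir = ".", seed = 42,
                             sigma_max = 6, z_max = 20, noise_std = 3) {
  if (n < 1L) pl_stop("invalidParams", "n must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n * length(blur_levels))
  idx <- 0L
  for (z in blur_levels) {
    for (i in seq_len(n)) {
      idx <- idx + 1L
      s <- derive_seed(seed, idx)
      scene <- random_scene(s, z_cm = z, sigma_max = sigma_max,
                            z_max = z_max, noise_std = noise_std)
      fname <- sprintf("eye_z%02d_%03d.png", as.integer(round(z)), i)
      write_eye_image(scene$image, file.path(out_dir, fname))
      tr <- scene$truth
      rows[[idx]] <- data.frame(
        filename = fname, x0 = tr$x0, y0 = tr$y0, a = tr$a, b = tr$b,
        angle_rad = tr$angle, blur_sigma = tr$blur_sigma,
        defocus_z_cm = z, seed = s)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
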