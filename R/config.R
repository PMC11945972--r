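#' Pipeline configuration
#'
#' Collects every tunable of the localization pipeline with its default.
#' The two shape-index weights come from the method's design
#' (`lambda1 = 0.6`, `lambda2 = 0.4`); the remaining values parameterize the
#' grayscale stage (histogram smoothing, projection cut, mask expansion) and
#' the geometric stage (opening radius, minimum candidate area).
#'
#' @param smooth_window Odd width (gray levels) of the centered moving average
#'   applied to the histogram before valley detection.
#' @param min_peak_frac A histogram peak is "significant" when its smoothed
#'   count reaches this fraction of the total pixel count.
#' @param projection_frac Fraction of a projection profile's maximum used to
#'   delimit its main interval.
#' @param expand_divisor The rough-region rectangle is expanded on every side
#'   by `floor(long_side / expand_divisor)` pixels.
#' @param max_foreground_frac Sanity cap: if thresholding marks more than this
#'   fraction of the image as dark foreground, the grayscale stage declares
#'   that no pupil candidate exists (the pupil is a small dark minority).
#' @param opening_radius Radius (px) of the structuring element of the
#'   morphological opening; radius 1 is a 3x3 element.
#' @param min_area Minimum candidate region area (px) considered by the
#'   shape-index screening.
#' @param lambda1,lambda2 Weights of the inertia-ratio and ellipse-fit terms
#'   of the pupil shape index; they must sum to 1.
#' @param sigma_max,z_max Defocus model of the synthetic generator: Gaussian
#'   blur sigma (px) at the largest defocus distance `z_max` (cm).
#' @param log_level One of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @return A named list of class `pupil_config`.
#' @examples
#' cfg <- pupil_config(lambda1 = 0.7, lambda2 = 0.3)
#' cfg$lambda1
#' @seealso [locate_pupil()], [load_pupil_config()]
#' @export
pupil_config <- function(smooth_window = 5L,
                         min_peak_frac = 0.001,
                         projection_frac = 0.15,
                         expand_divisor = 20L,
                         max_foreground_frac = 0.5,
                         opening_radius = 1L,
                         min_area = 15L,
                         lambda1 = 0.6,
                         lambda2 = 0.4,
                         sigma_max = 6,
                         z_max = 20,
                         log_level = "info") {
  cfg <- list(
    smooth_window = as.integer(smooth_window),
    min_peak_frac = min_peak_frac,
    projection_frac = projection_frac,
    expand_divisor = as.integer(expand_divisor),
    max_foreground_frac = max_foreground_frac,
    opening_radius = as.integer(opening_radius),
    min_area = as.integer(min_area),
    lambda1 = lambda1,
    lambda2 = lambda2,
    sigma_max = sigma_max,
    z_max = z_max,
    log_level = log_level
  )
  class(cfg) <- "pupil_config"
  validate_pupil_config(cfg)
}

validate_pupil_config <- function(cfg) {
  if (cfg$smooth_window < 1L || cfg$smooth_window %% 2L == 0L)
    pl_stop("invalidConfig", "smooth_window must be an odd integer >= 1")
  if (cfg$projection_frac <= 0 || cfg$projection_frac >= 1)
    pl_stop("invalidConfig", "projection_frac must lie in (0, 1)")
  if (cfg$expand_divisor < 1L)
    pl_stop("invalidConfig", "expand_divisor must be >= 1")
  if (abs(cfg$lambda1 + cfg$lambda2 - 1) > 1e-9 || cfg$lambda1 < 0 || cfg$lambda2 < 0)
    pl_stop("invalidConfig", "lambda1 and lambda2 must be non-negative and sum to 1")
  if (!cfg$log_level %in% c("debug", "info", "warning", "error"))
    pl_stop("invalidConfig", "unknown log_level")
  cfg
}

#' @export
print.pupil_config <- function(x, ...) {
  cat("Pupil localization configuration:\n")
  for (k in setdiff(names(x), "log_level"))
    cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  cat(sprintf("  %-20s %s\n", "log_level", x$log_level))
  invisible(x)
}

#' Read / write a configuration file
#'
#' Configurations are stored as a flat YAML mapping; unknown keys are
#' rejected so typos fail loudly. `load(save(cfg))` reproduces `cfg`.
#'
#' @param path File path.
#' @param cfg A [pupil_config()] object.
#' @return `load_pupil_config()` returns a `pupil_config`;
#'   `save_pupil_config()` returns `path` invisibly.
#' @export
load_pupil_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pupil_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    pl_stop("invalidConfig", paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  do.call(pupil_config, vals)
}

#' @rdname load_pupil_config
#' @export
save_pupil_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pupil_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## Minimal leveled logger used by the CLI and the pipeline warnings.
.pl_log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

pl_log <- function(level, msg, threshold = getOption("pupilloc.log_level", "info")) {
  if (.pl_log_levels[[level]] >= .pl_log_levels[[threshold]])
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    toupper(level), msg))
  invisible(NULL)
}
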