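## Evaluation: Euclidean localization error, thresholded accuracy, and the
## blur-stratified benchmark harness.

#' Euclidean localization error
#'
#' `sqrt((x - x0)^2 + (y - y0)^2)` between a predicted and a true pupil
#' center, in pixels.
#'
#' @param pred,truth Numeric `c(x, y)`.
#' @return Non-negative distance in pixels.
#' @examples
#' localization_error(c(3, 4), c(0, 0))  # 5
#' @export
localization_error <- function(pred, truth) {
  stopifnot(length(pred) == 2L, length(truth) == 2L,
            all(is.finite(pred)), all(is.finite(truth)))
  sqrt(sum((as.numeric(pred) - as.numeric(truth))^2))
}

#' Correctness criterion for a localization
#'
#' A localization counts as correct when its error is within 1% of the
#' number of pixels on the long side of the image (inclusive) — the ground
#' truth itself carries slight annotation uncertainty at that scale.
#'
#' @param error Localization error (px).
#' @param img_w,img_h Image dimensions.
#' @return Logical.
#' @examples
#' is_correct(6.4, 640, 480)  # TRUE: threshold is exactly 6.4 px
#' @export
is_correct <- function(error, img_w, img_h) {
  stopifnot(error >= 0)
  error <= 0.01 * max(img_w, img_h)
}

#' Accuracy over evaluation records
#'
#' Ratio of correctly located images to all images. Records with no
#' detection count as incorrect (they stay in the denominator).
#'
#' @param records Data frame with a logical `correct` column (`NA` is
#'   treated as incorrect), or a logical vector.
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(records) {
  correct <- if (is.data.frame(records)) records$correct else records
  if (length(correct) == 0L)
    pl_stop("emptyEvaluation", "no records to evaluate")
  mean(correct %in% TRUE)
}

#' Run the blur-stratified localization benchmark
#'
#' Locates the pupil on every image of a ground-truth manifest (as written
#' by [generate_dataset()]), computes per-image errors against the true
#' centers, and aggregates mean error and accuracy per defocus level and
#' overall. Missing or unreadable images are logged, marked failed, and
#' count as incorrect; their errors are excluded from mean-error
#' aggregation. Per-image wall-clock times are recorded as information
#' only.
#'
#' @param manifest Data frame or path to a manifest CSV with columns
#'   `filename, x0, y0, defocus_z_cm` (other columns are carried along).
#' @param cfg A [pupil_config()].
#' @param image_dir Directory the filenames are relative to; defaults to
#'   the manifest's own directory when `manifest` is a path, else `"."`.
#' @return Object of class `pupil_benchmark`: list with `records` (per-image
#'   data frame), `levels` (per-defocus-level `n`, `mean_error_px`,
#'   `accuracy`), and `overall`.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' man <- generate_dataset(3, blur_levels = c(0, 20), out_dir = dir, seed = 1)
#' bm <- run_benchmark(man, image_dir = dir)
#' summary(bm)
#' }
#' @export
run_benchmark <- function(manifest, cfg = pupil_config(), image_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(image_dir)) image_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest)
  }
  if (is.null(image_dir)) image_dir <- "."
  if (nrow(manifest) == 0L) pl_stop("emptyEvaluation", "empty manifest")
  stopifnot(all(c("filename", "x0", "y0") %in% names(manifest)))
  if (!"defocus_z_cm" %in% names(manifest)) manifest$defocus_z_cm <- NA_real_

  n <- nrow(manifest)
  records <- data.frame(
    filename = manifest$filename, defocus_z_cm = manifest$defocus_z_cm,
    status = NA_character_, xc = NA_real_, yc = NA_real_,
    x0 = manifest$x0, y0 = manifest$y0,
    error = NA_real_, correct = FALSE, time_s = NA_real_)
  for (i in seq_len(n)) {
    path <- file.path(image_dir, manifest$filename[i])
    if (!file.exists(path)) {
      pl_log("warning", paste0("missing image: ", path))
      records$status[i] <- "read_error"
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(locate_pupil(read_eye_image(path), cfg),
                    pupilloc_error = function(e) {
                      pl_log("warning", conditionMessage(e)); NULL
                    })
    records$time_s[i] <- proc.time()[["elapsed"]] - t0
    if (is.null(res)) { records$status[i] <- "read_error"; next }
    records$status[i] <- res$status
    if (res$status == "ok") {
      records$xc[i] <- res$xc; records$yc[i] <- res$yc
      records$error[i] <- localization_error(c(res$xc, res$yc),
                                             c(manifest$x0[i], manifest$y0[i]))
      records$correct[i] <- is_correct(records$error[i],
                                       res$dim[2], res$dim[1])
    }
  }
  agg <- function(rec) {
    c(n = nrow(rec),
      mean_error_px = mean(rec$error, na.rm = TRUE),
      accuracy = mean(rec$correct %in% TRUE))
  }
  lvls <- sort(unique(records$defocus_z_cm), na.last = TRUE)
  levels_df <- do.call(rbind, lapply(lvls, function(z) {
    rec <- if (is.na(z)) records[is.na(records$defocus_z_cm), ]
           else records[records$defocus_z_cm %in% z, ]
    data.frame(defocus_z_cm = z, n = nrow(rec),
               mean_error_px = mean(rec$error, na.rm = TRUE),
               accuracy = mean(rec$correct %in% TRUE))
  }))
  overall <- list(n = n,
                  n_failed = sum(records$status != "ok"),
                  mean_error_px = mean(records$error, na.rm = TRUE),
                  accuracy = mean(records$correct %in% TRUE),
                  mean_time_s = mean(records$time_s, na.rm = TRUE))
  structure(list(records = records, levels = levels_df, overall = overall),
            class = "pupil_benchmark")
}

#' @export
print.pupil_benchmark <- function(x, ...) {
  cat(sprintf("Pupil localization benchmark: %d images, accuracy %.1f%%, mean error %.3f px\n",
              x$overall$n, 100 * x$overall$accuracy, x$overall$mean_error_px))
  invisible(x)
}

#' @export
summary.pupil_benchmark <- function(object, ...) {
  cat("Per-defocus-level results:\n")
  lv <- object$levels
  lv$accuracy_pct <- 100 * lv$accuracy
  print(lv[, c("defocus_z_cm", "n", "mean_error_px", "accuracy_pct")],
        row.names = FALSE, digits = 4)
  cat(sprintf("Overall: n = %d (%d failed), mean error %.3f px, accuracy %.2f%%, mean time %.1f ms\n",
              object$overall$n, object$overall$n_failed,
              object$overall$mean_error_px, 100 * object$overall$accuracy,
              1000 * object$overall$mean_time_s))
  invisible(object)
}

#' @export
as.data.frame.pupil_benchmark <- function(x, ...) x$records

#' Write a benchmark report
#'
#' Writes the per-record CSV and a JSON report with the schema
#' `{levels: [{z_cm, n, mean_error_px, accuracy}], overall: {...}}`.
#'
#' @param bm A [run_benchmark()] result.
#' @param csv_path,json_path Output paths (`NULL` skips that format).
#' @return `bm`, invisibly.
#' @export
write_benchmark_report <- function(bm, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(bm, "pupil_benchmark"))
  if (!is.null(csv_path))
    utils::write.csv(bm$records, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    lv <- bm$levels
    report <- list(
      levels = lapply(seq_len(nrow(lv)), function(i)
        list(z_cm = lv$defocus_z_cm[i], n = lv$n[i],
             mean_error_px = lv$mean_error_px[i], accuracy = lv$accuracy[i])),
      overall = bm$overall)
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(bm)
}
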