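## Shared internal helpers: classed conditions and the rectangle type.

# Classed errors so callers can distinguish recoverable pipeline failures
# (no valley, no candidate region, ...) from programming errors.
pl_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pupilloc_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

pl_warn <- function(msg) warning(msg, call. = FALSE)

#' Axis-aligned pixel rectangle
#'
#' Rectangles use 0-based pixel indices, inclusive at `(x0, y0)` and exclusive
#' at `(x1, y1)`, with `x` the column index and `y` the row index.
#'
#' @param x0,y0 Inclusive top-left corner (0-based).
#' @param x1,y1 Exclusive bottom-right corner.
#' @return An object of class `pl_rect`: a named integer vector
#'   `c(x0, y0, x1, y1)`.
#' @examples
#' pl_rect(10, 20, 40, 60)
#' @export
pl_rect <- function(x0, y0, x1, y1) {
  r <- c(x0 = as.integer(x0), y0 = as.integer(y0),
         x1 = as.integer(x1), y1 = as.integer(y1))
  if (r["x0"] < 0L || r["y0"] < 0L || r["x1"] <= r["x0"] || r["y1"] <= r["y0"])
    pl_stop("invalidRect", "rectangle must satisfy 0 <= x0 < x1, 0 <= y0 < y1")
  class(r) <- "pl_rect"
  r
}

#' @export
print.pl_rect <- function(x, ...) {
  cat(sprintf("<pl_rect> x [%d, %d) x y [%d, %d)  (%d x %d px)\n",
              x["x0"], x["x1"], x["y0"], x["y1"],
              x["x1"] - x["x0"], x["y1"] - x["y0"]))
  invisible(x)
}

rect_width  <- function(r) unname(r["x1"] - r["x0"])
rect_height <- function(r) unname(r["y1"] - r["y0"])

# Validate an 8-bit grayscale image matrix (H x W, [y, x] indexing).
check_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    pl_stop("invalidImage", "image must be a numeric matrix (H x W)")
  if (nrow(img) < 1L || ncol(img) < 1L)
    pl_stop("emptyImage", "image has zero pixels")
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    pl_stop("invalidImage", "intensities must lie in [0, 255] with no NA")
  invisible(img)
}
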