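#' Read a grayscale eye image
#'
#' Decodes PNG, JPEG, TIFF or PGM (P2/P5) files into an 8-bit grayscale
#' matrix. RGB images are converted with the Rec. 601 luma weights
#' (0.299 R + 0.587 G + 0.114 B); inputs with more than 8 bits per sample are
#' rescaled to \[0, 255\] with a warning.
#'
#' @param path Image file path.
#' @return An `H x W` numeric matrix of integer-valued intensities in
#'   \[0, 255\], indexed `img[y + 1, x + 1]` (row = y, column = x, 0-based
#'   pixel coordinates with centers at integers).
#' @examples
#' \dontrun{
#' img <- read_eye_image("eye.png")
#' }
#' @export
read_eye_image <- function(path) {
  if (!file.exists(path))
    pl_stop("missingImage", paste0("cannot read image: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp")
    pl_stop("unsupportedFormat",
            "BMP decoding is not supported; convert to PNG/PGM first")
  if (ext %in% c("pgm", "pnm")) return(read_pgm(path))
  arr <- tryCatch(EBImage::imageData(EBImage::readImage(path)),
                  error = function(e)
                    pl_stop("readError", paste0("failed to decode ", path, ": ",
                                                conditionMessage(e))))
  # EBImage stores [x, y(, channel)] in [0, 1]
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    wts <- if (nc >= 3L) c(0.299, 0.587, 0.114) else rep(1 / nc, nc)
    g <- matrix(0, dim(arr)[1], dim(arr)[2])
    for (k in seq_along(wts)) g <- g + wts[k] * arr[, , k]
    arr <- g
  }
  img <- round(t(arr) * 255)
  img[img < 0] <- 0; img[img > 255] <- 255
  check_gray_image(img)
}

# Minimal PGM reader (ASCII P2 and binary P5, maxval up to 65535).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) pl_stop("readError", "truncated PGM header")
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5"))
    pl_stop("unsupportedFormat", paste0("not a PGM file (magic ", magic, ")"))
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1L || h < 1L)
    pl_stop("readError", "invalid PGM header")
  n <- w * h
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval < 256L) {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "big")
  }
  if (length(vals) != n) pl_stop("readError", "truncated PGM pixel data")
  img <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (maxval > 255L) {
    pl_warn("rescaling >8-bit PGM to [0, 255]")
    img <- round(img * 255 / maxval)
  }
  check_gray_image(img)
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img `H x W` matrix of intensities in \[0, 255\].
#' @param path Output file path (`.png`).
#' @return `path`, invisibly.
#' @export
write_eye_image <- function(img, path) {
  check_gray_image(img)
  EBImage::writeImage(t(img) / 255, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}
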