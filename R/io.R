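# Image input/output. The native interchange format is plain (ASCII) PPM
# (P3), which needs no binary decoder; PNG is supported when the optional
# `png` package is installed.

#' Write an image as plain PPM (P3)
#'
#' 8-bit ASCII PPM: channels are scaled by 255 and rounded half-up.
#'
#' @param img An [rgb_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path) {
  img <- if (inherits(img, "rgb_image")) img else rgb_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  vals <- as.integer(floor(img * 255 + 0.5))
  arr <- array(vals, dim = dim(img))
  # interleave R,G,B per pixel, pixels in row-major (English reading) order
  flat <- as.vector(aperm(arr, c(3L, 2L, 1L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(flat[seq(1, length(flat), 3)],
                   flat[seq(2, length(flat), 3)],
                   flat[seq(3, length(flat), 3)]), con)
  invisible(path)
}

#' Read a plain PPM (P3) image
#'
#' @param path Path to a P3 PPM file.
#' @return An [rgb_image()] with channels divided by the file's maxval.
#' @export
read_ppm <- function(path) {
  raw_lines <- readLines(path)
  raw_lines <- sub("#.*$", "", raw_lines)           # strip comments
  toks <- scan(text = paste(raw_lines, collapse = " "), what = character(),
               quiet = TRUE)
  if (length(toks) < 4L || toks[1] != "P3") stop("not a plain (P3) PPM file: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != 3L * w * h) stop("truncated PPM file: ", path)
  m <- matrix(vals, ncol = 3L, byrow = TRUE) / maxval   # pixels row-major
  out <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) out[, , k] <- matrix(m[, k], h, w, byrow = TRUE)
  rgb_image(out)
}

#' Read an image (PPM or PNG)
#'
#' Dispatches on the file extension; `.png` requires the optional `png`
#' package, everything else is treated as plain PPM.
#'
#' @param path Image path.
#' @return An [rgb_image()] with channels in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package; use plain PPM instead")
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    return(rgb_image(a[, , 1:3, drop = FALSE]))
  }
  read_ppm(path)
}

#' Write an image (PPM or PNG)
#'
#' @param img An [rgb_image()].
#' @param path Output path; `.png` requires the optional `png` package.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the 'png' package; use plain PPM instead")
    img <- if (inherits(img, "rgb_image")) img else rgb_image(img)
    png::writePNG(unclass(img), path)
    return(invisible(path))
  }
  write_ppm(img, path)
}
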