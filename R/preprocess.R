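# Pre-processing: circular mean filtering that blurs away edge/semantic
# structure before feature extraction, and the BT.709 grayscale used by the
# entropy and watershed computations.

#' Grayscale image container
#'
#' Integer matrix with values in `[0, 255]`, row 1 at the top.
#'
#' @param x Numeric matrix of values in `[0, 255]`.
#' @return An object of class `gray_image` (integer matrix).
#' @export
gray_image <- function(x) {
  if (!is.matrix(x)) stop("gray_image requires a matrix")
  if (anyNA(x) || any(x < 0) || any(x > 255))
    stop("gray_image values must lie in [0, 255]")
  storage.mode(x) <- "integer"
  structure(x, class = "gray_image")
}

## Horizontal windowed row sums of M with half-width w, zero outside support.
## Returns S[i, j] = sum_{x = j-w .. j+w, in-image} M[i, x].
.row_window_sum <- function(M, w) {
  W <- ncol(M)
  cs <- cbind(0, t(apply(M, 1L, cumsum)))           # H x (W+1) padded cumsum
  hi <- pmin(seq_len(W) + w, W) + 1L
  lo <- pmax(seq_len(W) - w - 1L, 0L) + 1L
  cs[, hi, drop = FALSE] - cs[, lo, drop = FALSE]
}

## Shift the rows of M down by dy (dy < 0 shifts up), zero-filling: the
## result at row i holds M[i - dy, ] when in range.
.row_shift <- function(M, dy) {
  H <- nrow(M)
  out <- matrix(0, H, ncol(M))
  src <- seq_len(H) - dy
  keep <- src >= 1L & src <= H
  out[keep, ] <- M[src[keep], , drop = FALSE]
  out
}

#' Circular mean filter
#'
#' Replaces each value by the mean over the circular template of the given
#' radius centered on it: pixels `(x, y)` with
#' `(x - i)^2 + (y - j)^2 <= radius^2` (center included). At the borders the
#' template is intersected with the image and the mean renormalized, so no
#' out-of-image values are invented.
#'
#' @param M Numeric matrix (one channel).
#' @param radius Template radius in pixels, non-negative integer;
#'   `radius = 0` is the identity.
#' @return Filtered matrix of the same dimensions.
#' @export
circular_mean_filter <- function(M, radius) {
  if (!is.matrix(M)) stop("circular_mean_filter requires a matrix")
  radius <- as.integer(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 0L)
    stop("radius must be a single non-negative integer")
  if (radius > min(dim(M)))
    stop(sprintf("radius %d exceeds the smaller image dimension %d; choose a smaller smoothing radius",
                 radius, min(dim(M))))
  if (radius == 0L) return(M)
  rng <- range(M)
  if (rng[1] == rng[2]) return(M)        # mean of constants, exactly
  num <- matrix(0, nrow(M), ncol(M))
  den <- matrix(0, nrow(M), ncol(M))
  ones <- matrix(1, nrow(M), ncol(M))
  for (dy in -radius:radius) {
    w <- as.integer(floor(sqrt(radius^2 - dy^2)))   # half-width of disk row dy
    num <- num + .row_shift(.row_window_sum(M, w), dy)
    den <- den + .row_shift(.row_window_sum(ones, w), dy)
  }
  num / den
}

#' Smooth a multi-color material
#'
#' Applies the circular mean filter independently to the R, G and B
#' channels. The default radius of 50 pixels is the smoothing degree at
#' which edge/semantic information in film-scene material ceases to be
#' recognizable.
#'
#' @param img An [rgb_image()].
#' @param radius Smoothing radius in pixels (default 50).
#' @return The smoothed [rgb_image()].
#' @export
smooth_material <- function(img, radius = 50L) {
  img <- if (inherits(img, "rgb_image")) img else rgb_image(img)
  out <- array(0, dim = dim(img))
  for (k in 1:3) out[, , k] <- circular_mean_filter(img[, , k], radius)
  rgb_image(out)
}

#' BT.709 grayscale of an RGB image
#'
#' Luma `0.2126 R + 0.7152 G + 0.0722 B` on the `[0, 1]` channels, scaled
#' to `[0, 255]` and rounded half-up.
#'
#' @param img An [rgb_image()].
#' @return A [gray_image()].
#' @export
to_gray <- function(img) {
  img <- if (inherits(img, "rgb_image")) img else rgb_image(img)
  d <- dim(img)
  y <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  gray_image(matrix(floor(y * 255 + 0.5), d[1], d[2]))
}
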