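# RGB -> XYZ -> CIELAB conversion chain (BT.709 primaries, D65 reference
# white), plus the polar hue-angle/chroma derivation and the algebraic
# inverse used to render palettes back to RGB.

## BT.709 RGB -> XYZ matrix applied to channels normalized to [0,1].
.RGB2XYZ <- matrix(c(
  0.412453, 0.357580, 0.180423,
  0.212671, 0.715160, 0.072169,
  0.019334, 0.119193, 0.950227
), nrow = 3L, byrow = TRUE)

## D65 reference white used for the XYZ normalization step.
.D65_WHITE <- c(X = 0.950456, Y = 1.0, Z = 1.088754)

## CIELAB transfer-function knot: linear branch below (6/29)^3.
.LAB_KNOT <- (6 / 29)^3

# ---------------------------------------------------------------------------
# image containers -----------------------------------------------------------

#' RGB image container
#'
#' Wraps a numeric `height x width x 3` array with channels in `[0, 1]`
#' (8-bit inputs are divided by 255 by [read_image()]). Pixel `[i, j, ]`
#' is row `i` from the top, column `j` from the left.
#'
#' @param x Numeric array `h x w x 3` with all values in `[0, 1]`, or a
#'   matrix `h x w` that is replicated across the three channels.
#' @return An object of class `rgb_image` (the validated array).
#' @export
rgb_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("rgb_image requires an h x w x 3 array")
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("rgb_image requires height >= 1 and width >= 1")
  storage.mode(x) <- "double"
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop("rgb_image channels must lie in [0, 1]")
  structure(x, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, channels in [%.3f, %.3f]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' CIELAB image container
#'
#' A numeric `height x width x 3` array holding per-pixel
#' (L*, a*, b*): lightness in `[0, 100]` for images converted from RGB,
#' and the red/green and yellow/blue opponent axes.
#'
#' @param x Numeric array `h x w x 3` of finite values.
#' @return An object of class `lab_image`.
#' @export
lab_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("lab_image requires an h x w x 3 array")
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("lab_image values must be finite")
  structure(x, class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<lab_image %d x %d, L* in [%.2f, %.2f]>\n",
              d[1], d[2], min(x[, , 1]), max(x[, , 1])))
  invisible(x)
}

## Flatten an h x w x 3 array to an n x 3 channel matrix and back.
.flatten3 <- function(x) {
  d <- dim(x)
  list(m = matrix(x, ncol = 3L), dim = d)
}

.unflatten3 <- function(m, d) array(m, dim = d)

# ---------------------------------------------------------------------------
# forward chain --------------------------------------------------------------

#' Convert normalized RGB to XYZ tristimulus values
#'
#' Applies the BT.709 linear 3x3 matrix directly to the `[0, 1]` channel
#' values. No gamma expansion is performed by default (see
#' [rgb_to_lab()] for the optional flag); the conversion chain treats the
#' stored channel values themselves as the tristimulus inputs.
#'
#' @param img An [rgb_image()] (or bare `h x w x 3` array in `[0, 1]`).
#' @return `h x w x 3` array of (X, Y, Z).
#' @export
rgb_to_xyz <- function(img) {
  img <- if (inherits(img, "rgb_image")) img else rgb_image(img)
  f <- .flatten3(img)
  .unflatten3(f$m %*% t(.RGB2XYZ), f$dim)
}

#' Normalize XYZ for the D65 white point
#'
#' Divides each channel by the D65 reference white
#' (X = 0.950456, Y = 1, Z = 1.088754).
#'
#' @param xyz `h x w x 3` array (or `n x 3` matrix) of XYZ values.
#' @return Array of the same shape with the white point mapped to (1, 1, 1).
#' @export
normalize_d65 <- function(xyz) {
  if (!all(is.finite(xyz))) stop("XYZ values must be finite")
  if (is.matrix(xyz)) return(sweep(xyz, 2L, .D65_WHITE, "/"))
  f <- .flatten3(xyz)
  .unflatten3(sweep(f$m, 2L, .D65_WHITE, "/"), f$dim)
}

#' CIELAB transfer function f(t)
#'
#' Cube root above the knot `(6/29)^3`, linear continuation
#' `(1/3) (29/6)^2 t + 16/116` below it. Continuous and monotone
#' increasing on the non-negative reals.
#'
#' @param t Numeric vector, `t >= 0`.
#' @return `f(t)`, same shape as `t`.
#' @export
lab_transfer <- function(t) {
  ifelse(t > .LAB_KNOT, t^(1 / 3), (1 / 3) * (29 / 6)^2 * t + 16 / 116)
}

#' Convert white-point-normalized XYZ to CIELAB
#'
#' `L* = 116 f(Y) - 16`, `a* = 500 (f(X) - f(Y))`, `b* = 200 (f(Y) - f(Z))`.
#'
#' @param xyz `h x w x 3` array of D65-normalized XYZ (see [normalize_d65()]).
#' @return A [lab_image()].
#' @export
xyz_to_lab <- function(xyz) {
  f <- .flatten3(xyz)
  fx <- lab_transfer(f$m[, 1]); fy <- lab_transfer(f$m[, 2]); fz <- lab_transfer(f$m[, 3])
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  lab_image(.unflatten3(lab, f$dim))
}

## sRGB electro-optical transfer (gamma expansion), optional in rgb_to_lab.
.srgb_expand <- function(u) ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
.srgb_compress <- function(u) ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)

#' Convert an RGB image to CIELAB
#'
#' Composition of [rgb_to_xyz()], [normalize_d65()] and [xyz_to_lab()].
#' By default the matrix is applied to the raw normalized channels with no
#' gamma expansion; set `gamma = TRUE` for a colorimetrically standard sRGB
#' decoding before the matrix.
#'
#' @param img An [rgb_image()].
#' @param gamma Apply the sRGB gamma expansion before the linear matrix
#'   (default `FALSE`).
#' @return A [lab_image()].
#' @export
rgb_to_lab <- function(img, gamma = FALSE) {
  img <- if (inherits(img, "rgb_image")) img else rgb_image(img)
  if (gamma) {
    img <- structure(array(.srgb_expand(img), dim = dim(img)), class = "rgb_image")
  }
  xyz_to_lab(normalize_d65(rgb_to_xyz(img)))
}

# ---------------------------------------------------------------------------
# polar coordinates ----------------------------------------------------------

#' Hue angle and chroma from CIELAB
#'
#' Polar coordinates of the chromatic (a*, b*) plane: hue angle `h` via the
#' two-argument arctangent in degrees `[0, 360)`, chroma
#' `C* = sqrt(a*^2 + b*^2)`. Achromatic pixels (`a* = b* = 0`) are assigned
#' `h = 0` by convention; every downstream use multiplies by `C*`, so the
#' choice is inert.
#'
#' @param lab A [lab_image()].
#' @return `h x w x 2` array with slices `h` (degrees) and `C*`.
#' @export
lab_to_hue_chroma <- function(lab) {
  d <- dim(lab)
  a <- matrix(lab[, , 2], d[1], d[2])
  b <- matrix(lab[, , 3], d[1], d[2])
  h <- atan2(b, a) * 180 / pi
  h <- ifelse(h < 0, h + 360, h)
  h[h >= 360] <- 0            # guard against 360 from rounding of tiny negatives
  cc <- sqrt(a^2 + b^2)
  h[cc == 0] <- 0
  structure(array(c(h, cc), dim = c(dim(a), 2L)), class = "hue_chroma_image")
}

# ---------------------------------------------------------------------------
# inverse chain --------------------------------------------------------------

## Inverse of lab_transfer: t = u^3 above the knot, linear below.
.lab_transfer_inv <- function(u) {
  ifelse(u > 6 / 29, u^3, (u - 16 / 116) * 3 * (6 / 29)^2)
}

#' Convert CIELAB back to RGB
#'
#' Exact algebraic inverse of [rgb_to_lab()] (same no-gamma default).
#' Out-of-gamut results are clipped to `[0, 1]` with a warning.
#'
#' @param lab A [lab_image()] (or `n x 3` matrix of L*, a*, b* rows).
#' @param gamma Apply sRGB gamma compression after the inverse matrix
#'   (matches `gamma = TRUE` in [rgb_to_lab()]).
#' @return An [rgb_image()] (or `n x 3` matrix when given a matrix).
#' @export
lab_to_rgb <- function(lab, gamma = FALSE) {
  was_matrix <- is.matrix(lab)
  m <- if (was_matrix) lab else .flatten3(lab)$m
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(.lab_transfer_inv(fx), .lab_transfer_inv(fy), .lab_transfer_inv(fz))
  xyz <- sweep(xyz, 2L, .D65_WHITE, "*")
  rgb <- xyz %*% t(solve(.RGB2XYZ))
  if (gamma) rgb <- .srgb_compress(pmax(rgb, 0))
  if (any(rgb < -1e-9) || any(rgb > 1 + 1e-9))
    warning("lab_to_rgb: out-of-gamut colors clipped to [0, 1]")
  rgb <- pmin(pmax(rgb, 0), 1)
  if (was_matrix) return(rgb)
  rgb_image(.unflatten3(rgb, dim(lab)))
}
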