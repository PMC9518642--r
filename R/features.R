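# The 16-dimensional multi-color physical feature vector:
#   f1..f9   color moments of L*, a*, b* (mean, population sd, signed cube
#            root of the third central moment)
#   f10      color richness: Shannon entropy of the 256-bin grayscale
#            histogram, in bits
#   f11,f12  space density: watershed region count and region-size sd
#   f13      color tone contrast: chromatic scatter in the (a*, b*) plane
#   f14      lightness contrast: mean squared 8-neighbor L* difference
#   f15      cool/warm contrast: same machinery on the warm-cool raster
#   f16      area difference: sd of the palette cluster pixel counts

FEATURE_NAMES <- paste0("f", 1:16)

#' Color moments (f1-f9)
#'
#' First-, second- and third-order moments of the L*, a* and b*
#' distributions: per-dimension mean, population standard deviation, and
#' signed cube root of the mean cubed deviation (the odd root keeps the
#' sign of skewed distributions).
#'
#' @param lab A [lab_image()] (or `n x 3` matrix of pixel Lab rows).
#' @return Named numeric vector `f1..f9`.
#' @export
color_moments <- function(lab) {
  m <- if (is.matrix(lab)) lab else .flatten3(lab)$m
  if (nrow(m) < 1L) stop("empty image")
  mu <- colMeans(m)
  ctr <- sweep(m, 2L, mu)
  sds <- sqrt(colMeans(ctr^2))
  thirds <- .signed_cbrt(colMeans(ctr^3))
  stats::setNames(c(mu, sds, thirds), paste0("f", 1:9))
}

#' Color richness (f10)
#'
#' Shannon entropy of the 256-bin grayscale histogram, in bits
#' (`0 log2 0 := 0`). Maximal at 8 bits for a histogram uniform over all
#' 256 levels.
#'
#' @param gray A [gray_image()].
#' @return Entropy in bits.
#' @export
color_richness <- function(gray) {
  if (length(gray) < 1L) stop("empty image")
  p <- tabulate(as.integer(gray) + 1L, nbins = 256L) / length(gray)
  p <- p[p > 0]
  -sum(p * log2(p)) + 0   # + 0 normalizes IEEE -0 for the pure case
}

#' Space density (f11, f12)
#'
#' Region count `N` and the population standard deviation of the region
#' pixel counts from a watershed segmentation.
#'
#' @param labels A [label_map()].
#' @return Named numeric vector `c(f11, f12)`.
#' @export
space_density <- function(labels) {
  sizes <- region_sizes(labels)
  if (length(sizes) == 0L) stop("label map contains no regions")
  c(f11 = length(sizes), f12 = sqrt(.pop_var(sizes)))
}

#' Color tone contrast (f13)
#'
#' Root mean squared deviation of the per-pixel chromatic point (a*, b*)
#' from the image-mean chromatic point; algebraically equal to
#' `sqrt(var(a*) + var(b*))` with population variances. Spatially blind:
#' invariant under any pixel permutation.
#'
#' @param lab A [lab_image()].
#' @return Non-negative scalar.
#' @export
color_tone_contrast <- function(lab) {
  m <- if (is.matrix(lab)) lab else .flatten3(lab)$m
  sqrt(mean((m[, 2] - mean(m[, 2]))^2 + (m[, 3] - mean(m[, 3]))^2))
}

## Mean squared difference over all ordered (center, in-image 8-neighbor)
## pairs of a scalar raster; the machinery behind f14 and f15.
.neighbor_contrast <- function(M) {
  H <- nrow(M); W <- ncol(M)
  if (H * W == 1L) return(0)           # no pairs; defined as 0
  offsets <- .neighbor_offsets(8L)
  total <- 0; npairs <- 0
  for (off in offsets) {
    dy <- off[1]; dx <- off[2]
    if (max(1L, 1L + dy) > min(H, H + dy) ||
        max(1L, 1L + dx) > min(W, W + dx)) next   # offset falls off the image
    r1 <- max(1L, 1L + dy):min(H, H + dy)
    c1 <- max(1L, 1L + dx):min(W, W + dx)
    r0 <- r1 - dy; c0 <- c1 - dx
    d <- M[r1, c1, drop = FALSE] - M[r0, c0, drop = FALSE]
    total <- total + sum(d * d)
    npairs <- npairs + length(d)
  }
  total / npairs
}

#' Lightness contrast (f14)
#'
#' Sum over every pixel and each of its in-image 8-neighbors of the squared
#' L* difference, divided by the number of ordered (center, neighbor) pairs
#' counted. Border pixels contribute only their in-image neighbors; units
#' are squared L*.
#'
#' @param lab A [lab_image()] (or a numeric matrix taken as the L* plane).
#' @return Non-negative scalar.
#' @export
lightness_contrast <- function(lab) {
  L <- if (is.matrix(lab)) lab else lab[, , 1]
  .neighbor_contrast(L)
}

#' Per-pixel warm-cool degree
#'
#' Scalar warmth of each pixel from its hue angle and chroma:
#' `WC = -0.89 + 0.052 C* [cos(h - 50) + 0.16 cos(2h - 350)]`
#' with angles in degrees. Achromatic pixels (`C* = 0`) sit at the
#' constant -0.89 regardless of hue.
#'
#' @param hc Output of [lab_to_hue_chroma()] (`h x w x 2` array).
#' @return Numeric matrix of warm-cool values.
#' @export
coolwarm_degree <- function(hc) {
  d <- dim(hc)
  h <- matrix(hc[, , 1], d[1], d[2])
  cc <- matrix(hc[, , 2], d[1], d[2])
  deg <- pi / 180
  -0.89 + 0.052 * cc * (cos((h - 50) * deg) + 0.16 * cos((2 * h - 350) * deg))
}

#' Cool/warm contrast (f15)
#'
#' The 8-neighborhood mean squared difference of [lightness_contrast()]
#' applied to the warm-cool raster.
#'
#' @param wc Warm-cool matrix from [coolwarm_degree()].
#' @return Non-negative scalar.
#' @export
coolwarm_contrast <- function(wc) .neighbor_contrast(wc)

#' Area difference (f16)
#'
#' Population standard deviation of the palette cluster pixel counts,
#' measuring how unequally the dominant colors share the image area.
#'
#' @param p A [color_palette()].
#' @return Non-negative scalar, in pixels.
#' @export
area_difference <- function(p) {
  if (!inherits(p, "color_palette")) stop("p must be a color_palette")
  sqrt(.pop_var(p$counts))
}

#' Extract the full 16-dimensional feature vector
#'
#' Runs the whole pipeline on one material: circular mean smoothing, CIELAB
#' conversion, BT.709 grayscale, hue/chroma, K-means palette and watershed
#' segmentation, then assembles `f1..f16`. All downstream features (entropy,
#' watershed, palette) are computed on the smoothed image.
#'
#' @param img An [rgb_image()].
#' @param smooth_radius Circular filter radius in pixels (default 50); set
#'   to 0 to skip smoothing.
#' @param j Palette cluster count (default 8).
#' @param seed RNG seed for the palette initialization (default 0).
#' @param connectivity Watershed adjacency, 4 or 8 (default 8).
#' @param gamma Passed to [rgb_to_lab()] (default FALSE: the matrix is
#'   applied to the raw normalized channels).
#' @return Named numeric vector `f1..f16` in fixed order.
#' @export
extract_features <- function(img, smooth_radius = 50L, j = 8L, seed = 0L,
                             connectivity = 8L, gamma = FALSE) {
  img <- if (inherits(img, "rgb_image")) img else rgb_image(img)
  sm <- smooth_material(img, smooth_radius)
  lab <- rgb_to_lab(sm, gamma = gamma)
  gray <- to_gray(sm)
  hc <- lab_to_hue_chroma(lab)
  pal <- kmeans_palette(lab, j = j, seed = seed)
  labels <- watershed_immersion(gray, connectivity = connectivity)
  v <- c(color_moments(lab),
         f10 = color_richness(gray),
         space_density(labels),
         f13 = color_tone_contrast(lab),
         f14 = lightness_contrast(lab),
         f15 = coolwarm_contrast(coolwarm_degree(hc)),
         f16 = area_difference(pal))
  stats::setNames(as.numeric(v), FEATURE_NAMES)
}
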