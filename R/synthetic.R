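# Synthetic fixture generators: analytically known inputs for every other
# module (uniform fields, two-tone images, block mosaics with exact palette
# and region ground truth, rating matrices with controlled rater noise, and
# feature datasets carrying a known linear harmony signal).

#' Uniform (single-color) image
#'
#' @param color Length-3 RGB vector in `[0, 1]`.
#' @param height,width Image size in pixels.
#' @return An [rgb_image()].
#' @export
make_uniform <- function(color, height, width) {
  stopifnot(length(color) == 3L)
  rgb_image(array(rep(color, each = height * width), dim = c(height, width, 3L)))
}

#' Two-tone image with a vertical boundary
#'
#' Left columns in `color_left`, right columns in `color_right`; the
#' boundary sits after `round(split * width)` columns.
#'
#' @param color_left,color_right Length-3 RGB vectors in `[0, 1]`.
#' @param height,width Image size in pixels.
#' @param split Fraction of columns given to the left color (default 0.5).
#' @return An [rgb_image()].
#' @export
make_two_tone <- function(color_left, color_right, height, width, split = 0.5) {
  wl <- max(1L, min(width - 1L, as.integer(round(split * width))))
  out <- array(0, dim = c(height, width, 3L))
  for (k in 1:3) {
    out[, seq_len(wl), k] <- color_left[k]
    out[, (wl + 1L):width, k] <- color_right[k]
  }
  rgb_image(out)
}

#' Block mosaic with known palette and region structure
#'
#' Horizontal bands (full-width, stacked top to bottom) with areas
#' proportional to `proportions` (largest-remainder rounding of rows).
#' Returns the image together with the exact dominant-color palette and
#' band label map it realizes, so tests never re-derive ground truth from
#' the image.
#'
#' @param colors `m x 3` matrix of RGB rows in `[0, 1]`.
#' @param proportions Positive weights summing to 1, one per color.
#' @param height,width Image size in pixels; `height >= m`.
#' @return List with `image` ([rgb_image()]), `palette`
#'   ([color_palette()] in CIELAB), `labels` ([label_map()] of bands) and
#'   `rows` (band heights).
#' @export
make_blocks <- function(colors, proportions, height, width) {
  colors <- matrix(as.numeric(colors), ncol = 3L)
  m <- nrow(colors)
  if (length(proportions) != m) stop("one proportion per color required")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (m > height) stop("more colors than pixel rows")
  rows <- .largest_remainder(proportions, height)
  if (any(rows == 0L)) stop("a proportion rounds to zero rows; enlarge the image")
  out <- array(0, dim = c(height, width, 3L))
  labels <- matrix(0L, height, width)
  at <- 0L
  for (i in seq_len(m)) {
    rr <- (at + 1L):(at + rows[i])
    for (k in 1:3) out[rr, , k] <- colors[i, k]
    labels[rr, ] <- i
    at <- at + rows[i]
  }
  img <- rgb_image(out)
  lab_colors <- .flatten3(rgb_to_lab(rgb_image(array(colors, dim = c(m, 1L, 3L)))))$m
  list(image = img,
       palette = color_palette(lab_colors, rows * width),
       labels = label_map(labels),
       rows = rows)
}

#' Synthetic rating matrix
#'
#' Emulates a 5-level semantic-differential rating study: each cell is the
#' material's true score plus independent Gaussian rater noise, rounded to
#' the nearest integer and clipped to `{-2, ..., 2}`.
#'
#' @param n_materials,n_raters Grid dimensions (the reference study used
#'   164 materials and 84 raters).
#' @param true_scores Length-`n_materials` vector of latent scores;
#'   default: evenly spread over `[-2, 2]`.
#' @param noise_sd Rater noise standard deviation (`>= 0`).
#' @param seed RNG seed.
#' @return Integer matrix `n_materials x n_raters` with dimnames
#'   `material_i` / `rater_j`.
#' @export
make_rating_matrix <- function(n_materials, n_raters, true_scores = NULL,
                               noise_sd = 0.5, seed = 0L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(true_scores)) true_scores <- seq(-2, 2, length.out = n_materials)
  if (length(true_scores) != n_materials) stop("true_scores length mismatch")
  .with_seed(seed, {
    noise <- matrix(stats::rnorm(n_materials * n_raters, sd = noise_sd),
                    n_materials, n_raters)
    x <- round(true_scores + noise)
    x <- pmin(pmax(x, -2), 2)
    storage.mode(x) <- "integer"
    dimnames(x) <- list(paste0("material_", seq_len(n_materials)),
                        paste0("rater_", seq_len(n_raters)))
    x
  })
}

#' Synthetic feature dataset with a known linear harmony signal
#'
#' Draws features uniformly on `[0, 1]` per dimension (i.e., already on
#' the normalized scale) and generates targets as the model's prediction
#' plus Gaussian noise.
#'
#' @param n Number of samples (`>= 10`).
#' @param model A [harmony_model()]; default the bundled
#'   [reference_harmony_model()].
#' @param noise_sd Target noise standard deviation (default 0).
#' @param seed RNG seed.
#' @param all_features Generate all 16 features (default) rather than only
#'   the model's subset.
#' @return List with `features` (matrix), `targets` (numeric) and
#'   `true_scores` (noise-free predictions).
#' @export
make_feature_dataset <- function(n, model = reference_harmony_model(),
                                 noise_sd = 0, seed = 0L, all_features = TRUE) {
  if (n < 10L) stop("n must be >= 10")
  nm <- if (all_features) FEATURE_NAMES else names(model$coefficients)
  .with_seed(seed, {
    X <- matrix(stats::runif(n * length(nm)), n, length(nm),
                dimnames = list(NULL, nm))
    truth <- predict_harmony(model, X)
    y <- truth + stats::rnorm(n, sd = noise_sd)
    list(features = X, targets = y, true_scores = truth)
  })
}
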