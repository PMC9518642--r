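# Dominant-color palette construction: Lloyd's K-means on per-pixel CIELAB
# vectors with k-means++ seeding, and rendering of the proportional
# rectangular palette strip.

#' Dominant-color palette container
#'
#' Ordered dominant colors of an image: cluster centroids in CIELAB with
#' the number of pixels assigned to each. Ordered by descending count,
#' ties broken by L*, then a*, then b*.
#'
#' @param centroids `j x 3` matrix of (L*, a*, b*) centroids.
#' @param counts Integer vector of cluster sizes, same length as rows of
#'   `centroids`; must sum to the clustered pixel count.
#' @return An object of class `color_palette`.
#' @export
color_palette <- function(centroids, counts) {
  centroids <- matrix(as.numeric(centroids), ncol = 3L,
                      dimnames = list(NULL, c("L", "a", "b")))
  counts <- as.integer(counts)
  if (nrow(centroids) != length(counts)) stop("centroids/counts length mismatch")
  if (length(counts) < 1L || any(counts < 0L)) stop("counts must be non-negative, j >= 1")
  ord <- order(-counts, centroids[, 1], centroids[, 2], centroids[, 3])
  structure(list(centroids = centroids[ord, , drop = FALSE],
                 counts = counts[ord],
                 j = length(counts)),
            class = "color_palette")
}

#' @export
print.color_palette <- function(x, ...) {
  cat(sprintf("<color_palette: %d dominant colors, %d pixels>\n",
              x$j, sum(x$counts)))
  df <- data.frame(round(x$centroids, 2), count = x$counts,
                   fraction = round(x$counts / sum(x$counts), 4))
  print(df, row.names = FALSE)
  invisible(x)
}

## Squared Euclidean distances between the rows of X (n x d) and C (k x d).
.sqdist <- function(X, C) {
  n <- nrow(X); k <- nrow(C)
  d2 <- matrix(rowSums(X^2), n, k) + matrix(rowSums(C^2), n, k, byrow = TRUE) -
    2 * X %*% t(C)
  pmax(d2, 0)      # clamp the tiny negatives of catastrophic cancellation
}

## k-means++ seeding (needs an active RNG stream).
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- .sqdist(X, X[centers[1], , drop = FALSE])[, 1]
  for (i in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, .sqdist(X, X[centers[i + 1L], , drop = FALSE])[, 1])
  }
  X[centers, , drop = FALSE]
}

#' K-means dominant-color palette
#'
#' Lloyd's algorithm on the per-pixel (L*, a*, b*) vectors: each pixel is
#' assigned to its nearest centroid by Euclidean distance, centroids are
#' recomputed as cluster means, and the two steps iterate until the largest
#' centroid movement falls below `tol` (or `max_iter` iterations).
#' Initialization is k-means++ under the given seed; clusters that empty
#' out are re-seeded at the pixel farthest from its centroid. If the image
#' has no more distinct colors than `j`, the distinct colors themselves are
#' the centroids and the effective number of clusters is reported.
#'
#' @param lab A [lab_image()] (or `n x 3` matrix of pixel Lab rows).
#' @param j Number of clusters requested (default 8).
#' @param seed Integer RNG seed for reproducible initialization.
#' @param max_iter Iteration cap (default 300).
#' @param tol Convergence threshold on centroid movement (default 1e-6).
#' @return A [color_palette()].
#' @export
kmeans_palette <- function(lab, j = 8L, seed = 0L, max_iter = 300L, tol = 1e-6) {
  X <- if (is.matrix(lab)) lab else .flatten3(lab)$m
  n <- nrow(X)
  if (n < 1L) stop("empty image")
  j <- as.integer(j)
  if (j < 1L) stop("j must be >= 1")

  distinct <- unique(X)
  if (nrow(distinct) <= j) {
    # fewer distinct colors than requested clusters: the optimum is the
    # distinct colors themselves; effective j shrinks.
    key <- apply(X, 1L, paste, collapse = "\r")
    dkey <- apply(distinct, 1L, paste, collapse = "\r")
    counts <- as.integer(table(factor(key, levels = dkey)))
    merged <- .collapse_close(distinct, counts)
    return(color_palette(merged$centroids, merged$counts))
  }

  C <- .with_seed(seed, .kmeanspp_init(X, j))
  assign <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- .sqdist(X, C)
    assign <- max.col(-d2, ties.method = "first")
    newC <- C
    sizes <- tabulate(assign, nbins = j)
    means <- rowsum(X, assign)
    nonempty <- which(sizes > 0L)
    newC[nonempty, ] <- means[as.character(nonempty), , drop = FALSE] / sizes[nonempty]
    for (e in which(sizes == 0L)) {
      # re-seed an empty cluster at the point farthest from its centroid
      far <- which.max(d2[cbind(seq_len(n), assign)])
      newC[e, ] <- X[far, ]
      assign[far] <- e
      d2[far, ] <- 0  # don't pick the same point twice
    }
    moved <- max(sqrt(rowSums((newC - C)^2)))
    C <- newC
    if (moved < tol) break
  }
  d2 <- .sqdist(X, C)
  assign <- max.col(-d2, ties.method = "first")
  sizes <- tabulate(assign, nbins = j)
  merged <- .collapse_close(C, sizes)
  color_palette(merged$centroids, merged$counts)
}

## Merge centroids that coincide up to numerical noise (degenerate inputs);
## counts accumulate onto the first member of each group.
.collapse_close <- function(C, counts, tol = 1e-9) {
  j <- nrow(C)
  keep <- rep(TRUE, j)
  if (j > 1L) {
    for (a in seq_len(j - 1L)) for (b in seq(a + 1L, j)) {
      if (keep[a] && keep[b] && sqrt(sum((C[a, ] - C[b, ])^2)) < tol) {
        counts[a] <- counts[a] + counts[b]
        keep[b] <- FALSE
      }
    }
  }
  list(centroids = C[keep, , drop = FALSE], counts = counts[keep])
}

#' Render a palette as a proportional strip
#'
#' Horizontal rectangular strip in which segment `i` has width proportional
#' to the cluster count `n_i` (largest-remainder rounding to whole pixels);
#' colors are converted back to RGB via [lab_to_rgb()].
#'
#' @param p A [color_palette()].
#' @param width,height Strip dimensions in pixels.
#' @return An [rgb_image()].
#' @export
render_palette <- function(p, width = 400L, height = 50L) {
  if (!inherits(p, "color_palette")) stop("p must be a color_palette")
  widths <- .largest_remainder(p$counts, as.integer(width))
  rgb <- lab_to_rgb(p$centroids)
  out <- array(0, dim = c(height, width, 3L))
  at <- 0L
  for (i in seq_len(p$j)) {
    if (widths[i] > 0L) {
      cols <- (at + 1L):(at + widths[i])
      for (k in 1:3) out[, cols, k] <- rgb[i, k]
      at <- at + widths[i]
    }
  }
  rgb_image(out)
}
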