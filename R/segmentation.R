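# Watershed by immersion on the grayscale topography. Flooding proceeds
# level by level from the regional minima; basins grow by geodesic-distance
# waves inside each gray-level plateau, pixels reached by two or more basins
# at the same geodesic distance become watershed-line pixels, and plateau
# components reached by no existing basin seed new basins (new regional
# minima appearing at that altitude).

#' Region label map container
#'
#' Integer matrix of per-pixel region labels: positive integers `1..N` for
#' the catchment basins, `0` for watershed-line pixels (shared boundary
#' points belonging to no region).
#'
#' @param x Integer matrix of labels `>= 0`.
#' @return An object of class `label_map` with attribute `n_regions`.
#' @export
label_map <- function(x) {
  if (!is.matrix(x)) stop("label_map requires a matrix")
  storage.mode(x) <- "integer"
  if (anyNA(x) || any(x < 0L)) stop("labels must be non-negative integers")
  structure(x, class = "label_map", n_regions = max(x, 0L))
}

## Shift matrix by (dy, dx), filling vacated cells with `fill`.
.shift2 <- function(M, dy, dx, fill) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(fill, H, W)
  sr <- seq_len(H) - dy; sc <- seq_len(W) - dx
  kr <- sr >= 1L & sr <= H; kc <- sc >= 1L & sc <= W
  out[kr, kc] <- M[sr[kr], sc[kc], drop = FALSE]
  out
}

.neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else if (connectivity == 8L) {
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
         c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  } else stop("connectivity must be 4 or 8")
}

## Logical dilation of `front` restricted to `mask`.
.dilate_in <- function(front, mask, offsets) {
  out <- matrix(FALSE, nrow(front), ncol(front))
  for (off in offsets) out <- out | .shift2(front, off[1], off[2], FALSE)
  out & mask
}

#' Watershed segmentation by immersion
#'
#' Treats the grayscale image as a topographic surface and floods it from
#' below, level by level, from `h_min` upward. Within the plateau of each
#' gray level, existing basins claim pixels in order of geodesic distance
#' through the plateau; a pixel whose minimal-distance claimants include
#' two or more distinct basins becomes a watershed-line pixel (label 0).
#' Plateau pixels reachable from no basin but connected to an existing
#' watershed line also join the line; plateau components reachable from
#' nothing are new regional minima and seed new basins. The flooding is
#' fully deterministic and independent of pixel processing order.
#'
#' @param gray A [gray_image()] (or numeric matrix; any finite values are
#'   accepted, only their ordering matters).
#' @param connectivity Pixel adjacency, 4 or 8 (default 8).
#' @return A [label_map()] with `N = attr(., "n_regions")` basins.
#' @export
watershed_immersion <- function(gray, connectivity = 8L) {
  if (!is.matrix(gray)) stop("watershed_immersion requires a matrix")
  if (length(gray) == 0L) stop("empty image")
  offsets <- .neighbor_offsets(as.integer(connectivity))
  H <- nrow(gray); W <- ncol(gray)
  UNASSIGNED <- -1L; TIE <- -2L
  lab <- matrix(UNASSIGNED, H, W)
  nextlab <- 0L

  for (h in sort(unique(as.vector(gray)))) {
    P <- gray == h                       # this level's plateau pixels

    ## Phase A: geodesic waves from existing basins through the plateau.
    front <- lab > 0L
    repeat {
      first <- matrix(NA_integer_, H, W)
      tie <- matrix(FALSE, H, W)
      for (off in offsets) {
        nl <- .shift2(lab, off[1], off[2], UNASSIGNED)
        nw <- .shift2(front, off[1], off[2], FALSE)
        tie <- tie | (nw & nl == TIE)
        pos <- nw & nl > 0L
        tie <- tie | (pos & !is.na(first) & nl != first)
        fill <- pos & is.na(first)
        first[fill] <- nl[fill]
      }
      cand <- P & lab == UNASSIGNED & (tie | !is.na(first))
      if (!any(cand)) break
      lab[cand & tie] <- TIE
      take <- cand & !tie
      lab[take] <- first[take]
      front <- cand
    }

    ## Phase B: pixels reachable only via watershed-line pixels join the line.
    front <- (lab == 0L | lab == TIE)
    repeat {
      cand <- .dilate_in(front, P & lab == UNASSIGNED, offsets)
      if (!any(cand)) break
      lab[cand] <- TIE
      front <- cand
    }

    ## Phase C: untouched plateau components are new regional minima.
    remaining <- P & lab == UNASSIGNED
    while (any(remaining)) {
      seed <- matrix(FALSE, H, W)
      seed[which(remaining)[1L]] <- TRUE   # smallest linear index first
      repeat {
        grown <- seed | .dilate_in(seed, remaining, offsets)
        if (identical(grown, seed)) break
        seed <- grown
      }
      nextlab <- nextlab + 1L
      lab[seed] <- nextlab
      remaining <- remaining & !seed
    }

    lab[lab == TIE] <- 0L
  }
  label_map(lab)
}

#' Pixel counts of watershed regions
#'
#' Counts the pixels carrying each basin label `1..N`; watershed-line
#' pixels (label 0) belong to no region and are excluded, so
#' `sum(region_sizes(x)) + line pixels = height * width`.
#'
#' @param labels A [label_map()].
#' @return Integer vector of length `N` of region sizes.
#' @export
region_sizes <- function(labels) {
  if (!is.matrix(labels)) stop("region_sizes requires a label matrix")
  n <- max(labels, 0L)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}
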