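# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check: plain per-pixel loops, explicit
# queue-free flooding, direct summation.

## All in-image neighbors of (i, j) under the given connectivity.
.o_nbrs <- function(i, j, H, W, connectivity = 8L) {
  offs <- if (connectivity == 4L) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  }
  out <- list()
  for (o in offs) {
    r <- i + o[1]; c <- j + o[2]
    if (r >= 1 && r <= H && c >= 1 && c <= W) out[[length(out) + 1L]] <- c(r, c)
  }
  out
}

## Mean squared difference over ordered (center, in-image 8-neighbor)
## pairs, by explicit double loop.
oracle_neighbor_contrast <- function(M) {
  H <- nrow(M); W <- ncol(M)
  total <- 0; npairs <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    for (q in .o_nbrs(i, j, H, W, 8L)) {
      total <- total + (M[i, j] - M[q[1], q[2]])^2
      npairs <- npairs + 1L
    }
  }
  if (npairs == 0L) 0 else total / npairs
}

## Level-by-level immersion flooding by explicit breadth-first waves:
## per-basin geodesic distances inside each gray-level plateau, then
## nearest-basin assignment with ties on the watershed line, then
## line-adjacent spill, then new minima in smallest-linear-index order.
oracle_watershed <- function(gray, connectivity = 8L) {
  H <- nrow(gray); W <- ncol(gray)
  lab <- matrix(-1L, H, W)
  nextlab <- 0L
  for (h in sort(unique(as.vector(gray)))) {
    inP <- gray == h
    P <- which(inP)                       # linear (column-major) indices
    Pij <- arrayInd(P, c(H, W))
    basins <- sort(unique(lab[lab > 0L]))
    dists <- list()
    for (b in basins) {
      d <- matrix(Inf, H, W)
      for (r in seq_along(P)) {           # distance 1: adjacent to basin b
        i <- Pij[r, 1]; j <- Pij[r, 2]
        for (q in .o_nbrs(i, j, H, W, connectivity))
          if (lab[q[1], q[2]] == b) { d[i, j] <- 1; break }
      }
      dd <- 1
      repeat {                            # breadth-first waves through plateau
        changed <- FALSE
        for (r in seq_along(P)) {
          i <- Pij[r, 1]; j <- Pij[r, 2]
          if (is.finite(d[i, j])) next
          for (q in .o_nbrs(i, j, H, W, connectivity))
            if (inP[q[1], q[2]] && d[q[1], q[2]] == dd) {
              d[i, j] <- dd + 1; changed <- TRUE; break
            }
        }
        if (!changed) break
        dd <- dd + 1
      }
      dists[[as.character(b)]] <- d
    }
    for (r in seq_along(P)) {             # nearest-basin rule
      i <- Pij[r, 1]; j <- Pij[r, 2]
      dv <- vapply(basins, function(b) dists[[as.character(b)]][i, j], numeric(1))
      if (length(dv) && any(is.finite(dv))) {
        winners <- basins[dv == min(dv)]
        lab[i, j] <- if (length(winners) == 1L) winners else 0L
      }
    }
    repeat {                              # spill from the watershed line
      changed <- FALSE
      for (r in seq_along(P)) {
        i <- Pij[r, 1]; j <- Pij[r, 2]
        if (lab[i, j] != -1L) next
        for (q in .o_nbrs(i, j, H, W, connectivity))
          if (lab[q[1], q[2]] == 0L) { lab[i, j] <- 0L; changed <- TRUE; break }
      }
      if (!changed) break
    }
    repeat {                              # new minima, smallest index first
      rem <- which(inP & lab == -1L)
      if (!length(rem)) break
      comp <- rem[1L]
      repeat {
        grew <- FALSE
        for (p in setdiff(rem, comp)) {
          ij <- arrayInd(p, c(H, W))
          for (q in .o_nbrs(ij[1], ij[2], H, W, connectivity))
            if (((q[2] - 1L) * H + q[1]) %in% comp) {
              comp <- c(comp, p); grew <- TRUE; break
            }
        }
        if (!grew) break
      }
      nextlab <- nextlab + 1L
      lab[comp] <- nextlab
    }
  }
  lab
}

## Circular mean filter by explicit per-pixel template enumeration.
oracle_circular_mean <- function(M, radius) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0; cnt <- 0L
    for (x in seq_len(H)) for (y in seq_len(W)) {
      if ((x - i)^2 + (y - j)^2 <= radius^2) { acc <- acc + M[x, y]; cnt <- cnt + 1L }
    }
    out[i, j] <- acc / cnt
  }
  out
}

## Drop class/attributes from a label map for strict value comparison.
strip_labels <- function(x) matrix(as.integer(x), nrow(x), ncol(x))

## Random test rasters.
rand_gray <- function(h, w, levels = 5L, seed = 0L) {
  set.seed(seed)
  matrix(sample.int(levels, h * w, replace = TRUE) - 1L, h, w)
}

rand_matrix <- function(h, w, seed = 0L, lo = 0, hi = 100) {
  set.seed(seed)
  matrix(runif(h * w, lo, hi), h, w)
}

rand_rgb <- function(h, w, seed = 0L) {
  set.seed(seed)
  colorharmony::rgb_image(array(runif(h * w * 3), dim = c(h, w, 3L)))
}
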