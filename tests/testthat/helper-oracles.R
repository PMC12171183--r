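# Independent brute-force oracles used across tests. These deliberately
# re-derive quantities from first principles (pair counting, simplex
# re-enumeration, literal fixed-point growth) and never call the package
# path they check.

# Ripley K by direct O(n^2) pair counting
brute_ripley_k <- function(pts, radii, volume) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  vapply(radii, function(r) volume / n^2 * sum(d[upper.tri(d)] <= r) * 2,
         numeric(1))
}

# Delaunay summary re-derived from a produced simplex list
brute_tess_stats <- function(pts, simplices) {
  edges <- unique(do.call(rbind, lapply(seq_len(nrow(simplices)), function(i) {
    v <- sort(simplices[i, ])
    t(combn(v, 2))
  })))
  elen <- apply(edges, 1, function(e) sqrt(sum((pts[e[1], ] - pts[e[2], ])^2)))
  vols <- apply(simplices, 1, function(v) {
    m <- rbind(pts[v[2], ] - pts[v[1], ],
               pts[v[3], ] - pts[v[1], ],
               pts[v[4], ] - pts[v[1], ])
    abs(det(m)) / 6
  })
  list(mean_edge = mean(elen), mean_vol = mean(vols),
       n_edges = nrow(edges), total_vol = sum(vols))
}

# literal fixed-point region growth: repeatedly add any eligible pixel
# within Euclidean distance r of the current region
brute_grow <- function(ff, roi, med, r, seed_rc) {
  nr <- nrow(ff); nc <- ncol(ff)
  elig <- roi & is.finite(ff) & abs(ff - med) <= med
  region <- matrix(FALSE, nr, nc)
  region[seed_rc[1], seed_rc[2]] <- TRUE
  coords <- as.matrix(expand.grid(r = seq_len(nr), c = seq_len(nc)))
  repeat {
    reg_idx <- which(region)
    reg_rc <- coords[reg_idx, , drop = FALSE]
    cand <- which(elig & !region)
    if (length(cand) == 0L) break
    added <- FALSE
    for (ci in cand) {
      rc <- coords[ci, ]
      d2 <- (reg_rc[, 1] - rc[1])^2 + (reg_rc[, 2] - rc[2])^2
      if (any(d2 <= r^2)) {
        region[ci] <- TRUE
        added <- TRUE
      }
    }
    if (!added) break
  }
  region
}

# 60x60 pocket fixture: low-FF field split by a 10-pixel-wide high-FF band
make_pocket_slice <- function(band_cols = 26:35) {
  ff <- matrix(0.03, 60, 60)
  ff[, band_cols] <- 0.6
  roi <- matrix(TRUE, 60, 60)
  list(ff = ff, roi = roi)
}
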