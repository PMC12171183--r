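#' Synthetic muscle phantom specification
#'
#' Describes a ground-truthed synthetic fat-fraction volume: an elliptical
#' muscle cylinder with low-FF background, branch-like tubular IMF clusters
#' (persistent random walks along the muscle axis), optional diffuse
#' spherical clusters, and sub-threshold noise singletons that a correct
#' small-cluster filter must remove. Background FF is truncated so it can
#' never exceed twice the slice median, guaranteeing the region-growing
#' threshold separates muscle from planted fat by construction.
#'
#' @param shape grid dimensions (x, y, slices).
#' @param spacing voxel size in mm; the default mimics ~1.1 mm in-plane
#'   pixels with 2 mm slices.
#' @param background_ff_mean,background_ff_sd truncated-normal background
#'   FF parameters (dimensionless).
#' @param n_branches number of tubular clusters.
#' @param branch_step_sd random-walk step noise, mm per slice.
#' @param branch_radius in-plane tube radius in pixels.
#' @param branch_ff length-2 FF range assigned to cluster voxels.
#' @param n_diffuse_clusters number of spherical blob clusters (soleus-like
#'   multifocal mode).
#' @param diffuse_radius blob radius in voxels.
#' @param n_noise_singletons isolated single high-FF voxels (components of
#'   size 1, below the 4-voxel filter threshold).
#' @param proximal_gradient > 0 anchors every branch at the proximal end so
#'   fat density increases distal to proximal; 0 places branches uniformly.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 40L), spacing = c(1.1, 1.1, 2.0),
                         background_ff_mean = 0.03, background_ff_sd = 0.01,
                         n_branches = 4L, branch_step_sd = 1.0,
                         branch_radius = 1L, branch_ff = c(0.25, 0.60),
                         n_diffuse_clusters = 0L, diffuse_radius = 2.0,
                         n_noise_singletons = 8L, proximal_gradient = 0,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 16), length(spacing) == 3L,
            all(spacing > 0), background_ff_mean > 0, background_ff_sd > 0,
            n_branches >= 0, branch_radius >= 1,
            length(branch_ff) == 2L, branch_ff[1] < branch_ff[2],
            branch_ff[1] > 4 * background_ff_mean,
            n_diffuse_clusters >= 0, n_noise_singletons >= 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 background_ff_mean = background_ff_mean,
                 background_ff_sd = background_ff_sd,
                 n_branches = as.integer(n_branches),
                 branch_step_sd = branch_step_sd,
                 branch_radius = as.integer(branch_radius),
                 branch_ff = as.numeric(branch_ff),
                 n_diffuse_clusters = as.integer(n_diffuse_clusters),
                 diffuse_radius = diffuse_radius,
                 n_noise_singletons = as.integer(n_noise_singletons),
                 proximal_gradient = proximal_gradient,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Phantom presets
#'
#' `"young"`: sparse branching (4 tubes). `"old"`: the same muscle with
#' three times as many tubes, emulating the denser clustering seen with
#' ageing. `"sol_diffuse"`: few tubes plus several distinct spherical
#' high-density clusters, the soleus-like multifocal morphology.
#'
#' @param name preset name.
#' @param seed seed stored in the returned spec.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("young", "old", "sol_diffuse"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    young = phantom_spec(n_branches = 4L, seed = seed),
    old = phantom_spec(n_branches = 12L, seed = seed),
    sol_diffuse = phantom_spec(n_branches = 2L, n_diffuse_clusters = 5L,
                               seed = seed))
}

# truncated normal on [lo, hi] via inverse-CDF sampling
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic phantom volume with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return List of class `imf_phantom`: `ff` ([ff_volume]), `mask`
#'   ([muscle_mask]), `truth` (3D logical ground-truth IMF mask, every
#'   component >= 4 voxels), `singletons` (3D logical mask of planted
#'   noise voxels, disjoint from `truth`), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  a <- 0.40 * nx; b <- 0.40 * ny
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ell <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
  mask <- array(rep(ell, nz), dim = spec$shape)

  # interior region keeping planted fat clear of the 2-pixel ROI erosion
  margin <- 4
  ai <- a - margin; bi <- b - margin
  inside <- function(x, y) ((x - cx) / ai)^2 + ((y - cy) / bi)^2 <= 1

  truth <- array(FALSE, spec$shape)
  rpx <- spec$branch_radius
  disk <- which(outer((-rpx:rpx)^2, (-rpx:rpx)^2, `+`) <= rpx^2, arr.ind = TRUE) -
    (rpx + 1L)
  stamp <- function(arr, x0, y0, z) {
    px <- round(x0) + disk[, 1]; py <- round(y0) + disk[, 2]
    ok <- px >= 1 & px <= nx & py >= 1 & py <= ny & inside(px, py)
    arr[cbind(px[ok], py[ok], z)] <- TRUE
    arr
  }

  minlen <- max(4L, as.integer(round(0.3 * nz)))
  step_sd_px <- spec$branch_step_sd / mean(spec$spacing[1:2])
  for (br in seq_len(spec$n_branches)) {
    if (spec$proximal_gradient > 0) {
      z2 <- nz
      z1 <- sample(seq(max(2L, as.integer(nz * 0.15)), nz - minlen + 1L), 1L)
    } else {
      len <- sample(seq(minlen, nz - 2L), 1L)
      z1 <- sample(seq_len(nz - len + 1L), 1L)
      z2 <- z1 + len - 1L
    }
    repeat {   # rejection-sample a start point inside the safe ellipse
      x <- runif(1, cx - ai, cx + ai); y <- runif(1, cy - bi, cy + bi)
      if (inside(x, y)) break
    }
    vx <- rnorm(1, 0, step_sd_px); vy <- rnorm(1, 0, step_sd_px)
    for (z in z1:z2) {
      truth <- stamp(truth, x, y, z)
      vx <- 0.7 * vx + rnorm(1, 0, step_sd_px)
      vy <- 0.7 * vy + rnorm(1, 0, step_sd_px)
      x <- x + vx; y <- y + vy
      u <- ((x - cx) / ai)^2 + ((y - cy) / bi)^2
      if (u > 1) {   # reflect back inside and damp the outward velocity
        s <- 0.97 / sqrt(u)
        x <- cx + (x - cx) * s; y <- cy + (y - cy) * s
        vx <- -0.5 * vx; vy <- -0.5 * vy
      }
    }
  }

  if (spec$n_diffuse_clusters > 0) {
    rr <- spec$diffuse_radius
    off <- expand.grid(dx = -ceiling(rr):ceiling(rr),
                       dy = -ceiling(rr):ceiling(rr),
                       dz = -ceiling(rr):ceiling(rr))
    off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= rr^2, ]
    for (cl in seq_len(spec$n_diffuse_clusters)) {
      repeat {
        x <- runif(1, cx - ai, cx + ai); y <- runif(1, cy - bi, cy + bi)
        if (inside(x, y)) break
      }
      z <- sample(seq(3L, nz - 2L), 1L)
      px <- round(x) + off$dx; py <- round(y) + off$dy; pz <- z + off$dz
      ok <- px >= 1 & px <= nx & py >= 1 & py <= ny & pz >= 1 & pz <= nz &
        inside(px, py)
      truth[cbind(px[ok], py[ok], pz[ok])] <- TRUE
    }
  }

  # a clipped or fast-moving walk can shed fragments below the 4-voxel
  # filter size; drop them so the ground truth is exactly recoverable
  if (any(truth)) truth <- filter_small_clusters(truth, 4L, 26L)$mask
  if (!any(truth) && (spec$n_branches > 0 || spec$n_diffuse_clusters > 0))
    stop("phantom ground truth is empty")

  # noise singletons: isolated voxels >= 2 voxels (Chebyshev) from any truth
  singles <- array(FALSE, spec$shape)
  placed <- 0L; tries <- 0L
  while (placed < spec$n_noise_singletons && tries < 20000L) {
    tries <- tries + 1L
    x <- sample.int(nx, 1L); y <- sample.int(ny, 1L)
    z <- sample(seq(2L, nz - 1L), 1L)
    if (!inside(x, y)) next
    xr <- max(1, x - 2):min(nx, x + 2)
    yr <- max(1, y - 2):min(ny, y + 2)
    zr <- max(1, z - 2):min(nz, z + 2)
    if (any(truth[xr, yr, zr]) || any(singles[xr, yr, zr])) next
    singles[x, y, z] <- TRUE
    placed <- placed + 1L
  }
  if (placed < spec$n_noise_singletons)
    warning("placed only ", placed, " of ", spec$n_noise_singletons,
            " noise singletons")

  nvox <- prod(spec$shape)
  ff <- array(rtruncnorm(nvox, spec$background_ff_mean, spec$background_ff_sd,
                         0, 1.8 * spec$background_ff_mean), spec$shape)
  ff[!mask] <- 0.8                       # subcutaneous-fat-like surround
  nf <- sum(truth)
  ff[truth] <- runif(nf, spec$branch_ff[1], spec$branch_ff[2])
  ff[singles] <- 0.45

  list_out <- list(ff = ff_volume(ff, spec$spacing),
                   mask = muscle_mask(mask, spec$spacing,
                                      muscle_label = "phantom"),
                   truth = truth, singletons = singles, spec = spec)
  class(list_out) <- "imf_phantom"
  list_out
}

#' @export
print.imf_phantom <- function(x, ...) {
  cat("<imf_phantom> ", paste(x$spec$shape, collapse = " x "), " grid, ",
      sum(x$truth), " truth voxels, ", sum(x$singletons),
      " noise singletons (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Dice overlap between two binary masks
#'
#' @param a,b binary arrays of the same shape.
#' @return `2|A ∩ B| / (|A| + |B|)`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NaN)
  2 * sum(a & b) / denom
}
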