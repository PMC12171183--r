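#' Delaunay tessellation summary of an IMF point cloud
#'
#' Tetrahedralises the cloud and summarises local point density by the mean
#' unique-edge length (each edge counted once however many tetrahedra share
#' it) and the mean tetrahedron volume. To remove the dependence on muscle
#' size, normalised variants divide edges by `muscle_volume^(1/3)` and
#' volumes by `muscle_volume`.
#'
#' Voxel-centre clouds are cospherical almost everywhere, which is
#' degenerate for Delaunay triangulation. A deterministic sub-resolution
#' jitter (uniform, at most 1e-6 distance units, fixed seed) resolves the
#' topology; edge lengths and volumes are always measured on the original
#' coordinates, so metric summaries are exact under rescaling.
#'
#' @param cloud a [mask_to_point_cloud()] object, or an n x 3 matrix.
#' @param muscle_volume reference volume; taken from the cloud when absent.
#' @param jitter apply the degeneracy-breaking jitter (default `TRUE`).
#' @param jitter_seed integer seed for the jitter stream.
#' @return Object of class `tessellation_summary`: `mean_edge_length`,
#'   `mean_tet_volume`, `normalized_mean_edge`, `normalized_mean_volume`,
#'   `n_points`, `n_tets`, `n_edges`, `muscle_volume`, `simplices`
#'   (m x 4 vertex indices), `edge_lengths`, `tet_volumes`.
#' @export
delaunay_summary <- function(cloud, muscle_volume = NULL, jitter = TRUE,
                             jitter_seed = 1L) {
  pts <- if (inherits(cloud, "muscle_point_cloud")) cloud$points else as.matrix(cloud)
  if (is.null(muscle_volume) && inherits(cloud, "muscle_point_cloud"))
    muscle_volume <- cloud$muscle_volume
  n <- nrow(pts)
  if (n < 5L) stop("need at least 5 points for a 3D tessellation summary")
  build <- pts
  if (jitter) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(jitter_seed)
    build <- pts + matrix(runif(3 * n, -5e-7, 5e-7), n, 3)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  tets <- tryCatch(.delaunay3_cpp(build), error = function(e) {
    if (!jitter)
      stop("degenerate point cloud (coplanar/cospherical); retry with jitter = TRUE")
    stop(e)
  })
  if (nrow(tets) == 0L)
    stop("degenerate point cloud: tessellation produced no tetrahedra")
  # unique edge set over all tetrahedra
  pair_idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  a <- tets[, pair_idx[, 1]]
  b <- tets[, pair_idx[, 2]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  id <- (as.numeric(lo) - 1) * n + as.numeric(hi)
  keep <- !duplicated(id)
  lo <- as.vector(lo)[keep]; hi <- as.vector(hi)[keep]
  elen <- sqrt(rowSums((pts[lo, , drop = FALSE] - pts[hi, , drop = FALSE])^2))
  # tetrahedron volumes from the original coordinates
  p0 <- pts[tets[, 1], , drop = FALSE]
  e1 <- pts[tets[, 2], , drop = FALSE] - p0
  e2 <- pts[tets[, 3], , drop = FALSE] - p0
  e3 <- pts[tets[, 4], , drop = FALSE] - p0
  cx <- e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]
  cy <- e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]
  cz <- e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  vol <- abs(e1[, 1] * cx + e1[, 2] * cy + e1[, 3] * cz) / 6
  mv <- if (is.null(muscle_volume)) NA_real_ else muscle_volume
  structure(list(mean_edge_length = mean(elen),
                 mean_tet_volume = mean(vol),
                 normalized_mean_edge = mean(elen) / mv^(1 / 3),
                 normalized_mean_volume = mean(vol) / mv,
                 n_points = n, n_tets = nrow(tets), n_edges = length(elen),
                 muscle_volume = mv,
                 simplices = tets, edge_lengths = elen, tet_volumes = vol),
            class = "tessellation_summary")
}

#' @export
print.tessellation_summary <- function(x, ...) {
  cat("<tessellation_summary> ", x$n_points, " points, ", x$n_tets,
      " tetrahedra\n  mean edge ", signif(x$mean_edge_length, 5),
      ", mean volume ", signif(x$mean_tet_volume, 5), "\n", sep = "")
  invisible(x)
}

# domain volume helper: box volume or muscle-mask volume
domain_volume <- function(cloud, domain) {
  if (domain == "box") {
    bd <- cloud$bounding_domain
    prod(bd$upper - bd$lower)
  } else cloud$muscle_volume
}

#' Ripley's K function for a 3D point cloud
#'
#' Empirical `K(r) = (V / n^2) * sum_{i != j} 1[d_ij <= r]`, the
#' volume-scaled mean number of neighbours within distance `r`. No edge
#' correction is applied by default; under complete spatial randomness the
#' expectation is `(4/3) * pi * r^3`.
#'
#' @param cloud a [mask_to_point_cloud()] object, or an n x 3 matrix (then
#'   `volume` is required).
#' @param radii increasing positive distances (in the cloud's units).
#' @param domain `"box"` (axis-aligned muscle bounding box, default) or
#'   `"mask"` (muscle mask volume).
#' @param volume explicit domain volume overriding `domain`.
#' @return Numeric vector of K values, one per radius.
#' @export
ripley_k <- function(cloud, radii, domain = c("box", "mask"), volume = NULL) {
  domain <- match.arg(domain)
  if (inherits(cloud, "muscle_point_cloud")) {
    pts <- cloud$points
    if (is.null(volume)) volume <- domain_volume(cloud, domain)
    diam <- sqrt(sum((cloud$bounding_domain$upper - cloud$bounding_domain$lower)^2))
    if (max(radii) > diam)
      warning("largest radius exceeds the domain diameter")
  } else {
    pts <- as.matrix(cloud)
    if (is.null(volume)) stop("volume required for a bare point matrix")
  }
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points")
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE))
    stop("radii must be positive and strictly increasing")
  counts <- .pair_counts_cpp(pts, as.numeric(radii))
  volume / n^2 * counts
}

#' Closed-form CSR expectation of K in 3D
#'
#' @param radii numeric distances.
#' @return `(4/3) * pi * radii^3`.
#' @export
csr_expectation <- function(radii) 4 / 3 * pi * radii^3

#' Monte-Carlo CSR envelope for Ripley's K
#'
#' Simulates `n_sims` uniform (binomial) point patterns of `n_points` in the
#' domain and returns the pointwise 2.5 and 97.5 percentiles of their
#' empirical K. At least 39 simulations are required for a meaningful 95%
#' envelope; 199 is the conventional choice. Deterministic given `seed`.
#'
#' @param n_points points per simulated pattern.
#' @param domain either a list with `lower`/`upper` (a box), or a
#'   [muscle_mask] (uniform sampling inside the mask).
#' @param radii increasing positive distances.
#' @param n_sims number of CSR simulations (>= 1; >= 39 for 95% coverage).
#' @param seed integer seed.
#' @return List with `low`, `high` (per-radius envelope bounds) and `sims`
#'   (the n_sims x length(radii) matrix of simulated K curves).
#' @export
csr_envelope <- function(n_points, domain, radii, n_sims = 199L, seed = 1L) {
  stopifnot(n_points >= 2, n_sims >= 1)
  if (n_sims < 39L)
    warning("fewer than 39 simulations: the 95% envelope is not calibrated")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (inherits(domain, "muscle_mask")) {
    idx <- which(domain$data, arr.ind = TRUE)
    sp <- domain$spacing
    vol <- nrow(idx) * prod(sp)
    sample_fun <- function(n) {
      pick <- idx[sample.int(nrow(idx), n, replace = TRUE), , drop = FALSE]
      (pick - 1 + matrix(runif(3 * n), n, 3)) * rep(sp, each = n)
    }
  } else {
    lower <- domain$lower; upper <- domain$upper
    vol <- prod(upper - lower)
    sample_fun <- function(n)
      matrix(runif(3 * n, rep(lower, each = n), rep(upper, each = n)), n, 3)
  }
  sims <- matrix(NA_real_, n_sims, length(radii))
  for (s in seq_len(n_sims)) {
    pts <- sample_fun(n_points)
    sims[s, ] <- vol / n_points^2 * .pair_counts_cpp(pts, as.numeric(radii))
  }
  list(low = apply(sims, 2, quantile, probs = 0.025, names = FALSE),
       high = apply(sims, 2, quantile, probs = 0.975, names = FALSE),
       sims = sims)
}

#' L-function transform of Ripley's K
#'
#' `mode = "besag"` uses the Besag-style transform `L = sqrt(K / pi)`;
#' with `center = TRUE` the same transform of the CSR expectation is
#' subtracted so CSR plots as a horizontal zero line. `mode = "standard3d"`
#' uses the 3D variance-stabilised form `(3K / (4 pi))^(1/3)`, centred by
#' subtracting `r` (its CSR value).
#'
#' @param K non-negative K values.
#' @param radii matching distances.
#' @param mode `"besag"` or `"standard3d"`.
#' @param center subtract the CSR reference so CSR maps to zero.
#' @return Numeric vector of L values.
#' @export
l_function <- function(K, radii, mode = c("besag", "standard3d"), center = TRUE) {
  mode <- match.arg(mode)
  if (any(K < 0)) stop("K values must be non-negative")
  if (mode == "besag") {
    L <- sqrt(K / pi)
    if (center) L <- L - sqrt(csr_expectation(radii) / pi)
  } else {
    L <- (3 * K / (4 * pi))^(1 / 3)
    if (center) L <- L - radii
  }
  L
}

#' Maximum clustering distance
#'
#' The largest distance at which the upper bound of the K-function
#' confidence envelope remains above the CSR expectation line; the crossing
#' is linearly interpolated between grid points. When the envelope never
#' exceeds CSR, 0 is returned with attribute `flag = "no detectable
#' clustering"`. When it is still above CSR at the largest radius, that
#' radius is returned with attribute `flag = "censored at grid end"`.
#'
#' @param radii increasing distances.
#' @param envelope_high upper envelope of the data (across CSR simulations
#'   for one subject, or across participants for a group curve).
#' @param csr CSR expectation at `radii` (default the closed form).
#' @return The maximum clustering distance (scalar).
#' @export
max_clustering_distance <- function(radii, envelope_high,
                                    csr = csr_expectation(radii)) {
  stopifnot(length(radii) == length(envelope_high),
            length(radii) == length(csr))
  d <- envelope_high - csr
  above <- which(d > 0)
  if (length(above) == 0L)
    return(structure(0, flag = "no detectable clustering"))
  k <- max(above)
  if (k == length(radii))
    return(structure(radii[k], flag = "censored at grid end"))
  # linear interpolation of the down-crossing between radii[k] and radii[k+1]
  r0 <- radii[k]; r1 <- radii[k + 1]
  d0 <- d[k]; d1 <- d[k + 1]
  r0 + d0 / (d0 - d1) * (r1 - r0)
}

#' Full Ripley analysis of an IMF point cloud
#'
#' Computes K, the centred L transform, the closed-form CSR expectation,
#' a Monte-Carlo CSR envelope, and the maximum clustering distance.
#'
#' @inheritParams ripley_k
#' @param n_sims CSR simulations for the envelope.
#' @param seed envelope seed.
#' @param mode L-transform mode, see [l_function()].
#' @return Object of class `ripley_result` with fields `radii`, `K`, `L`,
#'   `csr_expectation`, `envelope_low`, `envelope_high`,
#'   `max_clustering_distance`, `n_points`.
#' @export
ripley_analysis <- function(cloud, radii, domain = c("box", "mask"),
                            n_sims = 199L, seed = 1L, mode = "besag") {
  domain <- match.arg(domain)
  K <- ripley_k(cloud, radii, domain)
  n <- nrow(cloud$points)
  dom <- if (domain == "mask") cloud$mask_domain else cloud$bounding_domain
  env <- csr_envelope(n, dom, radii, n_sims = n_sims, seed = seed)
  # the data curve's envelope: K plus the CSR simulation spread recentred on
  # the data is not used; the reported envelope is the CSR band and the
  # clustering distance compares the data-side upper bound (here K itself
  # when a single subject is analysed) against the CSR expectation
  mcd <- max_clustering_distance(radii, K)
  structure(list(radii = radii, K = K,
                 L = l_function(K, radii, mode = mode),
                 csr_expectation = csr_expectation(radii),
                 envelope_low = env$low, envelope_high = env$high,
                 max_clustering_distance = as.numeric(mcd),
                 mcd_flag = attr(mcd, "flag"),
                 n_points = n),
            class = "ripley_result")
}

#' @export
print.ripley_result <- function(x, ...) {
  cat("<ripley_result> ", x$n_points, " points, ", length(x$radii),
      " radii; max clustering distance ",
      signif(x$max_clustering_distance, 5),
      if (!is.null(x$mcd_flag)) paste0(" (", x$mcd_flag, ")"), "\n", sep = "")
  invisible(x)
}

#' Group K envelope across participants
#'
#' Pointwise 2.5/97.5 percentile band of per-participant K curves, the
#' group-level input to [max_clustering_distance()].
#'
#' @param k_curves matrix, one row per participant, columns matching `radii`.
#' @return List with `low` and `high`.
#' @export
participant_envelope <- function(k_curves) {
  list(low = apply(k_curves, 2, quantile, probs = 0.025, names = FALSE),
       high = apply(k_curves, 2, quantile, probs = 0.975, names = FALSE))
}
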