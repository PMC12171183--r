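#' Region-growing parameters
#'
#' Defaults follow the reference protocol: 2-pixel ROI erosion (excludes
#' boundary blood vessels), a 20-pixel search radius so muscle pockets
#' enclosed by fat are still reached, a 4-voxel minimum cluster size, and
#' 26-connectivity for the 3D small-cluster filter.
#'
#' @param erosion_pixels non-negative integer, per-slice erosion depth.
#' @param search_radius_r integer >= 1, region-growing search radius in
#'   pixels (Euclidean disk).
#' @param min_cluster_voxels integer >= 1, minimum 3D component size kept.
#' @param connectivity_3d 6, 18 or 26; neighbourhood for the 3D filter.
#' @param single_pass logical; if `TRUE`, growth performs a single disk
#'   sweep around the seed instead of iterating to a fixed point.
#' @param threshold_scale multiplier applied to each slice's FF median
#'   before growth (1 = protocol value); the sensitivity-analysis knob for
#'   threshold perturbation.
#' @return A `growth_params` list.
#' @export
growth_params <- function(erosion_pixels = 2L, search_radius_r = 20L,
                          min_cluster_voxels = 4L, connectivity_3d = 26L,
                          single_pass = FALSE, threshold_scale = 1) {
  stopifnot(erosion_pixels >= 0, search_radius_r >= 1, min_cluster_voxels >= 1,
            connectivity_3d %in% c(6L, 18L, 26L), threshold_scale > 0)
  structure(list(erosion_pixels = as.integer(erosion_pixels),
                 search_radius_r = as.integer(search_radius_r),
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 connectivity_3d = as.integer(connectivity_3d),
                 single_pass = isTRUE(single_pass),
                 threshold_scale = as.numeric(threshold_scale)),
            class = "growth_params")
}

#' Erode a per-slice ROI
#'
#' Applies `n` iterations of binary erosion with a 4-connected cross
#' structuring element. Pixels outside the image are background, so an ROI
#' touching the image border is eroded there too.
#'
#' @param mask_slice 2D logical/binary matrix.
#' @param n non-negative number of erosion passes.
#' @return Logical matrix of the same shape.
#' @export
erode_slice_roi <- function(mask_slice, n) {
  stopifnot(n >= 0)
  m <- mask_slice != 0
  nr <- nrow(m); nc <- ncol(m)
  f_row <- rep(FALSE, nc); f_col <- rep(FALSE, nr)
  for (i in seq_len(n)) {
    m <- m &
      rbind(f_row, m[-nr, , drop = FALSE]) &
      rbind(m[-1, , drop = FALSE], f_row) &
      cbind(f_col, m[, -nc, drop = FALSE]) &
      cbind(m[, -1, drop = FALSE], f_col)
  }
  dimnames(m) <- NULL
  m
}

#' Median fat fraction over a slice ROI
#'
#' @param ff_slice 2D numeric matrix of FF values.
#' @param roi 2D logical matrix, the (eroded) muscle ROI.
#' @return The median FF over ROI pixels, NaNs excluded.
#' @export
slice_ff_median <- function(ff_slice, roi) {
  if (!any(roi)) stop("empty ROI")
  v <- ff_slice[roi]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("all FF values in the ROI are undefined (NaN)")
  median(v)
}

#' Grow the muscle-tissue region within one slice
#'
#' Starting from the seed pixel (the ROI pixel whose FF is closest to the
#' slice median; ties broken by smallest row, then column), the region
#' repeatedly admits any ROI pixel within Euclidean distance `r` (pixels) of
#' a region pixel whose FF deviation satisfies
#' `|FF - ff_median| <= ff_median` (equivalently `FF <= 2 * ff_median`).
#' The long search radius lets growth jump across fat bands so muscle
#' pockets surrounded by fat are still captured.
#'
#' @param ff_slice 2D numeric FF matrix.
#' @param roi 2D logical ROI.
#' @param ff_median the slice median FF (see [slice_ff_median()]).
#' @param r search radius in pixels, >= 1.
#' @param single_pass if `TRUE`, perform a single disk sweep from the seed
#'   (no transitive growth).
#' @return Logical matrix: the grown muscle-tissue region.
#' @export
grow_muscle_region <- function(ff_slice, roi, ff_median, r = 20L,
                               single_pass = FALSE) {
  if (!any(roi)) stop("empty ROI")
  stopifnot(r >= 1)
  dev <- abs(ff_slice - ff_median)
  dev[!roi | !is.finite(ff_slice)] <- Inf
  best <- min(dev)
  cand <- which(dev == best, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  seed <- cand[1, ]
  seed_idx0 <- (seed[2] - 1L) * nrow(ff_slice) + (seed[1] - 1L)
  region <- .grow_region_cpp(ff_slice, matrix(as.logical(roi), nrow(roi)),
                             ff_median, as.integer(r), as.integer(seed_idx0),
                             isTRUE(single_pass))
  if (sum(region) == 1L)
    warning("no pixel satisfies the growth condition beyond the seed")
  region
}

#' Complement the grown muscle region to obtain per-slice IMF pixels
#'
#' @param roi 2D logical eroded ROI.
#' @param muscle_region 2D logical region from [grow_muscle_region()];
#'   must be a subset of `roi` (the seed pixel is exempt, it may fail the
#'   growth condition itself).
#' @return Logical matrix `roi & !muscle_region`.
#' @export
imf_mask_from_growth <- function(roi, muscle_region) {
  if (any(muscle_region & !roi))
    stop("muscle_region is not contained in the ROI")
  roi & !muscle_region
}

#' Remove small 3D connected components
#'
#' @param imf_mask_3d 3D binary array.
#' @param min_voxels minimum component size kept (components with fewer
#'   voxels are removed).
#' @param connectivity 6, 18 or 26.
#' @return List with `mask` (filtered logical array) and `removed`
#'   (number of deleted components).
#' @export
filter_small_clusters <- function(imf_mask_3d, min_voxels = 4L,
                                  connectivity = 26L) {
  stopifnot(min_voxels >= 1)
  lab <- .label3d_cpp(as.logical(imf_mask_3d), dim(imf_mask_3d),
                      as.integer(connectivity))
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0L)
    return(list(mask = array(FALSE, dim(imf_mask_3d)), removed = 0L))
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  keep <- sizes >= min_voxels
  out <- array(FALSE, dim(imf_mask_3d))
  out[lab > 0L] <- keep[lab[lab > 0L]]
  list(mask = out, removed = sum(!keep))
}

#' Extract intramuscular fat clusters from a fat-fraction volume
#'
#' Full per-muscle pipeline: for every slice where the muscle is visible,
#' the segmentation is eroded, the slice-median FF computed, a muscle-tissue
#' region grown from the closest-to-median seed, and the IMF pixels taken as
#' the complement within the eroded ROI. The stacked per-slice IMF pixels
#' are then filtered in 3D to remove components smaller than
#' `min_cluster_voxels`. Deterministic for fixed inputs.
#'
#' @param ff an [ff_volume].
#' @param mask a [muscle_mask] on the same grid.
#' @param params a [growth_params] object.
#' @return An object of class `imf_result`: `imf_mask` (filtered 3D logical),
#'   `muscle_region` (grown muscle tissue), `eroded_roi`, `per_slice`
#'   (data frame with `slice`, `ff_median`, `n_roi`, `n_imf_prefilter`,
#'   `analyzed`), `removed_small_clusters`, `excluded_slices`, `params`,
#'   plus grid metadata.
#' @export
extract_imf <- function(ff, mask, params = growth_params()) {
  check_same_grid(ff, mask)
  ax <- ff$slice_axis
  perm <- c(setdiff(1:3, ax), ax)        # slice axis last
  ffd <- aperm(ff$data, perm)
  mkd <- aperm(mask$data, perm)
  nz <- dim(ffd)[3]
  imf_pre <- array(FALSE, dim(ffd))
  musc <- array(FALSE, dim(ffd))
  eroded <- array(FALSE, dim(ffd))
  rec <- data.frame(slice = seq_len(nz), ff_median = NA_real_,
                    n_roi = 0L, n_imf_prefilter = 0L, analyzed = FALSE)
  excluded <- integer(0)
  for (k in seq_len(nz)) {
    msl <- mkd[, , k]
    if (!any(msl)) next
    roi <- erode_slice_roi(msl, params$erosion_pixels)
    if (!any(roi)) {       # erosion emptied the slice: skip, record
      excluded <- c(excluded, k)
      next
    }
    ffs <- ffd[, , k]
    med <- slice_ff_median(ffs, roi)
    med_used <- med * params$threshold_scale
    region <- suppressWarnings(
      grow_muscle_region(ffs, roi, med_used, params$search_radius_r,
                         params$single_pass))
    region <- region & roi   # seed aside, growth is ROI-confined by contract
    imf_sl <- imf_mask_from_growth(roi, region)
    imf_pre[, , k] <- imf_sl
    musc[, , k] <- region
    eroded[, , k] <- roi
    rec$ff_median[k] <- med
    rec$n_roi[k] <- sum(roi)
    rec$n_imf_prefilter[k] <- sum(imf_sl)
    rec$analyzed[k] <- TRUE
  }
  if (!any(rec$analyzed)) stop("no analyzable slices in this volume")
  flt <- filter_small_clusters(imf_pre, params$min_cluster_voxels,
                               params$connectivity_3d)
  iperm <- order(perm)
  structure(list(imf_mask = aperm(flt$mask, iperm),
                 muscle_region = aperm(musc, iperm),
                 eroded_roi = aperm(eroded, iperm),
                 per_slice = rec,
                 removed_small_clusters = flt$removed,
                 excluded_slices = excluded,
                 params = params,
                 spacing = ff$spacing,
                 slice_axis = ax,
                 distal_to_proximal = ff$distal_to_proximal),
            class = "imf_result")
}

#' @export
print.imf_result <- function(x, ...) {
  cat("<imf_result> ", sum(x$imf_mask), " IMF voxels across ",
      sum(x$per_slice$analyzed), " slices; ",
      x$removed_small_clusters, " small clusters removed\n", sep = "")
  invisible(x)
}
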