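#' Fat-fraction volume
#'
#' Container for a 3D fat-fraction (FF) map. FF is stored dimensionless in
#' \[0, 1\] (fat signal over fat + water); all printed reports use percent.
#' `NaN` marks voxels where FF is undefined (zero total signal); finite
#' values outside \[0, 1\] are rejected.
#'
#' @param data 3D numeric array of fat fractions in \[0, 1\] (NaN allowed).
#' @param spacing numeric length-3, voxel size in mm along each array axis;
#'   strictly positive.
#' @param slice_axis which array axis runs along the muscle (1, 2 or 3).
#' @param distal_to_proximal logical; `TRUE` when increasing slice index
#'   moves from the distal to the proximal end of the muscle.
#' @return An object of class `ff_volume`.
#' @export
ff_volume <- function(data, spacing, slice_axis = 3L, distal_to_proximal = TRUE) {
  if (length(dim(data)) != 3L) stop("FF data must be a 3D array")
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("slice_axis must be 1, 2 or 3")
  fin <- data[is.finite(data)]
  if (length(fin) && (min(fin) < 0 || max(fin) > 1))
    stop("finite FF values must lie in [0, 1]")
  structure(list(data = data, spacing = as.numeric(spacing),
                 slice_axis = slice_axis,
                 distal_to_proximal = isTRUE(distal_to_proximal)),
            class = "ff_volume")
}

#' Binary muscle mask
#'
#' @param data 3D array coercible to logical (values in \{0, 1\}).
#' @param muscle_label identifier, e.g. `"MG"`, `"LG"`, `"SOL"`.
#' @inheritParams ff_volume
#' @return An object of class `muscle_mask`.
#' @export
muscle_mask <- function(data, spacing, muscle_label = "muscle",
                        slice_axis = 3L, distal_to_proximal = TRUE) {
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("mask values must be binary {0, 1}")
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  d <- array(as.logical(data), dim = dim(data))
  structure(list(data = d, spacing = as.numeric(spacing),
                 muscle_label = as.character(muscle_label),
                 slice_axis = as.integer(slice_axis),
                 distal_to_proximal = isTRUE(distal_to_proximal)),
            class = "muscle_mask")
}

#' @export
print.ff_volume <- function(x, ...) {
  cat("<ff_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, slice axis ", x$slice_axis,
      if (x$distal_to_proximal) " (distal→proximal)\n" else " (proximal→distal)\n",
      sep = "")
  fin <- x$data[is.finite(x$data)]
  if (length(fin))
    cat("  FF range ", sprintf("%.1f%%..%.1f%%", 100 * min(fin), 100 * max(fin)), "\n", sep = "")
  invisible(x)
}

#' @export
print.muscle_mask <- function(x, ...) {
  cat("<muscle_mask '", x$muscle_label, "'> ",
      paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

#' Compute a fat-fraction map from fat and water signal volumes
#'
#' FF is the fat-to-total signal ratio, `fat / (fat + water)`, evaluated
#' voxelwise. Voxels with zero total signal get `NaN`.
#'
#' @param fat_signal,water_signal non-negative 3D arrays of equal shape.
#' @inheritParams ff_volume
#' @return An [ff_volume].
#' @examples
#' f <- array(c(50, 0, 30), c(3, 1, 1)); w <- array(c(50, 80, 70), c(3, 1, 1))
#' compute_ff_map(f, w, spacing = c(1, 1, 1))$data[, 1, 1]  # 0.5 0.0 0.3
#' @export
compute_ff_map <- function(fat_signal, water_signal, spacing,
                           slice_axis = 3L, distal_to_proximal = TRUE) {
  if (!identical(dim(fat_signal), dim(water_signal)))
    stop("fat and water volumes must have the same shape")
  if (any(fat_signal < 0, na.rm = TRUE) || any(water_signal < 0, na.rm = TRUE))
    stop("signal values must be non-negative")
  tot <- fat_signal + water_signal
  ff <- fat_signal / tot
  ff[tot == 0] <- NaN
  ff_volume(ff, spacing, slice_axis, distal_to_proximal)
}

#' Read a fat-fraction volume or muscle mask from NIfTI
#'
#' FF volumes stored in percent (max value > 1.5) are rescaled to \[0, 1\]
#' with a warning. Masks are binarised at 0.5 but must contain only values
#' within 1e-6 of 0 or 1.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param kind `"ff"` or `"mask"`.
#' @param muscle_label label attached when `kind = "mask"`.
#' @inheritParams ff_volume
#' @return An [ff_volume] or [muscle_mask].
#' @export
read_volume <- function(path, kind = c("ff", "mask"), muscle_label = "muscle",
                        slice_axis = 3L, distal_to_proximal = TRUE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), "D")
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (kind == "ff") {
    mx <- suppressWarnings(max(arr[is.finite(arr)]))
    if (is.finite(mx) && mx > 1.5) {
      warning("FF volume appears to be in percent (max = ", signif(mx, 4),
              "); rescaling to [0, 1]")
      arr <- arr / 100
    }
    ff_volume(arr, spacing, slice_axis, distal_to_proximal)
  } else {
    dev <- pmin(abs(arr), abs(arr - 1))
    if (any(dev > 1e-6, na.rm = TRUE))
      stop("mask contains non-binary values")
    muscle_mask(arr > 0.5, spacing, muscle_label, slice_axis, distal_to_proximal)
  }
}

#' Write a volume or mask to NIfTI
#'
#' @param x an [ff_volume], [muscle_mask], or 3D array.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param spacing voxel spacing, required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "ff_volume") || inherits(x, "muscle_mask")) {
    arr <- x$data
    spacing <- x$spacing
  } else {
    arr <- x
    if (is.null(spacing)) stop("spacing required for bare arrays")
  }
  storage.mode(arr) <- if (is.logical(arr)) "integer" else "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert an IMF mask to a physical point cloud
#'
#' Each foreground voxel becomes a point at its voxel centre,
#' `(index - 1 + 0.5) * spacing` in mm (0-based index convention), or in
#' voxel units when `units = "voxel"`. The enclosing muscle supplies the
#' reference volume and the CSR bounding domain (the axis-aligned bounding
#' box of the muscle foreground).
#'
#' @param imf_mask 3D binary array (e.g. `imf_mask` from [extract_imf()]),
#'   or an `imf_result`.
#' @param muscle 	a [muscle_mask] on the same grid.
#' @param units `"mm"` (default) or `"voxel"` (unit spacing, the paper-style
#'   "a.u." axis for Ripley analyses).
#' @return An object of class `muscle_point_cloud` with elements `points`
#'   (n x 3 matrix), `muscle_volume`, `bounding_domain` (list with `lower`,
#'   `upper`), `mask_domain` (the muscle mask, for mask-based CSR sampling),
#'   `spacing`, `units`.
#' @export
mask_to_point_cloud <- function(imf_mask, muscle, units = c("mm", "voxel")) {
  units <- match.arg(units)
  if (inherits(imf_mask, "imf_result")) imf_mask <- imf_mask$imf_mask
  if (!inherits(muscle, "muscle_mask")) stop("muscle must be a muscle_mask")
  if (!identical(dim(imf_mask), dim(muscle$data)))
    stop("IMF mask and muscle mask grids differ")
  if (any(imf_mask & !muscle$data))
    stop("IMF mask extends outside the muscle mask")
  idx <- which(imf_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no IMF clusters: the IMF mask is empty")
  sp <- if (units == "mm") muscle$spacing else c(1, 1, 1)
  pts <- sweep(idx - 0.5, 2, sp, `*`)
  colnames(pts) <- c("x", "y", "z")
  voxvol <- prod(sp)
  midx <- which(muscle$data, arr.ind = TRUE)
  lower <- (apply(midx, 2, min) - 1) * sp
  upper <- apply(midx, 2, max) * sp
  structure(list(points = unname(pts),
                 muscle_volume = nrow(midx) * voxvol,
                 bounding_domain = list(lower = unname(lower), upper = unname(upper)),
                 mask_domain = muscle, spacing = sp, units = units),
            class = "muscle_point_cloud")
}

#' @export
print.muscle_point_cloud <- function(x, ...) {
  cat("<muscle_point_cloud> ", nrow(x$points), " points (", x$units,
      "), muscle volume ", signif(x$muscle_volume, 5), "\n", sep = "")
  invisible(x)
}

# shared grid check
check_same_grid <- function(ff, mask) {
  stopifnot(inherits(ff, "ff_volume"), inherits(mask, "muscle_mask"))
  if (!identical(dim(ff$data), dim(mask$data)))
    stop("FF volume and mask have different shapes")
  if (max(abs(ff$spacing - mask$spacing)) > 1e-6)
    stop("FF volume and mask have different voxel spacing")
  if (ff$slice_axis != mask$slice_axis)
    stop("FF volume and mask disagree on the slice axis")
  invisible(TRUE)
}
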