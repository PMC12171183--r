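#' Map analyzed slice indices to percent muscle length
#'
#' Linear map with 0% at the distal end and 100% at the proximal end. When
#' the acquisition runs proximal-to-distal (`distal_to_proximal = FALSE`)
#' the order is flipped before mapping.
#'
#' @param slice_indices ordered integer slice indices (>= 2 slices).
#' @param distal_to_proximal orientation flag of the volume.
#' @return Numeric vector in \[0, 100\], one value per input slice.
#' @export
to_percent_length <- function(slice_indices, distal_to_proximal = TRUE) {
  n <- length(slice_indices)
  if (n < 2L) stop("need at least two analyzed slices for a length profile")
  s <- as.numeric(slice_indices)
  p <- (s - s[1]) / (s[n] - s[1]) * 100
  if (!distal_to_proximal) p <- 100 - p
  p
}

#' Per-slice 2D metrics: mean FF and FF pixel percentage
#'
#' For every analyzed slice, `mean_ff` is the average FF over the full
#' eroded muscle ROI (an index of IMF magnitude) and `ff_pixel_percentage`
#' is 100 x (IMF-mask pixels / ROI pixels), the proportion of the muscle
#' cross-section occupied by extracted IMF clusters. Rows are ordered
#' distal to proximal.
#'
#' @param ff the [ff_volume] used for extraction.
#' @param imf an `imf_result` from [extract_imf()].
#' @return Data frame with columns `slice`, `percent_length`, `mean_ff`,
#'   `ff_pixel_percentage`, `n_roi_pixels`, `n_imf_pixels`.
#' @export
slice_metrics <- function(ff, imf) {
  stopifnot(inherits(ff, "ff_volume"), inherits(imf, "imf_result"))
  ax <- imf$slice_axis
  perm <- c(setdiff(1:3, ax), ax)
  ffd <- aperm(ff$data, perm)
  roi <- aperm(imf$eroded_roi, perm)
  im <- aperm(imf$imf_mask, perm)
  ks <- imf$per_slice$slice[imf$per_slice$analyzed]
  pct <- to_percent_length(ks, imf$distal_to_proximal)
  out <- data.frame(slice = ks, percent_length = pct,
                    mean_ff = NA_real_, ff_pixel_percentage = NA_real_,
                    n_roi_pixels = NA_integer_, n_imf_pixels = NA_integer_)
  for (i in seq_along(ks)) {
    k <- ks[i]
    r <- roi[, , k]
    v <- ffd[, , k][r]
    out$mean_ff[i] <- mean(v[is.finite(v)])
    out$n_roi_pixels[i] <- sum(r)
    out$n_imf_pixels[i] <- sum(im[, , k])
    out$ff_pixel_percentage[i] <- 100 * out$n_imf_pixels[i] / out$n_roi_pixels[i]
  }
  out[order(out$percent_length), , drop = FALSE]
}

#' Scott's-rule kernel bandwidth
#'
#' One-dimensional Scott bandwidth `h = sd(x) * n^(-1/5)`.
#'
#' @param values numeric vector, n >= 2 with nonzero variance.
#' @return The bandwidth (same units as `values`).
#' @export
scott_bandwidth <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least two values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate profile: zero variance")
  s * n^(-1 / 5)
}

#' Density contours of a metric along the muscle length
#'
#' Gaussian product-kernel density over (percent length, metric value) with
#' independent Scott's-rule bandwidths per axis, as used for along-muscle
#' contour plots. Profiles from several participants may be pooled by
#' row-binding before the call. The density ridge (the modal metric value
#' at each percent-length grid column) yields the reported peak value and
#' its location.
#'
#' @param profiles data frame from [slice_metrics()] (one or several,
#'   row-bound).
#' @param metric `"ff_pixel_percentage"` or `"mean_ff"`.
#' @param n_grid grid resolution per axis.
#' @return Object of class `profile_density`: `x` (percent length grid),
#'   `y` (metric grid), `z` (density matrix), `bandwidth` (length 2),
#'   `peak_value`, `peak_location_percent`, `peak_density`, `metric_name`.
#' @export
profile_density <- function(profiles, metric = c("ff_pixel_percentage", "mean_ff"),
                            n_grid = 100L) {
  metric <- match.arg(metric)
  px <- profiles$percent_length
  py <- profiles[[metric]]
  ok <- is.finite(px) & is.finite(py)
  px <- px[ok]; py <- py[ok]
  hx <- scott_bandwidth(px)
  hy <- scott_bandwidth(py)
  # grid extends 4 bandwidths beyond the data so the kernel mass is captured
  gx <- seq(min(px) - 4 * hx, max(px) + 4 * hx, length.out = n_grid)
  gy <- seq(min(py) - 4 * hy, max(py) + 4 * hy, length.out = n_grid)
  kx <- outer(gx, px, function(g, p) dnorm((g - p) / hx) / hx)
  ky <- outer(gy, py, function(g, p) dnorm((g - p) / hy) / hy)
  z <- kx %*% t(ky) / length(px)
  ridge_iy <- apply(z, 1, which.max)
  ridge_y <- gy[ridge_iy]
  # the ridge is flat near a smooth maximum; the plateau midpoint is a far
  # stabler location estimate than the first grid cell attaining the max.
  # Only grid columns inside the observed length range are eligible (the
  # grid itself is padded for normalisation).
  cell_y <- gy[2] - gy[1]
  sel <- gx >= min(px) & gx <= max(px)
  rsel <- ridge_y[sel]
  plateau <- gx[sel][rsel >= max(rsel) - cell_y]
  structure(list(x = gx, y = gy, z = z, bandwidth = c(x = hx, y = hy),
                 ridge = ridge_y,
                 peak_value = max(rsel),
                 peak_location_percent = median(plateau),
                 peak_density = max(z),
                 metric_name = metric, n = length(px)),
            class = "profile_density")
}

#' @export
print.profile_density <- function(x, ...) {
  cat("<profile_density> ", x$metric_name, ": bandwidths (",
      signif(x$bandwidth[1], 4), ", ", signif(x$bandwidth[2], 4),
      "), ridge peak ", signif(x$peak_value, 4), " at ",
      signif(x$peak_location_percent, 4), "% length\n", sep = "")
  invisible(x)
}

#' Pearson correlation between the two along-muscle profiles
#'
#' @param mean_ff_curve,ffpp_curve numeric vectors of equal length >= 3
#'   (mean FF and FF pixel percentage along the muscle).
#' @return Pearson r.
#' @export
profile_correlation <- function(mean_ff_curve, ffpp_curve) {
  if (length(mean_ff_curve) != length(ffpp_curve))
    stop("curves must have equal length")
  if (length(mean_ff_curve) < 3L) stop("need at least 3 points")
  if (sd(mean_ff_curve) == 0 || sd(ffpp_curve) == 0)
    stop("zero variance in a profile")
  cor(mean_ff_curve, ffpp_curve)
}
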