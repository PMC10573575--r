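## En face choroidal maps: thickness, Otsu vessel binarization, CVI.

#' En face choroidal thickness map
#'
#' Thickness at each A-scan is `(csi - bm) * axial_spacing_um`.  Depends only
#' on the surfaces, never on intensities, so it is invariant to the
#' attenuation-compensation parameters once the surfaces are fixed.
#'
#' @param surfaces A [surface_set].
#' @param axial_spacing_um Axial sampling in micrometers.
#' @return An [enface_map] in um.
#' @export
thickness_map <- function(surfaces, axial_spacing_um) {
  stopifnot(inherits(surfaces, "surface_set"), axial_spacing_um > 0)
  enface_map((surfaces$csi - surfaces$bm) * axial_spacing_um, units = "um")
}

#' Otsu threshold on a 256-bin histogram
#'
#' Splits the value range into 256 equal bins and returns the bin edge
#' maximizing the between-class variance `n0 * n1 * (m0 - m1)^2`, with class
#' statistics computed exactly from the values in each class (per-bin sums,
#' not bin midpoints).  Ties are broken toward the lower threshold.  For
#' vessel segmentation the input is every attenuation-corrected voxel of the
#' choroidal slab of one eye-visit (global thresholding).
#'
#' @param values Numeric vector/array; `NA` dropped.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value (numeric scalar).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need at least 2 values to threshold")
  rng <- range(v)
  if (rng[1] == rng[2]) stop("cannot threshold constant input")
  width <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(floor((v - rng[1]) / width) + 1L, n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(v, group = bin)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  n0 <- cumsum(as.numeric(cnt))[-n_bins]
  s0 <- cumsum(sums)[-n_bins]
  N <- length(v); S <- sum(v)
  n1 <- N - n0; s1 <- S - s0
  bcv <- rep(-Inf, n_bins - 1L)
  ok <- n0 > 0L & n1 > 0L
  bcv[ok] <- n0[ok] * n1[ok] * (s0[ok] / n0[ok] - s1[ok] / n1[ok])^2
  k <- which.max(bcv)  # first maximum = lowest threshold on ties
  rng[1] + k * width
}

#' Despeckle a corrected volume for vessel binarization
#'
#' Prepares the attenuation-compensated volume for global Otsu thresholding:
#' maps intensities to a logarithmic scale (OCT speckle is multiplicative,
#' so the log makes the vessel and stroma classes symmetric with equal
#' spread, which is where a between-class-variance split is unbiased), then
#' applies an axial running median and a mild axial Gaussian.  Filtering is
#' axial only: choroidal vessels are thin laterally at wide-field A-scan
#' spacing, so lateral averaging would destroy their contrast.
#'
#' @param x An [oct_volume] or 3-D array (attenuation-corrected).
#' @param median_k Axial running-median window (odd; default 7).
#' @param sigma_z Axial Gaussian sigma in voxels (default 2).
#' @param log_scale Work on `log(x + offset)` (default `TRUE`).
#' @param offset Additive offset guarding `log(0)`; default `1e-6` times the
#'   volume maximum.
#' @return Same type as the input.
#' @export
despeckle_volume <- function(x, median_k = 7L, sigma_z = 2,
                             log_scale = TRUE, offset = NULL) {
  is_vol <- inherits(x, "oct_volume")
  arr <- if (is_vol) x$intensity else x
  if (log_scale) {
    if (is.null(offset)) offset <- 1e-6 * max(arr)
    arr <- log(arr + offset)
  }
  if (median_k > 1L) arr <- running_median_z(arr, median_k)
  if (sigma_z > 0) arr <- gaussian_smooth_3d(arr, sigma_z = sigma_z)
  if (is_vol) {
    x$intensity <- arr
    x
  } else arr
}

## Axial running median per A-scan (stats::runmed per column).
running_median_z <- function(arr, k) {
  d <- dim(arr)
  k <- min(as.integer(k), if (d[3] %% 2L == 1L) d[3] else d[3] - 1L)
  if (k < 3L) return(arr)
  out <- arr
  for (y in seq_len(d[1])) for (x in seq_len(d[2]))
    out[y, x, ] <- stats::runmed(arr[y, x, ], k)
  out
}

#' Binarize choroidal vessels within the slab
#'
#' A slab voxel (z in `[round(bm), round(csi))` of its A-scan) is a vessel
#' voxel iff its corrected intensity is strictly below the threshold; vessel
#' lumens are hyporeflective in structural OCT.  Voxels outside the slab are
#' always `FALSE`.
#'
#' @param volume An [oct_volume] or 3-D array (attenuation-corrected).
#' @param surfaces A [surface_set].
#' @param threshold Threshold from [otsu_threshold()].
#' @return 3-D logical array aligned with the volume (class `vessel_mask`).
#' @export
binarize_vessels <- function(volume, surfaces, threshold) {
  arr <- if (inherits(volume, "oct_volume")) volume$intensity else volume
  d <- dim(arr)
  zt <- round_half_up(surfaces$bm)
  zb <- round_half_up(surfaces$csi)
  mask <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) {
    inslab <- z >= zt & z < zb
    if (!any(inslab)) next
    sl <- arr[, , z] < threshold
    mask[, , z] <- inslab & sl
  }
  class(mask) <- c("vessel_mask", class(mask))
  mask
}

#' Extract the slab voxel values of a volume
#'
#' Convenience used to feed [otsu_threshold()]: all corrected intensities
#' with z in `[round(bm), round(csi))` of their A-scan.
#'
#' @param volume An [oct_volume] or 3-D array.
#' @param surfaces A [surface_set].
#' @return Numeric vector of slab voxel values.
#' @export
slab_values <- function(volume, surfaces) {
  arr <- if (inherits(volume, "oct_volume")) volume$intensity else volume
  d <- dim(arr)
  zt <- round_half_up(surfaces$bm)
  zb <- round_half_up(surfaces$csi)
  out <- vector("list", d[3])
  for (z in seq_len(d[3])) {
    inslab <- z >= zt & z < zb
    if (any(inslab)) out[[z]] <- arr[, , z][inslab]
  }
  unlist(out, use.names = FALSE)
}

#' Majority cleanup of a vessel mask
#'
#' Axial majority vote (running median on the binary labels) per A-scan,
#' re-restricted to the choroidal slab: removes isolated misclassified
#' voxels while preserving vessel cross-sections wider than half the
#' window.
#'
#' @param vessel_mask Output of [binarize_vessels()].
#' @param surfaces A [surface_set].
#' @param k Odd window length in voxels (default 9).
#' @return Cleaned `vessel_mask`.
#' @export
clean_vessel_mask <- function(vessel_mask, surfaces, k = 9L) {
  d <- dim(vessel_mask)
  cleaned <- running_median_z(vessel_mask + 0, k) > 0.5
  zt <- round_half_up(surfaces$bm)
  zb <- round_half_up(surfaces$csi)
  for (z in seq_len(d[3])) cleaned[, , z] <- cleaned[, , z] & (z >= zt & z < zb)
  class(cleaned) <- c("vessel_mask", class(cleaned))
  cleaned
}

#' Per-A-scan CVI map
#'
#' The choroidal vascularity index of an A-scan is the ratio of its vessel
#' voxel count to its slab voxel count over `[round(bm), round(csi))`.
#' A-scans with an empty slab are missing.
#'
#' @param vessel_mask Output of [binarize_vessels()].
#' @param surfaces A [surface_set].
#' @return An [enface_map] with `units = "ratio"`.
#' @export
cvi_map <- function(vessel_mask, surfaces) {
  d <- dim(vessel_mask)
  zt <- round_half_up(surfaces$bm)
  zb <- round_half_up(surfaces$csi)
  if (!all(dim(zt) == d[1:2])) stop("mask and surfaces are not aligned")
  slab <- pmax(zb - zt, 0L)
  cnt <- matrix(0L, d[1], d[2])
  for (z in seq_len(d[3])) cnt <- cnt + vessel_mask[, , z]
  enface_map(ifelse(slab > 0L, cnt / slab, NA_real_), units = "ratio")
}

#' Global CVI of a volume
#'
#' Total vessel voxels over total slab voxels.  Identical to the
#' slab-count-weighted mean of the [cvi_map()] (integer identity).
#'
#' @inheritParams cvi_map
#' @return Numeric scalar in \[0, 1\].
#' @export
cvi_global <- function(vessel_mask, surfaces) {
  zt <- round_half_up(surfaces$bm)
  zb <- round_half_up(surfaces$csi)
  slab_total <- sum(pmax(zb - zt, 0L))
  if (slab_total == 0L) return(NA_real_)
  sum(vessel_mask) / slab_total
}
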