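## Segmentation of Bruch's membrane (BM) and the choroidal-scleral interface
## (CSI).
##
## Each B-scan is segmented independently with a shortest-path dynamic
## program over its columns; cost is the signed axial derivative of a
## Gaussian-smoothed volume (a scale-space edge detector), transitions are
## limited to `max_step` voxels per column, and the resulting surface is
## optionally median-filtered across the en face grid and refined to
## sub-voxel precision by a parabolic fit around the integer optimum.

#' Surface set (BM + CSI)
#'
#' @param bm,csi Numeric matrices `[y, x]` of fractional 1-based axial
#'   depths with `1 <= bm <= csi` everywhere.
#' @param provenance Character matrix (`"auto"` or `"corrected"`) per A-scan.
#' @return An object of class `surface_set`.
#' @export
surface_set <- function(bm, csi, provenance = NULL) {
  bm <- map_values(bm); csi <- map_values(csi)
  if (!all(dim(bm) == dim(csi))) stop("bm and csi must share a grid")
  if (any(is.na(bm)) || any(is.na(csi)))
    stop("surfaces must not contain missing values")
  if (any(bm < 1 - 1e-9)) stop("bm depths must be >= 1 (1-based voxel index)")
  n_bad <- sum(csi < bm - 1e-9)
  if (n_bad > 0)
    stop(sprintf("csi < bm at %d A-scan(s)", n_bad))
  if (is.null(provenance))
    provenance <- matrix("auto", nrow(bm), ncol(bm))
  if (!all(dim(provenance) == dim(bm))) stop("provenance shape mismatch")
  structure(list(bm = bm, csi = csi, provenance = provenance),
            class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface_set> %d x %d A-scans, %d corrected\n",
              nrow(x$bm), ncol(x$bm), sum(x$provenance == "corrected")))
  cat(sprintf("  bm [%.1f, %.1f], csi [%.1f, %.1f] (voxel depth)\n",
              min(x$bm), max(x$bm), min(x$csi), max(x$csi)))
  invisible(x)
}

## ---- smoothing helpers --------------------------------------------------

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

## Convolve a 3-D array along one dimension with edge replication.
convolve_dim <- function(arr, kernel, dim_i) {
  r <- (length(kernel) - 1L) / 2
  d <- dim(arr)
  out <- array(0, dim = d)
  n <- d[dim_i]
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    shifted <- switch(dim_i,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kernel[j] * shifted
  }
  out
}

gaussian_smooth_3d <- function(arr, sigma_z = 0, sigma_lat = 0) {
  if (sigma_z > 0) arr <- convolve_dim(arr, gauss_kernel(sigma_z), 3L)
  if (sigma_lat > 0) {
    k <- gauss_kernel(sigma_lat)
    arr <- convolve_dim(arr, k, 1L)
    arr <- convolve_dim(arr, k, 2L)
  }
  arr
}

## Grey-scale morphological closing along z with a flat window of `len`
## voxels: fills dark gaps (vessel lumens) narrower than the window while
## leaving wide monotone steps such as the CSI in place.
closing_z <- function(arr, len) {
  if (len <= 1L) return(arr)
  half <- floor(len / 2)
  n <- dim(arr)[3]
  dil <- arr
  for (off in seq_len(half)) {
    lo <- pmin(pmax(seq_len(n) + off, 1L), n)
    hi <- pmin(pmax(seq_len(n) - off, 1L), n)
    dil <- pmax(dil, arr[, , lo, drop = FALSE], arr[, , hi, drop = FALSE])
  }
  ero <- dil
  for (off in seq_len(half)) {
    lo <- pmin(pmax(seq_len(n) + off, 1L), n)
    hi <- pmin(pmax(seq_len(n) - off, 1L), n)
    ero <- pmin(ero, dil[, , lo, drop = FALSE], dil[, , hi, drop = FALSE])
  }
  ero
}

## 3 x 3 median filter with edge replication (surface smoothing across the
## en face grid).
median_filter_2d <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  stack <- array(0, dim = c(ny, nx, 9L))
  k <- 0L
  for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    iy <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
    ix <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
    stack[, , k] <- m[iy, ix]
  }
  apply(stack, c(1, 2), stats::median)
}

#' Minimum-cost path through a cost matrix (per-B-scan dynamic program)
#'
#' Finds, for a cost matrix with one row per column position `x` and one
#' column per depth `z`, the depth path `z(x)` minimizing the total cost
#' subject to `|z(x+1) - z(x)| <= max_step`.  Ties are broken toward smaller
#' `z`.  Exported because it is the segmentation primitive and is checked
#' against exhaustive enumeration in the tests.
#'
#' @param cost Numeric matrix `[x, z]` of finite costs.
#' @param max_step Maximum permitted depth change between adjacent columns.
#' @return A list with `path` (integer depth per column) and `cost` (total).
#' @export
dp_min_path <- function(cost, max_step = 2L) {
  if (!all(is.finite(cost))) stop("non-finite costs in dynamic program")
  nx <- nrow(cost); nz <- ncol(cost)
  max_step <- as.integer(max_step)
  M <- cost[1, ]
  P <- matrix(0L, nx, nz)
  if (nx > 1) {
    for (x in 2:nx) {
      best <- rep(Inf, nz)
      ptr <- integer(nz)
      for (d in seq(-max_step, max_step)) {
        idx <- seq_len(nz) + d
        ok <- idx >= 1L & idx <= nz
        v <- rep(Inf, nz)
        v[ok] <- M[idx[ok]]
        upd <- v < best
        best[upd] <- v[upd]
        ptr[upd] <- idx[upd]
      }
      M <- cost[x, ] + best
      P[x, ] <- ptr
    }
  }
  z_end <- which.min(M)
  path <- integer(nx)
  path[nx] <- z_end
  if (nx > 1) {
    for (x in seq(nx, 2L)) path[x - 1L] <- P[x, path[x]]
  }
  list(path = path, cost = M[z_end])
}

## Parabolic sub-voxel refinement of a path on its cost profile.
refine_subvoxel <- function(path, cost) {
  nz <- ncol(cost)
  out <- as.numeric(path)
  for (x in seq_along(path)) {
    z <- path[x]
    if (z <= 1L || z >= nz) next
    c0 <- cost[x, z]; cl <- cost[x, z - 1L]; ch <- cost[x, z + 1L]
    denom <- cl - 2 * c0 + ch
    if (is.finite(denom) && denom > 0) {
      dz <- 0.5 * (cl - ch) / denom
      out[x] <- z + max(min(dz, 0.5), -0.5)
    }
  }
  out
}

#' Segment one surface by per-B-scan dynamic programming
#'
#' Cost at `(x, z)` is the signed axial derivative of the (smoothed) volume:
#' with `polarity = "bright_above"` the program seeks the strongest
#' bright-to-dark transition going deeper (the BM at the RPE base, or the
#' CSI); `"dark_above"` seeks dark-to-bright transitions.
#'
#' @param volume An [oct_volume] or 3-D array (attenuation-corrected).
#' @param polarity `"bright_above"` or `"dark_above"`.
#' @param max_step Maximum depth step between adjacent A-scans (voxels).
#' @param band Integer `c(z_lo, z_hi)` global search band (1-based,
#'   inclusive).
#' @param lo,hi Optional per-A-scan matrices further restricting the band
#'   (used for surfaces constrained relative to another surface).
#' @param smooth_sigma,lateral_sigma Gaussian smoothing (voxels) applied
#'   before differentiation.
#' @param median_filter Apply a 3 x 3 median filter to the surface
#'   (default `TRUE`).
#' @param subvoxel Parabolic sub-voxel refinement (default `TRUE`).
#' @return Numeric matrix `[y, x]` of fractional depths.
#' @export
segment_surface <- function(volume, polarity = c("bright_above", "dark_above"),
                            max_step = 2L, band = NULL, lo = NULL, hi = NULL,
                            smooth_sigma = 1.5, lateral_sigma = 1,
                            median_filter = TRUE, subvoxel = TRUE) {
  polarity <- match.arg(polarity)
  arr <- if (inherits(volume, "oct_volume")) volume$intensity else volume
  d <- dim(arr)
  if (is.null(band)) band <- c(2L, d[3] - 1L)
  band <- as.integer(round(band))
  if (band[1] > band[2] || band[1] < 1L || band[2] > d[3])
    stop("empty or out-of-range search band")
  sm <- gaussian_smooth_3d(arr, sigma_z = smooth_sigma,
                           sigma_lat = lateral_sigma)
  ## central axial derivative
  n <- d[3]
  zl <- pmax(seq_len(n) - 1L, 1L)
  zh <- pmin(seq_len(n) + 1L, n)
  deriv <- (sm[, , zh, drop = FALSE] - sm[, , zl, drop = FALSE]) / 2
  cost_arr <- if (polarity == "bright_above") deriv else -deriv
  if (!all(is.finite(cost_arr))) stop("non-finite costs in segmentation")
  zs <- band[1]:band[2]
  BIG <- max(abs(cost_arr)) * length(zs) * d[2] + 1
  out <- matrix(0, d[1], d[2])
  for (y in seq_len(d[1])) {
    cmat <- matrix(cost_arr[y, , zs], d[2], length(zs))
    if (!is.null(lo) || !is.null(hi)) {
      zmat <- matrix(zs, d[2], length(zs), byrow = TRUE)
      if (!is.null(lo)) cmat[zmat < matrix(lo[y, ], d[2], length(zs))] <- BIG
      if (!is.null(hi)) cmat[zmat > matrix(hi[y, ], d[2], length(zs))] <- BIG
    }
    res <- dp_min_path(cmat, max_step = max_step)
    z_path <- if (subvoxel) refine_subvoxel(res$path, cmat) else res$path
    out[y, ] <- zs[1] - 1L + z_path
  }
  if (median_filter) out <- median_filter_2d(out)
  pmin(pmax(out, 1), d[3])
}

#' Segment the choroid: Bruch's membrane and the choroidal-scleral interface
#'
#' BM is found on the raw volume as the strongest bright-to-dark edge in a
#' band around the brightest axial sample of each A-scan (the RPE complex,
#' always the dominant reflector in raw structural OCT); the CSI as the
#' strongest bright-to-dark edge in a band below the BM on the
#' attenuation-compensated volume.  Because the compensation leaves the
#' choroid depth-flat while the inner sclera is markedly dimmer, the CSI
#' step dominates scattered vessel-wall edges once the volume is smoothed at
#' the CSI scale; an optional grey-scale closing along depth
#' (`closing_depth_um > 0`) can additionally fill vessel lumens.  Columns
#' where the CSI would cross above the BM are clamped to it; if more than
#' `max_clamped_frac` of A-scans need clamping the segmentation is considered
#' failed.
#'
#' @param volume An [oct_volume] (raw intensities).
#' @param corrected Optional precomputed attenuation-compensated volume (an
#'   [oct_volume] or array); computed internally when `NULL` and
#'   `compensate = TRUE`.
#' @param compensate Use attenuation compensation for the CSI search
#'   (default `TRUE`; `FALSE` searches the raw volume, mainly useful to
#'   quantify how much the compensation helps under shadows).
#' @param attenuation List of [compensate_attenuation()] arguments.
#' @param max_step Maximum surface step between adjacent A-scans (voxels).
#' @param smooth_sigma,lateral_sigma Pre-derivative smoothing for BM
#'   (voxels).
#' @param csi_smooth_sigma,csi_lateral_sigma Smoothing for the CSI search.
#' @param closing_depth_um Depth window (um) of the optional vessel-filling
#'   grey-scale closing; 0 (default) disables it.
#' @param max_thickness_um Maximum plausible choroidal thickness (limits the
#'   CSI band below the BM).
#' @param min_thickness_um Minimum thickness (lower edge of the CSI band).
#'   The default 30 um keeps the CSI search clear of the strong RPE-base
#'   edge; pass 0 when segmenting a choroid known to be near-zero thickness.
#' @param median_filter,subvoxel Passed to [segment_surface()].
#' @param max_clamped_frac Error threshold on the clamped-column fraction.
#' @return A [surface_set] with attribute `n_clamped`.  Surface depths are
#'   boundary voxel indices: the (fractional) index of the first voxel of
#'   the deeper tissue, half a voxel below the edge midpoint that
#'   [segment_surface()] reports.
#' @export
segment_choroid <- function(volume, corrected = NULL, compensate = TRUE,
                            attenuation = list(), max_step = 2L,
                            smooth_sigma = 1.5, lateral_sigma = 1,
                            csi_smooth_sigma = 3, csi_lateral_sigma = 2,
                            closing_depth_um = 0,
                            max_thickness_um = 400, min_thickness_um = 30,
                            median_filter = TRUE, subvoxel = TRUE,
                            max_clamped_frac = 0.05) {
  stopifnot(inherits(volume, "oct_volume"))
  arr <- volume$intensity
  d <- dim(arr)
  ax <- volume$axial_spacing_um
  sm <- gaussian_smooth_3d(arr, sigma_z = smooth_sigma, sigma_lat = lateral_sigma)
  ## RPE locator: brightest axial sample per A-scan of the raw volume
  guard <- max(4L, round(20 / ax))
  zmax <- d[3] - guard
  cur <- matrix(-Inf, d[1], d[2]); arg <- matrix(1L, d[1], d[2])
  for (z in seq(2L, zmax)) {
    s <- sm[, , z]
    upd <- s > cur
    cur[upd] <- s[upd]; arg[upd] <- z
  }
  q <- stats::quantile(arg, c(0.02, 0.98))
  bm_band <- c(max(2L, floor(q[1]) - round(15 / ax)),
               min(d[3] - 1L, ceiling(q[2]) + round(30 / ax)))
  bm <- segment_surface(arr, "bright_above", max_step = max_step,
                        band = bm_band, smooth_sigma = smooth_sigma,
                        lateral_sigma = lateral_sigma,
                        median_filter = median_filter, subvoxel = subvoxel)
  ## CSI: compensated + vessel-filled volume, search strictly below the BM.
  ## Lateral smoothing happens before the closing so the depth-max does not
  ## inflate speckle peaks.
  csi_src <- if (isTRUE(compensate)) {
    if (is.null(corrected))
      corrected <- do.call(compensate_attenuation, c(list(volume), attenuation))
    if (inherits(corrected, "oct_volume")) corrected$intensity else corrected
  } else arr
  presm <- gaussian_smooth_3d(csi_src, sigma_z = 0,
                              sigma_lat = csi_lateral_sigma)
  closed <- closing_z(presm, len = max(1L, round(closing_depth_um / ax)))
  min_vox <- max(0, round(min_thickness_um / ax))
  max_vox <- round(max_thickness_um / ax)
  lo <- round_half_up(bm) + min_vox
  hi <- pmin(round_half_up(bm) + max_vox, d[3] - 4L)
  csi_band <- c(max(2L, min(lo)), min(d[3] - 1L, max(hi)))
  csi <- segment_surface(closed, "bright_above", max_step = max_step,
                         band = csi_band, lo = lo, hi = hi,
                         smooth_sigma = csi_smooth_sigma, lateral_sigma = 0,
                         median_filter = median_filter, subvoxel = subvoxel)
  ## The dynamic program localizes the edge midpoint (half a voxel above the
  ## first voxel of the deeper tissue); surfaces are reported as boundary
  ## voxel indices, so shift both by +0.5.
  bm <- bm + 0.5
  csi <- csi + 0.5
  n_clamped <- sum(csi < bm)
  if (n_clamped / length(bm) > max_clamped_frac)
    stop(sprintf(
      "segmentation failure: csi clamped below bm at %.1f%% of A-scans (limit %.1f%%)",
      100 * n_clamped / length(bm), 100 * max_clamped_frac))
  csi <- pmax(csi, bm)
  out <- surface_set(bm, csi)
  attr(out, "n_clamped") <- n_clamped
  attr(out, "bm_band") <- bm_band
  out
}

#' Apply sparse manual corrections to a surface set
#'
#' @param surfaces A [surface_set].
#' @param corrections A data frame (or CSV path) with columns `surface`
#'   (`"bm"` or `"csi"`), `y`, `x` (1-based A-scan coordinates) and `z` (new
#'   depth).
#' @return The corrected [surface_set]; corrected A-scans get provenance
#'   `"corrected"`.
#' @export
apply_corrections <- function(surfaces, corrections) {
  stopifnot(inherits(surfaces, "surface_set"))
  if (is.character(corrections))
    corrections <- utils::read.csv(corrections, stringsAsFactors = FALSE)
  if (nrow(corrections) == 0) return(surfaces)
  need <- c("surface", "y", "x", "z")
  if (!all(need %in% names(corrections)))
    stop("corrections must have columns: ", paste(need, collapse = ", "))
  bm <- surfaces$bm; csi <- surfaces$csi; prov <- surfaces$provenance
  ny <- nrow(bm); nx <- ncol(bm)
  for (i in seq_len(nrow(corrections))) {
    cr <- corrections[i, ]
    if (cr$y < 1 || cr$y > ny || cr$x < 1 || cr$x > nx)
      stop(sprintf("correction out of grid at row %d (y=%d, x=%d)", i, cr$y, cr$x))
    if (cr$surface == "bm") bm[cr$y, cr$x] <- cr$z
    else if (cr$surface == "csi") csi[cr$y, cr$x] <- cr$z
    else stop(sprintf("unknown surface '%s' in corrections row %d", cr$surface, i))
    prov[cr$y, cr$x] <- "corrected"
  }
  bad <- which(csi < bm - 1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("correction(s) violate bm <= csi at: %s",
                 paste(sprintf("(y=%d, x=%d)", bad[, 1], bad[, 2]),
                       collapse = ", ")))
  }
  surface_set(bm, csi, provenance = prov)
}
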