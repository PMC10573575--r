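## Fovea-centered regions, exclusion masks and regional means.
##
## The analysis regions are a fovea-centered 5-mm-diameter circle, an 11-mm-
## diameter circle, and the 3-mm-wide annular rim between their outer
## boundaries ("5-mm circle" and "11-mm circle" are diameters: an 11-mm
## radius could not fit a 12-mm scan, and the rim's quoted 6-mm width matches
## the diameter difference).  Pixel membership uses the pixel-center test in
## physical units, consistent with the integer pixel-ratio arithmetic used
## for CVI.

#' Fovea-centered circular mask
#'
#' @param shape `c(ny, nx)` of the en face grid.
#' @param center_px Fovea center `c(x, y)` in (fractional) pixel coordinates.
#' @param diameter_mm Circle diameter in millimeters.
#' @param spacing_um Lateral pixel spacing in micrometers.
#' @return Logical matrix `[y, x]`; `TRUE` where the pixel center lies within
#'   `diameter_mm / 2` of the fovea.  Errors if the circle does not fit on
#'   the grid, reporting the overflow in pixels.
#' @export
circle_mask <- function(shape, center_px, diameter_mm, spacing_um) {
  stopifnot(length(shape) >= 2, diameter_mm >= 0, spacing_um > 0)
  ny <- shape[1]; nx <- shape[2]
  r_px <- diameter_mm * 1000 / 2 / spacing_um
  over <- max(r_px - (center_px[1] - 1), r_px - (nx - center_px[1]),
              r_px - (center_px[2] - 1), r_px - (ny - center_px[2]))
  if (over > 0)
    stop(sprintf("circle of diameter %.3g mm exceeds the grid by %.2f px",
                 diameter_mm, over))
  g <- grid_coords(nx, ny)
  (g$x - center_px[1])^2 + (g$y - center_px[2])^2 <= r_px^2
}

#' Region specification and masks
#'
#' @param fovea_center_px Fovea `c(x, y)` in pixels.
#' @param lateral_spacing_um Lateral spacing in micrometers.
#' @param diameters_mm Inner and outer circle diameters (default `c(5, 11)`).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(fovea_center_px, lateral_spacing_um,
                        diameters_mm = c(5, 11)) {
  stopifnot(length(diameters_mm) == 2, all(diameters_mm > 0),
            diameters_mm[1] < diameters_mm[2])
  structure(list(fovea_center_px = fovea_center_px,
                 lateral_spacing_um = lateral_spacing_um,
                 diameters_mm = diameters_mm),
            class = "region_spec")
}

#' @param spec A [region_spec].
#' @param shape `c(ny, nx)` grid shape.
#' @return `region_masks`: named list of logical matrices `circle5`, `rim`,
#'   `circle11` (the rim is `circle11 & !circle5`).
#' @rdname region_spec
#' @export
region_masks <- function(spec, shape) {
  c5 <- circle_mask(shape, spec$fovea_center_px, spec$diameters_mm[1],
                    spec$lateral_spacing_um)
  c11 <- circle_mask(shape, spec$fovea_center_px, spec$diameters_mm[2],
                     spec$lateral_spacing_um)
  list(circle5 = c5, rim = c11 & !c5, circle11 = c11)
}

#' Union of masks
#' @param masks List of logical matrices (possibly empty).
#' @param shape Grid shape, used when `masks` is empty.
#' @return Logical matrix.
#' @export
union_masks <- function(masks, shape = NULL) {
  masks <- Filter(Negate(is.null), masks)
  if (!length(masks)) {
    if (is.null(shape)) stop("need a shape for an empty mask union")
    return(matrix(FALSE, shape[1], shape[2]))
  }
  out <- masks[[1]]
  for (m in masks[-1]) {
    if (!all(dim(m) == dim(out))) stop("mask shape mismatch in union")
    out <- out | m
  }
  out
}

#' Effective analysis mask for a region
#'
#' `region & !onh & !combined_exclusion`.  The combined exclusion is the
#' union of every visit's manually outlined artifact mask, registered to the
#' reference frame, so that an area unreliable at any visit is excluded from
#' all visits of that eye.
#'
#' @param region_mask Logical region matrix.
#' @param onh_mask Optional optic-nerve-head mask.
#' @param combined_exclusion Optional combined exclusion mask.
#' @return Logical analysis mask.
#' @export
combine_exclusions <- function(region_mask, onh_mask = NULL,
                               combined_exclusion = NULL) {
  out <- region_mask
  for (m in list(onh_mask, combined_exclusion)) {
    if (is.null(m)) next
    if (!all(dim(m) == dim(out)))
      stop("exclusion mask shape mismatch")
    out <- out & !m
  }
  out
}

#' CVI eligibility rule
#'
#' An eye is excluded from CVI analysis when the excluded area is more than
#' 10% of the 5-mm circle's area; exactly 10% is still eligible.
#'
#' @param combined_exclusion Logical exclusion mask (reference frame).
#' @param circle5_mask Logical 5-mm circle mask.
#' @param threshold Eligibility threshold (default 0.10).
#' @return List with `eligible` (logical) and `excluded_fraction`.
#' @export
cvi_eligibility <- function(combined_exclusion, circle5_mask,
                            threshold = 0.10) {
  n5 <- sum(circle5_mask)
  if (n5 == 0L) stop("empty 5-mm circle mask")
  if (is.null(combined_exclusion)) {
    frac <- 0
  } else {
    if (!all(dim(combined_exclusion) == dim(circle5_mask)))
      stop("exclusion mask shape mismatch")
    frac <- sum(combined_exclusion & circle5_mask) / n5
  }
  list(eligible = frac <= threshold, excluded_fraction = frac)
}

#' Regional mean of an en face map
#'
#' Unweighted mean over the included, non-missing pixels.  An empty
#' intersection yields an explicit missing result, never a silent zero.
#'
#' @param map An [enface_map] or matrix.
#' @param mask Logical analysis mask.
#' @return List with `mean` (NA when no pixel contributes) and `n_pixels`.
#' @export
regional_mean <- function(map, mask) {
  v <- map_values(map)
  if (!all(dim(mask) == dim(v))) stop("mask shape mismatch")
  sel <- mask & !is.na(v)
  n <- sum(sel)
  list(mean = if (n > 0L) mean(v[sel]) else NA_real_, n_pixels = n)
}
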