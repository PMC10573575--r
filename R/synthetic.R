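## Synthetic OCT phantoms with known choroidal ground truth.
##
## The phantom emulates the geometry of a 12 x 12-mm swept-source scan:
## 500 x 500 A-scans at 24 um lateral spacing at full scale, or a desk-scale
## 64 x 64 grid covering the same 12-mm field (lateral spacing grows so the
## fovea-centered circles still fit).  Anatomy along each A-scan, top to
## bottom: vitreous, retina, a thin bright RPE band ending at Bruch's
## membrane (BM), the choroid (bright stroma with dark vessel lumens) down to
## the choroidal-scleral interface (CSI), then sclera.  The forward model
## applies per-tissue two-way extinction, optional extra shadow discs, and
## multiplicative gamma speckle.  Ground truth (surfaces, thickness, vessel
## mask and per-A-scan vessel fraction) is recorded before noise.

TISSUES <- c("vitreous", "retina", "rpe", "stroma", "vessel", "sclera")

#' Phantom parameters
#'
#' Defaults describe the desk-scale study conditions: a 64 x 64 x 256 voxel
#' grid spanning a 12 x 12-mm field with 1.95-um axial sampling, a smoothly
#' varying BM depth and choroidal thickness, and a vessel fraction of 0.6
#' (the choroidal vascularity observed in this disease range).  Vessels are
#' hyporeflective cylinders (stroma 180, vessel 60 on an 8-bit-like scale) so
#' global Otsu thresholding is a realistic segmentation strategy; speckle is
#' multiplicative gamma noise with shape 4.
#'
#' @param grid_nx,grid_ny Number of A-scan columns / B-scan rows.
#' @param grid_nz Number of axial samples.
#' @param lateral_spacing_um Lateral spacing; defaults to `12000 / grid_nx` so
#'   the field of view stays 12 mm at any grid size.
#' @param axial_spacing_um Axial sampling (default 1.95 um).
#' @param bm_depth_um `c(mean, amplitude)` of the BM depth field in um.
#' @param thickness_um `c(mean, amplitude)` of the choroidal thickness field.
#' @param vessel_fraction_target Target global vessel fraction in \[0, 1\];
#'   the generator stops within +/- 0.01 of it.
#' @param vessel_radius_um Range of vessel radii, um.
#' @param levels Named tissue reflectivity levels.
#' @param attenuation_um1 Named per-tissue extinction coefficients (1/um).
#'   The default (`NULL`) ties extinction to reflectivity
#'   (`levels * 2.5e-3 / 180`), the regime assumed by depth-resolved
#'   attenuation compensation; set all to zero for an attenuation-free
#'   phantom.
#' @param speckle Logical; multiply by gamma speckle?
#' @param speckle_shape Gamma shape parameter (mean-1 noise; default 4).
#' @param shadow_artifacts List of `list(center_px = c(x, y), radius_px,
#'   factor, from_um)` extra shadow discs (factor < 1 multiplies the signal
#'   below depth `from_um` inside the disc).
#' @param retina_thickness_um,rpe_thickness_um Inner-layer geometry, um.
#' @param sclera_deep_level,sclera_ramp_um The scleral reflectivity grades
#'   from `levels["sclera"]` at the CSI up to `sclera_deep_level` over
#'   `sclera_ramp_um` (the inner sclera is hyporeflective next to the bright
#'   stroma, then backscatter rises with depth).  This also ensures the
#'   imaged depth captures essentially the whole backscatter tail, which the
#'   tail-normalizing attenuation compensation relies on.
#' @param onh Optional `list(offset_mm = c(x, y), radius_mm)` optic nerve head
#'   disc recorded in the volume metadata (set `NULL` to omit).
#' @param full_scale Logical; use the native 500 x 500 x 1536 grid at 24-um
#'   lateral spacing.
#' @param seed Integer root seed; sub-stages draw from fixed offsets of it.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid_nx = 64, grid_ny = 64, grid_nz = 256,
                           lateral_spacing_um = NULL, axial_spacing_um = 1.95,
                           bm_depth_um = c(mean = 230, amplitude = 15),
                           thickness_um = c(mean = 150, amplitude = 20),
                           vessel_fraction_target = 0.6,
                           vessel_radius_um = c(20, 60),
                           levels = c(vitreous = 10, retina = 120, rpe = 250,
                                      stroma = 180, vessel = 60, sclera = 40),
                           attenuation_um1 = NULL,
                           speckle = TRUE, speckle_shape = 4,
                           shadow_artifacts = list(),
                           retina_thickness_um = 120, rpe_thickness_um = 12,
                           sclera_deep_level = 400, sclera_ramp_um = 120,
                           onh = list(offset_mm = c(x = 4, y = 0),
                                      radius_mm = 0.75),
                           full_scale = FALSE, seed = 1L) {
  if (isTRUE(full_scale)) {
    grid_nx <- 500L; grid_ny <- 500L; grid_nz <- 1536L
    if (is.null(lateral_spacing_um)) lateral_spacing_um <- 24
  }
  if (is.null(lateral_spacing_um)) lateral_spacing_um <- 12000 / grid_nx
  ## Default optics follow the depth-resolved attenuation model underlying
  ## the compensation: backscattered intensity (signal squared) proportional
  ## to the local extinction coefficient, anchored at 2.5e-3 /um for the
  ## choroidal stroma.  Under this law the exponent-2 compensation yields a
  ## depth-flat corrected signal proportional to extinction.
  if (is.null(attenuation_um1))
    attenuation_um1 <- (levels / 180)^2 * 2.5e-3
  p <- list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
            grid_nz = as.integer(grid_nz),
            lateral_spacing_um = lateral_spacing_um,
            axial_spacing_um = axial_spacing_um,
            bm_depth_um = bm_depth_um, thickness_um = thickness_um,
            vessel_fraction_target = vessel_fraction_target,
            vessel_radius_um = vessel_radius_um,
            levels = levels, attenuation_um1 = attenuation_um1,
            speckle = isTRUE(speckle), speckle_shape = speckle_shape,
            shadow_artifacts = shadow_artifacts,
            retina_thickness_um = retina_thickness_um,
            rpe_thickness_um = rpe_thickness_um,
            sclera_deep_level = sclera_deep_level,
            sclera_ramp_um = sclera_ramp_um,
            onh = onh, seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  if (p$vessel_fraction_target < 0 || p$vessel_fraction_target > 1)
    stop("vessel_fraction_target must be in [0, 1]")
  if (p$lateral_spacing_um <= 0 || p$axial_spacing_um <= 0)
    stop("spacings must be > 0")
  if (!all(TISSUES %in% names(p$levels)) ||
      !all(TISSUES %in% names(p$attenuation_um1)))
    stop("levels and attenuation_um1 must name all tissues: ",
         paste(TISSUES, collapse = ", "))
  if (any(p$attenuation_um1 < 0)) stop("attenuation coefficients must be >= 0")
  if (p$speckle_shape <= 0) stop("speckle_shape must be > 0")
  depth_um <- p$grid_nz * p$axial_spacing_um
  max_bottom <- sum(p$bm_depth_um) + sum(p$thickness_um)
  if (max_bottom >= depth_um)
    stop(sprintf("BM depth + thickness (%.0f um) exceeds the axial extent (%.0f um)",
                 max_bottom, depth_um))
  top_um <- p$bm_depth_um[["mean"]] - p$bm_depth_um[["amplitude"]] -
    p$retina_thickness_um - p$rpe_thickness_um
  if (top_um <= 0) stop("retina + RPE do not fit above the shallowest BM")
  invisible(p)
}

## ---- smooth random fields ----------------------------------------------
## Band-limited field: white noise on a coarse control grid, bilinearly
## interpolated, normalized so the realized |deviation| peaks at `amplitude`.
## Returned as a closure over continuous (x, y) pixel coordinates so the
## longitudinal generator can evaluate the same anatomy under a rigid
## transform without resampling error.

smooth_field_2d <- function(nx, ny, mean, amplitude, seed, n_coarse = 5) {
  set.seed(seed)
  ncx <- n_coarse + 2L; ncy <- n_coarse + 2L
  coef <- matrix(stats::rnorm(ncx * ncy), ncy, ncx)
  eval_raw <- function(x, y) {
    cx <- 1 + (pmin(pmax(x, 1), nx) - 1) / max(nx - 1, 1) * (ncx - 1)
    cy <- 1 + (pmin(pmax(y, 1), ny) - 1) / max(ny - 1, 1) * (ncy - 1)
    interp2_clamped(coef, cx, cy)
  }
  gx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  gy <- matrix(rep(seq_len(ny), nx), ny, nx)
  base_vals <- eval_raw(gx, gy)
  scale <- max(abs(base_vals))
  if (scale == 0) scale <- 1
  function(x, y) mean + amplitude * eval_raw(x, y) / scale
}

## Bilinear interpolation on a matrix [row = y, col = x], coords clamped.
interp2_clamped <- function(m, x, y) {
  dims <- dim(x)
  nyc <- nrow(m); nxc <- ncol(m)
  x <- pmin(pmax(as.vector(x), 1), nxc)
  y <- pmin(pmax(as.vector(y), 1), nyc)
  x0 <- pmin(floor(x), nxc - 1L); y0 <- pmin(floor(y), nyc - 1L)
  fx <- x - x0; fy <- y - y0
  v00 <- m[cbind(y0, x0)];      v01 <- m[cbind(y0, x0 + 1L)]
  v10 <- m[cbind(y0 + 1L, x0)]; v11 <- m[cbind(y0 + 1L, x0 + 1L)]
  out <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  dim(out) <- dims
  out
}

grid_coords <- function(nx, ny) {
  list(x = matrix(rep(seq_len(nx), each = ny), ny, nx),
       y = matrix(rep(seq_len(ny), nx), ny, nx))
}

## ---- vessels ------------------------------------------------------------
## Vessels are cylinders with axes in the en face plane, described by a
## lateral center, direction angle, length, radius, and a depth expressed as
## a fraction of the local choroidal slab (so they follow the anatomy).

cylinder_voxels <- function(cyl, bm_vox, csi_vox, zt, zb, p) {
  ny <- p$grid_ny; nx <- p$grid_nx; nz <- p$grid_nz
  g <- grid_coords(nx, ny)
  ux <- cos(cyl$phi); uy <- sin(cyl$phi)
  rx <- g$x - cyl$x0; ry <- g$y - cyl$y0
  along <- (rx * ux + ry * uy) * p$lateral_spacing_um
  perp <- abs(rx * uy - ry * ux) * p$lateral_spacing_um
  half_len <- cyl$len_px * p$lateral_spacing_um / 2
  cols <- which(perp <= cyl$r_um & abs(along) <= half_len)
  if (!length(cols)) return(integer(0))
  half_ax <- sqrt(pmax(cyl$r_um^2 - perp[cols]^2, 0)) / p$axial_spacing_um
  zc <- bm_vox[cols] + cyl$f * (csi_vox[cols] - bm_vox[cols])
  zlo <- pmax(ceiling(zc - half_ax), zt[cols])
  zhi <- pmin(floor(zc + half_ax), zb[cols] - 1L)
  keep <- which(zhi >= zlo)
  if (!length(keep)) return(integer(0))
  plane <- ny * nx
  idx_list <- lapply(keep, function(i) {
    cols[i] + plane * (seq.int(zlo[i], zhi[i]) - 1L)
  })
  unlist(idx_list, use.names = FALSE)
}

## Cylinder centers are sampled from a margin-extended window so the line
## coverage (and hence the vessel fraction) is statistically homogeneous
## across the whole field, including the grid edges.
sample_cylinder <- function(p, r_um = NULL) {
  ext <- p$grid_nx / 2
  list(x0 = stats::runif(1, 1 - ext, p$grid_nx + ext),
       y0 = stats::runif(1, 1 - ext, p$grid_ny + ext),
       phi = stats::runif(1, 0, pi),
       f = stats::runif(1, 0.12, 0.88),
       r_um = if (is.null(r_um))
         stats::runif(1, p$vessel_radius_um[1], p$vessel_radius_um[2]) else r_um,
       len_px = stats::runif(1, p$grid_nx / 3, p$grid_nx))
}

## Fill the slab with cylinders until the global vessel fraction is within
## `band` of `target`.  Placement is biased against heavy overlap (a new
## cylinder must contribute at least 25% fresh voxels) until rejections force
## the bias off.  Returns the mask, the cylinder list and the achieved
## fraction; errors if the target is unreachable.
place_vessels <- function(p, bm_vox, csi_vox, zt, zb, target, seed,
                          band = 0.01, cylinders = list(),
                          mask = NULL, max_attempts = 20000L) {
  set.seed(seed)
  ny <- p$grid_ny; nx <- p$grid_nx; nz <- p$grid_nz
  if (is.null(mask)) mask <- array(FALSE, dim = c(ny, nx, nz))
  slab_total <- sum(pmax(zb - zt, 0L))
  n_ves <- sum(mask)
  if (target <= 0) {
    return(list(mask = mask, cylinders = cylinders,
                fraction = if (slab_total > 0) n_ves / slab_total else 0))
  }
  if (slab_total == 0L) stop("empty choroidal slab: no vessels can be placed")
  attempts <- 0L; rejects <- 0L
  while (n_ves / slab_total < target - band) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(
        "vessel fraction target %.3f unreachable; achieved %.3f after %d attempts",
        target, n_ves / slab_total, max_attempts))
    gap <- target - n_ves / slab_total
    r <- if (gap < 0.02) p$vessel_radius_um[1] else NULL
    cyl <- sample_cylinder(p, r_um = r)
    if (gap < 0.005) cyl$len_px <- cyl$len_px / 3
    vox <- cylinder_voxels(cyl, bm_vox, csi_vox, zt, zb, p)
    if (!length(vox)) next
    new <- vox[!mask[vox]]
    if (length(new) / length(vox) < 0.25 && rejects < 500L) {
      rejects <- rejects + 1L
      next
    }
    if ((n_ves + length(new)) / slab_total > target + band) next
    mask[new] <- TRUE
    n_ves <- n_ves + length(new)
    cylinders[[length(cylinders) + 1L]] <- cyl
  }
  list(mask = mask, cylinders = cylinders, fraction = n_ves / slab_total)
}

## ---- rendering ----------------------------------------------------------

render_phantom_volume <- function(p, bm_vox, csi_vox, zt, zb, vessel_mask,
                                  speckle_seed) {
  ny <- p$grid_ny; nx <- p$grid_nx; nz <- p$grid_nz
  ax <- p$axial_spacing_um
  v_end <- round_half_up(bm_vox - (p$retina_thickness_um + p$rpe_thickness_um) / ax)
  rpe_top <- round_half_up(bm_vox - p$rpe_thickness_um / ax)
  lv <- p$levels; mu_t <- p$attenuation_um1
  intensity <- array(0, dim = c(ny, nx, nz))
  trans <- matrix(1, ny, nx)
  for (z in seq_len(nz)) {
    lab_level <- matrix(lv[["vitreous"]], ny, nx)
    lab_mu <- matrix(mu_t[["vitreous"]], ny, nx)
    in_ret <- z >= v_end & z < rpe_top
    in_rpe <- z >= rpe_top & z < zt
    in_cho <- z >= zt & z < zb
    in_scl <- z >= zb
    lab_level[in_ret] <- lv[["retina"]];  lab_mu[in_ret] <- mu_t[["retina"]]
    lab_level[in_rpe] <- lv[["rpe"]];     lab_mu[in_rpe] <- mu_t[["rpe"]]
    lab_level[in_cho] <- lv[["stroma"]];  lab_mu[in_cho] <- mu_t[["stroma"]]
    if (any(in_scl)) {
      ## graded sclera: reflectivity rises with depth below the CSI, the
      ## extinction scaling with it as in the rest of the model
      depth_below <- (z - zb[in_scl]) * ax
      lvl <- pmin(lv[["sclera"]] +
                    (p$sclera_deep_level - lv[["sclera"]]) *
                    depth_below / p$sclera_ramp_um,
                  p$sclera_deep_level)
      lab_level[in_scl] <- lvl
      lab_mu[in_scl] <- mu_t[["sclera"]] * (lvl / lv[["sclera"]])^2
    }
    ves <- vessel_mask[, , z]
    lab_level[ves] <- lv[["vessel"]]; lab_mu[ves] <- mu_t[["vessel"]]
    intensity[, , z] <- lab_level * trans
    trans <- trans * exp(-2 * lab_mu * ax)
  }
  if (length(p$shadow_artifacts)) {
    g <- grid_coords(nx, ny)
    for (s in p$shadow_artifacts) {
      disc <- (g$x - s$center_px[1])^2 + (g$y - s$center_px[2])^2 <=
        s$radius_px^2
      zfrom <- max(1L, round_half_up(1 + s$from_um / ax))
      for (z in zfrom:nz) {
        slice <- intensity[, , z]
        slice[disc] <- slice[disc] * s$factor
        intensity[, , z] <- slice
      }
    }
  }
  if (p$speckle) {
    set.seed(speckle_seed)
    intensity <- intensity *
      array(stats::rgamma(length(intensity), shape = p$speckle_shape,
                          rate = p$speckle_shape), dim = dim(intensity))
  }
  intensity
}

phantom_onh_mask <- function(p, fovea_xy) {
  if (is.null(p$onh)) return(NULL)
  g <- grid_coords(p$grid_nx, p$grid_ny)
  cx <- fovea_xy[1] + p$onh$offset_mm[1] * 1000 / p$lateral_spacing_um
  cy <- fovea_xy[2] + p$onh$offset_mm[2] * 1000 / p$lateral_spacing_um
  r_px <- p$onh$radius_mm * 1000 / p$lateral_spacing_um
  (g$x - cx)^2 + (g$y - cy)^2 <= r_px^2
}

#' Generate a synthetic OCT phantom with ground truth
#'
#' Draws smooth BM-depth and thickness fields, fills the choroidal slab with
#' hyporeflective vessel cylinders until the global vessel fraction is within
#' 0.01 of `vessel_fraction_target`, renders tissue reflectivities under
#' forward per-tissue attenuation (plus any configured shadow discs), and
#' finally multiplies by gamma speckle.  Truth is recorded before noise.
#'
#' @param params A [phantom_params] object.
#' @param visit_label,patient_id,eye_id Metadata for the emitted volume.
#' @return A list with elements `volume` (an [oct_volume]) and `truth`, a
#'   `phantom_truth` list carrying `true_thickness_map` (um),
#'   `true_vessel_mask` (3-D logical), `true_vessel_fraction_map`, `true_bm`,
#'   `true_csi` (fractional 1-based voxel depths), the achieved global vessel
#'   `fraction`, the cylinder list, and `applied_transform`.
#' @export
generate_phantom <- function(params = phantom_params(),
                             visit_label = "exudation",
                             patient_id = "PHANTOM", eye_id = "PH_OD") {
  p <- params
  bm_fn <- smooth_field_2d(p$grid_nx, p$grid_ny, p$bm_depth_um[["mean"]],
                           p$bm_depth_um[["amplitude"]], seed = p$seed + 11L)
  th_fn <- smooth_field_2d(p$grid_nx, p$grid_ny, p$thickness_um[["mean"]],
                           p$thickness_um[["amplitude"]], seed = p$seed + 12L)
  build_phantom_visit(p, bm_fn, th_fn,
                      delta_thickness_um = 0, fraction_target = p$vessel_fraction_target,
                      transform = c(dx_px = 0, dy_px = 0, dtheta_deg = 0),
                      vessel_seed = p$seed + 13L, speckle_seed = p$seed + 17L,
                      visit_label = visit_label, patient_id = patient_id,
                      eye_id = eye_id)
}

## Shared renderer for baseline and longitudinal visits.  `transform` moves
## the anatomy (fields and vessels) in the en face plane; fields are evaluated
## at rigidly back-transformed coordinates so no resampling error enters the
## ground truth.
build_phantom_visit <- function(p, bm_fn, th_fn, delta_thickness_um,
                                fraction_target, transform, vessel_seed,
                                speckle_seed, visit_label, patient_id, eye_id,
                                base_cylinders = NULL) {
  ny <- p$grid_ny; nx <- p$grid_nx; ax <- p$axial_spacing_um
  g <- grid_coords(nx, ny)
  center <- c((nx + 1) / 2, (ny + 1) / 2)
  inv <- invert_transform(rigid_transform_2d(transform[1], transform[2],
                                             transform[3]))
  src <- apply_rigid_xy(g$x, g$y, inv, center)
  bm_um <- bm_fn(src$x, src$y)
  th_um <- pmax(th_fn(src$x, src$y) + delta_thickness_um, 0)
  bm_vox <- 1 + bm_um / ax
  csi_vox <- 1 + (bm_um + th_um) / ax
  zt <- round_half_up(bm_vox); zb <- round_half_up(csi_vox)
  if (any(zb > p$grid_nz))
    stop("thickness field exceeds the axial grid")
  if (is.null(base_cylinders)) {
    ves <- place_vessels(p, bm_vox, csi_vox, zt, zb,
                         target = fraction_target, seed = vessel_seed)
  } else {
    cyls <- lapply(base_cylinders, transform_cylinder,
                   transform = transform, center = center)
    mask <- array(FALSE, dim = c(ny, nx, p$grid_nz))
    for (cyl in cyls) {
      vox <- cylinder_voxels(cyl, bm_vox, csi_vox, zt, zb, p)
      mask[vox] <- TRUE
    }
    ves <- adjust_vessel_fraction(p, bm_vox, csi_vox, zt, zb, mask, cyls,
                                  target = fraction_target, seed = vessel_seed)
  }
  slab_cnt <- pmax(zb - zt, 0L)
  ves_cnt <- matrix(0L, ny, nx)
  for (z in seq_len(p$grid_nz)) ves_cnt <- ves_cnt + ves$mask[, , z]
  frac_map <- ifelse(slab_cnt > 0L, ves_cnt / slab_cnt, NA_real_)
  intensity <- render_phantom_volume(p, bm_vox, csi_vox, zt, zb, ves$mask,
                                     speckle_seed)
  fovea <- apply_rigid_xy(center[1], center[2],
                          rigid_transform_2d(transform[1], transform[2],
                                             transform[3]), center)
  fovea_xy <- c(fovea$x, fovea$y)
  if (fovea_xy[1] < 1 || fovea_xy[1] > nx || fovea_xy[2] < 1 || fovea_xy[2] > ny)
    stop("visit transform moves the fovea off the scan grid")
  volume <- oct_volume(intensity, axial_spacing_um = ax,
                       lateral_spacing_um = p$lateral_spacing_um,
                       fovea_center = fovea_xy,
                       onh_mask = phantom_onh_mask(p, fovea_xy),
                       signal_strength = 10L, visit_label = visit_label,
                       patient_id = patient_id, eye_id = eye_id)
  truth <- structure(list(
    true_thickness_map = th_um,
    true_bm = bm_vox, true_csi = csi_vox,
    true_vessel_mask = ves$mask,
    true_vessel_fraction_map = frac_map,
    fraction = ves$fraction,
    cylinders = ves$cylinders,
    applied_transform = c(dx_px = unname(transform[1]),
                          dy_px = unname(transform[2]),
                          dtheta_deg = unname(transform[3]))
  ), class = "phantom_truth")
  list(volume = volume, truth = truth)
}

transform_cylinder <- function(cyl, transform, center) {
  tf <- rigid_transform_2d(transform[1], transform[2], transform[3])
  q <- apply_rigid_xy(cyl$x0, cyl$y0, tf, center)
  cyl$x0 <- q$x; cyl$y0 <- q$y
  cyl$phi <- cyl$phi + transform[3] * pi / 180
  cyl
}

## Nudge an inherited vessel mask to a new fraction target: drop the most
## recently placed cylinders while above target, then top up with small
## cylinders.  Granularity of the top-up stage is ~0.001 of the slab.
adjust_vessel_fraction <- function(p, bm_vox, csi_vox, zt, zb, mask, cylinders,
                                   target, seed, band = 0.002) {
  slab_total <- sum(pmax(zb - zt, 0L))
  frac <- sum(mask) / slab_total
  while (frac > target + band && length(cylinders)) {
    cylinders <- cylinders[-length(cylinders)]
    mask[] <- FALSE
    for (cyl in cylinders) {
      vox <- cylinder_voxels(cyl, bm_vox, csi_vox, zt, zb, p)
      mask[vox] <- TRUE
    }
    frac <- sum(mask) / slab_total
  }
  if (frac < target - band) {
    p_small <- p
    p_small$vessel_radius_um <- c(p$vessel_radius_um[1] / 2,
                                  p$vessel_radius_um[1])
    res <- place_vessels(p_small, bm_vox, csi_vox, zt, zb, target = target,
                         seed = seed, band = band, cylinders = cylinders,
                         mask = mask)
    return(res)
  }
  list(mask = mask, cylinders = cylinders, fraction = frac)
}

#' Generate a longitudinal series of phantoms
#'
#' Visits share one baseline anatomy; each visit adds a programmed uniform
#' thickness change and a vessel-fraction change, then moves the whole
#' anatomy by a rigid en face transform (as eye/scan placement differs
#' between acquisitions).  Defaults program the three-visit course observed
#' in exudative AMD: thickness +12.7 um from pretreatment to the day of
#' exudation, then -19.5 um after treatment; CVI +0.014 then -0.017.
#'
#' @param params A [phantom_params].
#' @param delta_thickness_um Per-visit additive thickness change relative to
#'   the baseline field (first element is the baseline visit).
#' @param delta_vessel_fraction Per-visit additive vessel-fraction change.
#' @param transforms List of per-visit rigid transforms `c(dx_px, dy_px,
#'   dtheta_deg)` applied to the anatomy.
#' @param visit_labels Visit labels; defaults to the three study visits.
#' @param patient_id,eye_id Metadata.
#' @return A named list (one element per visit) of `list(volume, truth)`.
#' @export
generate_longitudinal_phantoms <- function(params = phantom_params(),
    delta_thickness_um = c(0, 12.7, 12.7 - 19.5),
    delta_vessel_fraction = c(0, 0.014, 0.014 - 0.017),
    transforms = list(c(2, -1, 0.5), c(0, 0, 0), c(-2, 2, -0.5)),
    visit_labels = NULL, patient_id = "PHANTOM", eye_id = "PH_OD") {
  p <- params
  n_visit <- length(delta_thickness_um)
  if (n_visit < 2L) stop("a longitudinal series needs at least 2 visits")
  if (length(delta_vessel_fraction) != n_visit ||
      length(transforms) != n_visit)
    stop("deltas and transforms must have one entry per visit")
  if (is.null(visit_labels)) {
    visit_labels <- if (n_visit == 3L) VISIT_LABELS else
      paste0("visit", seq_len(n_visit))
  }
  bm_fn <- smooth_field_2d(p$grid_nx, p$grid_ny, p$bm_depth_um[["mean"]],
                           p$bm_depth_um[["amplitude"]], seed = p$seed + 11L)
  th_fn <- smooth_field_2d(p$grid_nx, p$grid_ny, p$thickness_um[["mean"]],
                           p$thickness_um[["amplitude"]], seed = p$seed + 12L)
  ## Canonical (untransformed, zero-delta) anatomy owns the vessel layout;
  ## every visit re-renders it under its own delta + rigid transform.
  g <- grid_coords(p$grid_nx, p$grid_ny)
  bm_um0 <- bm_fn(g$x, g$y); th_um0 <- th_fn(g$x, g$y)
  bm_vox0 <- 1 + bm_um0 / p$axial_spacing_um
  csi_vox0 <- 1 + (bm_um0 + th_um0) / p$axial_spacing_um
  zt0 <- round_half_up(bm_vox0); zb0 <- round_half_up(csi_vox0)
  canon <- place_vessels(p, bm_vox0, csi_vox0, zt0, zb0,
                         target = p$vessel_fraction_target,
                         seed = p$seed + 13L)
  out <- vector("list", n_visit)
  for (k in seq_len(n_visit)) {
    out[[k]] <- build_phantom_visit(p, bm_fn, th_fn,
      delta_thickness_um = delta_thickness_um[k],
      fraction_target = canon$fraction + delta_vessel_fraction[k],
      transform = unlist(transforms[[k]]),
      vessel_seed = p$seed + 13L + 100L * k,
      speckle_seed = p$seed + 17L + 1000L * k,
      visit_label = if (visit_labels[k] %in% VISIT_LABELS)
        visit_labels[k] else "exudation",
      patient_id = patient_id, eye_id = eye_id,
      base_cylinders = canon$cylinders)
  }
  names(out) <- visit_labels
  out
}
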