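## Rigid en face registration of longitudinal visits.
##
## Visits of the same eye are aligned on structured en face projections
## (retinal-vessel projections on real data; any structured projection works).
## The model is rigid: rotation about the image center followed by a
## translation.  Translation is estimated by phase correlation with local
## DFT upsampling for subpixel precision; rotation by exhaustive search on a
## fine grid, scored by normalized cross-correlation after warping.

#' Rigid 2-D transform
#'
#' Maps a point `p` (x, y in pixel coordinates) of the moving image into the
#' fixed frame as `q = R(theta) (p - c) + c + t` where `c` is the image
#' center, `t = (dx_px, dy_px)`.  [warp_enface()] resamples the moving image
#' accordingly.
#'
#' @param dx_px,dy_px Translation in pixels.
#' @param dtheta_deg Rotation in degrees (counter-clockwise in x-right,
#'   y-down pixel coordinates).
#' @param fixed_id,moving_id Optional visit identifiers.
#' @param score Optional registration score (normalized cross-correlation).
#' @return An object of class `rigid_transform_2d`.
#' @export
rigid_transform_2d <- function(dx_px, dy_px, dtheta_deg,
                               fixed_id = NA_character_,
                               moving_id = NA_character_, score = NA_real_) {
  structure(list(dx_px = as.numeric(dx_px), dy_px = as.numeric(dy_px),
                 dtheta_deg = as.numeric(dtheta_deg),
                 fixed_id = fixed_id, moving_id = moving_id,
                 score = score),
            class = "rigid_transform_2d")
}

#' @export
print.rigid_transform_2d <- function(x, ...) {
  cat(sprintf("<rigid_transform_2d> dx %.3f px, dy %.3f px, dtheta %.3f deg",
              x$dx_px, x$dy_px, x$dtheta_deg))
  if (!is.na(x$score)) cat(sprintf(" (score %.4f)", x$score))
  cat("\n")
  invisible(x)
}

## Apply the forward transform to coordinates (vectorized).
apply_rigid_xy <- function(x, y, tf, center) {
  th <- tf$dtheta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  rx <- x - center[1]; ry <- y - center[2]
  list(x = ct * rx - st * ry + center[1] + tf$dx_px,
       y = st * rx + ct * ry + center[2] + tf$dy_px)
}

#' Invert a rigid transform
#' @param tf A [rigid_transform_2d].
#' @return The inverse [rigid_transform_2d].
#' @export
invert_transform <- function(tf) {
  th <- -tf$dtheta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  rigid_transform_2d(-(ct * tf$dx_px - st * tf$dy_px),
                     -(st * tf$dx_px + ct * tf$dy_px),
                     -tf$dtheta_deg,
                     fixed_id = tf$moving_id, moving_id = tf$fixed_id)
}

## Bilinear sampling of a matrix at fractional (x, y); NA outside.
bilinear_sample <- function(img, xq, yq) {
  ny <- nrow(img); nx <- ncol(img)
  out <- rep(NA_real_, length(xq))
  ok <- xq >= 1 & xq <= nx & yq >= 1 & yq <= ny & !is.na(xq) & !is.na(yq)
  if (any(ok)) {
    x <- xq[ok]; y <- yq[ok]
    x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
    fx <- x - x0; fy <- y - y0
    v <- img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
      img[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
      img[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
      img[cbind(y0 + 1L, x0 + 1L)] * fx * fy
    out[ok] <- v
  }
  out
}

## Nearest-neighbour sampling; `fill` outside.
nearest_sample <- function(img, xq, yq, fill) {
  ny <- nrow(img); nx <- ncol(img)
  xr <- round_half_up(xq); yr <- round_half_up(yq)
  ok <- xr >= 1 & xr <= nx & yr >= 1 & yr <= ny
  out <- rep(fill, length(xq))
  out[ok] <- img[cbind(yr[ok], xr[ok])]
  out
}

#' Warp an en face map or mask with a rigid transform
#'
#' Resamples the moving image into the fixed frame: output pixel `q` takes
#' the value of the moving image at `T^{-1}(q)`.  Scalar maps use bilinear
#' interpolation with `NA` outside (and wherever a neighbour is missing);
#' logical masks use nearest-neighbour with `FALSE` outside, so a warp can
#' never invent `TRUE` pixels.
#'
#' @param x An [enface_map], numeric matrix, or logical matrix.
#' @param transform A [rigid_transform_2d] mapping moving into fixed.
#' @param interpolation `"auto"` (linear for numeric, nearest for logical),
#'   `"linear"` or `"nearest"`.
#' @return Same type as `x`.
#' @export
warp_enface <- function(x, transform,
                        interpolation = c("auto", "linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_map <- inherits(x, "enface_map")
  img <- map_values(x)
  is_mask <- is.logical(img)
  if (interpolation == "auto")
    interpolation <- if (is_mask) "nearest" else "linear"
  ny <- nrow(img); nx <- ncol(img)
  center <- c((nx + 1) / 2, (ny + 1) / 2)
  g <- grid_coords(nx, ny)
  inv <- invert_transform(transform)
  src <- apply_rigid_xy(g$x, g$y, inv, center)
  if (interpolation == "nearest") {
    fill <- if (is_mask) FALSE else NA
    vals <- nearest_sample(img, src$x, src$y, fill = fill)
  } else {
    vals <- bilinear_sample(img + 0, src$x, src$y)
    if (is_mask) vals <- !is.na(vals) & vals >= 0.5
  }
  out <- matrix(vals, ny, nx)
  if (is_mask && interpolation == "nearest") storage.mode(out) <- "logical"
  if (is_map) enface_map(out, units = x$units) else out
}

## Pure rotation about the image center with a constant fill value
## (used while scanning candidate rotations).
rotate_image <- function(img, theta_deg, fill = mean(img)) {
  out <- warp_enface(img, rigid_transform_2d(0, 0, theta_deg),
                     interpolation = "linear")
  out[is.na(out)] <- fill
  out
}

## Phase correlation between two equally shaped matrices.  Returns the
## translation (dx, dy) such that shifting `moving` by it aligns it with
## `fixed`, refined on a local DFT-upsampled grid.
phase_correlate <- function(fixed, moving, upsample = 10) {
  ny <- nrow(fixed); nx <- ncol(fixed)
  Ff <- stats::fft(fixed - mean(fixed))
  Fm <- stats::fft(moving - mean(moving))
  R <- Ff * Conj(Fm)
  R <- R / (Mod(R) + .Machine$double.eps)
  r <- Re(stats::fft(R, inverse = TRUE)) / (nx * ny)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  sy <- pk[1] - 1L; sx <- pk[2] - 1L
  if (sy > ny / 2) sy <- sy - ny
  if (sx > nx / 2) sx <- sx - nx
  if (upsample > 1) {
    ky <- c(0:(floor(ny / 2) - 1L), -(ceiling(ny / 2)):-1L)
    kx <- c(0:(floor(nx / 2) - 1L), -(ceiling(nx / 2)):-1L)
    uy <- sy + seq(-1, 1, by = 1 / upsample)
    ux <- sx + seq(-1, 1, by = 1 / upsample)
    Ey <- exp(2i * pi * outer(uy, ky) / ny)
    Ex <- exp(2i * pi * outer(ux, kx) / nx)
    rr <- Re(Ey %*% R %*% t(Ex))
    pk2 <- which(rr == max(rr), arr.ind = TRUE)[1, ]
    sy <- uy[pk2[1]]; sx <- ux[pk2[2]]
  }
  c(dx = sx, dy = sy)
}

ncc_overlap <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 16 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    return(-Inf)
  stats::cor(a[ok], b[ok])
}

#' Register a moving en face image to a fixed one (rigid)
#'
#' Scans candidate rotations on a grid (default +/- 5 degrees in 0.25-degree
#' steps); for each, estimates the translation by phase correlation with
#' subpixel DFT upsampling, and returns the candidate whose warp maximizes
#' the normalized cross-correlation with the fixed image.
#'
#' @param moving,fixed [enface_map]s or matrices of identical shape.
#' @param rotation_bound_deg Half-width of the rotation search (default 5).
#' @param rotation_step_deg Rotation grid step (default 0.25).
#' @param upsample Subpixel upsampling factor for the translation (default
#'   10, i.e. 0.1-px resolution).
#' @return A [rigid_transform_2d] such that `warp_enface(moving, transform)`
#'   aligns with `fixed`; its `score` field holds the winning correlation.
#' @export
register_enface <- function(moving, fixed, rotation_bound_deg = 5,
                            rotation_step_deg = 0.25, upsample = 10) {
  mv <- map_values(moving); fx <- map_values(fixed)
  if (!all(dim(mv) == dim(fx))) stop("moving and fixed must share a grid")
  mv_f <- mv; mv_f[is.na(mv_f)] <- mean(mv, na.rm = TRUE)
  fx_f <- fx; fx_f[is.na(fx_f)] <- mean(fx, na.rm = TRUE)
  if (stats::sd(mv_f) == 0 || stats::sd(fx_f) == 0)
    stop("cannot register a flat (zero-variance) image")
  thetas <- if (rotation_bound_deg > 0)
    seq(-rotation_bound_deg, rotation_bound_deg, by = rotation_step_deg)
  else 0
  best <- NULL; best_score <- -Inf
  for (th in thetas) {
    rot <- rotate_image(mv_f, th)
    sh <- phase_correlate(fx_f, rot, upsample = upsample)
    cand <- rigid_transform_2d(sh["dx"], sh["dy"], th)
    warped <- warp_enface(mv_f, cand, interpolation = "linear")
    sc <- ncc_overlap(warped, fx_f)
    if (sc > best_score) {
      best_score <- sc
      best <- cand
    }
  }
  best$score <- best_score
  best
}

#' Serialize / load a rigid transform as JSON
#' @param tf A [rigid_transform_2d].
#' @param path JSON path.
#' @return `write_transform`: invisibly `path`; `read_transform`: the
#'   transform.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(unclass(tf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform_2d(x$dx_px, x$dy_px, x$dtheta_deg,
                     fixed_id = x$fixed_id %||% NA_character_,
                     moving_id = x$moving_id %||% NA_character_,
                     score = x$score %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
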