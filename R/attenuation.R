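#' Depth-resolved attenuation compensation
#'
#' Compensates depth attenuation and shadowing in an OCT volume with the
#' contrast-enhanced, depth-resolved formulation: for every A-scan,
#'
#' \deqn{A_c(z) = \frac{I(z)^n}{2\sum_{z' \ge z} I(z')^n + \epsilon}}
#'
#' where the tail sum runs from the voxel itself to the bottom of the A-scan.
#' Dividing by the remaining tail energy removes the cumulative extinction a
#' beam suffered above `z`, which suppresses shadows cast by overlying
#' structures and sharpens the choroidal-scleral interface.  The contrast
#' exponent `n` (default 2) controls how strongly bright voxels dominate the
#' tail; `epsilon` keeps the output finite where the tail vanishes.
#'
#' @param x An [oct_volume], a 3-D array `[y, x, z]`, or a numeric vector
#'   (treated as a single A-scan).
#' @param exponent_n Positive contrast exponent (default 2).
#' @param epsilon Positive stabilizer.  Default `1e-8 * max(x)^n`, which makes
#'   the result invariant to a global rescaling of the input.
#' @param rescale `"none"` (default) or `"max"` to rescale the output to
#'   \[0, 1\] by its per-volume maximum.
#' @return The corrected object, same type as the input.  Corrected values are
#'   dimensionless.
#' @export
compensate_attenuation <- function(x, exponent_n = 2, epsilon = NULL,
                                   rescale = c("none", "max")) {
  rescale <- match.arg(rescale)
  if (!is.numeric(exponent_n) || exponent_n <= 0) stop("exponent_n must be > 0")
  is_vol <- inherits(x, "oct_volume")
  arr <- if (is_vol) x$intensity else x
  was_vector <- is.null(dim(arr))
  if (was_vector) arr <- array(arr, dim = c(1, 1, length(arr)))
  if (anyNA(arr)) stop("input intensities contain missing values")
  if (any(arr < 0)) stop("input intensities must be nonnegative")
  d <- dim(arr)
  a <- arr^exponent_n
  mx <- max(arr)
  if (is.null(epsilon)) {
    epsilon <- if (mx > 0) 1e-8 * mx^exponent_n else 1e-8
  }
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  tail_sum <- a
  if (d[3] >= 2L) {
    for (z in seq(d[3] - 1L, 1L)) {
      tail_sum[, , z] <- tail_sum[, , z] + tail_sum[, , z + 1L]
    }
  }
  out <- a / (2 * tail_sum + epsilon)
  if (rescale == "max") {
    m <- max(out)
    if (m > 0) out <- out / m
  }
  if (was_vector) out <- as.vector(out)
  if (is_vol) {
    x$intensity <- out
    x
  } else {
    out
  }
}
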