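#' @keywords internal
"_PACKAGE"

## Recognised visit labels, in chronological order.
VISIT_LABELS <- c("pretreatment", "exudation", "post_treatment")

## Round-half-up used everywhere a fractional surface depth is converted to a
## voxel index, so that thickness/CVI pixel counting is reproducible.
round_half_up <- function(x) floor(x + 0.5)

#' OCT intensity volume
#'
#' Container for a 3-D OCT intensity volume plus the acquisition metadata the
#' quantification pipeline needs.  The array is indexed `[y, x, z]`: `y` is the
#' B-scan (row) position, `x` the A-scan (column) position within a B-scan and
#' `z` the axial sample, with `z = 1` on the vitreous side and `z` increasing
#' toward the sclera.  Physical position along an axis is
#' `(index - 1) * spacing`.
#'
#' @param intensity Nonnegative numeric 3-D array `[y, x, z]`.
#' @param axial_spacing_um Axial sampling interval in micrometers.
#' @param lateral_spacing_um Distance between adjacent A-scans in micrometers.
#'   The default 24 corresponds to a 12 x 12-mm field sampled at 500 x 500
#'   A-scan positions.
#' @param fovea_center Fovea position as `c(x, y)` in (possibly fractional)
#'   pixel coordinates; defaults to the grid center.
#' @param onh_mask Optional logical matrix `[y, x]` marking the optic nerve
#'   head.
#' @param laterality `"OD"` or `"OS"`.
#' @param signal_strength Device quality score, integer 0-10.
#' @param visit_label One of `"pretreatment"`, `"exudation"`,
#'   `"post_treatment"`.
#' @param mnv_type Macular neovascularization type (1, 2, 3) or `NA` when
#'   unknown.  This is an input label; the package does not grade MNV.
#' @param patient_id,eye_id Identifiers used for clustering in the statistics.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, axial_spacing_um, lateral_spacing_um = 24,
                       fovea_center = NULL, onh_mask = NULL,
                       laterality = "OD", signal_strength = 10L,
                       visit_label = "exudation", mnv_type = NA_integer_,
                       patient_id = "P01", eye_id = "E01") {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("intensity must be a 3-D array [y, x, z]")
  if (anyNA(intensity) || any(intensity < 0))
    stop("intensity must be nonnegative and free of missing values")
  if (!is.numeric(axial_spacing_um) || axial_spacing_um <= 0)
    stop("axial_spacing_um must be > 0")
  if (!is.numeric(lateral_spacing_um) || lateral_spacing_um <= 0)
    stop("lateral_spacing_um must be > 0")
  d <- dim(intensity)
  if (is.null(fovea_center)) fovea_center <- c(x = (d[2] + 1) / 2, y = (d[1] + 1) / 2)
  fovea_center <- as.numeric(fovea_center)
  if (length(fovea_center) != 2L ||
      fovea_center[1] < 1 || fovea_center[1] > d[2] ||
      fovea_center[2] < 1 || fovea_center[2] > d[1])
    stop("fovea_center (x, y) must lie inside the en face grid")
  if (!is.null(onh_mask)) {
    onh_mask <- as.matrix(onh_mask)
    if (!all(dim(onh_mask) == d[1:2])) stop("onh_mask shape mismatch")
    storage.mode(onh_mask) <- "logical"
  }
  laterality <- match.arg(laterality, c("OD", "OS"))
  visit_label <- match.arg(visit_label, VISIT_LABELS)
  signal_strength <- as.integer(signal_strength)
  if (is.na(signal_strength) || signal_strength < 0L || signal_strength > 10L)
    stop("signal_strength must be an integer in 0..10")
  structure(list(
    intensity = intensity,
    axial_spacing_um = axial_spacing_um,
    lateral_spacing_um = lateral_spacing_um,
    fovea_center = c(x = fovea_center[1], y = fovea_center[2]),
    onh_mask = onh_mask,
    laterality = laterality,
    signal_strength = signal_strength,
    visit_label = visit_label,
    mnv_type = if (is.na(mnv_type)) NA_integer_ else as.integer(mnv_type),
    patient_id = as.character(patient_id),
    eye_id = as.character(eye_id)
  ), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<oct_volume> %d x %d A-scans, %d axial samples (%s, %s, eye %s)\n",
    d[1], d[2], d[3], x$visit_label, x$laterality, x$eye_id))
  cat(sprintf("  lateral %.3g um, axial %.3g um, signal strength %d\n",
              x$lateral_spacing_um, x$axial_spacing_um, x$signal_strength))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$intensity)

#' En face map
#'
#' A 2-D scalar map aligned with the `(y, x)` lateral grid of its parent
#' volume, one value per A-scan position.  Missing A-scans are `NA`.
#'
#' @param values Numeric matrix `[y, x]`; `NA` marks missing positions.
#' @param units `"um"` (thickness), `"ratio"` (CVI-type, values in \[0, 1\]) or
#'   `"intensity"`.
#' @return An object of class `enface_map`.
#' @export
enface_map <- function(values, units = c("um", "ratio", "intensity")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (units == "ratio") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      stop("ratio-type en face maps must have values in [0, 1]")
  }
  structure(list(values = values, units = units), class = "enface_map")
}

#' @export
as.matrix.enface_map <- function(x, ...) x$values

#' @export
print.enface_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<enface_map> %d x %d [%s], %d missing\n",
              d[1], d[2], x$units, sum(is.na(x$values))))
  invisible(x)
}

## Accept either an enface_map or a bare matrix in map-consuming functions.
map_values <- function(x) {
  if (inherits(x, "enface_map")) x$values else as.matrix(x)
}

#' Scan-quality gate
#'
#' Volumes with a signal strength below `min_signal` are rejected; the device
#' convention is that a score *less than* 7 is unusable, so 7 itself passes.
#'
#' @param volume An [oct_volume].
#' @param min_signal Minimum acceptable signal strength (default 7).
#' @return A list with elements `pass` (logical) and `reason` (character).
#' @export
quality_gate <- function(volume, min_signal = 7) {
  stopifnot(inherits(volume, "oct_volume"))
  if (volume$signal_strength < min_signal) {
    list(pass = FALSE,
         reason = sprintf("quality_gate: signal_strength %d < %d",
                          volume$signal_strength, as.integer(min_signal)))
  } else {
    list(pass = TRUE,
         reason = sprintf("signal_strength %d >= %d",
                          volume$signal_strength, as.integer(min_signal)))
  }
}

#' Project an axial slab to an en face map
#'
#' Reduces the intensities of each A-scan over the half-open voxel interval
#' `[round(top), round(bottom))` (1-based indices, round-half-up).  The
#' half-open convention means a boundary voxel shared by two stacked slabs is
#' counted exactly once.  A-scans with an empty slab are missing in the output.
#'
#' @param volume An [oct_volume] or 3-D array.
#' @param top,bottom Numeric matrices `[y, x]` of (fractional) 1-based axial
#'   indices with `top <= bottom` everywhere.
#' @param reducer `"mean"`, `"max"` or `"sum"`.
#' @return An [enface_map] with `units = "intensity"`.
#' @export
project_slab <- function(volume, top, bottom, reducer = c("mean", "max", "sum")) {
  reducer <- match.arg(reducer)
  arr <- if (inherits(volume, "oct_volume")) volume$intensity else volume
  d <- dim(arr)
  top <- map_values(top); bottom <- map_values(bottom)
  if (!all(dim(top) == d[1:2]) || !all(dim(bottom) == d[1:2]))
    stop("surface grids must match the en face shape of the volume")
  n_cross <- sum(top > bottom, na.rm = TRUE)
  if (n_cross > 0)
    stop(sprintf("surfaces cross (top > bottom) at %d A-scan(s)", n_cross))
  zt <- round_half_up(top); zb <- round_half_up(bottom)
  if (any(zt < 1, na.rm = TRUE) || any(zb > d[3] + 1, na.rm = TRUE))
    stop("surfaces outside the axial range of the volume")
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  mx <- matrix(-Inf, d[1], d[2])
  for (z in seq_len(d[3])) {
    inz <- !is.na(zt) & !is.na(zb) & z >= zt & z < zb
    if (!any(inz)) next
    slice <- arr[, , z]
    acc[inz] <- acc[inz] + slice[inz]
    cnt[inz] <- cnt[inz] + 1L
    mx[inz] <- pmax(mx[inz], slice[inz])
  }
  out <- switch(reducer,
    mean = ifelse(cnt > 0L, acc / cnt, NA_real_),
    sum  = ifelse(cnt > 0L, acc, NA_real_),
    max  = ifelse(cnt > 0L, mx, NA_real_))
  enface_map(out, units = "intensity")
}

## ---- file formats -------------------------------------------------------
## Volumes: multi-page TIFF (one page per z) + JSON sidecar.  Grids/masks:
## headerless CSV, row = y.  TIFF pages store values / intensity_scale in
## 16-bit; integer-valued volumes are flagged so the round trip is exact.

required_metadata <- c("ny", "nx", "nz", "intensity_scale", "values_are_integer",
                       "axial_spacing_um", "lateral_spacing_um", "fovea_center",
                       "laterality", "signal_strength", "visit_label",
                       "patient_id", "eye_id")

#' Write an OCT volume as multi-page TIFF plus JSON metadata
#'
#' @param volume An [oct_volume].
#' @param path Output TIFF path.
#' @param metadata_path JSON sidecar path (default: `path` with `.json`).
#' @return Invisibly, the metadata list.
#' @export
write_volume <- function(volume, path, metadata_path = NULL) {
  stopifnot(inherits(volume, "oct_volume"))
  if (is.null(metadata_path)) metadata_path <- paste0(path, ".json")
  arr <- volume$intensity
  d <- dim(arr)
  integral <- all(arr == round(arr)) && max(arr) <= 65535
  scale <- if (integral) 65535 else max(arr, 1e-12)
  pages <- lapply(seq_len(d[3]), function(z) arr[, , z] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(ny = d[1], nx = d[2], nz = d[3],
               intensity_scale = scale, values_are_integer = integral,
               axial_spacing_um = volume$axial_spacing_um,
               lateral_spacing_um = volume$lateral_spacing_um,
               fovea_center = as.numeric(volume$fovea_center),
               laterality = volume$laterality,
               signal_strength = volume$signal_strength,
               visit_label = volume$visit_label,
               mnv_type = if (is.na(volume$mnv_type)) NULL else volume$mnv_type,
               patient_id = volume$patient_id,
               eye_id = volume$eye_id,
               has_onh_mask = !is.null(volume$onh_mask))
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(volume$onh_mask))
    write_grid_csv(volume$onh_mask * 1L, paste0(path, "_onh.csv"))
  invisible(meta)
}

#' Read an OCT volume written by [write_volume()]
#'
#' @param path TIFF path.
#' @param metadata_path JSON sidecar path (default: `path` with `.json`).
#' @return An [oct_volume].
#' @export
read_volume <- function(path, metadata_path = NULL) {
  if (is.null(metadata_path)) metadata_path <- paste0(path, ".json")
  if (!file.exists(metadata_path))
    stop(sprintf("metadata file not found: %s", metadata_path))
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  missing <- setdiff(required_metadata, names(meta))
  if (length(missing))
    stop(sprintf("metadata missing required field(s): %s",
                 paste(missing, collapse = ", ")))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$nz)
    stop(sprintf("TIFF page count %d does not match metadata nz = %d",
                 length(pages), meta$nz))
  if (!all(dim(pages[[1]]) == c(meta$ny, meta$nx)))
    stop("TIFF page shape does not match metadata ny/nx")
  arr <- array(0, dim = c(meta$ny, meta$nx, meta$nz))
  for (z in seq_len(meta$nz)) arr[, , z] <- pages[[z]] * meta$intensity_scale
  if (isTRUE(meta$values_are_integer)) arr <- round(arr)
  onh <- NULL
  if (isTRUE(meta$has_onh_mask)) {
    onh_path <- paste0(path, "_onh.csv")
    if (file.exists(onh_path)) onh <- read_grid_csv(onh_path) != 0
  }
  oct_volume(arr,
             axial_spacing_um = meta$axial_spacing_um,
             lateral_spacing_um = meta$lateral_spacing_um,
             fovea_center = meta$fovea_center,
             onh_mask = onh,
             laterality = meta$laterality,
             signal_strength = meta$signal_strength,
             visit_label = meta$visit_label,
             mnv_type = if (is.null(meta$mnv_type)) NA_integer_
               else as.integer(meta$mnv_type),
             patient_id = meta$patient_id,
             eye_id = meta$eye_id)
}

#' Write / read a 2-D grid (surface, map or mask) as headerless CSV
#'
#' Rows correspond to the `y` (B-scan) axis.  `NA` round-trips as an empty
#' field.
#'
#' @param mat Numeric or logical matrix.
#' @param path CSV path.
#' @return `write_grid_csv`: invisibly `path`; `read_grid_csv`: a numeric
#'   matrix.
#' @export
write_grid_csv <- function(mat, path) {
  mat <- map_values(mat)
  utils::write.table(mat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   na.strings = "", colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}
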