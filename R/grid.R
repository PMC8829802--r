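#' Define the common voxel grid of a run
#'
#' All volumetric objects in a simulation/analysis run live on a single
#' common grid (the synthetic stand-in for a template space). The grid
#' records the array shape and the physical voxel size in mm.
#'
#' @param shape Integer vector of length 3, array dimensions (all >= 1).
#' @param voxel_size Numeric vector of length 3 (or scalar, recycled), mm per
#'   axis; all > 0.
#' @param origin Origin convention tag; voxel centre coordinates are
#'   `(index - 0.5) * voxel_size` under the default `"corner"` convention.
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(shape, voxel_size = 2, origin = "corner") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("`voxel_size` must be > 0 on every axis")
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, %s mm\n",
              paste(x$shape, collapse = " x "),
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

#' @export
format.voxel_grid <- function(x, ...) {
  sprintf("%s @ %s mm", paste(x$shape, collapse = "x"),
          paste(format(x$voxel_size), collapse = "x"))
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch between %s: %s vs %s",
                 what, format(a), format(b)))
  invisible(TRUE)
}

#' Voxel centre coordinates (mm) along each axis
#' @noRd
grid_axes_mm <- function(grid) {
  lapply(1:3, function(a)
    (seq_len(grid$shape[a]) - 0.5) * grid$voxel_size[a])
}

#' Physical volume of one voxel in ml (mm^3 / 1000)
#' @noRd
voxel_volume_ml <- function(grid) prod(grid$voxel_size) / 1000

check_volume <- function(x, grid, what = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L ||
      !identical(as.integer(dim(x)), grid$shape))
    stop(sprintf("%s does not match the grid: dims %s vs shape %s", what,
                 paste(dim(x), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  invisible(TRUE)
}

#' Kinetic and physical constants shared by the signal models
#'
#' Defaults follow consensus recommendations for pCASL quantification:
#' water partition coefficient 0.9 ml/g, blood T1 1650 ms at 3 T, pCASL
#' labeling efficiency 0.85, and mean brain density 1.05 g/ml.
#'
#' @param lambda_partition Blood-brain partition coefficient of water, ml/g.
#' @param t1_blood Longitudinal relaxation time of arterial blood, ms.
#' @param labeling_efficiency pCASL inversion efficiency, in (0, 1].
#' @param brain_density Brain tissue density, g/ml.
#' @return A `kinetic_constants` object.
#' @export
kinetic_constants <- function(lambda_partition = 0.9, t1_blood = 1650,
                              labeling_efficiency = 0.85,
                              brain_density = 1.05) {
  if (lambda_partition <= 0) stop("lambda_partition must be > 0")
  if (t1_blood <= 0) stop("t1_blood must be > 0")
  if (labeling_efficiency <= 0 || labeling_efficiency > 1)
    stop("labeling_efficiency must be in (0, 1]")
  if (brain_density <= 0) stop("brain_density must be > 0")
  structure(list(lambda_partition = lambda_partition, t1_blood = t1_blood,
                 labeling_efficiency = labeling_efficiency,
                 brain_density = brain_density),
            class = "kinetic_constants")
}

#' ASL sequence parameters
#'
#' Timing and calibration parameters for a pCASL acquisition. The defaults
#' mirror a clinical single-delay protocol (LD 1800 ms, PLD 2000 ms). The
#' background suppression factor is the net attenuation of the perfusion
#' signal by the suppression pulses (two inversions at ~0.91 efficiency
#' each gives 0.83).
#'
#' @param label_duration Labeling duration, ms (> 0).
#' @param post_label_delay Post-labeling delay, ms (>= 0).
#' @param constants A [kinetic_constants()] object.
#' @param background_suppression_factor Net signal scaling in (0, 1].
#' @return An `asl_params` object.
#' @export
asl_params <- function(label_duration = 1800, post_label_delay = 2000,
                       constants = kinetic_constants(),
                       background_suppression_factor = 0.83) {
  if (label_duration <= 0) stop("label_duration must be > 0")
  if (post_label_delay < 0) stop("post_label_delay must be >= 0")
  if (background_suppression_factor <= 0 || background_suppression_factor > 1)
    stop("background_suppression_factor must be in (0, 1]")
  stopifnot(inherits(constants, "kinetic_constants"))
  structure(list(label_duration = label_duration,
                 post_label_delay = post_label_delay,
                 constants = constants,
                 background_suppression_factor = background_suppression_factor),
            class = "asl_params")
}

#' Construct a CBF map
#'
#' The common currency of all comparisons in the package: a 3D perfusion
#' volume with its grid, the modality that produced it, whether values are
#' absolute (ml/100 g/min) or relative (dimensionless multiples of a
#' reference mean), and a validity mask marking voxels where quantification
#' succeeded.
#'
#' @param values 3D numeric array.
#' @param grid A [voxel_grid()].
#' @param modality One of `"pet"`, `"asl_sd"`, `"asl_te"`, `"truth"`.
#' @param scale `"absolute"` or `"relative"`.
#' @param valid Logical 3D array; defaults to finite voxels.
#' @return A `cbf_map` object.
#' @export
cbf_map <- function(values, grid,
                    modality = c("pet", "asl_sd", "asl_te", "truth"),
                    scale = c("absolute", "relative"), valid = NULL) {
  modality <- match.arg(modality)
  scale <- match.arg(scale)
  check_volume(values, grid, "cbf values")
  if (is.null(valid)) valid <- is.finite(values)
  check_volume(valid, grid, "validity mask")
  valid <- valid & is.finite(values)
  values[!valid] <- NA_real_
  structure(list(values = values, grid = grid, modality = modality,
                 scale = scale, valid = valid),
            class = "cbf_map")
}

#' @export
print.cbf_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<cbf_map> %s, %s [%s]; %d valid voxels, mean %.2f\n",
              x$modality, x$scale, format(x$grid), sum(x$valid),
              mean(v)))
  invisible(x)
}
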