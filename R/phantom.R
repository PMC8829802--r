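#' Build a digital brain phantom with known perfusion ground truth
#'
#' Generates an ellipsoidal-shell head model on the common grid: a cortical
#' grey-matter (GM) shell around a white-matter (WM) core with a central
#' CSF cavity standing in for the ventricles. Focal hypoperfused lesions are
#' spherical regions where true CBF is reduced by a stated fraction.
#' Arterial transit time (ATT) increases smoothly from the centre of the
#' brain to the periphery (distal vascular territories fill later), with a
#' small seed-controlled smooth modulation.
#'
#' Label codes: 0 background, 1 GM, 2 WM, 3 CSF, 4 lesion. CSF carries zero
#' perfusion. Lesion voxels retain the M0 of their underlying tissue.
#'
#' @param grid A [voxel_grid()].
#' @param lesion_spec List of lesions, each a list/vector with `center`
#'   (length-3, mm), `radius` (mm, > 0) and `cbf_reduction` (fraction in
#'   [0, 1] by which CBF is reduced inside the sphere).
#' @param gm_cbf,wm_cbf True perfusion of GM and WM, ml/100 g/min
#'   (`gm_cbf > wm_cbf > 0`).
#' @param att_range Length-2 numeric, ms; ATT varies smoothly within this
#'   range inside the brain.
#' @param seed Integer seed controlling the ATT modulation field.
#' @param cbf_scale Global multiplier applied to all true CBF values
#'   (models between-subject variation in global perfusion).
#' @return A `tissue_phantom` with elements `grid`, `labels`, `true_cbf`
#'   (ml/100 g/min), `true_att` (ms), `m0` (a.u.) and `brain_mask`.
#' @export
#' @examples
#' ph <- build_phantom(voxel_grid(c(32, 32, 24), 4), seed = 1)
#' table(ph$labels[ph$brain_mask])
build_phantom <- function(grid, lesion_spec = list(),
                          gm_cbf = 60, wm_cbf = 20,
                          att_range = c(700, 1700), seed = 1,
                          cbf_scale = 1) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!(gm_cbf > wm_cbf && wm_cbf > 0))
    stop("require gm_cbf > wm_cbf > 0")
  if (length(att_range) != 2L || att_range[1] > att_range[2] ||
      att_range[1] < 0)
    stop("`att_range` must be an increasing non-negative pair (ms)")
  if (cbf_scale <= 0) stop("`cbf_scale` must be > 0")

  extent <- grid$shape * grid$voxel_size
  centre <- extent / 2
  semi <- 0.45 * extent          # brain ellipsoid semi-axes, mm
  ax <- grid_axes_mm(grid)
  # normalized elliptical radius r in [0, ...]; r <= 1 is brain
  rx <- (ax[[1]] - centre[1]) / semi[1]
  ry <- (ax[[2]] - centre[2]) / semi[2]
  rz <- (ax[[3]] - centre[3]) / semi[3]
  r2 <- outer(outer(rx^2, ry^2, `+`), rz^2, `+`)
  r <- sqrt(r2)

  brain_mask <- r <= 1
  labels <- array(0L, grid$shape)
  labels[brain_mask] <- 1L                       # GM shell by default
  labels[r <= 0.72] <- 2L                        # WM core
  labels[r <= 0.22] <- 3L                        # central CSF

  true_cbf <- array(0, grid$shape)
  true_cbf[labels == 1L] <- gm_cbf
  true_cbf[labels == 2L] <- wm_cbf

  m0 <- array(0, grid$shape)
  m0[labels == 1L] <- 850
  m0[labels == 2L] <- 700
  m0[labels == 3L] <- 1000

  # smooth ATT field: radial trend plus a low-frequency seeded modulation
  set.seed(seed)
  phase <- stats::runif(3, 0, 2 * pi)
  wobble <- 0.5 + 0.5 * sin(outer(outer(
    2 * pi * ax[[1]] / extent[1] + phase[1],
    2 * pi * ax[[2]] / extent[2] + phase[2], `+`),
    2 * pi * ax[[3]] / extent[3] + phase[3], `+`))
  u <- 0.8 * pmin(r, 1) + 0.2 * wobble           # in [0, 1]
  true_att <- array(0, grid$shape)
  true_att[brain_mask] <- att_range[1] +
    (att_range[2] - att_range[1]) * u[brain_mask]

  # carve lesions
  coords <- grid_axes_mm(grid)
  for (les in lesion_spec) {
    les <- as.list(les)
    ctr <- as.numeric(les$center)
    rad <- as.numeric(les$radius)
    red <- as.numeric(les$cbf_reduction)
    if (length(ctr) != 3L || rad <= 0) stop("invalid lesion geometry")
    if (red < 0 || red > 1) stop("cbf_reduction must be in [0, 1]")
    cidx <- round(ctr / grid$voxel_size + 0.5)
    if (any(cidx < 1) || any(cidx > grid$shape) ||
        !brain_mask[cidx[1], cidx[2], cidx[3]])
      stop(sprintf("lesion center (%s mm) lies outside the brain mask",
                   paste(format(ctr), collapse = ", ")))
    d2 <- outer(outer((coords[[1]] - ctr[1])^2, (coords[[2]] - ctr[2])^2,
                      `+`), (coords[[3]] - ctr[3])^2, `+`)
    inside <- d2 <= rad^2 & (labels == 1L | labels == 2L | labels == 4L)
    true_cbf[inside] <- true_cbf[inside] * (1 - red)
    labels[inside] <- 4L
  }

  true_cbf <- true_cbf * cbf_scale

  structure(list(grid = grid, labels = labels, true_cbf = true_cbf,
                 true_att = true_att, m0 = m0, brain_mask = brain_mask),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf(
    "<tissue_phantom> %s; brain %d voxels (GM %d, WM %d, CSF %d, lesion %d)\n",
    format(x$grid), sum(x$brain_mask), sum(x$labels == 1L),
    sum(x$labels == 2L), sum(x$labels == 3L), sum(x$labels == 4L)))
  invisible(x)
}

#' Gamma-variate arterial input function
#'
#' Synthesizes the arterial tracer concentration following a bolus
#' injection as a gamma-variate, the standard parametric bolus shape:
#' `A(t) = peak_value * (t/tp)^shape * exp(shape * (1 - t/tp))`, which is
#' zero at t = 0 and attains its unique maximum `peak_value` at `tp`.
#'
#' @param peak_time Time of the peak, s (> 0).
#' @param peak_value Peak activity concentration, kBq/ml (> 0).
#' @param shape Dimensionless shape parameter (> 0); larger values give a
#'   narrower bolus.
#' @param times Strictly increasing sample times, s.
#' @return An `input_function` with `times` (s) and `activity` (kBq/ml).
#' @export
gamma_variate_aif <- function(peak_time = 30, peak_value = 30, shape = 3,
                              times = seq(0, 300, by = 0.5)) {
  if (peak_time <= 0) stop("peak_time must be > 0")
  if (peak_value <= 0) stop("peak_value must be > 0")
  if (shape <= 0) stop("shape must be > 0")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(times < 0)) stop("`times` must be non-negative")
  tt <- times / peak_time
  activity <- ifelse(times <= 0, 0,
                     peak_value * tt^shape * exp(shape * (1 - tt)))
  structure(list(times = times, activity = activity),
            class = "input_function")
}

#' Synthetic ROI parcellation of the phantom cortex
#'
#' Splits the phantom's grey matter into 13 equal azimuthal sectors around
#' the vertical axis: 12 "disease" ROIs plus one posterior sector used as
#' the reference region (the stand-in for the occipital reference of
#' ROI-based hypoperfusion analyses). Lesion voxels keep the sector of
#' their location, so lesioned cortex remains inside its ROI.
#'
#' @param phantom A [build_phantom()] result.
#' @param n_disease_rois Number of non-reference ROIs (default 12).
#' @return A `roi_atlas` with `grid`, `labels` (0 outside GM), `names`
#'   (data.frame label/name) and `reference_roi`.
#' @export
phantom_atlas <- function(phantom, n_disease_rois = 12) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  grid <- phantom$grid
  n_rois <- n_disease_rois + 1L
  extent <- grid$shape * grid$voxel_size
  centre <- extent / 2
  ax <- grid_axes_mm(grid)
  xg <- outer(outer(ax[[1]] - centre[1], rep(1, grid$shape[2])),
              rep(1, grid$shape[3]))
  yg <- outer(outer(rep(1, grid$shape[1]), ax[[2]] - centre[2]),
              rep(1, grid$shape[3]))
  theta <- atan2(yg, xg)                       # (-pi, pi]; -pi/2 "posterior"
  sector <- 1L + ((floor((theta + pi) / (2 * pi) * n_rois)) %% n_rois)
  cortical <- phantom$labels == 1L | phantom$labels == 4L
  labels <- array(0L, grid$shape)
  labels[cortical] <- as.integer(sector[cortical])
  # the sector containing the posterior direction (theta = -pi/2) is the
  # reference region
  ref_label <- 1L + (floor((-pi / 2 + pi) / (2 * pi) * n_rois) %% n_rois)
  nms <- character(n_rois)
  nms[ref_label] <- "reference"
  nms[nms == ""] <- paste0("roi_", sprintf("%02d", seq_len(n_disease_rois)))
  nm <- data.frame(label = seq_len(n_rois), name = nms)
  roi_atlas(labels, grid, nm, reference_roi = "reference")
}

#' Construct an ROI atlas
#'
#' @param labels Integer 3D label volume (0 = outside atlas).
#' @param grid A [voxel_grid()].
#' @param names data.frame with columns `label` and `name`.
#' @param reference_roi Name of the reference region (must appear in
#'   `names$name`).
#' @return A `roi_atlas` object. Every listed ROI must be non-empty.
#' @export
roi_atlas <- function(labels, grid, names, reference_roi) {
  check_volume(labels, grid, "atlas labels")
  stopifnot(is.data.frame(names), all(c("label", "name") %in% colnames(names)))
  if (!reference_roi %in% names$name)
    stop("reference_roi not found in the name table")
  for (lb in names$label)
    if (!any(labels == lb))
      stop(sprintf("ROI '%s' (label %d) is empty in the atlas volume",
                   names$name[names$label == lb], lb))
  structure(list(grid = grid, labels = labels, names = names,
                 reference_roi = reference_roi),
            class = "roi_atlas")
}
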