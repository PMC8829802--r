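#' Whole-brain (or masked) time-activity curve at frame midpoints
#'
#' @param dynamic A [simulate_pet_dynamic()] image (or any
#'   `dynamic_pet_image`).
#' @param mask Logical 3D array on the same grid, non-empty.
#' @return A `tac` with `times` (frame midpoints, s) and `activity`
#'   (unweighted mean over mask voxels, kBq/ml).
#' @export
frame_midpoint_tac <- function(dynamic, mask) {
  stopifnot(inherits(dynamic, "dynamic_pet_image"))
  check_volume(mask, dynamic$grid, "mask")
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  nfr <- length(dynamic$schedule$duration)
  m <- matrix(dynamic$data, ncol = nfr)
  activity <- colMeans(m[idx, , drop = FALSE])
  structure(list(times = dynamic$schedule$mid, activity = activity),
            class = "tac")
}

#' Whole-brain CBF from phase-contrast vessel measurements
#'
#' Total inflow is the sum over feeding vessels of mean velocity times
#' cross-sectional area (cm/s x mm^2 = 0.6 ml/min), scaled by brain mass:
#' `f_wb = 100 * sum(v_k A_k * 0.6) / brain_mass` in ml/100 g/min.
#'
#' @param pc A `pc_flow` (see [simulate_pc()]) or a list with `velocity`
#'   (cm/s), `area` (mm^2) and `brain_mass` (g).
#' @return Whole-brain CBF, ml/100 g/min.
#' @export
pc_whole_brain_cbf <- function(pc) {
  if (is.null(pc$velocity) || is.null(pc$area) || is.null(pc$brain_mass))
    stop("pc must carry velocity, area and brain_mass")
  if (pc$brain_mass <= 0) stop("brain_mass must be > 0")
  if (any(pc$area <= 0)) stop("vessel areas must be > 0")
  flow_ml_min <- sum(pc$velocity * pc$area * 0.6)
  100 * flow_ml_min / pc$brain_mass
}

#' Quadrature weights for Eq.-style integrals on a midpoint time grid
#'
#' Returns the augmented time grid {0, midpoints < T, T} (minutes), the
#' trapezoid weight vector for a single integral over [0, T], and the
#' weight vector for the double integral int_0^T int_0^t ds dt, both as
#' linear functionals of the sampled activities. Activity at t = 0 is
#' anchored at zero; activity at T is interpolated (constant extension
#' past the last midpoint).
#' @noRd
pmr_quadrature <- function(mid_s, T_s) {
  keep <- which(mid_s < T_s - 1e-12)
  t_min <- c(0, mid_s[keep], T_s) / 60
  n <- length(t_min)
  dt <- diff(t_min)
  w <- numeric(n)                       # single-integral trapezoid weights
  w[1:(n - 1)] <- w[1:(n - 1)] + dt / 2
  w[2:n] <- w[2:n] + dt / 2
  # cumulative-trapezoid operator Wc (lower triangular): I = Wc %*% y
  Wc <- matrix(0, n, n)
  for (j in 2:n) {
    Wc[j:n, j - 1] <- Wc[j:n, j - 1] + dt[j - 1] / 2
    Wc[j:n, j] <- Wc[j:n, j] + dt[j - 1] / 2
  }
  w2 <- as.vector(crossprod(Wc, w))     # double-integral weights
  list(keep = keep, t_min = t_min, w = w, w2 = w2)
}

# interpolate a set of curves sampled at midpoints onto the augmented grid:
# rows = voxels; returns matrix with leading 0 column and trailing value at T
augment_curves <- function(m, mid_s, keep, T_s) {
  if (length(keep) == 0L) {             # T before the first midpoint
    at_T <- m[, 1L] * T_s / mid_s[1L]   # linear from the (0, 0) anchor
  } else if (T_s > mid_s[length(mid_s)]) {
    at_T <- m[, ncol(m)]                # constant extension
  } else {
    i <- max(keep)
    at_T <- m[, i] + (m[, i + 1L] - m[, i]) *
      (T_s - mid_s[i]) / (mid_s[i + 1L] - mid_s[i])
  }
  cbind(0, m[, keep, drop = FALSE], at_T)
}

#' Voxelwise CBF from dynamic PET calibrated by whole-brain flow
#'
#' Computes per-voxel perfusion from a dynamic water-PET image without
#' arterial sampling, using the whole-brain curve and an independently
#' measured whole-brain CBF (from phase-contrast MRI) as the calibration:
#' \deqn{f_i = \frac{\int_0^T C_i\,dt}{\frac{1}{f_{wb}}\int_0^T C_{wb}\,dt
#'   + \frac{1}{\lambda}\int_0^T\!\!\int_0^t C_{wb}\,ds\,dt
#'   - \frac{1}{\lambda}\int_0^T\!\!\int_0^t C_i\,ds\,dt}}
#' All integrals are trapezoidal on the frame-midpoint samples with an
#' implicit (0, 0) anchor (activity is zero at injection). Internally time
#' is in minutes and flows in ml/g/min; the returned map is in
#' ml/100 g/min. Voxels whose denominator is not positive are marked
#' invalid rather than clipped. The blood-volume signal contribution is
#' not modeled, matching the method as published (a known source of CBF
#' overestimation).
#'
#' @param dynamic A `dynamic_pet_image`.
#' @param wb_tac The whole-brain [frame_midpoint_tac()]; must share the
#'   frame schedule.
#' @param f_wb Whole-brain CBF from [pc_whole_brain_cbf()], ml/100 g/min.
#' @param lambda Water partition coefficient, ml/g.
#' @param integration_time T, s (default 300 = 5 min).
#' @param mask Optional logical 3D array restricting quantification
#'   (voxels outside are invalid).
#' @return A [cbf_map()] (modality `"pet"`, absolute).
#' @export
pmrflow_cbf <- function(dynamic, wb_tac, f_wb, lambda = 0.9,
                        integration_time = 300, mask = NULL) {
  stopifnot(inherits(dynamic, "dynamic_pet_image"), inherits(wb_tac, "tac"))
  if (f_wb <= 0) stop("f_wb must be > 0")
  sched <- dynamic$schedule
  if (length(wb_tac$times) != length(sched$mid) ||
      max(abs(wb_tac$times - sched$mid)) > 1e-6)
    stop("wb_tac frame times do not match the dynamic image schedule")
  T_s <- integration_time
  if (T_s <= 0 || T_s > max(sched$end) + 1e-9)
    stop("integration_time must be in (0, last frame end]")

  q <- pmr_quadrature(sched$mid, T_s)
  nfr <- length(sched$mid)
  m <- matrix(dynamic$data, ncol = nfr)
  if (!is.null(mask)) {
    check_volume(mask, dynamic$grid, "mask")
    vox <- which(mask)
  } else {
    vox <- seq_len(nrow(m))
  }
  mi <- augment_curves(m[vox, , drop = FALSE], sched$mid, q$keep, T_s)
  wb <- augment_curves(matrix(wb_tac$activity, nrow = 1), sched$mid,
                       q$keep, T_s)

  S_i <- as.vector(mi %*% q$w)          # int C_i dt
  D_i <- as.vector(mi %*% q$w2)         # int int C_i
  S_wb <- sum(wb * q$w)
  D_wb <- sum(wb * q$w2)

  fwb_g <- f_wb / 100                   # ml/g/min
  denom <- S_wb / fwb_g + (D_wb - D_i) / lambda
  f <- ifelse(denom > 0, 100 * S_i / denom, NA_real_)

  values <- array(NA_real_, dynamic$grid$shape)
  values[vox] <- f
  valid <- array(FALSE, dynamic$grid$shape)
  valid[vox] <- denom > 0
  cbf_map(values, dynamic$grid, modality = "pet", scale = "absolute",
          valid = valid)
}

# 1D Gaussian convolution along each axis with zero padding; `x` is a 3D
# array. Kernel is the discretely normalized Gaussian truncated at 3 sigma.
separable_gaussian <- function(x, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    d <- dim(xp)
    mat <- matrix(xp, nrow = d[1])
    pad <- matrix(0, r, ncol(mat))
    fil <- stats::filter(rbind(pad, mat, pad), k, sides = 2)
    mat <- as.matrix(fil[(r + 1):(r + d[1]), , drop = FALSE])
    x <- aperm(array(mat, d), order(perm))
  }
  x
}

#' Gaussian smoothing of a volume or CBF map, renormalized within a mask
#'
#' Separable Gaussian filter with `sigma = fwhm / (2 sqrt(2 log 2))` per
#' axis (in mm, converted to voxels via the grid). Smoothing is restricted
#' to and renormalized within the mask (for a `cbf_map`, its validity
#' mask): the smoothed field is `G(x * m) / G(m)` inside the mask, so a
#' constant field stays constant and no signal bleeds in from outside.
#' `fwhm = 0` is the identity.
#'
#' @param x A [cbf_map()] or a plain 3D array.
#' @param fwhm Full width at half maximum, mm (>= 0).
#' @param grid Required when `x` is a plain array.
#' @param mask Optional mask for the plain-array case.
#' @return Same type as `x`.
#' @export
smooth_gaussian <- function(x, fwhm, grid = NULL, mask = NULL) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (inherits(x, "cbf_map")) {
    if (fwhm == 0) return(x)
    sm <- smooth_gaussian(ifelse(x$valid, x$values, 0), fwhm, x$grid,
                          mask = x$valid)
    return(cbf_map(sm, x$grid, modality = x$modality, scale = x$scale,
                   valid = x$valid))
  }
  if (is.null(grid)) stop("grid required for array input")
  check_volume(x, grid, "volume")
  if (fwhm == 0) return(x)
  sigma_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / grid$voxel_size
  if (is.null(mask)) return(separable_gaussian(x, sigma_vox))
  m <- array(as.numeric(mask), dim(x))
  num <- separable_gaussian(x * m, sigma_vox)
  den <- separable_gaussian(m, sigma_vox)
  out <- array(0, dim(x))
  inside <- mask & den > 0
  out[inside] <- num[inside] / den[inside]
  out
}

#' Grey-to-white-matter contrast ratio
#'
#' @param map A [cbf_map()].
#' @param labels Phantom-style label volume (1 = GM, 2 = WM; lesion voxels
#'   are excluded).
#' @return `mean(GM) / mean(WM)` over valid voxels.
#' @export
gm_wm_contrast <- function(map, labels) {
  stopifnot(inherits(map, "cbf_map"))
  check_volume(labels, map$grid, "labels")
  gm <- map$values[labels == 1L & map$valid]
  wm <- map$values[labels == 2L & map$valid]
  if (length(gm) == 0L || length(wm) == 0L)
    stop("GM and WM label sets must be non-empty")
  mw <- mean(wm)
  if (mw == 0) stop("WM mean is zero; contrast undefined")
  mean(gm) / mw
}
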