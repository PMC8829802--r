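#' Frame schedule of a dynamic PET acquisition
#'
#' Frames must be contiguous and non-overlapping. The default reproduces a
#' 5-minute water-PET protocol: 20 frames of 3 s, 6 of 5 s, 6 of 10 s and
#' 5 of 30 s (37 frames, 300 s).
#'
#' @param frame_durations Numeric vector of frame lengths, s.
#' @return A `frame_schedule` with `start`, `duration`, `end` and `mid` (s).
#' @export
frame_schedule <- function(frame_durations = c(rep(3, 20), rep(5, 6),
                                               rep(10, 6), rep(30, 5))) {
  if (any(frame_durations <= 0)) stop("frame durations must be > 0")
  start <- cumsum(c(0, frame_durations[-length(frame_durations)]))
  structure(list(start = start, duration = frame_durations,
                 end = start + frame_durations,
                 mid = start + frame_durations / 2),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, 0-%g s\n",
              length(x$duration), max(x$end)))
  invisible(x)
}

#' One-tissue-compartment tissue curve for piecewise-constant CBF
#'
#' Integrates dC/dt = k1 * Ca(t) - k2 * C(t) with an exact exponential
#' update per fine-grid step (trapezoidal treatment of the forcing term).
#' Times in seconds; k1, k2 per second.
#' @noRd
one_tissue_curve <- function(ca, dt, k1, k2) {
  n <- length(ca)
  C <- numeric(n)
  if (k1 == 0) return(C)
  e <- exp(-k2 * dt)
  for (i in 2:n)
    C[i] <- C[i - 1] * e + k1 * dt / 2 * (ca[i] + ca[i - 1] * e)
  C
}

#' Simulate a dynamic water-PET acquisition from a phantom
#'
#' Each voxel's instantaneous activity follows the one-tissue compartment
#' model `dC/dt = (f/100) Ca(t) - (f/(100*lambda)) C(t)` with CBF `f` in
#' ml/100 g/min (converted internally to per-second rates) and `lambda` the
#' water partition coefficient. Frame values are time-averages of the
#' continuous solution over each frame. Simulated curves are
#' decay-corrected, as reconstructed PET frames are. When `noise_sd > 0`,
#' independent Gaussian noise with standard deviation
#' `noise_sd / sqrt(frame_duration)` is added per voxel and frame,
#' mimicking count statistics (longer frames average more counts).
#'
#' Because the phantom's CBF is piecewise constant, the ODE is solved once
#' per unique CBF value on a fine time grid (`dt` seconds) and mapped back
#' to voxels, which keeps whole-volume simulation fast and exact.
#'
#' @param phantom A [build_phantom()] result.
#' @param aif An [gamma_variate_aif()] input function; its support must
#'   cover the schedule.
#' @param schedule A [frame_schedule()].
#' @param noise_sd Frame noise scale, kBq/ml (0 = noiseless).
#' @param seed Integer seed for the noise stream.
#' @param lambda Partition coefficient, ml/g.
#' @param dt Fine integration step, s.
#' @return A `dynamic_pet_image` with `data` (4D, kBq/ml), `schedule`,
#'   `grid`.
#' @export
simulate_pet_dynamic <- function(phantom, aif, schedule, noise_sd = 0,
                                 seed = 1, lambda = 0.9, dt = 0.02) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(aif, "input_function"),
            inherits(schedule, "frame_schedule"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (max(schedule$end) > max(aif$times) + 1e-9)
    stop("frame schedule extends beyond the input-function support")

  tf <- seq(0, max(schedule$end), by = dt)
  ca <- stats::approx(aif$times, aif$activity, xout = tf, rule = 2)$y

  fvals <- sort(unique(as.vector(phantom$true_cbf)))
  nfr <- length(schedule$duration)
  curves <- matrix(0, length(fvals), nfr)
  for (j in seq_along(fvals)) {
    f <- fvals[j]
    k1 <- f / 100 / 60                 # ml/g/s
    k2 <- k1 / lambda                  # 1/s
    C <- one_tissue_curve(ca, dt, k1, k2)
    # trapezoid average of the fine-grid solution over each frame
    for (k in seq_len(nfr)) {
      i0 <- round(schedule$start[k] / dt) + 1L
      i1 <- round(schedule$end[k] / dt) + 1L
      seg <- C[i0:i1]
      w <- c(0.5, rep(1, length(seg) - 2L), 0.5)
      curves[j, k] <- sum(seg * w) * dt / schedule$duration[k]
    }
  }

  fidx <- match(as.vector(phantom$true_cbf), fvals)
  data <- array(curves[fidx, ], c(phantom$grid$shape, nfr))
  if (noise_sd > 0) {
    set.seed(seed)
    nvox <- prod(phantom$grid$shape)
    for (k in seq_len(nfr)) {
      sdk <- noise_sd / sqrt(schedule$duration[k])
      data[, , , k] <- data[, , , k] + stats::rnorm(nvox, 0, sdk)
    }
  }
  structure(list(data = data, schedule = schedule, grid = phantom$grid),
            class = "dynamic_pet_image")
}

#' Simulate phase-contrast vessel flow measurements
#'
#' Draws per-vessel mean velocities and cross-sectional areas within
#' physiological bounds for the feeding arteries (internal carotid and
#' vertebral), then rescales the velocities so that the implied whole-brain
#' CBF equals `target_fwb` exactly. Brain mass is the phantom brain volume
#' times brain density.
#'
#' @param phantom A [build_phantom()] result.
#' @param target_fwb Whole-brain CBF the measurement should imply,
#'   ml/100 g/min.
#' @param n_vessels Number of feeding vessels (default 4: 2 ICA + 2 VA).
#' @param seed Integer seed.
#' @param constants A [kinetic_constants()] (for brain density).
#' @return A `pc_flow` with `velocity` (cm/s), `area` (mm^2),
#'   `brain_mass` (g).
#' @export
simulate_pc <- function(phantom, target_fwb, n_vessels = 4, seed = 1,
                        constants = kinetic_constants()) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (target_fwb <= 0) stop("target_fwb must be > 0")
  if (n_vessels < 1) stop("n_vessels must be >= 1")
  brain_vol_ml <- sum(phantom$brain_mask) * voxel_volume_ml(phantom$grid)
  brain_mass <- brain_vol_ml * constants$brain_density
  set.seed(seed)
  velocity <- stats::runif(n_vessels, 15, 35)    # cm/s
  area <- stats::runif(n_vessels, 15, 30)        # mm^2
  implied <- 100 * sum(velocity * area * 0.6) / brain_mass
  velocity <- velocity * target_fwb / implied
  structure(list(velocity = velocity, area = area, brain_mass = brain_mass),
            class = "pc_flow")
}
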