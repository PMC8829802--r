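#' Single-compartment pCASL difference signal
#'
#' The piecewise solution of the single-compartment (general kinetic)
#' model for pCASL labeling, with the apparent tissue T1 approximated by
#' the blood T1 (the label is assumed to relax at the blood rate; an
#' optional tissue-T1 mode is available via `t1_apparent`). With times in
#' ms and CBF `f` in ml/100 g/min:
#' \itemize{
#'   \item `t < att`: 0 (label has not arrived);
#'   \item `att <= t < att + ld` (rising):
#'     `2 a m0 (f/6000) T1' exp(-att/T1b) (1 - exp(-(t - att)/T1'))`;
#'   \item `t >= att + ld` (decay): the rising value at `att + ld` times
#'     `exp(-(t - att - ld)/T1')`.
#' }
#' where `a` is the labeling efficiency, `T1b` the blood T1 and `T1'` the
#' apparent T1 (seconds inside the formula; f/6000 converts to ml/g/s).
#' The result is multiplied by the background suppression factor.
#'
#' `f`, `att` and `m0` may be arrays of a common shape; `t` and `ld` are
#' scalars (ms).
#'
#' @param f CBF, ml/100 g/min.
#' @param att Arterial transit time, ms (>= 0).
#' @param t Time since the start of labeling, ms (>= 0).
#' @param ld Labeling duration, ms (> 0).
#' @param m0 Equilibrium magnetization, a.u.
#' @param params An [asl_params()] (only constants and suppression factor
#'   are used; `ld` is passed explicitly).
#' @param t1_apparent Apparent tissue T1, ms; defaults to the blood T1.
#' @return Difference signal (control - label), a.u., same shape as `f`.
#' @export
buxton_signal <- function(f, att, t, ld, m0, params = asl_params(),
                          t1_apparent = NULL) {
  if (any(att < 0)) stop("att must be >= 0")
  if (ld <= 0) stop("ld must be > 0")
  if (t < 0) stop("t must be >= 0")
  kc <- params$constants
  t1b <- kc$t1_blood / 1000                   # s
  t1p <- if (is.null(t1_apparent)) t1b else t1_apparent / 1000
  alpha <- kc$labeling_efficiency
  fs <- f / 6000                              # ml/g/s
  att_s <- att / 1000
  t_s <- t / 1000
  ld_s <- ld / 1000

  amp <- 2 * alpha * m0 * fs * t1p * exp(-att_s / t1b)
  rising <- amp * (1 - exp(-pmax(t_s - att_s, 0) / t1p))
  plateau <- amp * (1 - exp(-ld_s / t1p)) *
    exp(-pmax(t_s - att_s - ld_s, 0) / t1p)
  dm <- ifelse(t_s < att_s, 0,
               ifelse(t_s < att_s + ld_s, rising, plateau))
  dm * params$background_suppression_factor
}

new_asl_acquisition <- function(grid, volumes, m0, params, mode,
                                scheme = NULL) {
  structure(list(grid = grid, volumes = volumes, m0 = m0, params = params,
                 mode = mode, scheme = scheme),
            class = "asl_acquisition")
}

#' @export
print.asl_acquisition <- function(x, ...) {
  cat(sprintf("<asl_acquisition> mode %s, %d volumes, %s\n",
              x$mode, dim(x$volumes)[4], format(x$grid)))
  invisible(x)
}

#' Simulate a single-delay pCASL acquisition
#'
#' Control volumes are the static (background-suppressed) M0-proportional
#' signal; label volumes are control minus the single-compartment
#' difference signal evaluated at `t = LD + PLD` with the phantom's
#' per-voxel CBF and transit time. Independent Gaussian noise is added per
#' volume when `noise_sd > 0`. Volumes are interleaved
#' control, label, control, label, ...
#'
#' @param phantom A [build_phantom()] result.
#' @param params An [asl_params()].
#' @param n_pairs Number of control/label pairs.
#' @param noise_sd Per-volume Gaussian noise SD, a.u.
#' @param seed Integer seed.
#' @return An `asl_acquisition` in SD mode (2 * n_pairs volumes).
#' @export
simulate_asl_sd <- function(phantom, params = asl_params(), n_pairs = 16,
                            noise_sd = 0, seed = 1) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  grid <- phantom$grid
  static <- phantom$m0 * params$background_suppression_factor
  t_img <- params$label_duration + params$post_label_delay
  # the labeled magnetization pool is arterial blood: M0b = M0_tissue / lambda
  m0b <- phantom$m0 / params$constants$lambda_partition
  dm <- buxton_signal(phantom$true_cbf, phantom$true_att, t_img,
                      params$label_duration, m0b, params)
  nvol <- 2L * n_pairs
  volumes <- array(0, c(grid$shape, nvol))
  for (i in seq_len(n_pairs)) {
    volumes[, , , 2L * i - 1L] <- static
    volumes[, , , 2L * i] <- static - dm
  }
  if (noise_sd > 0) {
    set.seed(seed)
    volumes <- volumes + array(stats::rnorm(length(volumes), 0, noise_sd),
                               dim(volumes))
  }
  new_asl_acquisition(grid, volumes, phantom$m0, params, mode = "sd")
}

#' Simulate a Hadamard time-encoded pCASL acquisition
#'
#' Each of the N encoded volumes is the static signal minus the sum of the
#' labeled sub-boli's difference signals for that encoding row. Sub-bolus k
#' contributes the single-compartment signal with its own labeling duration
#' and effective post-labeling delay from [hadamard_timing()], evaluated at
#' readout (`t = LD_k + PLD_k` relative to that sub-bolus's start).
#'
#' @param phantom A [build_phantom()] result.
#' @param scheme A [hadamard_scheme()].
#' @param params An [asl_params()] (its LD/PLD are ignored; timing comes
#'   from the scheme).
#' @param noise_sd Per-volume Gaussian noise SD, a.u.
#' @param seed Integer seed.
#' @return An `asl_acquisition` in TE mode (N volumes).
#' @export
simulate_asl_te <- function(phantom, scheme = hadamard_scheme(),
                            params = asl_params(), noise_sd = 0, seed = 1) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(scheme, "hadamard_scheme"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  grid <- phantom$grid
  timing <- hadamard_timing(scheme)
  H <- scheme$encoding_matrix
  n <- scheme$n_encode
  k_sub <- ncol(H)
  static <- phantom$m0 * params$background_suppression_factor
  m0b <- phantom$m0 / params$constants$lambda_partition  # blood M0
  dm <- vector("list", k_sub)
  for (k in seq_len(k_sub))
    dm[[k]] <- buxton_signal(phantom$true_cbf, phantom$true_att,
                             timing$sub_bolus_lds[k] + timing$effective_plds[k],
                             timing$sub_bolus_lds[k], m0b, params)
  volumes <- array(0, c(grid$shape, n))
  for (i in seq_len(n)) {
    v <- static
    for (k in seq_len(k_sub))
      if (H[i, k] > 0) v <- v - dm[[k]]
    volumes[, , , i] <- v
  }
  if (noise_sd > 0) {
    set.seed(seed)
    volumes <- volumes + array(stats::rnorm(length(volumes), 0, noise_sd),
                               dim(volumes))
  }
  new_asl_acquisition(grid, volumes, phantom$m0, params, mode = "te",
                      scheme = scheme)
}
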