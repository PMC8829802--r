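new_pw_set <- function(grid, dm, effective_plds, sub_bolus_lds, params) {
  structure(list(grid = grid, dm = dm, effective_plds = effective_plds,
                 sub_bolus_lds = sub_bolus_lds, params = params),
            class = "perfusion_weighted_set")
}

#' Pairwise subtraction of a single-delay acquisition
#'
#' Averages control - label over all pairs into a single perfusion-weighted
#' difference image.
#'
#' @param acq An SD-mode `asl_acquisition` (even volume count, interleaved
#'   control/label).
#' @return A `perfusion_weighted_set` with one difference volume; its
#'   effective PLD/LD are the sequence's PLD and LD.
#' @export
pairwise_subtract <- function(acq) {
  stopifnot(inherits(acq, "asl_acquisition"))
  if (acq$mode != "sd") stop("pairwise_subtract expects an SD acquisition")
  nvol <- dim(acq$volumes)[4]
  if (nvol %% 2L != 0L) stop("odd volume count: not label/control pairs")
  ctrl <- seq(1L, nvol, by = 2L)
  lab <- ctrl + 1L
  dm <- array(0, acq$grid$shape)
  for (i in seq_along(ctrl))
    dm <- dm + (acq$volumes[, , , ctrl[i]] - acq$volumes[, , , lab[i]])
  dm <- dm / length(ctrl)
  new_pw_set(acq$grid, array(dm, c(acq$grid$shape, 1L)),
             effective_plds = acq$params$post_label_delay,
             sub_bolus_lds = acq$params$label_duration,
             params = acq$params)
}

#' Decode a Hadamard time-encoded acquisition
#'
#' Recovers the per-sub-bolus difference images by signed linear
#' combination of the N encoded volumes: for sub-bolus k with encoding
#' column h_k, `dM_k = -(2/N) * sum_i h_ik * volume_i`. The sign follows
#' the convention that +1 marks a labeled sub-bolus (label signal is
#' subtracted from the static image), so decoded images are non-negative
#' for noiseless simulated data. The decode is exactly linear and inverts
#' the encoding for arbitrary sub-bolus signals.
#'
#' @param acq A TE-mode `asl_acquisition` with its scheme attached.
#' @return A `perfusion_weighted_set` with N - 1 difference volumes and
#'   per-sub-bolus effective PLDs/LDs from [hadamard_timing()].
#' @export
hadamard_decode <- function(acq) {
  stopifnot(inherits(acq, "asl_acquisition"))
  if (acq$mode != "te" || is.null(acq$scheme))
    stop("hadamard_decode expects a TE acquisition with a scheme")
  H <- acq$scheme$encoding_matrix
  n <- acq$scheme$n_encode
  if (dim(acq$volumes)[4] != n)
    stop(sprintf("volume count (%d) does not match scheme N (%d)",
                 dim(acq$volumes)[4], n))
  k_sub <- ncol(H)
  dm <- array(0, c(acq$grid$shape, k_sub))
  for (k in seq_len(k_sub)) {
    acc <- array(0, acq$grid$shape)
    for (i in seq_len(n))
      acc <- acc - H[i, k] * acq$volumes[, , , i]
    dm[, , , k] <- (2 / n) * acc
  }
  timing <- hadamard_timing(acq$scheme)
  new_pw_set(acq$grid, dm, timing$effective_plds, timing$sub_bolus_lds,
             acq$params)
}

#' Single-delay CBF quantification (consensus closed form)
#'
#' Inverts the single-compartment model at one delay:
#' \deqn{CBF = \frac{6000\,\lambda\,\Delta M\,e^{PLD/T1b}}
#'   {2\,\alpha_{eff}\,T1b\,M_0\,(1 - e^{-LD/T1b})}}
#' in ml/100 g/min, with `alpha_eff` the labeling efficiency times the
#' background suppression factor and T1b in seconds. Exact for transit
#' times no longer than the PLD (under the blood-T1 apparent-relaxation
#' model the transit-time factors cancel). Voxels with non-positive M0
#' are invalid.
#'
#' @param pw A single-volume `perfusion_weighted_set`.
#' @param m0 Equilibrium magnetization volume, a.u.
#' @param params An [asl_params()].
#' @return A [cbf_map()] (modality `"asl_sd"`, absolute).
#' @export
quantify_sd_cbf <- function(pw, m0, params = NULL) {
  stopifnot(inherits(pw, "perfusion_weighted_set"))
  if (dim(pw$dm)[4] != 1L)
    stop("quantify_sd_cbf expects a single difference volume")
  if (is.null(params)) params <- pw$params
  kc <- params$constants
  t1b <- kc$t1_blood / 1000
  if (t1b <= 0) stop("t1_blood must be > 0")
  alpha_eff <- kc$labeling_efficiency * params$background_suppression_factor
  pld <- pw$effective_plds[1] / 1000
  ld <- pw$sub_bolus_lds[1] / 1000
  check_volume(m0, pw$grid, "m0")
  dm <- pw$dm[, , , 1L]
  valid <- m0 > 0
  cbf <- array(NA_real_, pw$grid$shape)
  cbf[valid] <- 6000 * kc$lambda_partition * dm[valid] * exp(pld / t1b) /
    (2 * alpha_eff * t1b * m0[valid] * (1 - exp(-ld / t1b)))
  cbf_map(cbf, pw$grid, modality = "asl_sd", scale = "absolute",
          valid = valid)
}

#' Joint CBF and transit-time fitting of a time-encoded series
#'
#' Voxelwise bounded least-squares fit of the single-compartment signal
#' over (CBF, ATT) to the decoded per-sub-bolus difference images. At a
#' fixed transit time the model is linear in CBF, so the fit is performed
#' as a dense grid search over ATT (default 5 ms steps) with the
#' closed-form CBF at each candidate, selecting the residual-norm
#' minimizer; CBF is constrained non-negative and ATT to `att_bounds`.
#' This deterministic fit replaces spatially regularized Bayesian
#' estimation; the downstream concordance analysis is agnostic to the
#' fitting engine.
#'
#' Voxels whose difference series is entirely (numerically) zero get
#' CBF 0 with ATT at the lower bound and are flagged low-confidence.
#'
#' @param pw A decoded `perfusion_weighted_set` (>= 3 sub-boli).
#' @param m0 Equilibrium magnetization volume.
#' @param params An [asl_params()].
#' @param att_bounds Length-2 ATT search bounds, ms.
#' @param att_step Grid resolution, ms.
#' @param mask Optional logical volume restricting the fit.
#' @param include_first Include the first (free-lunch) sub-bolus in the
#'   fit (default TRUE).
#' @return List with `cbf` (a [cbf_map()], modality `"asl_te"`), `att`
#'   (an `att_map` with `values` ms and `valid`), and `low_confidence`
#'   (logical volume).
#' @export
fit_te_cbf_att <- function(pw, m0, params = NULL,
                           att_bounds = NULL, att_step = 5,
                           mask = NULL, include_first = TRUE) {
  stopifnot(inherits(pw, "perfusion_weighted_set"))
  if (is.null(params)) params <- pw$params
  k_all <- dim(pw$dm)[4]
  sel <- if (include_first) seq_len(k_all) else seq_len(k_all)[-1]
  if (length(sel) < 3L)
    stop("need at least 3 sub-boli to fit (CBF, ATT)")
  check_volume(m0, pw$grid, "m0")
  if (is.null(att_bounds))
    att_bounds <- c(0, max(pw$effective_plds) + max(pw$sub_bolus_lds))
  if (length(att_bounds) != 2L || att_bounds[1] > att_bounds[2])
    stop("att_bounds must be an increasing pair (ms)")

  plds <- pw$effective_plds[sel]
  lds <- pw$sub_bolus_lds[sel]
  att_grid <- seq(att_bounds[1], att_bounds[2], by = att_step)

  voxmask <- m0 > 0
  if (!is.null(mask)) {
    check_volume(mask, pw$grid, "mask")
    voxmask <- voxmask & mask
  }
  vox <- which(voxmask)
  nk <- length(sel)
  # reference the signal to blood magnetization (M0b = M0_tissue / lambda),
  # matching the single-compartment model the basis is built from
  lam <- params$constants$lambda_partition
  Y <- matrix(pw$dm, ncol = k_all)[vox, sel, drop = FALSE] * (lam / m0[vox])

  # model basis: dM_k at unit CBF and unit blood M0, per candidate ATT
  # (nk x n_att); candidates whose basis is entirely zero (label never
  # arrives before any readout) are unusable and dropped
  G <- vapply(att_grid, function(a)
    vapply(seq_len(nk), function(k)
      buxton_signal(1, a, lds[k] + plds[k], lds[k], 1, params),
      numeric(1)),
    numeric(nk))
  gg <- colSums(G^2)
  usable <- gg > 0
  if (!any(usable)) stop("no usable ATT candidates within att_bounds")
  att_grid <- att_grid[usable]
  G <- G[, usable, drop = FALSE]
  gg <- gg[usable]
  yy <- rowSums(Y^2)
  num <- Y %*% G                         # vox x n_att
  fhat <- sweep(num, 2, gg, `/`)
  fhat[fhat < 0] <- 0
  rss <- yy - 2 * fhat * num + sweep(fhat^2, 2, gg, `*`)
  best <- max.col(-rss, ties.method = "first")
  f <- fhat[cbind(seq_along(vox), best)]
  att <- att_grid[best]

  low <- yy <= .Machine$double.eps * nk | f == 0
  att[low] <- att_bounds[1]

  cbf_v <- array(NA_real_, pw$grid$shape)
  att_v <- array(NA_real_, pw$grid$shape)
  cbf_v[vox] <- f
  att_v[vox] <- att
  lowv <- array(FALSE, pw$grid$shape)
  lowv[vox] <- low
  valid <- array(FALSE, pw$grid$shape)
  valid[vox] <- TRUE
  list(cbf = cbf_map(cbf_v, pw$grid, modality = "asl_te",
                     scale = "absolute", valid = valid),
       att = structure(list(grid = pw$grid, values = att_v, valid = valid),
                       class = "att_map"),
       low_confidence = lowv)
}

#' Rescale a CBF map so its brain mean equals a measured whole-brain CBF
#'
#' Intensity normalization to the whole-brain perfusion measured by
#' phase-contrast MRI: one global scale factor, so relative spatial
#' structure is preserved and the operation is idempotent.
#'
#' @param map A [cbf_map()].
#' @param f_wb Target whole-brain CBF, ml/100 g/min.
#' @param brain_mask Logical volume defining "whole brain".
#' @return A rescaled absolute [cbf_map()].
#' @export
normalize_to_wb <- function(map, f_wb, brain_mask) {
  stopifnot(inherits(map, "cbf_map"))
  check_volume(brain_mask, map$grid, "brain_mask")
  mu <- mean(map$values[brain_mask & map$valid])
  if (!is.finite(mu) || mu <= 0)
    stop("brain mean of the map is not positive; cannot normalize")
  values <- map$values * (f_wb / mu)
  cbf_map(values, map$grid, modality = map$modality, scale = "absolute",
          valid = map$valid)
}

#' Relative CBF (normalized to a reference region mean)
#'
#' @param map A [cbf_map()].
#' @param reference Logical volume (whole-brain mask or a named reference
#'   region such as the occipital sector of the synthetic atlas).
#' @return A relative [cbf_map()] (values are multiples of the reference
#'   mean).
#' @export
relative_cbf <- function(map, reference) {
  stopifnot(inherits(map, "cbf_map"))
  check_volume(reference, map$grid, "reference mask")
  v <- map$values[reference & map$valid]
  if (length(v) == 0L) stop("reference region is empty (no valid voxels)")
  mu <- mean(v)
  if (!is.finite(mu) || mu <= 0) stop("reference mean must be > 0")
  cbf_map(map$values / mu, map$grid, modality = map$modality,
          scale = "relative", valid = map$valid)
}
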