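test_that("single-compartment signal follows its piecewise closed form", {
  par <- asl_params()
  # before label arrival the signal is zero
  expect_equal(buxton_signal(60, 1500, 1000, 1800, 900, par), 0)
  # zero labeling efficiency kills the signal everywhere
  par0 <- asl_params(constants = kinetic_constants(labeling_efficiency =
                                                     1e-12))
  expect_lt(abs(buxton_signal(60, 500, 3800, 1800, 900, par0)), 1e-9)
  # rising-segment endpoint: term-by-term hand evaluation
  f <- 60; att <- 500; ld <- 1800; m0 <- 900
  t <- att + ld
  t1b <- 1.65; alpha <- 0.85; bsf <- 0.83
  hand <- 2 * alpha * m0 * (f / 6000) * t1b * exp(-0.5 / t1b) *
    (1 - exp(-1.8 / t1b)) * bsf
  expect_equal(buxton_signal(f, att, t, ld, m0, par), hand,
               tolerance = 1e-12)
  expect_error(buxton_signal(60, -1, 100, 1800, 900, par), "att")
  expect_error(buxton_signal(60, 500, 100, 0, 900, par), "ld")
})

test_that("SD simulation produces the modeled pairwise difference", {
  grid <- tiny_grid()
  # zero flow -> all differences zero
  ph0 <- small_phantom(grid)
  ph0$true_cbf[] <- 0
  acq0 <- simulate_asl_sd(ph0, n_pairs = 3)
  expect_true(all(pairwise_subtract(acq0)$dm == 0))
  # noiseless mean difference equals the model signal voxelwise
  ph <- small_phantom(grid)
  par <- asl_params()
  acq <- simulate_asl_sd(ph, par, n_pairs = 4)
  pw <- pairwise_subtract(acq)
  dm_expect <- buxton_signal(ph$true_cbf, ph$true_att,
                             par$label_duration + par$post_label_delay,
                             par$label_duration,
                             ph$m0 / par$constants$lambda_partition, par)
  expect_equal(pw$dm[, , , 1], dm_expect, tolerance = 1e-12)
  # odd volume counts are rejected
  odd <- acq
  odd$volumes <- acq$volumes[, , , 1:5]
  expect_error(pairwise_subtract(odd), "odd")
})

test_that("per-pair difference noise scales as sqrt(2) times volume noise", {
  grid <- tiny_grid()
  ph <- small_phantom(grid)
  ph$true_cbf[] <- 0                      # pure-noise differences
  acq <- simulate_asl_sd(ph, n_pairs = 16, noise_sd = 3, seed = 11)
  nvol <- dim(acq$volumes)[4]
  d <- acq$volumes[, , , seq(1, nvol, 2)] - acq$volumes[, , , seq(2, nvol, 2)]
  expect_equal(sd(as.vector(d)), sqrt(2) * 3, tolerance = 0.15 * sqrt(2) * 3)
})

test_that("SD quantification inverts the signal model where ATT <= PLD", {
  ph <- small_phantom()
  par <- asl_params()
  map <- quantify_sd_cbf(pairwise_subtract(simulate_asl_sd(ph, par)),
                         ph$m0, par)
  ok <- ph$brain_mask & ph$true_cbf > 0 &
    ph$true_att <= par$post_label_delay
  relerr <- abs(map$values[ok] - ph$true_cbf[ok]) / ph$true_cbf[ok]
  expect_lt(max(relerr), 0.02)
  # zero difference signal -> zero CBF
  pw0 <- pairwise_subtract(simulate_asl_sd(ph, par))
  pw0$dm[] <- 0
  expect_true(all(quantify_sd_cbf(pw0, ph$m0, par)$values[ph$m0 > 0] == 0))
  # homogeneity: degree 1 in dm, degree -1 in m0
  pw <- pairwise_subtract(simulate_asl_sd(ph, par))
  pw2 <- pw; pw2$dm <- 2 * pw$dm
  m1 <- quantify_sd_cbf(pw, ph$m0, par)
  m2 <- quantify_sd_cbf(pw2, 2 * ph$m0, par)
  expect_equal(m1$values[m1$valid], m2$values[m2$valid], tolerance = 1e-12)
})

test_that("TE fit recovers CBF and transit time on self-consistent data", {
  ph <- small_phantom()
  par <- asl_params()
  scheme <- hadamard_scheme()
  fit <- fit_te_cbf_att(hadamard_decode(simulate_asl_te(ph, scheme, par)),
                        ph$m0, par, mask = ph$brain_mask)
  ok <- ph$brain_mask & ph$true_cbf > 0
  relerr <- abs(fit$cbf$values[ok] - ph$true_cbf[ok]) / ph$true_cbf[ok]
  expect_lt(max(relerr), 0.02)
  expect_lt(max(abs(fit$att$values[ok] - ph$true_att[ok])), 50)
  expect_true(all(fit$cbf$values[fit$cbf$valid] >= 0))
})

test_that("an all-zero difference series fits to zero flow, low confidence", {
  ph <- small_phantom(tiny_grid())
  par <- asl_params()
  dec <- hadamard_decode(simulate_asl_te(ph, hadamard_scheme(), par))
  dec$dm[] <- 0
  fit <- fit_te_cbf_att(dec, ph$m0, par, mask = ph$brain_mask)
  inb <- ph$brain_mask
  expect_true(all(fit$cbf$values[inb] == 0))
  expect_true(all(fit$att$values[inb] == 0))
  expect_true(all(fit$low_confidence[inb]))
  expect_error(fit_te_cbf_att(
    structure(list(grid = ph$grid,
                   dm = dec$dm[, , , 1:2, drop = FALSE],
                   effective_plds = dec$effective_plds[1:2],
                   sub_bolus_lds = dec$sub_bolus_lds[1:2],
                   params = par),
              class = "perfusion_weighted_set"),
    ph$m0, par), "at least 3")
})

test_that("TE flow estimates are unbiased across the transit-time sweep", {
  # single-voxel phantoms across ATT 700-1700 ms at fixed true CBF 50
  par <- asl_params()
  scheme <- hadamard_scheme()
  tim <- hadamard_timing(scheme)
  grid <- voxel_grid(c(3L, 3L, 3L), 8)
  # 1700 ms itself is excluded: there the label reaches only the
  # free-lunch readout and (f, att) is no longer identifiable
  for (att in seq(700, 1600, by = 225)) {
    ph <- build_phantom(grid, gm_cbf = 60, wm_cbf = 20, seed = 1)
    ph$brain_mask[] <- TRUE
    ph$true_cbf[] <- 50
    ph$true_att[] <- att
    ph$m0[] <- 900
    fit <- fit_te_cbf_att(hadamard_decode(simulate_asl_te(ph, scheme, par)),
                          ph$m0, par)
    expect_equal(fit$cbf$values[2, 2, 2], 50, tolerance = 0.02)
    expect_lt(abs(fit$att$values[2, 2, 2] - att), 50)
  }
})

test_that("SD and TE quantification agree on noiseless data", {
  # both invert the same kinetic model where ATT is at or below the
  # shortest effective PLD
  ph <- small_phantom()
  par <- asl_params()
  sd_map <- quantify_sd_cbf(pairwise_subtract(simulate_asl_sd(ph, par)),
                            ph$m0, par)
  fit <- fit_te_cbf_att(
    hadamard_decode(simulate_asl_te(ph, hadamard_scheme(), par)),
    ph$m0, par, mask = ph$brain_mask)
  ok <- ph$brain_mask & ph$true_cbf > 0 & ph$true_att <= 2000
  rel <- abs(fit$cbf$values[ok] - sd_map$values[ok]) / sd_map$values[ok]
  expect_lt(max(rel), 0.03)
})

test_that("whole-brain normalization fixes the mean and is idempotent", {
  ph <- small_phantom()
  par <- asl_params()
  map <- quantify_sd_cbf(pairwise_subtract(simulate_asl_sd(ph, par)),
                         ph$m0, par)
  norm <- normalize_to_wb(map, 50, ph$brain_mask)
  expect_equal(mean(norm$values[ph$brain_mask & norm$valid]), 50,
               tolerance = 1e-12)
  # idempotent
  norm2 <- normalize_to_wb(norm, 50, ph$brain_mask)
  expect_equal(norm2$values[norm2$valid], norm$values[norm$valid],
               tolerance = 1e-12)
  # single global scale: voxel ratios preserved
  v <- which(map$valid & map$values > 0)[c(10, 200)]
  expect_equal(norm$values[v[1]] / norm$values[v[2]],
               map$values[v[1]] / map$values[v[2]], tolerance = 1e-12)
})

test_that("relative CBF rescales by the reference-region mean", {
  ph <- small_phantom()
  grid <- ph$grid
  vals <- ph$true_cbf
  map <- cbf_map(vals, grid, modality = "pet", valid = ph$brain_mask)
  rel <- relative_cbf(map, ph$brain_mask)
  expect_equal(rel$scale, "relative")
  mu <- mean(vals[ph$brain_mask])
  expect_equal(rel$values[rel$valid], vals[ph$brain_mask] / mu,
               tolerance = 1e-12)
  # global input scaling leaves the relative map unchanged
  rel2 <- relative_cbf(cbf_map(3 * vals, grid, modality = "pet",
                               valid = ph$brain_mask), ph$brain_mask)
  expect_equal(rel2$values[rel2$valid], rel$values[rel$valid],
               tolerance = 1e-12)
  # two different references differ by the ratio of reference means
  occ <- ph$labels == 1L & ph$true_cbf > 0
  occ[, 1:16, ] <- FALSE                     # a sub-region as reference
  rel3 <- relative_cbf(map, occ)
  ratio <- mean(vals[occ]) / mu
  pos <- rel$valid & vals > 0
  expect_equal(rel$values[pos] / rel3$values[pos],
               rep(ratio, sum(pos)), tolerance = 1e-12)
})
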