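# a compact two-ROI atlas on a small grid for mask-level fixtures
two_roi_atlas <- function(g = voxel_grid(c(20L, 20L, 10L), 2)) {
  lab <- array(0L, g$shape)
  lab[1:10, , ] <- 1L
  lab[11:20, , ] <- 2L
  roi_atlas(lab, g, data.frame(label = 1:2, name = c("A", "B")),
            reference_roi = "B")
}

test_that("ROI hypoperfusion calls respect the in-ROI extent rule", {
  atl <- two_roi_atlas()
  g <- atl$grid
  # empty mask: nothing flagged
  cls0 <- classify_roi_hypoperfusion(array(FALSE, g$shape), atl, 65)
  expect_false(any(cls0$hypoperfused))
  # 70-voxel blob fully inside ROI A (7 x 5 x 2)
  m <- array(FALSE, g$shape)
  m[2:8, 2:6, 2:3] <- TRUE
  cls <- classify_roi_hypoperfusion(m, atl, 65)
  expect_true(cls$hypoperfused[cls$roi == "A"])
  expect_false(cls$hypoperfused[cls$roi == "B"])
  expect_equal(cls$largest_cluster[cls$roi == "A"], 70L)
  # 70-voxel blob straddling A (40) and B (30): neither reaches 65
  m2 <- array(FALSE, g$shape)
  m2[7:13, 2:6, 2:3] <- TRUE           # x 7..10 in A (40), 11..13 in B (30)
  cls2 <- classify_roi_hypoperfusion(m2, atl, 65)
  expect_false(any(cls2$hypoperfused))
  expect_equal(sort(cls2$largest_cluster), c(30L, 40L))
  # whole-cluster attribution flags both
  cls3 <- classify_roi_hypoperfusion(m2, atl, 65, whole_cluster = TRUE)
  expect_true(all(cls3$hypoperfused))
})

test_that("sensitivity and specificity follow the contingency counts", {
  mk <- function(flags) data.frame(roi = paste0("r", seq_along(flags)),
                                   label = seq_along(flags),
                                   largest_cluster = 0L,
                                   hypoperfused = flags)
  ref <- mk(c(rep(TRUE, 7), rep(FALSE, 5)))
  tst <- mk(c(rep(TRUE, 5), FALSE, FALSE, TRUE, rep(FALSE, 4)))
  ss <- sensitivity_specificity(tst, ref)
  expect_equal(ss$sensitivity, 5 / 7, tolerance = 1e-12)
  expect_equal(ss$specificity, 4 / 5, tolerance = 1e-12)
  # identity
  ss1 <- sensitivity_specificity(ref, ref)
  expect_equal(ss1$sensitivity, 1)
  expect_equal(ss1$specificity, 1)
  # all-negative test
  ss0 <- sensitivity_specificity(mk(rep(FALSE, 12)), ref)
  expect_equal(ss0$sensitivity, 0)
  expect_equal(ss0$specificity, 1)
  # undefined denominators warn and return NA
  expect_warning(ssna <- sensitivity_specificity(mk(rep(FALSE, 3)),
                                                 mk(rep(FALSE, 3))),
                 "sensitivity")
  expect_true(is.na(ssna$sensitivity))
})

test_that("overlap partition splits shifted blocks as enumerated", {
  d <- c(8L, 8L, 3L)
  ref <- array(FALSE, d); ref[3:5, 3:5, 2] <- TRUE
  tst <- array(FALSE, d); tst[3:5, 4:6, 2] <- TRUE
  p <- overlap_partition(tst, ref)
  expect_equal(p$overlap_pct, 100 * 6 / 9, tolerance = 1e-12)
  expect_equal(p$adjacent_pct, 100 * 3 / 9, tolerance = 1e-12)
  expect_equal(p$isolated_pct, 0)
  # identical masks
  p1 <- overlap_partition(ref, ref)
  expect_equal(unlist(p1), c(overlap_pct = 100, adjacent_pct = 0,
                             isolated_pct = 0))
  # far-away component is isolated
  tst2 <- tst; tst2[7:8, 1, 1] <- TRUE
  p2 <- overlap_partition(tst2, ref)
  expect_equal(p2$isolated_pct, 100 * 2 / 11, tolerance = 1e-12)
  # percentages always sum to 100
  expect_equal(p2$overlap_pct + p2$adjacent_pct + p2$isolated_pct, 100,
               tolerance = 1e-9)
  expect_error(overlap_partition(array(FALSE, d), ref), "empty")
})

test_that("jaccard matches set arithmetic and its identities", {
  d <- c(6L, 6L, 2L)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[1:2, 1, 1] <- TRUE
  b[2:3, 1, 1] <- TRUE
  expect_equal(jaccard(a, b), 1 / 3, tolerance = 1e-12)
  expect_equal(jaccard(a, a), 1)
  b2 <- array(FALSE, d); b2[5:6, 5, 2] <- TRUE
  expect_equal(jaccard(a, b2), 0)
  expect_equal(jaccard(array(FALSE, d), array(FALSE, d)), 0)
  # symmetry, and the subset identity J = |test| / |ref|
  expect_equal(jaccard(a, b), jaccard(b, a))
  sub <- array(FALSE, d); sub[1, 1, 1] <- TRUE
  expect_equal(jaccard(sub, a), 1 / 2, tolerance = 1e-12)
  # cross-check against the overlap partition on the subset case
  p <- overlap_partition(sub, a)
  expect_equal(p$adjacent_pct + p$isolated_pct, 0)
})

test_that("cluster volume change is the signed percent difference", {
  d <- c(10L, 10L, 2L)
  ref <- array(FALSE, d); ref[1:10, 1:10, 1] <- TRUE   # 100 voxels
  tst <- array(FALSE, d); tst[1:10, 1:8, 1] <- TRUE    # 80 voxels
  expect_equal(cluster_volume_change(ref, tst), 20, tolerance = 1e-12)
  expect_equal(cluster_volume_change(ref, ref), 0)
  expect_equal(cluster_volume_change(ref, array(FALSE, d)), 100)
  expect_error(cluster_volume_change(array(FALSE, d), tst), "empty")
})

test_that("ROI means average valid voxels only", {
  atl <- two_roi_atlas()
  g <- atl$grid
  vals <- array(30, g$shape)
  vals[11:20, , ] <- 50
  m <- cbf_map(vals, g, modality = "pet")
  mus <- roi_mean_cbf(m, atl)
  expect_equal(unname(mus), c(30, 50))
  # uniform map: every ROI mean equals the constant
  mu <- roi_mean_cbf(cbf_map(array(7, g$shape), g, modality = "pet"), atl)
  expect_equal(unname(mu), c(7, 7))
  # invalid voxels are excluded (brute-force oracle)
  valid <- array(TRUE, g$shape); valid[1:5, , ] <- FALSE
  m2 <- cbf_map(vals, g, modality = "pet", valid = valid)
  mus2 <- roi_mean_cbf(m2, atl)
  oracle <- mean(vals[atl$labels == 1L & valid])
  expect_equal(unname(mus2["A"]), oracle, tolerance = 1e-12)
})

test_that("ROI regression recovers affine relations and Pearson r", {
  x <- c(20, 30, 40, 55, 60, 75)
  fit1 <- regress_rois(x, x)
  expect_equal(fit1$intercept, 0, tolerance = 1e-10)
  expect_equal(fit1$slope, 1, tolerance = 1e-12)
  expect_equal(fit1$r, 1, tolerance = 1e-12)
  fit2 <- regress_rois(x, 2 * x + 3)
  expect_equal(fit2$intercept, 3, tolerance = 1e-9)
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  # anticorrelated points: r against the formula oracle
  y <- c(5, 4, 4, 2, 2, 1)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(regress_rois(x, y)$r, r_oracle, tolerance = 1e-12)
  expect_error(regress_rois(rep(3, 5), 1:5), "variance")
  expect_error(regress_rois(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman bias and limits use the sample SD", {
  x <- c(10, 20, 30, 40)
  ba0 <- bland_altman(x, x)
  expect_equal(unlist(ba0), c(bias = 0, lower = 0, upper = 0))
  # d = {+2, -2}: bias 0, limits +-1.96 * 2.828
  ba <- bland_altman(c(0, 0), c(2, -2))
  expect_equal(ba$bias, 0)
  expect_equal(ba$upper, 1.96 * sqrt(8), tolerance = 1e-12)
  expect_equal(ba$upper, 5.544, tolerance = 1e-3)
  ba5 <- bland_altman(x, x + 5)
  expect_equal(unlist(ba5), c(bias = 5, lower = 5, upper = 5))
})

test_that("group ROI tests match hand-computed Welch statistics", {
  pat <- cbind(a = c(1, 2, 3))
  ctl <- cbind(a = c(4, 5, 6))
  res <- group_roi_test(pat, ctl)
  # means 2 vs 5, each variance 1, se = sqrt(2/3)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  res0 <- group_roi_test(pat, pat)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # label swap flips the sign, p unchanged
  resw <- group_roi_test(ctl, pat)
  expect_equal(resw$t, -res$t)
  expect_equal(resw$p, res$p)
  # paired mode equals stats::t.test paired oracle
  set.seed(4)
  a <- matrix(rnorm(10), 5, 2); b <- matrix(rnorm(10), 5, 2)
  rp <- group_roi_test(a, b, mode = "paired")
  or <- t.test(a[, 2], b[, 2], paired = TRUE)
  expect_equal(rp$t[2], unname(or$statistic), tolerance = 1e-12)
  expect_error(group_roi_test(pat[1, , drop = FALSE], ctl), "2 subjects")
})

test_that("column summaries reproduce published per-patient tables", {
  tab <- ftd_overlap_metrics()
  expect_equal(nrow(tab), 36L)
  flte_abs <- tab[tab$modality == "flte" & tab$scale == "absolute", ]
  s <- summarize_columns(flte_abs[, c("overlap", "adjacent", "isolated")],
                         digits = 1)
  expect_equal(s$overlap[1], 29.9)
  expect_equal(s$adjacent[1], 56.2)
  sj <- summarize_columns(flte_abs[, "jaccard", drop = FALSE], digits = 2)
  expect_equal(sj$jaccard[1], 0.11)
  # degenerate cases
  cc <- summarize_columns(data.frame(v = c(5, 5, 5)), digits = 2)
  expect_equal(cc$v, c(5, 0))
  two <- summarize_columns(data.frame(v = c(0, 100)), digits = 2)
  expect_equal(two$v, c(50, 70.71))
  expect_error(summarize_columns(data.frame(v = 1)), "2 rows")
})
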