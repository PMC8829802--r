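#' Classify atlas ROIs as hypoperfused
#'
#' An ROI is flagged hypoperfused when the largest connected component of
#' the hypoperfusion mask *restricted to that ROI* reaches the minimum
#' cluster extent. Restricting components to within the ROI means a
#' cluster straddling two ROIs counts only its in-ROI voxels in each
#' (switch with `whole_cluster = TRUE`, which attributes a cluster's full
#' size to every ROI it touches).
#'
#' @param mask Logical hypoperfusion mask.
#' @param atlas A [roi_atlas()] on the same grid.
#' @param min_voxels Extent threshold from [min_cluster_extent()].
#' @param connectivity 6, 18 or 26.
#' @param whole_cluster Attribute whole-cluster sizes across ROI borders.
#' @return A data.frame (`roi`, `label`, `largest_cluster`, `hypoperfused`)
#'   of class `roi_classification`.
#' @export
classify_roi_hypoperfusion <- function(mask, atlas, min_voxels,
                                       connectivity = 26,
                                       whole_cluster = FALSE) {
  stopifnot(inherits(atlas, "roi_atlas"))
  check_volume(mask, atlas$grid, "mask")
  res <- lapply(seq_len(nrow(atlas$names)), function(i) {
    lb <- atlas$names$label[i]
    roi <- atlas$labels == lb
    if (whole_cluster) {
      cl <- label_clusters(mask, connectivity)
      in_roi <- unique(cl$labels[roi & mask])
      in_roi <- in_roi[in_roi > 0]
      largest <- if (length(in_roi)) max(cl$sizes[in_roi]) else 0L
    } else {
      cl <- label_clusters(mask & roi, connectivity)
      largest <- if (length(cl$sizes)) max(cl$sizes) else 0L
    }
    data.frame(roi = atlas$names$name[i], label = lb,
               largest_cluster = as.integer(largest),
               hypoperfused = largest >= min_voxels)
  })
  out <- do.call(rbind, res)
  class(out) <- c("roi_classification", class(out))
  out
}

#' Sensitivity and specificity of ROI-level hypoperfusion calls
#'
#' Agreement of the test modality's ROI calls against the reference
#' modality (not diagnostic accuracy): sensitivity is the proportion of
#' reference-positive ROIs also called positive by the test; specificity
#' the proportion of reference-negative ROIs also called negative.
#'
#' @param test,reference `roi_classification` tables with one common ROI
#'   roster.
#' @return List with `sensitivity` and `specificity` (NA with a warning
#'   when the corresponding denominator is empty).
#' @export
sensitivity_specificity <- function(test, reference) {
  if (!identical(test$roi, reference$roi))
    stop("test and reference must share one ROI roster")
  refp <- reference$hypoperfused
  tp <- test$hypoperfused
  sens <- if (sum(refp) == 0L) {
    warning("no reference-positive ROIs; sensitivity undefined")
    NA_real_
  } else sum(tp & refp) / sum(refp)
  spec <- if (sum(!refp) == 0L) {
    warning("no reference-negative ROIs; specificity undefined")
    NA_real_
  } else sum(!tp & !refp) / sum(!refp)
  list(sensitivity = sens, specificity = spec)
}

#' Partition test-mask voxels into overlapping / adjacent / isolated
#'
#' Overlapping voxels are detected by both modalities; the remaining
#' test-only voxels are grouped into connected components, and a
#' component touching any overlap voxel (under the connectivity) is
#' adjacent while the rest are isolated. All three are percentages of the
#' test-mask voxel count and sum to 100.
#'
#' @param test_mask,ref_mask Logical volumes on one grid; `test_mask`
#'   non-empty.
#' @param connectivity 6, 18 or 26.
#' @return Named list `overlap_pct`, `adjacent_pct`, `isolated_pct`.
#' @export
overlap_partition <- function(test_mask, ref_mask, connectivity = 26) {
  stopifnot(identical(dim(test_mask), dim(ref_mask)))
  n_test <- sum(test_mask)
  if (n_test == 0L) stop("test mask is empty; percentages undefined")
  ov <- test_mask & ref_mask
  rest <- test_mask & !ov
  n_adj <- 0L
  if (any(rest)) {
    cl <- label_clusters(rest, connectivity)
    near_ov <- dilate_mask(ov, connectivity)
    adj_labels <- unique(cl$labels[rest & near_ov])
    adj_labels <- adj_labels[adj_labels > 0]
    if (length(adj_labels)) n_adj <- sum(cl$sizes[adj_labels])
  }
  n_ov <- sum(ov)
  n_iso <- n_test - n_ov - n_adj
  list(overlap_pct = 100 * n_ov / n_test,
       adjacent_pct = 100 * n_adj / n_test,
       isolated_pct = 100 * n_iso / n_test)
}

#' Jaccard similarity of two binary masks
#'
#' Intersection over union; 0 when both masks are empty.
#' @param mask_a,mask_b Logical volumes on one grid.
#' @return Value in [0, 1].
#' @export
jaccard <- function(mask_a, mask_b) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  u <- sum(mask_a | mask_b)
  if (u == 0L) return(0)
  sum(mask_a & mask_b) / u
}

#' Percent change in cluster volume between reference and test masks
#'
#' `100 * (|ref| - |test|) / |ref|`; positive when the test modality
#' detects a smaller volume than the reference.
#' @param ref_mask,test_mask Logical volumes.
#' @return Percent change.
#' @export
cluster_volume_change <- function(ref_mask, test_mask) {
  n_ref <- sum(ref_mask)
  if (n_ref == 0L) stop("reference mask is empty")
  100 * (n_ref - sum(test_mask)) / n_ref
}

#' Mean CBF per atlas ROI
#'
#' @param map A [cbf_map()].
#' @param atlas A [roi_atlas()] on the same grid.
#' @return Named numeric vector of means over valid voxels (NA where an
#'   ROI has no valid voxel).
#' @export
roi_mean_cbf <- function(map, atlas) {
  stopifnot(inherits(map, "cbf_map"), inherits(atlas, "roi_atlas"))
  stop_if_grid_mismatch(map$grid, atlas$grid, "map vs atlas")
  out <- vapply(atlas$names$label, function(lb) {
    v <- map$values[atlas$labels == lb & map$valid]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  names(out) <- atlas$names$name
  out
}

#' Ordinary least-squares agreement of two sets of ROI means
#'
#' @param x_means,y_means Paired per-ROI values (>= 3 finite pairs);
#'   regression of y on x.
#' @return List `intercept`, `slope`, `r` (Pearson).
#' @export
regress_rois <- function(x_means, y_means) {
  ok <- is.finite(x_means) & is.finite(y_means)
  x <- x_means[ok]; y <- y_means[ok]
  if (length(x) < 3L) stop("need at least 3 paired finite values")
  if (stats::var(x) == 0) stop("zero variance in x; regression undefined")
  fit <- stats::lm(y ~ x)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r = stats::cor(x, y))
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = y - x`; bias is `mean(d)` and the 95% limits of
#' agreement are `bias +- 1.96 sd(d)` (sample SD).
#'
#' @param x_means,y_means Paired values (>= 2 finite pairs).
#' @return List `bias`, `lower`, `upper`.
#' @export
bland_altman <- function(x_means, y_means) {
  ok <- is.finite(x_means) & is.finite(y_means)
  d <- y_means[ok] - x_means[ok]
  if (length(d) < 2L) stop("need at least 2 pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s)
}

#' Per-ROI group comparison of ROI means
#'
#' Compares patients to controls ROI by ROI. The default is Welch's
#' unequal-variance two-sample t-test (patients and controls are
#' independent subjects); `mode = "paired"` performs a paired t-test and
#' is appropriate when the two matrices are the same subjects measured by
#' two modalities.
#'
#' @param patient_values,control_values Matrices, subjects x ROIs, with
#'   matching ROI columns; >= 2 subjects per group.
#' @param mode `"welch"` or `"paired"`.
#' @return data.frame `roi`, `t`, `p` (two-sided).
#' @export
group_roi_test <- function(patient_values, control_values,
                           mode = c("welch", "paired")) {
  mode <- match.arg(mode)
  patient_values <- as.matrix(patient_values)
  control_values <- as.matrix(control_values)
  if (ncol(patient_values) != ncol(control_values))
    stop("ROI columns must match")
  if (nrow(patient_values) < 2L || nrow(control_values) < 2L)
    stop("need at least 2 subjects per group")
  rois <- colnames(patient_values)
  if (is.null(rois)) rois <- paste0("roi_", seq_len(ncol(patient_values)))
  res <- lapply(seq_len(ncol(patient_values)), function(j) {
    ht <- if (mode == "welch")
      stats::t.test(patient_values[, j], control_values[, j])
    else
      stats::t.test(patient_values[, j], control_values[, j], paired = TRUE)
    data.frame(roi = rois[j], t = unname(ht$statistic),
               p = ht$p.value)
  })
  do.call(rbind, res)
}

#' Column summaries in "mean +- SD" style
#'
#' Column means and sample SDs of a per-subject metric table, rounded to
#' a configurable precision per column (percent columns are convention-
#' ally printed to 1 decimal, similarity indices to 2).
#'
#' @param values data.frame or matrix of numeric columns (>= 2 rows).
#' @param digits Integer scalar or per-column vector of rounding digits.
#' @return data.frame with rows `mean` and `sd`.
#' @export
summarize_columns <- function(values, digits = 1) {
  values <- as.data.frame(values)
  num <- vapply(values, is.numeric, logical(1))
  values <- values[num]
  if (nrow(values) < 2L) stop("need at least 2 rows")
  digits <- rep_len(digits, ncol(values))
  mu <- mapply(function(v, d) round(mean(v), d), values, digits)
  s <- mapply(function(v, d) round(stats::sd(v), d), values, digits)
  out <- rbind(mean = mu, sd = s)
  as.data.frame(out)
}

#' Full concordance summary for one subject's pair of modalities
#'
#' Bundles the mask-level metrics between a test-modality hypoperfusion
#' mask and the reference-modality mask: ROI sensitivity/specificity,
#' overlap partition, Jaccard and cluster-volume change.
#'
#' @param test_mask,ref_mask Logical hypoperfusion masks.
#' @param atlas A [roi_atlas()].
#' @param min_voxels Cluster-extent threshold.
#' @param connectivity 6, 18 or 26.
#' @return One-row data.frame of class `concordance_summary`.
#' @export
concordance_summary <- function(test_mask, ref_mask, atlas, min_voxels,
                                connectivity = 26) {
  test_cls <- classify_roi_hypoperfusion(test_mask, atlas, min_voxels,
                                         connectivity)
  ref_cls <- classify_roi_hypoperfusion(ref_mask, atlas, min_voxels,
                                        connectivity)
  ss <- sensitivity_specificity(test_cls, ref_cls)
  part <- if (sum(test_mask) > 0)
    overlap_partition(test_mask, ref_mask, connectivity)
  else list(overlap_pct = NA_real_, adjacent_pct = NA_real_,
            isolated_pct = NA_real_)
  vc <- if (sum(ref_mask) > 0) cluster_volume_change(ref_mask, test_mask)
  else NA_real_
  out <- data.frame(sensitivity = ss$sensitivity,
                    specificity = ss$specificity,
                    overlap_pct = part$overlap_pct,
                    adjacent_pct = part$adjacent_pct,
                    isolated_pct = part$isolated_pct,
                    jaccard = jaccard(test_mask, ref_mask),
                    volume_change_pct = vc)
  class(out) <- c("concordance_summary", class(out))
  out
}
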