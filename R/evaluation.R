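#' Voxel-wise ROC curve and AUC
#'
#' Computes the empirical ROC over brain-mask voxels (prediction score vs.
#' binary ground truth) and its area by the trapezoidal rule. For cross-case
#' vertical averaging, sensitivity is also returned on a fixed
#' false-positive-rate grid (linear interpolation of the empirical curve).
#' AUC depends only on the ranking of the scores, so it is invariant under
#' strictly monotone transforms of the probabilities.
#'
#' @param map A `probability_map` or 3D numeric array of scores.
#' @param gt Binary ground-truth array, same shape.
#' @param brain_mask Optional binary mask restricting the voxels used
#'   (default: all voxels).
#' @param fpr_grid FPR grid for the interpolated curve.
#' @return List with `auc`, `curve` (data frame fpr/tpr) and `grid`
#'   (data frame fpr/sensitivity on `fpr_grid`).
#' @export
roc_auc <- function(map, gt, brain_mask = NULL, fpr_grid = seq(0, 1, by = 0.01)) {
  vals <- if (inherits(map, "probability_map")) map$values else map
  sel <- if (is.null(brain_mask)) rep(TRUE, length(vals)) else brain_mask != 0
  scores <- as.numeric(vals)[sel]
  labels <- as.integer(gt != 0)[sel]
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    abort("ROC requires at least one positive and one negative voxel in the mask")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(1L - lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # one point per distinct score
  tpr <- c(0, tp[keep] / n_pos)
  fpr <- c(0, fp[keep] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  ## vertical averaging grid: max tpr at each distinct fpr, then linear interp
  mx <- tapply(tpr, fpr, max)
  ufpr <- as.numeric(names(mx))
  sens <- stats::approx(ufpr, as.numeric(mx), xout = fpr_grid, rule = 2)$y
  list(auc = auc,
       curve = data.frame(fpr = fpr, tpr = tpr),
       grid = data.frame(fpr = fpr_grid, sensitivity = sens))
}

#' Youden-index threshold from a validation set
#'
#' Pools all validation voxels and returns the probability threshold
#' maximising the Youden index J = sensitivity + specificity - 1, where a
#' voxel is called positive iff its probability is >= the threshold.
#' Candidate thresholds are the observed probability values plus {0, 1}; ties
#' in J are broken toward the larger threshold.
#'
#' @param maps A `probability_map`/array or list of them (validation cases).
#' @param gts Matching ground-truth array or list.
#' @param brain_masks Optional matching mask or list.
#' @return List with `threshold`, `youden` (the maximised J) and the
#'   candidate table.
#' @export
youden_threshold <- function(maps, gts, brain_masks = NULL) {
  as_list <- function(x) if (is.list(x) && !inherits(x, "probability_map") &&
                             !is.array(x)) x else list(x)
  maps <- as_list(maps); gts <- as_list(gts)
  if (!is.null(brain_masks)) brain_masks <- as_list(brain_masks)
  if (length(maps) != length(gts)) abort("maps and gts must have equal length")
  scores <- numeric(0); labels <- integer(0)
  for (i in seq_along(maps)) {
    vals <- if (inherits(maps[[i]], "probability_map")) maps[[i]]$values else maps[[i]]
    sel <- if (is.null(brain_masks)) rep(TRUE, length(vals)) else brain_masks[[i]] != 0
    scores <- c(scores, as.numeric(vals)[sel])
    labels <- c(labels, as.integer(gts[[i]] != 0)[sel])
  }
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    abort("Youden threshold requires both classes in the pooled validation voxels")
  cand <- sort(unique(c(0, 1, scores)))
  sp <- sort(scores[labels == 1L])
  sn <- sort(scores[labels == 0L])
  tp <- n_pos - findInterval(cand, sp, left.open = TRUE)  # #(pos >= t)
  fp <- n_neg - findInterval(cand, sn, left.open = TRUE)
  j <- tp / n_pos - fp / n_neg
  best <- max(j)
  thr <- max(cand[j == best])  # ties toward the larger threshold
  list(threshold = thr, youden = best,
       candidates = data.frame(threshold = cand, sensitivity = tp / n_pos,
                               fpr = fp / n_neg, youden = j))
}

#' Voxel-wise segmentation metrics
#'
#' Dice, IoU (Jaccard), precision, recall and false-positive rate from the
#' voxel counts TP/FP/FN/TN within the brain mask. Degenerate cases follow
#' fixed conventions: recall = 1 when the ground truth is empty; precision =
#' 1 when there are neither predicted positives nor ground truth; Dice (and
#' IoU) = 1 when both are empty and 0 when exactly one is; FPR = 0 when there
#' are no negatives.
#'
#' @param pred Binary prediction array.
#' @param gt Binary ground-truth array, same shape.
#' @param brain_mask Optional binary mask (default all voxels).
#' @return One-row data frame: dice, iou, precision, recall, fpr, tp, fp, fn, tn.
#' @export
voxel_metrics <- function(pred, gt, brain_mask = NULL) {
  if (!identical(dim(pred), dim(gt))) abort("pred and gt shapes differ")
  sel <- if (is.null(brain_mask)) rep(TRUE, length(pred)) else brain_mask != 0
  p <- as.integer(pred != 0)[sel]
  g <- as.integer(gt != 0)[sel]
  tp <- sum(p == 1L & g == 1L); fp <- sum(p == 1L & g == 0L)
  fn <- sum(p == 0L & g == 1L); tn <- sum(p == 0L & g == 0L)
  dice <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  iou <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  precision <- if (tp + fp == 0) { if (tp + fn == 0) 1 else 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  fpr <- if (fp + tn == 0) 0 else fp / (fp + tn)
  data.frame(dice = dice, iou = iou, precision = precision, recall = recall,
             fpr = fpr, tp = tp, fp = fp, fn = fn, tn = tn)
}

## the 13 positive-direction neighbour offsets of 26-connectivity
conn26_offsets <- local({
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  g[g$dk > 0 | (g$dk == 0 & (g$dj > 0 | (g$dj == 0 & g$di > 0))), ]
})

#' Label 26-connected components of a binary mask
#'
#' Voxels are considered connected when their faces, edges or corners touch
#' (26-connectivity). Components are labelled 1..n in order of their first
#' voxel (column-major), and each component's volume is its voxel count times
#' the voxel volume.
#'
#' @param mask 3D binary array.
#' @param spacing Voxel spacing (mm), length 3; default 1 mm isotropic.
#' @return Object of class `lesion_label_map`: `labels` (3D integer array, 0 =
#'   background), `volumes_mm3` (per-label), `connectivity` (26).
#' @export
label_components <- function(mask, spacing = c(1, 1, 1)) {
  shp <- dim(mask)
  if (length(shp) != 3) abort("mask must be a 3D array")
  fg <- which(mask != 0)
  labels <- array(0L, shp)
  if (length(fg) == 0)
    return(structure(list(labels = labels, volumes_mm3 = numeric(0),
                          connectivity = 26L, voxel_spacing = spacing),
                     class = "lesion_label_map"))
  vid <- array(0L, shp)
  vid[fg] <- seq_along(fg)
  co <- arrayInd(fg, shp)
  edges <- vector("list", nrow(conn26_offsets))
  for (r in seq_len(nrow(conn26_offsets))) {
    di <- conn26_offsets$di[r]; dj <- conn26_offsets$dj[r]; dk <- conn26_offsets$dk[r]
    ni <- co[, 1] + di; nj <- co[, 2] + dj; nk <- co[, 3] + dk
    ok <- ni >= 1L & ni <= shp[1] & nj >= 1L & nj <= shp[2] & nk >= 1L & nk <= shp[3]
    if (!any(ok)) next
    nlin <- (nk[ok] - 1L) * shp[1] * shp[2] + (nj[ok] - 1L) * shp[1] + ni[ok]
    nv <- vid[nlin]
    hit <- nv > 0L
    if (any(hit))
      edges[[r]] <- cbind(vid[fg[ok]][hit], nv[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  relab <- match(memb, unique(memb))  # consecutive labels, first-voxel order
  labels[fg] <- relab
  vol_vox <- tabulate(relab)
  structure(list(labels = labels,
                 volumes_mm3 = vol_vox * prod(spacing),
                 connectivity = 26L,
                 voxel_spacing = spacing),
            class = "lesion_label_map")
}

#' Count false-positive lesions
#'
#' A predicted connected component is a false positive iff its voxel-wise
#' product with the ground truth is identically zero (no overlap with any
#' true lesion). Components smaller than `min_volume_mm3` are excluded before
#' counting; `min_volume_mm3 = 0` gives the "no size limit" count and 10 mm^3
#' (roughly 2 mm in linear dimension) the size-limited count.
#'
#' @param pred_components A `lesion_label_map` of the thresholded prediction
#'   (or a binary array, labelled internally with `spacing`).
#' @param gt Binary ground-truth array.
#' @param min_volume_mm3 Minimum component volume (mm^3) to count.
#' @param spacing Used only when `pred_components` is a bare array.
#' @return Integer count of false-positive components.
#' @export
count_lesion_fp <- function(pred_components, gt, min_volume_mm3 = 0,
                            spacing = c(1, 1, 1)) {
  if (!inherits(pred_components, "lesion_label_map"))
    pred_components <- label_components(pred_components, spacing)
  labs <- pred_components$labels
  if (!identical(dim(labs), dim(gt))) abort("shapes disagree")
  vols <- pred_components$volumes_mm3
  if (length(vols) == 0) return(0L)
  eligible <- which(vols >= min_volume_mm3)
  overlapping <- unique(labs[gt != 0 & labs > 0L])
  sum(!(eligible %in% overlapping))
}

#' Evaluate one case
#'
#' Composes the full per-case protocol: voxel-wise ROC/AUC over the brain
#' mask, thresholding of the probability map, voxel metrics, 26-connected
#' component labelling of the prediction, and lesion-wise false-positive
#' counts without a size limit and with the 10 mm^3 limit.
#'
#' @param map A `probability_map`.
#' @param study The matching [multisequence_study()].
#' @param threshold Probability threshold (typically from
#'   [youden_threshold()] on the validation set).
#' @param fpr_grid FPR grid passed to [roc_auc()].
#' @return List of class `case_metrics`: `metrics` (one-row data frame with
#'   auc, dice, iou, precision, recall, fpr, fp_all, fp_10mm3,
#'   threshold_used) and `roc` (the per-case grid curve).
#' @export
evaluate_case <- function(map, study, threshold,
                          fpr_grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(study, "multisequence_study"))
  roc <- roc_auc(map, study$ground_truth, study$brain_mask, fpr_grid)
  pred <- binarize(map, threshold)
  vm <- voxel_metrics(pred, study$ground_truth, study$brain_mask)
  comp <- label_components(pred, study$voxel_spacing)
  fp_all <- count_lesion_fp(comp, study$ground_truth, 0)
  fp_10 <- count_lesion_fp(comp, study$ground_truth, 10)
  metrics <- data.frame(auc = roc$auc, dice = vm$dice, iou = vm$iou,
                        precision = vm$precision, recall = vm$recall,
                        fpr = vm$fpr, fp_all = fp_all, fp_10mm3 = fp_10,
                        threshold_used = threshold)
  structure(list(metrics = metrics, roc = roc$grid), class = "case_metrics")
}

#' Compare two models on a per-case metric
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on the per-case values of
#' one metric, with significance declared at alpha = 0.05. When every value
#' in both groups is identical the test is degenerate and p = 1 is returned.
#'
#' @param metrics_a,metrics_b Data frames of per-case metrics (rows = cases)
#'   or numeric vectors.
#' @param metric Column name when data frames are given.
#' @param alpha Significance level.
#' @return List with `p_value`, `significant`, `statistic`, `metric`.
#' @export
compare_models <- function(metrics_a, metrics_b, metric = "dice", alpha = 0.05) {
  x <- if (is.data.frame(metrics_a)) metrics_a[[metric]] else as.numeric(metrics_a)
  y <- if (is.data.frame(metrics_b)) metrics_b[[metric]] else as.numeric(metrics_b)
  if (length(x) == 0 || length(y) == 0) abort("both groups must be nonempty")
  if (length(unique(c(x, y))) == 1L) {
    return(list(p_value = 1, significant = FALSE, statistic = NA_real_,
                metric = metric))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(p_value = p, significant = p <= alpha,
       statistic = unname(wt$statistic), metric = metric)
}

#' Summarise a cohort of case metrics
#'
#' Mean and sample standard deviation of every metric across cases, plus the
#' vertically averaged ROC: at each FPR grid point, the mean per-case
#' sensitivity with a normal-approximation 95% confidence band
#' (mean +/- 1.96 * sd / sqrt(n)).
#'
#' @param cases List of `case_metrics` (from [evaluate_case()]), or a data
#'   frame of per-case metric rows.
#' @return List of class `cohort_summary`: `table` (metric, mean, sd, n),
#'   `per_case` (the stacked metric rows) and, when ROC curves are available,
#'   `roc_band` (fpr, mean, lower, upper).
#' @export
summarize_cohort <- function(cases) {
  if (is.data.frame(cases)) {
    df <- cases
    rocs <- NULL
  } else {
    df <- do.call(rbind, lapply(cases, function(cs) cs$metrics))
    rocs <- lapply(cases, function(cs) cs$roc)
  }
  if (nrow(df) < 2) abort("cohort summary requires at least 2 cases")
  num <- df[vapply(df, is.numeric, logical(1))]
  tab <- data.frame(metric = names(num),
                    mean = vapply(num, mean, numeric(1)),
                    sd = vapply(num, stats::sd, numeric(1)),
                    n = nrow(df), row.names = NULL)
  out <- list(table = tab, per_case = df)
  if (!is.null(rocs)) {
    sens <- sapply(rocs, function(r) r$sensitivity)  # grid x cases
    mu <- rowMeans(sens)
    sdv <- apply(sens, 1, stats::sd)
    half <- 1.96 * sdv / sqrt(ncol(sens))
    out$roc_band <- data.frame(fpr = rocs[[1]]$fpr, mean = mu,
                               lower = pmax(0, mu - half),
                               upper = pmin(1, mu + half))
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary over", x$table$n[1], "cases\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Plot the cohort-averaged ROC with its 95% band
#'
#' @param summary A `cohort_summary` with an ROC band.
#' @return A ggplot object.
#' @export
plot_cohort_roc <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  if (is.null(summary$roc_band)) abort("summary carries no ROC curves")
  df <- summary$roc_band
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "False positive rate", y = "Sensitivity",
                  title = "Case-averaged ROC (95% CI band)") +
    ggplot2::coord_equal()
}
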