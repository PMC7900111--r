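test_that("ROC is perfect on its own labels, rank-invariant, and trapezoid-correct", {
  set.seed(41)
  gt <- random_binary_volume(c(10, 10, 5), 0.2)
  while (sum(gt) == 0) gt <- random_binary_volume(c(10, 10, 5), 0.2)
  perfect <- array(as.numeric(gt), dim(gt))
  expect_equal(roc_auc(perfect, gt)$auc, 1.0)

  scores <- make_scored_map(gt)
  a1 <- roc_auc(scores, gt)$auc
  a2 <- roc_auc(array(plogis(3 * scores - 1), dim(gt)), gt)$auc  # monotone transform
  expect_equal(a1, a2, tolerance = 1e-12)

  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  ref <- pROC::auc(pROC::roc(as.integer(gt), as.numeric(scores), quiet = TRUE,
                             direction = "<"))
  expect_equal(a1, as.numeric(ref), tolerance = 1e-10)
})

test_that("label-independent scores give AUC 0.5 on large volumes", {
  set.seed(42)
  n <- 1e5
  gt <- array(as.integer(runif(n) < 0.05), c(100, 100, 10))
  noise <- array(runif(n), dim(gt))
  expect_lt(abs(roc_auc(noise, gt)$auc - 0.5), 0.02)
  expect_error(roc_auc(noise, array(0L, dim(gt))), "positive")
})

test_that("voxel metrics match a brute-force counting oracle on random volumes", {
  set.seed(43)
  for (i in 1:100) {
    shp <- c(sample(4:8, 1), sample(4:8, 1), sample(3:6, 1))
    pred <- random_binary_volume(shp, runif(1, 0, 0.5))
    gt <- random_binary_volume(shp, runif(1, 0, 0.5))
    mask <- if (i %% 3 == 0) random_binary_volume(shp, 0.8) else NULL
    got <- voxel_metrics(pred, gt, mask)
    want <- oracle_voxel_metrics(pred, gt, mask)
    for (m in c("dice", "iou", "precision", "recall", "fpr", "tp", "fp", "fn", "tn"))
      expect_equal(as.numeric(got[[m]]), as.numeric(want[[m]]), info = m)
  }
})

test_that("hand-counted and degenerate voxel metric cases hold", {
  gt <- array(0L, c(4, 4, 2)); gt[1:4] <- 1L
  pred <- array(0L, c(4, 4, 2)); pred[3:6] <- 1L  # |gt|=4, |pred|=4, overlap 2
  vm <- voxel_metrics(pred, gt)
  expect_equal(vm$dice, 0.5)
  expect_equal(vm$iou, 1 / 3)
  expect_equal(vm$precision, 0.5)
  expect_equal(vm$recall, 0.5)

  ident <- voxel_metrics(gt, gt)
  expect_equal(unlist(ident[c("dice", "iou", "precision", "recall")]),
               c(dice = 1, iou = 1, precision = 1, recall = 1))
  expect_equal(ident$fpr, 0)

  empty <- array(0L, c(3, 3, 3))
  both <- voxel_metrics(empty, empty)
  expect_equal(both$dice, 1); expect_equal(both$precision, 1)
  one <- voxel_metrics(empty, array(1L, c(3, 3, 3)))
  expect_equal(one$dice, 0); expect_equal(one$recall, 0)
})

test_that("26-connectivity labelling matches a flood-fill oracle on random masks", {
  set.seed(44)
  for (i in 1:200) {
    shp <- c(sample(6:12, 1), sample(6:12, 1), sample(4:8, 1))
    mask <- random_binary_volume(shp, runif(1, 0.05, 0.4))
    got <- label_components(mask)$labels
    want <- oracle_flood_fill(mask)
    # same partition: labels must be a relabelling of each other
    expect_identical(max(got), max(want))
    if (max(got) > 0) {
      key <- paste(got[mask != 0], want[mask != 0])
      expect_identical(length(unique(key)), as.integer(max(got)))
    }
    expect_true(all((got > 0) == (mask != 0)))
  }
})

test_that("corner-touching voxels connect; separated voxels do not", {
  m <- array(0L, c(4, 4, 4))
  m[1, 1, 1] <- 1L; m[2, 2, 2] <- 1L   # touch only at a corner
  expect_identical(length(label_components(m)$volumes_mm3), 1L)

  m2 <- array(0L, c(5, 4, 4))
  m2[1, 1, 1] <- 1L; m2[3, 1, 1] <- 1L  # one background voxel between
  expect_identical(length(label_components(m2)$volumes_mm3), 2L)

  # voxel volume uses the spacing
  vols <- label_components(m, spacing = c(0.5, 0.5, 2))$volumes_mm3
  expect_equal(vols, 2 * 0.5 * 0.5 * 2)
})

test_that("lesion FP counts match the enumeration oracle, with and without size limits", {
  set.seed(45)
  for (i in 1:100) {
    shp <- c(sample(6:10, 1), sample(6:10, 1), sample(4:7, 1))
    pred <- random_binary_volume(shp, runif(1, 0.05, 0.35))
    gt <- random_binary_volume(shp, runif(1, 0, 0.2))
    spacing <- c(1, 1, runif(1, 0.5, 2))
    comp <- label_components(pred, spacing)
    for (lim in c(0, 5, 10))
      expect_identical(as.integer(count_lesion_fp(comp, gt, lim)),
                       as.integer(oracle_count_fp(pred, gt, lim, spacing)))
  }

  # prediction = gt: never a FP
  gt <- random_binary_volume(c(8, 8, 4), 0.2)
  expect_identical(as.integer(count_lesion_fp(label_components(gt), gt, 0)), 0L)

  # an 8-voxel non-overlapping component at 1 mm^3/voxel: FP without the
  # limit, filtered out at 10 mm^3
  pred <- array(0L, c(10, 10, 5)); pred[1:2, 1:2, 1:2] <- 1L
  empty <- array(0L, c(10, 10, 5))
  expect_identical(as.integer(count_lesion_fp(label_components(pred), empty, 0)), 1L)
  expect_identical(as.integer(count_lesion_fp(label_components(pred), empty, 10)), 0L)
})

test_that("FP counts are non-increasing in the size limit", {
  set.seed(46)
  for (i in 1:20) {
    gt <- random_binary_volume(c(12, 12, 6), 0.1)
    map <- array(runif(12 * 12 * 6), c(12, 12, 6))
    comp <- label_components(binarize(map, 0.6))
    prev_by_lim <- Inf
    for (lim in c(0, 2, 5, 10, 20)) {
      fp <- count_lesion_fp(comp, gt, lim)
      expect_lte(fp, prev_by_lim)
      prev_by_lim <- fp
    }
  }
})

test_that("Youden threshold matches the exhaustive oracle and its tie rules", {
  set.seed(47)
  for (i in 1:50) {
    n <- sample(50:200, 1)
    labels <- as.integer(runif(n) < 0.3)
    if (sum(labels) == 0 || sum(labels) == n) next
    scores <- round(runif(n), 2)  # coarse grid forces score ties
    got <- youden_threshold(array(scores, c(n, 1, 1)),
                            array(labels, c(n, 1, 1)))
    want <- oracle_youden(scores, labels)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
    expect_equal(got$youden, want$youden, tolerance = 1e-12)
  }

  # perfectly separated: any threshold in (0.1, 0.9] is optimal; the largest
  # candidate 0.9 must be returned
  sc <- array(c(rep(0.9, 5), rep(0.1, 5)), c(10, 1, 1))
  gt <- array(c(rep(1L, 5), rep(0L, 5)), c(10, 1, 1))
  expect_equal(youden_threshold(sc, gt)$threshold, 0.9)

  # single positive at 0.76 among lower negatives: forced argmax
  sc2 <- array(c(0.76, 0.3, 0.2, 0.1), c(4, 1, 1))
  gt2 <- array(c(1L, 0L, 0L, 0L), c(4, 1, 1))
  expect_equal(youden_threshold(sc2, gt2)$threshold, 0.76)
})

test_that("per-case Dice and IoU satisfy dice = 2*iou/(1+iou) to 1e-12", {
  set.seed(48)
  for (i in 1:50) {
    shp <- c(8, 8, 4)
    pred <- random_binary_volume(shp, runif(1, 0.1, 0.5))
    gt <- random_binary_volume(shp, runif(1, 0.1, 0.5))
    vm <- voxel_metrics(pred, gt)
    expect_lt(abs(vm$dice - 2 * vm$iou / (1 + vm$iou)), 1e-12)
  }
})

test_that("evaluate_case composes the individual operations exactly", {
  set.seed(49)
  st <- generate_phantom(tiny_phantom_config(seed = 50))
  map <- structure(list(values = array(runif(prod(dim(st))), dim(st)),
                        voxel_spacing = st$voxel_spacing,
                        pattern = st$pattern), class = "probability_map")
  thr <- 0.6
  cs <- evaluate_case(map, st, thr)
  pred <- binarize(map, thr)
  vm <- voxel_metrics(pred, st$ground_truth, st$brain_mask)
  expect_identical(cs$metrics$dice, vm$dice)
  expect_identical(cs$metrics$iou, vm$iou)
  expect_identical(cs$metrics$auc, roc_auc(map, st$ground_truth, st$brain_mask)$auc)
  comp <- label_components(pred, st$voxel_spacing)
  expect_identical(cs$metrics$fp_all, count_lesion_fp(comp, st$ground_truth, 0))
  expect_identical(cs$metrics$fp_10mm3, count_lesion_fp(comp, st$ground_truth, 10))
  expect_lte(cs$metrics$fp_10mm3, cs$metrics$fp_all)

  # a perfect map scores perfectly
  perfect <- map
  perfect$values <- array(0.001 + 0.998 * st$ground_truth, dim(st))
  ps <- evaluate_case(perfect, st, 0.5)$metrics
  expect_equal(ps[c("auc", "dice", "iou", "precision", "recall")],
               data.frame(auc = 1, dice = 1, iou = 1, precision = 1, recall = 1))
  expect_identical(ps$fp_all, 0L)
})

test_that("the Wilcoxon comparison matches exact enumeration", {
  expect_equal(compare_models(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)

  res_same <- compare_models(c(1, 1, 1), c(1, 1, 1))
  expect_equal(res_same$p_value, 1)
  expect_false(res_same$significant)

  set.seed(51)
  for (i in 1:25) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny, mean = runif(1, -1, 1))
    got <- compare_models(x, y)$p_value
    want <- oracle_wilcoxon_exact(x, y)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("cohort summaries average metrics and ROC curves correctly", {
  df <- data.frame(dice = c(0.8, 0.6, 0.7), iou = c(0.5, 0.4, 0.45))
  s <- summarize_cohort(df)
  expect_equal(s$table$mean[s$table$metric == "dice"], 0.7)
  expect_equal(s$table$sd[s$table$metric == "dice"], sd(c(0.8, 0.6, 0.7)))

  # identical cases: sd 0, and the averaged ROC is the curve itself
  set.seed(52)
  st <- generate_phantom(tiny_phantom_config(seed = 53))
  map <- structure(list(values = array(runif(prod(dim(st))), dim(st)),
                        voxel_spacing = st$voxel_spacing,
                        pattern = st$pattern), class = "probability_map")
  cs <- evaluate_case(map, st, 0.5)
  s2 <- summarize_cohort(list(cs, cs))
  expect_true(all(s2$table$sd == 0))
  expect_equal(s2$roc_band$mean, cs$roc$sensitivity)
  expect_equal(s2$roc_band$lower, pmax(0, cs$roc$sensitivity))
  p <- plot_cohort_roc(s2)
  expect_s3_class(p, "ggplot")
  expect_error(summarize_cohort(df[1, , drop = FALSE]), "at least 2")
})
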