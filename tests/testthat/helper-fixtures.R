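# Shared fixtures and independent brute-force oracles.
# Oracles are deliberately naive (explicit loops, exhaustive scans,
# enumeration) and never call the implementation they check.

tiny_phantom_config <- function(...) {
  defaults <- list(grid_shape = c(24L, 24L, 8L), lesion_count_range = c(1L, 2L),
                   lesion_radius_range = c(2, 4), vessel_count = 1L,
                   noise_sd = 0.2, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_config, args)
}

random_binary_volume <- function(shape, p = 0.2) {
  array(as.integer(stats::runif(prod(shape)) < p), shape)
}

## --- voxel metric oracle: explicit voxel loop ------------------------------
oracle_voxel_metrics <- function(pred, gt, mask = NULL) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (!is.null(mask) && mask[i] == 0) next
    p <- pred[i] != 0; g <- gt[i] != 0
    if (p && g) tp <- tp + 1L
    else if (p && !g) fp <- fp + 1L
    else if (!p && g) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    dice = if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    iou = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    precision = if (tp + fp == 0) {
      if (tp + fn == 0) 1 else 0
    } else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),
    fpr = if (fp + tn == 0) 0 else fp / (fp + tn)
  )
}

## --- 26-connectivity flood fill oracle -------------------------------------
oracle_flood_fill <- function(mask) {
  shp <- dim(mask)
  lab <- array(0L, shp)
  nxt <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, shp)
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ni <- co[1] + di; nj <- co[2] + dj; nk <- co[3] + dk
        if (ni < 1 || ni > shp[1] || nj < 1 || nj > shp[2] ||
            nk < 1 || nk > shp[3]) next
        lin <- (nk - 1L) * shp[1] * shp[2] + (nj - 1L) * shp[1] + ni
        if (mask[lin] != 0 && lab[lin] == 0L) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

## --- lesion FP oracle: enumerate components, test overlap by looping -------
oracle_count_fp <- function(pred, gt, min_volume_mm3, spacing = c(1, 1, 1)) {
  lab <- oracle_flood_fill(pred)
  if (max(lab) == 0) return(0L)
  fp <- 0L
  for (l in seq_len(max(lab))) {
    vox <- which(lab == l)
    if (length(vox) * prod(spacing) < min_volume_mm3) next
    if (all(gt[vox] == 0)) fp <- fp + 1L
  }
  fp
}

## --- Youden oracle: brute-force scan over all observed values + {0,1} ------
oracle_youden <- function(scores, labels) {
  cand <- sort(unique(c(0, 1, scores)))
  best_j <- -Inf; best_t <- NA
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  for (t in cand) {
    sens <- sum(scores >= t & labels == 1) / n_pos
    spec <- sum(scores < t & labels == 0) / n_neg
    j <- sens + spec - 1
    if (j >= best_j) { best_j <- j; best_t <- t }  # >= : ties toward larger t
  }
  list(threshold = best_t, youden = best_j)
}

## --- exact two-sided Wilcoxon rank-sum p by full enumeration ----------------
oracle_wilcoxon_exact <- function(x, y) {
  all_v <- c(x, y)
  n <- length(x)
  ranks <- rank(all_v)
  w_obs <- sum(ranks[seq_len(n)])
  combos <- utils::combn(length(all_v), n)
  w_null <- apply(combos, 2, function(ix) sum(ranks[ix]))
  mu <- mean(w_null)
  min(1, sum(abs(w_null - mu) >= abs(w_obs - mu) - 1e-12) / ncol(combos))
}

## quick standard-normal-ish probability map around a ground truth
make_scored_map <- function(gt, signal = 2, noise = 1) {
  array(stats::rnorm(length(gt), mean = signal * (gt != 0), sd = noise), dim(gt))
}
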