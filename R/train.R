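#' Training configuration
#'
#' @param epochs Number of passes over the training slabs.
#' @param batch_size Slabs per gradient step.
#' @param learning_rate Adam step size.
#' @param loss_name `"bce_dice"` (weighted cross-entropy plus soft Dice, the
#'   default: the soft-Dice term keeps training well-behaved under the heavy
#'   class imbalance of small lesions), `"bce"` or `"dice"`.
#' @param foreground_weight Cross-entropy weight on lesion voxels.
#' @param dropout_policy A [dropout_policy()]; use
#'   `dropout_policy(0)` for a plain no-dropout model (the baseline
#'   comparator trained on a fixed sequence subset).
#' @param slab_half_width 2.5D slab half-width (k = 2*half + 1 slices).
#' @param validation_fraction Fraction of training studies held out for the
#'   per-epoch validation loss when no explicit validation set is supplied.
#' @param seed RNG seed for slab shuffling and pattern sampling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 12L, batch_size = 8L, learning_rate = 0.01,
                         loss_name = c("bce_dice", "bce", "dice"),
                         foreground_weight = 8,
                         dropout_policy = ildseg::dropout_policy(3L),
                         slab_half_width = 2L,
                         validation_fraction = 0,
                         seed = 1L) {
  loss_name <- match.arg(loss_name)
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, loss_name = loss_name,
              foreground_weight = foreground_weight,
              dropout_policy = dropout_policy,
              slab_half_width = as.integer(slab_half_width),
              validation_fraction = validation_fraction,
              seed = as.integer(seed))
  if (cfg$epochs < 1) abort("epochs must be >= 1")
  if (cfg$foreground_weight <= 0) abort("foreground_weight must be > 0")
  if (cfg$batch_size < 1) abort("batch_size must be >= 1")
  structure(cfg, class = "train_config")
}

## Weighted binary cross-entropy + soft Dice on the sigmoid output.
## Returns the scalar loss and the gradient w.r.t. the pre-sigmoid logit.
seg_loss <- function(p, y, loss_name, fg_weight) {
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  n <- length(p)
  loss <- 0
  dp <- numeric(n)
  if (loss_name %in% c("bce", "bce_dice")) {
    w <- ifelse(y > 0, fg_weight, 1)
    sw <- sum(w)
    loss <- loss - sum(w * (y * log(pc) + (1 - y) * log(1 - pc))) / sw
    dp <- dp + w * (pc - y) / (pc * (1 - pc)) / sw
  }
  if (loss_name %in% c("dice", "bce_dice")) {
    smooth <- 1
    num <- 2 * sum(p * y) + smooth
    den <- sum(p) + sum(y) + smooth
    loss <- loss + 1 - num / den
    dp <- dp - (2 * y * den - num) / den^2
  }
  list(loss = loss, dlogit = dp * pc * (1 - pc))
}

## assemble one training batch: rows (B*H*W) x C, plus center-slice labels
build_batch <- function(studies, picks, cfg, policy_sampler) {
  H <- dim(studies[[1]])[1]; W <- dim(studies[[1]])[2]
  HW <- H * W
  k <- 2L * cfg$slab_half_width + 1L
  S <- n_sequences(studies[[1]])
  B <- nrow(picks)
  X <- matrix(0, B * HW, S * k)
  y <- numeric(B * HW)
  for (i in seq_len(B)) {
    st <- studies[[picks$study[i]]]
    slab <- extract_slab(st, picks$z[i], cfg$slab_half_width)
    pat <- policy_sampler(S)
    slab <- apply_input_dropout(slab, pat)
    rows <- ((i - 1L) * HW + 1L):(i * HW)
    X[rows, ] <- matrix(slab$values, HW, S * k)
    y[rows] <- as.numeric(st$ground_truth[, , picks$z[i]])
  }
  list(X = X, y = y, B = B, H = H, W = W)
}

#' Train a segmentation model with sequence-level input dropout
#'
#' Every gradient step samples a batch of 2.5D slabs; each slab independently
#' draws a fresh availability pattern from the dropout policy, has the dropped
#' sequences zeroed and the survivors upweighted by `1/(1-p)`
#' ([apply_input_dropout()]), and contributes the loss of its centre slice
#' against the ground truth. Studies are z-score normalised (within the brain
#' mask) before training, so dropout zeros coincide with the masked background
#' mean. Training is fully seeded: the same model, data and config reproduce
#' the same loss history.
#'
#' @param model A `seg_model` from [build_network()].
#' @param studies List of [multisequence_study()] (training set); every study
#'   must have a nonempty ground truth.
#' @param cfg A [train_config()].
#' @param val_studies Optional list of studies for the per-epoch validation
#'   loss (evaluated with all sequences available, no dropout).
#' @return List with `model` (trained) and `history` (data frame of per-epoch
#'   train/validation loss).
#' @export
train_model <- function(model, studies, cfg, val_studies = NULL) {
  stopifnot(inherits(model, "seg_model"), inherits(cfg, "train_config"))
  if (length(studies) < 1) abort("need at least one training study")
  for (st in studies)
    if (sum(st$ground_truth) == 0) abort("every training study must have a nonempty ground truth")
  set.seed(cfg$seed)
  studies <- lapply(studies, normalize_study)
  if (is.null(val_studies) && cfg$validation_fraction > 0) {
    n_val <- max(1L, floor(cfg$validation_fraction * length(studies)))
    vi <- sample(seq_along(studies), n_val)
    val_studies <- studies[vi]
    studies <- studies[-vi]
  } else if (!is.null(val_studies)) {
    val_studies <- lapply(val_studies, normalize_study)
  }

  S <- n_sequences(studies[[1]])
  if (cfg$dropout_policy$max_dropped >= S)
    abort("dropout policy max_dropped must be at most S - 1")
  shp <- dim(studies[[1]])
  k <- 2L * cfg$slab_half_width + 1L
  if (model$config$in_channels != S * k)
    abort(sprintf("model expects %d channels but data yields %d (S=%d, k=%d)",
                  model$config$in_channels, S * k, S, k))
  if (shp[3] < k) abort("volume depth smaller than the slab width")

  all_slabs <- expand.grid(study = seq_along(studies), z = seq_len(shp[3]))
  dilations <- c(1L, model$config$dilation_rates)
  ctx_memo <- new.env(parent = emptyenv())
  get_ctx <- function(B) {
    key <- as.character(B)
    if (is.null(ctx_memo[[key]]))
      ctx_memo[[key]] <- make_conv_context(shp[1], shp[2], B, dilations)
    ctx_memo[[key]]
  }
  sampler <- function(S) sample_pattern(cfg$dropout_policy, S)

  theta <- pack_params(model)
  m <- numeric(length(theta)); v <- numeric(length(theta)); tstep <- 0
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  pattern_log <- integer(0)

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(nrow(all_slabs))
    losses <- numeric(0)
    for (start in seq(1L, length(perm), by = cfg$batch_size)) {
      sel <- perm[start:min(start + cfg$batch_size - 1L, length(perm))]
      picks <- all_slabs[sel, , drop = FALSE]
      batch <- build_batch(studies, picks, cfg, function(S) {
        pat <- sampler(S)
        pattern_log <<- c(pattern_log, sum(!pat$available))
        pat
      })
      ctx <- get_ctx(batch$B)
      fwd <- network_forward(model, batch$X, ctx, keep_cache = TRUE)
      ls <- seg_loss(fwd$p, batch$y, cfg$loss_name, cfg$foreground_weight)
      if (!is.finite(ls$loss))
        abort(sprintf("non-finite loss at epoch %d (step starting %d): check learning rate and inputs",
                      epoch, start))
      losses <- c(losses, ls$loss)
      g <- network_backward(model, batch$X, fwd$cache, ls$dlogit, ctx)
      grad <- pack_grads(model, g)
      tstep <- tstep + 1
      m <- b1 * m + (1 - b1) * grad
      v <- b2 * v + (1 - b2) * grad^2
      mhat <- m / (1 - b1^tstep); vhat <- v / (1 - b2^tstep)
      theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + aeps)
      model <- unpack_params(model, theta)
    }
    val_loss <- NA_real_
    if (!is.null(val_studies) && length(val_studies) > 0)
      val_loss <- validation_loss(model, val_studies, cfg, get_ctx)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_loss = val_loss))
  }
  list(model = model, history = history,
       pattern_histogram = table(factor(pattern_log,
                                        levels = 0:cfg$dropout_policy$max_dropped)))
}

## mean loss over all validation slabs, all sequences available (no dropout)
validation_loss <- function(model, val_studies, cfg, get_ctx) {
  losses <- numeric(0)
  HW <- prod(dim(val_studies[[1]])[1:2])
  for (st in val_studies) {
    D <- dim(st)[3]
    for (z in seq_len(D)) {
      slab <- extract_slab(st, z, cfg$slab_half_width)
      slab <- apply_input_dropout(slab, st$pattern)
      X <- matrix(slab$values, HW, dim(slab$values)[3])
      fwd <- network_forward(model, X, get_ctx(1L), keep_cache = FALSE)
      y <- as.numeric(st$ground_truth[, , z])
      losses <- c(losses, seg_loss(fwd$p, y, cfg$loss_name, cfg$foreground_weight)$loss)
    }
  }
  mean(losses)
}
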