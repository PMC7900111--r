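#' Network configuration
#'
#' A compact fully-convolutional 2D segmentation network: a small stem of 3x3
#' convolutions followed by a pyramid of parallel 3x3 atrous (dilated)
#' convolutions at the configured rates, a 1x1 fusion layer and a 1x1 sigmoid
#' head. Dilated convolutions enlarge the receptive field without
#' downsampling, so the output probability map keeps the input's spatial
#' shape; width and depth scale through `base_width` and `n_stages`.
#'
#' @param in_channels Number of input channels (`S * k` for a slab stack of S
#'   sequences and k slices; 20 for the default 4 x 5).
#' @param base_width Feature channels per layer.
#' @param n_stages Number of stem convolutions (>= 1).
#' @param dilation_rates Integer atrous rates of the pyramid branches.
#' @param seed Seed for the deterministic weight initialisation.
#' @return Object of class `network_config`.
#' @export
network_config <- function(in_channels = 20L, base_width = 8L, n_stages = 2L,
                           dilation_rates = c(1L, 2L, 4L), seed = 1L) {
  cfg <- list(in_channels = as.integer(in_channels),
              base_width = as.integer(base_width),
              n_stages = as.integer(n_stages),
              dilation_rates = as.integer(dilation_rates),
              seed = as.integer(seed))
  if (cfg$in_channels < 1) abort("in_channels must be >= 1")
  if (cfg$base_width < 1 || cfg$n_stages < 1) abort("base_width and n_stages must be >= 1")
  if (length(cfg$dilation_rates) < 1 || any(cfg$dilation_rates < 1))
    abort("dilation_rates must be a nonempty set of integers >= 1")
  structure(cfg, class = "network_config")
}

## He-normal initialised conv layer; weights kept as one matrix per kernel tap
new_conv_layer <- function(cin, cout, ksize, dilation) {
  k2 <- ksize^2
  sdv <- sqrt(2 / (k2 * cin))
  W <- lapply(seq_len(k2), function(j) matrix(stats::rnorm(cin * cout, sd = sdv), cin, cout))
  list(W = W, b = numeric(cout), ksize = ksize, dilation = as.integer(dilation),
       cin = cin, cout = cout)
}

#' Build a segmentation network
#'
#' Initialisation is a deterministic function of the configuration seed: two
#' builds from the same config have identical parameters. The single output
#' channel passes through a sigmoid, so every voxel's output lies strictly in
#' (0, 1) and is read as the probability that the voxel belongs to a lesion.
#'
#' @param config A [network_config()].
#' @return Object of class `seg_model`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  w <- config$base_width
  stem <- vector("list", config$n_stages)
  stem[[1]] <- new_conv_layer(config$in_channels, w, 3L, 1L)
  for (i in seq_len(config$n_stages - 1L) + 1L)
    stem[[i]] <- new_conv_layer(w, w, 3L, 1L)
  aspp <- lapply(config$dilation_rates, function(r) new_conv_layer(w, w, 3L, r))
  fuse <- new_conv_layer(length(aspp) * w, w, 1L, 1L)
  head <- new_conv_layer(w, 1L, 1L, 1L)
  head$b <- -2  # start from a low foreground prior; lesions are rare
  structure(list(config = config, stem = stem, aspp = aspp,
                 fuse = fuse, head = head),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cfg <- x$config
  cat("Dilated-convolution segmentation network\n")
  cat(sprintf("  in_channels %d | width %d | stem depth %d | atrous rates %s\n",
              cfg$in_channels, cfg$base_width, cfg$n_stages,
              paste(cfg$dilation_rates, collapse = ",")))
  cat(sprintf("  parameters: %d\n", length(pack_params(x))))
  invisible(x)
}

## ---- convolution engine ----------------------------------------------------
## Feature maps are matrices of shape (B*H*W, C), images column-major in
## (H, W). A 'same' 3x3 convolution with dilation d is nine shifted
## matrix-multiplies; shifts are precomputed index vectors with out-of-bounds
## pixels pointing at a shared zero row (row n+1), i.e. zero padding.

conv_offsets <- expand.grid(dy = -1:1, dx = -1:1)

make_shift_indices <- function(H, W, B, dilation) {
  HW <- H * W
  n <- B * HW
  y <- rep(seq_len(H), times = W)
  x <- rep(seq_len(W), each = H)
  boff <- rep((seq_len(B) - 1L) * HW, each = HW)
  lapply(seq_len(9L), function(j) {
    yy <- y + conv_offsets$dy[j] * dilation
    xx <- x + conv_offsets$dx[j] * dilation
    ok <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
    base <- ifelse(ok, (xx - 1L) * H + yy, NA_integer_)
    idx <- rep(base, times = B) + boff
    idx[is.na(idx)] <- n + 1L
    idx
  })
}

## one context per (H, W, B): shift indices for every dilation the model uses
make_conv_context <- function(H, W, B, dilations) {
  ctx <- list(n = B * H * W, H = H, W = W, B = B)
  ctx$idx <- stats::setNames(
    lapply(sort(unique(dilations)), function(d) make_shift_indices(H, W, B, d)),
    as.character(sort(unique(dilations))))
  ctx
}

conv_fwd <- function(X, layer, ctx) {
  n <- nrow(X)
  if (layer$ksize == 1L) {
    Y <- X %*% layer$W[[1]]
  } else {
    idx <- ctx$idx[[as.character(layer$dilation)]]
    Xp <- rbind(X, 0)
    Y <- matrix(0, n, layer$cout)
    for (j in seq_len(9L))
      Y <- Y + Xp[idx[[j]], , drop = FALSE] %*% layer$W[[j]]
  }
  sweep(Y, 2L, layer$b, "+")
}

conv_bwd <- function(X, layer, dY, ctx) {
  n <- nrow(X)
  db <- colSums(dY)
  if (layer$ksize == 1L) {
    dW <- list(crossprod(X, dY))
    dX <- tcrossprod(dY, layer$W[[1]])
  } else {
    idx <- ctx$idx[[as.character(layer$dilation)]]
    Xp <- rbind(X, 0)
    dW <- vector("list", 9L)
    dX <- matrix(0, n, layer$cin)
    for (j in seq_len(9L)) {
      dW[[j]] <- crossprod(Xp[idx[[j]], , drop = FALSE], dY)
      tmp <- tcrossprod(dY, layer$W[[j]])
      inb <- idx[[j]] <= n
      ii <- idx[[j]][inb]
      dX[ii, ] <- dX[ii, ] + tmp[inb, , drop = FALSE]
    }
  }
  list(dX = dX, dW = dW, db = db)
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

## Forward pass over a batch matrix X of shape (B*H*W, in_channels).
## Returns the probability column and, optionally, the activation cache
## needed for backprop.
network_forward <- function(model, X, ctx, keep_cache = FALSE) {
  cache <- list(stem_in = list(), stem_z = list())
  A <- X
  for (i in seq_along(model$stem)) {
    if (keep_cache) cache$stem_in[[i]] <- A
    Z <- conv_fwd(A, model$stem[[i]], ctx)
    if (keep_cache) cache$stem_z[[i]] <- Z
    A <- relu(Z)
  }
  if (keep_cache) cache$stem_out <- A
  branch_a <- vector("list", length(model$aspp))
  if (keep_cache) cache$aspp_z <- vector("list", length(model$aspp))
  for (r in seq_along(model$aspp)) {
    Z <- conv_fwd(A, model$aspp[[r]], ctx)
    if (keep_cache) cache$aspp_z[[r]] <- Z
    branch_a[[r]] <- relu(Z)
  }
  Acat <- do.call(cbind, branch_a)
  if (keep_cache) cache$acat <- Acat
  Zf <- conv_fwd(Acat, model$fuse, ctx)
  if (keep_cache) cache$fuse_z <- Zf
  Af <- relu(Zf)
  if (keep_cache) cache$fuse_a <- Af
  Zh <- conv_fwd(Af, model$head, ctx)
  p <- sigmoid(Zh)
  list(p = as.numeric(p), cache = if (keep_cache) cache else NULL)
}

## Backward pass; dlogit is dLoss/d(pre-sigmoid output), length n.
## Returns gradients with the same structure as the model's layers.
network_backward <- function(model, X, cache, dlogit, ctx) {
  g <- list(stem = vector("list", length(model$stem)),
            aspp = vector("list", length(model$aspp)))
  dZh <- matrix(dlogit, ncol = 1L)
  bw <- conv_bwd(cache$fuse_a, model$head, dZh, ctx)
  g$head <- list(dW = bw$dW, db = bw$db)
  dAf <- bw$dX
  dZf <- dAf * (cache$fuse_z > 0)
  bw <- conv_bwd(cache$acat, model$fuse, dZf, ctx)
  g$fuse <- list(dW = bw$dW, db = bw$db)
  dAcat <- bw$dX
  w <- model$config$base_width
  dStemOut <- matrix(0, nrow(X), w)
  for (r in seq_along(model$aspp)) {
    cols <- ((r - 1L) * w + 1L):(r * w)
    dZr <- dAcat[, cols, drop = FALSE] * (cache$aspp_z[[r]] > 0)
    bw <- conv_bwd(cache$stem_out, model$aspp[[r]], dZr, ctx)
    g$aspp[[r]] <- list(dW = bw$dW, db = bw$db)
    dStemOut <- dStemOut + bw$dX
  }
  dA <- dStemOut
  for (i in rev(seq_along(model$stem))) {
    dZ <- dA * (cache$stem_z[[i]] > 0)
    bw <- conv_bwd(cache$stem_in[[i]], model$stem[[i]], dZ, ctx)
    g$stem[[i]] <- list(dW = bw$dW, db = bw$db)
    dA <- bw$dX
  }
  g
}

## ---- parameter packing (for the optimiser and numerical checks) ------------

layer_refs <- function(model) {
  refs <- list()
  for (i in seq_along(model$stem)) refs[[length(refs) + 1L]] <- c("stem", i)
  for (r in seq_along(model$aspp)) refs[[length(refs) + 1L]] <- c("aspp", r)
  refs[[length(refs) + 1L]] <- c("fuse", 0)
  refs[[length(refs) + 1L]] <- c("head", 0)
  refs
}

get_layer <- function(model, ref) {
  if (ref[1] %in% c("fuse", "head")) model[[ref[1]]]
  else model[[ref[1]]][[as.integer(ref[2])]]
}

pack_params <- function(model) {
  out <- lapply(layer_refs(model), function(ref) {
    ly <- get_layer(model, ref)
    c(unlist(ly$W), ly$b)
  })
  unlist(out)
}

unpack_params <- function(model, theta) {
  pos <- 1L
  for (ref in layer_refs(model)) {
    ly <- get_layer(model, ref)
    for (j in seq_along(ly$W)) {
      nv <- length(ly$W[[j]])
      ly$W[[j]][] <- theta[pos:(pos + nv - 1L)]
      pos <- pos + nv
    }
    nb <- length(ly$b)
    ly$b <- theta[pos:(pos + nb - 1L)]
    pos <- pos + nb
    if (ref[1] %in% c("fuse", "head")) model[[ref[1]]] <- ly
    else model[[ref[1]]][[as.integer(ref[2])]] <- ly
  }
  model
}

pack_grads <- function(model, g) {
  out <- list()
  i <- 0L
  for (ref in layer_refs(model)) {
    gl <- if (ref[1] == "stem") g$stem[[as.integer(ref[2])]]
          else if (ref[1] == "aspp") g$aspp[[as.integer(ref[2])]]
          else g[[ref[1]]]
    i <- i + 1L
    out[[i]] <- c(unlist(gl$dW), gl$db)
  }
  unlist(out)
}

## ---- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are plain JSON: the network configuration plus the flattened
#' parameter vector, so they are portable text files.
#'
#' @param model A `seg_model`.
#' @param path File path (`.json`).
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config), params = pack_params(model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, obj$config)
  model <- build_network(cfg)
  unpack_params(model, as.numeric(obj$params))
}
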