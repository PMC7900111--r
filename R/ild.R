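#' Sequence availability pattern
#'
#' Declares which pulse sequences of a study are present. The dropout
#' proportion `p` is the fraction of sequences that are unavailable; it drives
#' the `1/(1-p)` upweighting of the surviving input channels (see
#' [apply_input_dropout()]). At least one sequence must be available (`p < 1`):
#' an all-dropped pattern would hand the network an all-zero input tensor.
#'
#' @param available Logical vector (one entry per sequence), or a bit string
#'   such as `"0111"` where `1` means available, in sequence order.
#' @return Object of class `availability_pattern` with fields `available`
#'   (logical) and `p` (fraction dropped, exactly `n_dropped / S`).
#' @examples
#' availability_pattern("0111")$p  # 0.25
#' @export
availability_pattern <- function(available) {
  if (is.character(available)) {
    stopifnot(length(available) == 1)
    bits <- strsplit(available, "")[[1]]
    if (!all(bits %in% c("0", "1")))
      abort("pattern string must contain only 0 and 1")
    available <- bits == "1"
  }
  available <- as.logical(available)
  if (length(available) < 1 || anyNA(available))
    abort("`available` must be a non-empty logical vector")
  if (!any(available))
    abort("at least one sequence must be available (all-dropped pattern is inadmissible)")
  structure(list(available = available,
                 p = sum(!available) / length(available)),
            class = "availability_pattern")
}

pattern_to_string <- function(pattern) paste(as.integer(pattern$available), collapse = "")

#' @export
print.availability_pattern <- function(x, ...) {
  cat("Availability pattern", pattern_to_string(x),
      sprintf("(p = %d/%d dropped)\n", sum(!x$available), length(x$available)))
  invisible(x)
}

#' Training-time dropout policy
#'
#' Defines the distribution of the number of sequences dropped per training
#' sample. A pattern is drawn in two stages: the number dropped `d` is sampled
#' from `weights_over_num_dropped` on `{0, ..., max_dropped}`, then a
#' uniformly random subset of that size is dropped. With `max_dropped = S - 1`
#' (the default for S sequences) the all-dropped pattern can never occur, so
#' for four sequences training covers 0-3 dropped sequences: the full set and
#' every proper subset.
#'
#' @param max_dropped Maximum number of sequences dropped at once; must be
#'   at most `S - 1`.
#' @param weights_over_num_dropped Probability weights over `0:max_dropped`
#'   (normalised internally). Default uniform, so every subset size is trained
#'   equally often.
#' @return Object of class `dropout_policy`.
#' @export
dropout_policy <- function(max_dropped = 3L,
                           weights_over_num_dropped = NULL) {
  max_dropped <- as.integer(max_dropped)
  if (max_dropped < 0) abort("`max_dropped` must be >= 0")
  w <- weights_over_num_dropped %||% rep(1, max_dropped + 1L)
  if (length(w) != max_dropped + 1L || any(w < 0) || sum(w) <= 0)
    abort("`weights_over_num_dropped` must be nonnegative weights over 0:max_dropped")
  structure(list(max_dropped = max_dropped, weights = w / sum(w)),
            class = "dropout_policy")
}

#' Sample a training availability pattern
#'
#' Draws the number of dropped sequences from the policy and then a uniformly
#' random subset of sequences of that size to drop. The all-dropped pattern is
#' never produced: with all sequences zeroed the model would receive an input
#' tensor of all zeros.
#'
#' @param policy A [dropout_policy()].
#' @param S Number of sequences.
#' @return An [availability_pattern()]. Uses the current R RNG stream; seed
#'   with `set.seed()` for reproducibility.
#' @export
sample_pattern <- function(policy, S) {
  S <- as.integer(S)
  if (S < 1) abort("S must be >= 1")
  if (policy$max_dropped >= S)
    abort("policy max_dropped must be at most S - 1")
  d <- sample.int(policy$max_dropped + 1L, 1L, prob = policy$weights) - 1L
  avail <- rep(TRUE, S)
  if (d > 0) avail[sample.int(S, d)] <- FALSE
  availability_pattern(avail)
}

#' Apply sequence-level input dropout to a slab stack
#'
#' The core input-level dropout operation, applied identically during training
#' and inference: all `k` channels belonging to each unavailable sequence are
#' replaced by zeros (a sequence is dropped atomically, never slice-by-slice),
#' and every surviving channel is multiplied by `1/(1-p)`, where `p` is the
#' fraction of sequences dropped. The upweighting keeps the expected total
#' input activation equal to that of the complete input, so one network serves
#' the full sequence set and every proper subset.
#'
#' @param slab A [slab_stack] as returned by [extract_slab()].
#' @param pattern An [availability_pattern()] of the same number of sequences.
#' @return The slab with dropped channels zeroed, surviving channels scaled by
#'   `1/(1-p)`, and `pattern` recorded.
#' @examples
#' # dropping 1 of 4 sequences scales survivors by 1/(1-0.25) = 4/3
#' @export
apply_input_dropout <- function(slab, pattern) {
  stopifnot(inherits(slab, "slab_stack"), inherits(pattern, "availability_pattern"))
  S <- slab$n_sequences
  if (length(pattern$available) != S)
    abort("pattern length must match the slab's number of sequences")
  k <- slab$slab_width
  scale <- 1 / (1 - pattern$p)
  vals <- slab$values * scale
  for (s in which(!pattern$available)) {
    ch <- ((s - 1L) * k + 1L):(s * k)
    vals[, , ch] <- 0
  }
  slab$values <- vals
  slab$pattern <- pattern
  slab
}
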