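# 3D shuffle attention: grouped channel + spatial attention with channel
# shuffle, applicable to any (C,T,H,W) feature volume.

#' Shuffle-attention parameters
#'
#' Creates the parameter set for a 3D shuffle-attention block operating on a
#' feature volume with `channels` channels. The channels are divided into `G`
#' groups; within each group, the first half of the channels passes through a
#' channel-attention branch and the second half through a spatial-attention
#' branch, after which the halves are re-concatenated and a channel shuffle
#' mixes information across groups.
#'
#' Each branch owns one scale and one shift parameter per sub-feature
#' channel: the channel branch gates on `sigmoid(W1 * s + b1)` where `s` is
#' the per-channel global average, and the spatial branch gates on
#' `sigmoid(W2 * GN(x) + b2)` where `GN` normalizes each channel to zero mean
#' and unit variance over its `T x H x W` extent.
#'
#' The requested group count is clamped to the largest divisor of `channels`
#' not exceeding it for which each branch still holds at least one channel
#' (`channels / (2G) >= 1`); the effective value is stored in the result.
#'
#' @param channels number of channels `C` of the feature volume.
#' @param groups requested group count `G` (default 4).
#' @param eps group-normalization epsilon.
#' @return an object of class `sa_params` with elements `groups`, `eps`, and
#'   parameter vectors `w1`, `b1`, `w2`, `b2`, each of length `channels / 2`,
#'   blocked by group. Initialization is near-neutral: `w1 = 0, b1 = 0`
#'   (channel gate 0.5), `w2 = 1, b2 = 0`.
#' @export
sa_params <- function(channels, groups = 4L, eps = 1e-5) {
  G <- sa_effective_groups(channels, groups)
  half <- channels %/% 2L
  structure(list(
    channels = as.integer(channels),
    groups = G,
    eps = eps,
    w1 = rep(0, half), b1 = rep(0, half),
    w2 = rep(1, half), b2 = rep(0, half)
  ), class = "sa_params")
}

# Largest divisor of C not exceeding `groups` with C/(2G) >= 1.
sa_effective_groups <- function(channels, groups) {
  channels <- as.integer(channels)
  if (channels < 2L) stop("shuffle attention needs at least 2 channels")
  g <- min(as.integer(groups), channels %/% 2L)
  while (g > 1L && channels %% (2L * g) != 0L) g <- g - 1L
  g
}

check_grouping <- function(C, G) {
  if (G < 1L || C %% (2L * G) != 0L || C %/% (2L * G) < 1L) {
    stop(sprintf("invalid grouping: G = %d does not divide C = %d into halvable groups", G, C))
  }
}

#' Split a feature volume into attention sub-features
#'
#' Divides the channels of `x` into `G` equal groups and each group into a
#' channel-branch half and a spatial-branch half. Concatenating all returned
#' parts in order reproduces `x` exactly.
#'
#' @param x numeric 4-D array `(C,T,H,W)`.
#' @param G group count; must divide `C` with `C/(2G) >= 1`.
#' @return list of `G` lists, each with elements `xk1` (first half of the
#'   group's channels) and `xk2` (second half).
#' @export
sa_group_split <- function(x, G) {
  d <- dim4(x)
  G <- as.integer(G)
  check_grouping(d[1], G)
  per <- d[1] %/% G
  half <- per %/% 2L
  lapply(seq_len(G), function(k) {
    base <- (k - 1L) * per
    list(
      xk1 = x[base + seq_len(half), , , , drop = FALSE],
      xk2 = x[base + half + seq_len(per - half), , , , drop = FALSE]
    )
  })
}

#' Global average pooling over time and space
#'
#' Reduces a `(C,T,H,W)` volume to one statistic per channel, the mean over
#' the whole `T x H x W` extent.
#'
#' @param x numeric 4-D array.
#' @return numeric vector of length `C`.
#' @export
global_avg_pool <- function(x) {
  rowMeans(ch_mat(x))
}

#' Channel attention branch
#'
#' Gates each channel of `x` by `sigmoid(w1[c] * s[c] + b1[c])` where `s` is
#' the channel's global average. Output shape equals input shape.
#'
#' @param x numeric 4-D array `(C,T,H,W)`.
#' @param w1,b1 numeric vectors with one entry per channel of `x`.
#' @return gated array, same shape as `x`.
#' @export
sa_channel_branch <- function(x, w1, b1) {
  d <- dim4(x)
  if (length(w1) != d[1] || length(b1) != d[1]) {
    stop("channel-branch parameters must have one entry per channel")
  }
  s <- global_avg_pool(x)
  gate <- plogis(w1 * s + b1)
  y <- gate * x
  dim(y) <- d
  y
}

#' Spatial attention branch
#'
#' Normalizes each channel of `x` to zero mean and unit variance over its
#' `T x H x W` extent, applies the per-channel affine `w2, b2`, and gates the
#' original input with the sigmoid of the result.
#'
#' @param x numeric 4-D array `(C,T,H,W)`.
#' @param w2,b2 numeric vectors with one entry per channel of `x`.
#' @param eps normalization epsilon.
#' @return gated array, same shape as `x`.
#' @export
sa_spatial_branch <- function(x, w2, b2, eps = 1e-5) {
  d <- dim4(x)
  if (length(w2) != d[1] || length(b2) != d[1]) {
    stop("spatial-branch parameters must have one entry per channel")
  }
  xm <- ch_mat(x)
  mu <- rowMeans(xm)
  va <- rowMeans(xm * xm) - mu * mu
  xhat <- (xm - mu) / sqrt(va + eps)
  gate <- plogis(w2 * xhat + b2)
  y <- gate * xm
  dim(y) <- d
  y
}

#' Channel shuffle
#'
#' Reorders channels by the reshape-`(G, C/G)`-transpose-flatten permutation
#' (the ShuffleNet-v2 convention), letting information flow between the
#' attention groups. Applying the shuffle again with swapped factors
#' (`G' = C/G`) inverts it.
#'
#' @param x numeric 4-D array `(C,T,H,W)`.
#' @param G group count; must divide `C`.
#' @return array with permuted channels, same shape as `x`.
#' @export
channel_shuffle <- function(x, G) {
  d <- dim4(x)
  perm <- shuffle_perm(d[1], G)
  x[perm, , , , drop = FALSE]
}

# 1-based source indices of the reshape-(G, C/G)-transpose-flatten shuffle.
shuffle_perm <- function(C, G) {
  C <- as.integer(C)
  G <- as.integer(G)
  if (G < 1L || C %% G != 0L) stop("invalid grouping: G must divide C")
  per <- C %/% G
  i <- 0:(C - 1L)
  m <- i %/% G
  g <- i %% G
  g * per + m + 1L
}

#' Apply a full 3D shuffle-attention block
#'
#' Runs the complete block: group split, channel branch on the first half of
#' each group, spatial branch on the second half, re-concatenation, and
#' channel shuffle. The output has exactly the shape of the input, so the
#' block can be inserted anywhere in a 3D feature stack.
#'
#' @param x numeric 4-D array `(C,T,H,W)`.
#' @param p an [sa_params()] object created for `C` channels.
#' @return array of the same shape as `x`.
#' @export
sa_block <- function(x, p) {
  stopifnot(inherits(p, "sa_params"))
  d <- dim4(x)
  if (d[1] != p$channels) stop("sa_params channel count does not match input")
  tape <- tape_new()
  out <- t_sa_block(tape, tp_leaf(tape, x), list(
    w1 = p$w1, b1 = p$b1, w2 = p$w2, b2 = p$b2
  ), p$groups, p$eps)
  out$val
}

# Tape version used both by sa_block() and by the network forward pass.
# `pars` is a list with vectors w1,b1,w2,b2 (plain or nodes), blocked by
# group, each of length C/2.
t_sa_block <- function(tape, x, pars, G, eps = 1e-5) {
  d <- dim4(nd_val(x))
  C <- d[1]
  check_grouping(C, G)
  per <- C %/% G
  half <- per %/% 2L
  sub <- function(v, idx) {
    if (is_node(v)) t_vslice(tape, v, idx) else v[idx]
  }
  parts <- vector("list", 2L * G)
  for (k in seq_len(G)) {
    base <- (k - 1L) * per
    pidx <- (k - 1L) * half + seq_len(half)
    xk1 <- t_chslice(tape, x, base + seq_len(half))
    xk2 <- t_chslice(tape, x, base + half + seq_len(half))
    # channel branch: gate on the global average statistic
    s <- t_gap_all(tape, xk1)
    gate <- t_sigmoid(tape, t_vaffine(tape, s, sub(pars$w1, pidx), sub(pars$b1, pidx)))
    parts[[2L * k - 1L]] <- t_gate_ch(tape, xk1, gate)
    # spatial branch: gate on the normalized map
    gn <- t_chnorm(tape, xk2, sub(pars$w2, pidx), sub(pars$b2, pidx), eps = eps)
    parts[[2L * k]] <- t_mul(tape, t_sigmoid(tape, gn), xk2)
  }
  y <- t_concat_ch(tape, parts)
  t_perm_ch(tape, y, shuffle_perm(C, G))
}

# Slice of a parameter vector node.
t_vslice <- function(tape, v, idx) {
  vv <- nd_val(v)
  n <- length(vv)
  tp_node(tape, vv[idx], nd_id(v), function(g) {
    gv <- numeric(n)
    gv[idx] <- g
    list(gv)
  })
}
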