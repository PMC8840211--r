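# Differentiable tensor operations used to assemble the network.
#
# All feature volumes are numeric 4-D arrays with dim (C, T, H, W):
# channels, frames, rows, cols. Every t_* function takes a tape plus nodes
# and/or plain arrays, and returns a node.

dim4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

# View a (C,T,H,W) array as a C x (T*H*W) matrix without copying semantics.
ch_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  x
}

same_pad <- function(k) as.integer(k %/% 2)

## ---- convolutions -------------------------------------------------------

t_conv3d <- function(tape, x, w, stride = c(1L, 1L, 1L), pad = NULL) {
  xv <- nd_val(x)
  wv <- nd_val(w)
  if (is.null(pad)) pad <- same_pad(dim(wv)[3:5])
  stride <- as.integer(stride)
  pad <- as.integer(pad)
  y <- cpp_conv3d_fwd(xv, wv, stride, pad)
  xd <- dim(xv)
  wd <- dim(wv)
  tp_node(tape, y, c(nd_id(x), nd_id(w)), function(g) {
    dim(g) <- dim(y)
    list(
      if (nd_id(x) > 0L) cpp_conv3d_bwd_x(g, wv, stride, pad, xd),
      if (nd_id(w) > 0L) cpp_conv3d_bwd_w(g, xv, wd, stride, pad)
    )
  })
}

t_dwconv3d <- function(tape, x, w, stride = c(1L, 1L, 1L), pad = NULL) {
  xv <- nd_val(x)
  wv <- nd_val(w)
  if (is.null(pad)) pad <- same_pad(dim(wv)[2:4])
  stride <- as.integer(stride)
  pad <- as.integer(pad)
  y <- cpp_dwconv3d_fwd(xv, wv, stride, pad)
  xd <- dim(xv)
  wd <- dim(wv)
  tp_node(tape, y, c(nd_id(x), nd_id(w)), function(g) {
    dim(g) <- dim(y)
    list(
      if (nd_id(x) > 0L) cpp_dwconv3d_bwd_x(g, wv, stride, pad, xd),
      if (nd_id(w) > 0L) cpp_dwconv3d_bwd_w(g, xv, wd, stride, pad)
    )
  })
}

# Pointwise (1x1x1) convolution: w is a (Cout, Cin) matrix.
t_pconv <- function(tape, x, w) {
  xv <- nd_val(x)
  wv <- nd_val(w)
  d <- dim4(xv)
  xm <- ch_mat(xv)
  ym <- wv %*% xm
  y <- ym
  dim(y) <- c(nrow(wv), d[2:4])
  tp_node(tape, y, c(nd_id(x), nd_id(w)), function(g) {
    dim(g) <- c(nrow(wv), prod(d[2:4]))
    gx <- crossprod(wv, g)
    dim(gx) <- d
    list(gx, if (nd_id(w) > 0L) tcrossprod(g, xm))
  })
}

# Depthwise temporal transposed convolution, kernel (4,1,1), stride (2,1,1),
# padding (1,0,0): doubles the temporal extent, per channel. w is (C, 4).
t_dwtconv_t <- function(tape, x, w) {
  xv <- nd_val(x)
  wv <- nd_val(w)
  d <- dim4(xv)
  C <- d[1]
  T_ <- d[2]
  To <- 2L * T_
  y <- array(0, c(C, To, d[3], d[4]))
  for (k in 0:3) {
    i <- 0:(T_ - 1L)
    o <- 2L * i + k - 1L
    sel <- o >= 0L & o < To
    if (!any(sel)) next
    y[, o[sel] + 1L, , ] <- y[, o[sel] + 1L, , , drop = FALSE] +
      wv[, k + 1L] * xv[, i[sel] + 1L, , , drop = FALSE]
  }
  tp_node(tape, y, c(nd_id(x), nd_id(w)), function(g) {
    dim(g) <- c(C, To, d[3], d[4])
    gx <- array(0, d)
    gw <- if (nd_id(w) > 0L) matrix(0, C, 4) else NULL
    for (k in 0:3) {
      i <- 0:(T_ - 1L)
      o <- 2L * i + k - 1L
      sel <- o >= 0L & o < To
      if (!any(sel)) next
      gslice <- g[, o[sel] + 1L, , , drop = FALSE]
      xslice <- xv[, i[sel] + 1L, , , drop = FALSE]
      gx[, i[sel] + 1L, , ] <- gx[, i[sel] + 1L, , , drop = FALSE] + wv[, k + 1L] * gslice
      if (!is.null(gw)) gw[, k + 1L] <- rowSums(ch_mat(gslice * xslice))
    }
    list(gx, gw)
  })
}

## ---- normalization ------------------------------------------------------

# Per-channel normalization over all non-channel elements, with optional
# per-channel affine (batch-style normalization at batch size one; also the
# per-channel group normalization used inside the attention block when
# called without affine).
t_chnorm <- function(tape, x, gamma = NULL, beta = NULL, eps = 1e-5) {
  xv <- nd_val(x)
  d <- dim4(xv)
  n <- prod(d[-1])
  xm <- ch_mat(xv)
  mu <- rowMeans(xm)
  va <- rowMeans(xm * xm) - mu * mu
  inv <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * inv
  gv <- if (!is.null(gamma)) nd_val(gamma)
  bv <- if (!is.null(beta)) nd_val(beta)
  ym <- if (is.null(gv)) xhat else xhat * gv + bv
  y <- ym
  dim(y) <- d
  tp_node(tape, y, c(nd_id(x), nd_id(gamma), nd_id(beta)), function(g) {
    dim(g) <- c(d[1], n)
    gh <- if (is.null(gv)) g else g * gv
    m1 <- rowMeans(gh)
    m2 <- rowMeans(gh * xhat)
    gx <- inv * (gh - m1 - xhat * m2)
    dim(gx) <- d
    list(
      gx,
      if (!is.null(gamma) && nd_id(gamma) > 0L) rowSums(g * xhat),
      if (!is.null(beta) && nd_id(beta) > 0L) rowSums(g)
    )
  })
}

## ---- elementwise --------------------------------------------------------

t_relu6 <- function(tape, x) {
  xv <- nd_val(x)
  y <- pmin(pmax(xv, 0), 6)
  dim(y) <- dim(xv)
  tp_node(tape, y, nd_id(x), function(g) {
    list(g * (xv > 0 & xv < 6))
  })
}

t_hswish <- function(tape, x) {
  xv <- nd_val(x)
  y <- xv * pmin(pmax(xv + 3, 0), 6) / 6
  dim(y) <- dim(xv)
  tp_node(tape, y, nd_id(x), function(g) {
    dy <- ifelse(xv <= -3, 0, ifelse(xv >= 3, 1, (2 * xv + 3) / 6))
    list(g * dy)
  })
}

t_sigmoid <- function(tape, x) {
  xv <- nd_val(x)
  y <- 1 / (1 + exp(-xv))
  tp_node(tape, y, nd_id(x), function(g) list(g * y * (1 - y)))
}

t_tanh <- function(tape, x) {
  y <- tanh(nd_val(x))
  tp_node(tape, y, nd_id(x), function(g) list(g * (1 - y * y)))
}

t_add <- function(tape, a, b) {
  tp_node(tape, nd_val(a) + nd_val(b), c(nd_id(a), nd_id(b)),
          function(g) list(g, g))
}

t_sub <- function(tape, a, b) {
  tp_node(tape, nd_val(a) - nd_val(b), c(nd_id(a), nd_id(b)),
          function(g) list(g, -g))
}

t_mul <- function(tape, a, b) {
  av <- nd_val(a)
  bv <- nd_val(b)
  tp_node(tape, av * bv, c(nd_id(a), nd_id(b)),
          function(g) list(g * bv, g * av))
}

# Per-channel bias: y[c,..] = x[c,..] + b[c].
t_bias_ch <- function(tape, x, b) {
  xv <- nd_val(x)
  d <- dim4(xv)
  y <- xv + nd_val(b) # first dim is channels, vector recycles per channel
  tp_node(tape, y, c(nd_id(x), nd_id(b)), function(g) {
    dim(g) <- d
    list(g, if (nd_id(b) > 0L) rowSums(ch_mat(g)))
  })
}

# Per-channel gate: y[c,..] = gate[c] * x[c,..]; gate is a length-C vector.
t_gate_ch <- function(tape, x, gate) {
  xv <- nd_val(x)
  gv <- nd_val(gate)
  d <- dim4(xv)
  y <- gv * xv # first dim is channels, so the vector recycles per channel
  tp_node(tape, y, c(nd_id(x), nd_id(gate)), function(g) {
    dim(g) <- d
    list(
      gv * g,
      if (nd_id(gate) > 0L) rowSums(ch_mat(g * xv))
    )
  })
}

# Per-channel affine on a length-C vector: y = w*s + b (all length C).
t_vaffine <- function(tape, s, w, b) {
  sv <- nd_val(s)
  wv <- nd_val(w)
  tp_node(tape, wv * sv + nd_val(b), c(nd_id(s), nd_id(w), nd_id(b)),
          function(g) list(g * wv, g * sv, g))
}

## ---- reductions and shape ops ------------------------------------------

# Global average pool over (T,H,W): (C,T,H,W) -> length-C vector.
t_gap_all <- function(tape, x) {
  xv <- nd_val(x)
  d <- dim4(xv)
  n <- prod(d[-1])
  s <- rowMeans(ch_mat(xv))
  tp_node(tape, s, nd_id(x), function(g) {
    gx <- array(rep(g / n, n), d)
    list(gx)
  })
}

# Spatial average pool, temporal preserved: (C,T,H,W) -> (C,T,1,1).
t_gap_spatial <- function(tape, x) {
  xv <- nd_val(x)
  d <- dim4(xv)
  hw <- d[3] * d[4]
  xm <- xv
  dim(xm) <- c(d[1] * d[2], hw)
  y <- rowMeans(xm)
  dim(y) <- c(d[1], d[2], 1L, 1L)
  tp_node(tape, y, nd_id(x), function(g) {
    gx <- array(rep(as.vector(g) / hw, hw), d)
    list(gx)
  })
}

t_chslice <- function(tape, x, idx) {
  xv <- nd_val(x)
  d <- dim4(xv)
  y <- xv[idx, , , , drop = FALSE]
  tp_node(tape, y, nd_id(x), function(g) {
    dim(g) <- dim(y)
    gx <- array(0, d)
    gx[idx, , , ] <- g
    list(gx)
  })
}

t_concat_ch <- function(tape, parts) {
  vals <- lapply(parts, nd_val)
  cs <- vapply(vals, function(v) dim4(v)[1], integer(1))
  d1 <- dim(vals[[1]])
  y <- array(0, c(sum(cs), d1[2:4]))
  at <- 0L
  for (v in vals) {
    y[at + seq_len(dim(v)[1]), , , ] <- v
    at <- at + dim(v)[1]
  }
  ends <- cumsum(cs)
  starts <- ends - cs + 1L
  tp_node(tape, y, vapply(parts, nd_id, integer(1)), function(g) {
    dim(g) <- dim(y)
    lapply(seq_along(parts), function(i) {
      g[starts[i]:ends[i], , , , drop = FALSE]
    })
  })
}

t_perm_ch <- function(tape, x, perm) {
  xv <- nd_val(x)
  y <- xv[perm, , , , drop = FALSE]
  inv <- order(perm)
  tp_node(tape, y, nd_id(x), function(g) {
    dim(g) <- dim(y)
    list(g[inv, , , , drop = FALSE])
  })
}

t_tslice <- function(tape, x, ti) {
  xv <- nd_val(x)
  d <- dim4(xv)
  y <- xv[, ti, , , drop = FALSE]
  tp_node(tape, y, nd_id(x), function(g) {
    dim(g) <- dim(y)
    gx <- array(0, d)
    gx[, ti, , ] <- g
    list(gx)
  })
}

# Stack a list of (C,1,H,W) maps along time -> (C,T,H,W).
t_tstack <- function(tape, steps) {
  vals <- lapply(steps, nd_val)
  d <- dim4(vals[[1]])
  T_ <- length(vals)
  y <- array(0, c(d[1], T_, d[3], d[4]))
  for (t in seq_len(T_)) y[, t, , ] <- vals[[t]]
  tp_node(tape, y, vapply(steps, nd_id, integer(1)), function(g) {
    dim(g) <- dim(y)
    lapply(seq_len(T_), function(t) g[, t, , , drop = FALSE])
  })
}

t_mean_list <- function(tape, xs) {
  k <- length(xs)
  y <- Reduce(`+`, lapply(xs, nd_val)) / k
  tp_node(tape, y, vapply(xs, nd_id, integer(1)), function(g) {
    gk <- g / k
    rep(list(gk), k)
  })
}

## ---- loss ---------------------------------------------------------------

# Negative Pearson loss against a constant reference; epsilon inside the
# square roots keeps early training away from the zero-variance singularity.
t_neg_pearson <- function(tape, x, y, eps = 1e-8) {
  xv <- as.vector(nd_val(x))
  yv <- as.vector(y)
  stopifnot(length(xv) == length(yv))
  xc <- xv - mean(xv)
  yc <- yv - mean(yv)
  sxx <- sum(xc * xc) + eps
  syy <- sum(yc * yc) + eps
  sxy <- sum(xc * yc)
  denom <- sqrt(sxx) * sqrt(syy)
  r <- sxy / denom
  xd <- dim(nd_val(x))
  tp_node(tape, 1 - r, nd_id(x), function(g) {
    dr <- yc / denom - r * xc / sxx
    gx <- -g * dr
    if (!is.null(xd)) dim(gx) <- xd
    list(gx)
  })
}
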