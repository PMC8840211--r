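# Network assembly: stem convolution, inverted-residual Eblocks with 3D
# shuffle attention, pointwise expansion, depthwise-separable temporal
# decoder blocks (DCBlocks), stacked ConvGRU head, spatial pooling, and the
# 1x1x1 output convolution that yields the rPPG trace.

#' ReLU6 activation
#'
#' `min(max(x, 0), 6)`, applied elementwise.
#' @param x numeric vector or array.
#' @return same shape as `x`.
#' @export
relu6 <- function(x) pmin(pmax(x, 0), 6)

#' Hard swish activation
#'
#' The hardware-friendly swish approximation `x * ReLU6(x + 3) / 6`, applied
#' elementwise. Zero for `x <= -3`, identity for `x >= 3`.
#' @param x numeric vector or array.
#' @return same shape as `x`.
#' @export
h_swish <- function(x) x * relu6(x + 3) / 6

#' Layer-by-layer architecture table
#'
#' The ordered layer specification of the rPPG network: a 3x3x3 stem
#' convolution, eleven inverted-residual Eblocks (pointwise expansion,
#' depthwise 3-D convolution, optional shuffle-attention block, pointwise
#' projection), a 1x1x1 expansion to 576 channels, two depthwise-separable
#' temporal decoder blocks that restore the frame count, a three-layer
#' 64-channel ConvGRU head, spatial global average pooling, and a 1x1x1
#' output convolution. Strides are (temporal, height, width); the temporal
#' extent halves twice in the encoder and doubles twice in the decoder.
#'
#' @return a data.frame with one row per layer: `layer` (name), `op`
#'   (`stem`, `eblock`, `pwconv`, `dcblock`, `convgru`, `gap`, `head`),
#'   `kernel`, `exp` (expansion width), `out` (output channels), `st`, `sh`,
#'   `sw` (stride triple), `sa` (shuffle attention flag), and `nl`
#'   (nonlinearity: `relu6`, `hswish`, or `none`).
#' @export
esa_layer_table <- function() {
  eb <- function(i, k, e, o, s, sa, nl) {
    data.frame(layer = sprintf("eb%02d", i), op = "eblock", kernel = k,
               exp = e, out = o, st = s[1], sh = s[2], sw = s[3],
               sa = sa, nl = nl, stringsAsFactors = FALSE)
  }
  rbind(
    data.frame(layer = "stem", op = "stem", kernel = 3L, exp = NA_integer_,
               out = 16L, st = 1L, sh = 2L, sw = 2L, sa = FALSE, nl = "relu6",
               stringsAsFactors = FALSE),
    eb(1L, 3L, 16L, 16L, c(1L, 2L, 2L), TRUE, "relu6"),
    eb(2L, 3L, 72L, 24L, c(1L, 2L, 2L), FALSE, "relu6"),
    eb(3L, 3L, 88L, 24L, c(1L, 1L, 1L), FALSE, "relu6"),
    eb(4L, 5L, 96L, 40L, c(2L, 2L, 2L), TRUE, "hswish"),
    eb(5L, 5L, 240L, 40L, c(1L, 1L, 1L), TRUE, "hswish"),
    eb(6L, 5L, 240L, 40L, c(1L, 1L, 1L), TRUE, "hswish"),
    eb(7L, 5L, 120L, 48L, c(1L, 1L, 1L), TRUE, "hswish"),
    eb(8L, 5L, 144L, 48L, c(1L, 1L, 1L), TRUE, "hswish"),
    eb(9L, 5L, 288L, 96L, c(2L, 2L, 2L), TRUE, "hswish"),
    eb(10L, 5L, 576L, 96L, c(1L, 1L, 1L), TRUE, "hswish"),
    eb(11L, 5L, 576L, 96L, c(1L, 1L, 1L), TRUE, "hswish"),
    data.frame(layer = "pw576", op = "pwconv", kernel = 1L, exp = NA_integer_,
               out = 576L, st = 1L, sh = 1L, sw = 1L, sa = FALSE,
               nl = "hswish", stringsAsFactors = FALSE),
    data.frame(layer = c("dc1", "dc2"), op = "dcblock", kernel = 4L,
               exp = NA_integer_, out = c(288L, 144L), st = 2L, sh = 1L,
               sw = 1L, sa = FALSE, nl = "hswish", stringsAsFactors = FALSE),
    data.frame(layer = "convgru", op = "convgru", kernel = 3L,
               exp = NA_integer_, out = 64L, st = 1L, sh = 1L, sw = 1L,
               sa = FALSE, nl = "none", stringsAsFactors = FALSE),
    data.frame(layer = "gap", op = "gap", kernel = NA_integer_,
               exp = NA_integer_, out = 64L, st = 1L, sh = 1L, sw = 1L,
               sa = FALSE, nl = "none", stringsAsFactors = FALSE),
    data.frame(layer = "head", op = "head", kernel = 1L, exp = NA_integer_,
               out = 1L, st = 1L, sh = 1L, sw = 1L, sa = FALSE, nl = "none",
               stringsAsFactors = FALSE)
  )
}

#' Construct the rPPG network
#'
#' Builds the full spatiotemporal attention network described by
#' [esa_layer_table()] with freshly initialized parameters. The network maps
#' a `(3, T, H, W)` facial-video volume (frames at 30 fps, `T` divisible by
#' 4, `H` and `W` divisible by 32) to a length-`T` rPPG trace.
#'
#' Initialization: convolution kernels are He-scaled Gaussian, channel
#' normalizations start at identity, attention blocks start near-neutral
#' (channel gate 0.5, spatial gate centered), ConvGRU kernels small-variance
#' Gaussian with zero gate biases.
#'
#' @param sa_groups requested shuffle-attention group count (clamped per
#'   layer to a divisor of the expanded channel width).
#' @param gru_kernel spatial kernel extent of the ConvGRU convolutions.
#' @param seed integer seed for the parameter initialization.
#' @return an object of class `esa_rppgnet`: a list with the layer `table`,
#'   the flat named parameter list `params`, and `config`.
#' @export
esa_rppgnet <- function(sa_groups = 4L, gru_kernel = 3L, seed = 1L) {
  tab <- esa_layer_table()
  cfg <- list(sa_groups = as.integer(sa_groups),
              gru_kernel = as.integer(gru_kernel),
              eps = 1e-5, seed = as.integer(seed))
  params <- with_seed(seed, init_params(tab, cfg))
  structure(list(table = tab, params = params, config = cfg),
            class = "esa_rppgnet")
}

# Evaluate `expr` under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

he_conv <- function(cout, cin, kt, kh, kw) {
  fan_in <- cin * kt * kh * kw
  array(stats::rnorm(cout * cin * kt * kh * kw, sd = sqrt(2 / fan_in)),
        c(cout, cin, kt, kh, kw))
}

init_params <- function(tab, cfg) {
  p <- list()
  cin <- 3L
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    nm <- r$layer
    if (r$op == "stem") {
      p[[paste0(nm, ".w")]] <- he_conv(r$out, cin, r$kernel, r$kernel, r$kernel)
      p[[paste0(nm, ".bn.g")]] <- rep(1, r$out)
      p[[paste0(nm, ".bn.b")]] <- rep(0, r$out)
      cin <- r$out
    } else if (r$op == "eblock") {
      e <- r$exp
      p[[paste0(nm, ".pw1.w")]] <- matrix(stats::rnorm(e * cin, sd = sqrt(2 / cin)), e, cin)
      p[[paste0(nm, ".bn1.g")]] <- rep(1, e)
      p[[paste0(nm, ".bn1.b")]] <- rep(0, e)
      p[[paste0(nm, ".dw.w")]] <- array(
        stats::rnorm(e * r$kernel^3, sd = sqrt(2 / r$kernel^3)),
        c(e, r$kernel, r$kernel, r$kernel))
      p[[paste0(nm, ".bn2.g")]] <- rep(1, e)
      p[[paste0(nm, ".bn2.b")]] <- rep(0, e)
      if (r$sa) {
        half <- e %/% 2L
        p[[paste0(nm, ".sa.w1")]] <- rep(0, half)
        p[[paste0(nm, ".sa.b1")]] <- rep(0, half)
        p[[paste0(nm, ".sa.w2")]] <- rep(1, half)
        p[[paste0(nm, ".sa.b2")]] <- rep(0, half)
      }
      p[[paste0(nm, ".pw2.w")]] <- matrix(stats::rnorm(r$out * e, sd = sqrt(2 / e)), r$out, e)
      p[[paste0(nm, ".bn3.g")]] <- rep(1, r$out)
      p[[paste0(nm, ".bn3.b")]] <- rep(0, r$out)
      cin <- r$out
    } else if (r$op == "pwconv") {
      p[[paste0(nm, ".w")]] <- matrix(stats::rnorm(r$out * cin, sd = sqrt(2 / cin)), r$out, cin)
      p[[paste0(nm, ".bn.g")]] <- rep(1, r$out)
      p[[paste0(nm, ".bn.b")]] <- rep(0, r$out)
      cin <- r$out
    } else if (r$op == "dcblock") {
      p[[paste0(nm, ".dw.w")]] <- matrix(stats::rnorm(cin * 4, sd = sqrt(2 / 4)), cin, 4)
      p[[paste0(nm, ".bn1.g")]] <- rep(1, cin)
      p[[paste0(nm, ".bn1.b")]] <- rep(0, cin)
      p[[paste0(nm, ".pw.w")]] <- matrix(stats::rnorm(r$out * cin, sd = sqrt(2 / cin)), r$out, cin)
      p[[paste0(nm, ".bn2.g")]] <- rep(1, r$out)
      p[[paste0(nm, ".bn2.b")]] <- rep(0, r$out)
      cin <- r$out
    } else if (r$op == "convgru") {
      for (l in 1:3) {
        lp <- convgru_params(if (l == 1L) cin else r$out, r$out,
                             kernel = cfg$gru_kernel)
        for (f in c("wz", "wr", "w", "uz", "ur", "u", "bz", "br", "bh")) {
          p[[sprintf("gru%d.%s", l, f)]] <- lp[[f]]
        }
      }
      cin <- r$out
    } else if (r$op == "gap") {
      # no parameters
    } else if (r$op == "head") {
      p[[paste0(nm, ".w")]] <- matrix(stats::rnorm(r$out * cin, sd = sqrt(1 / cin)), r$out, cin)
      p[[paste0(nm, ".b")]] <- rep(0, r$out)
      cin <- r$out
    }
  }
  p
}

#' @export
print.esa_rppgnet <- function(x, ...) {
  pr <- profile_network(x)
  cat("Efficient spatiotemporal attention rPPG network\n")
  cat(sprintf("  layers: %d  parameters: %s (%.3f M)\n",
              nrow(x$table), format(pr$total_params, big.mark = ","),
              pr$total_params / 1e6))
  cat(sprintf("  complexity at 3x128x128x128 input: %.3f G MACs\n",
              pr$total_macs / 1e9))
  cat(sprintf("  attention groups: %d, ConvGRU kernel: %dx%d\n",
              x$config$sa_groups, x$config$gru_kernel, x$config$gru_kernel))
  invisible(x)
}

#' @export
coef.esa_rppgnet <- function(object, ...) object$params

check_input_contract <- function(d) {
  if (length(d) != 4L || d[1] != 3L) {
    stop("input must be a (3, T, H, W) volume")
  }
  if (d[2] %% 4L != 0L) {
    stop(sprintf("temporal extent T = %d must be divisible by 4", d[2]))
  }
  if (d[3] %% 32L != 0L || d[4] %% 32L != 0L) {
    stop(sprintf("spatial extent %d x %d must be a multiple of 32", d[3], d[4]))
  }
}

t_activation <- function(tape, x, nl) {
  switch(nl,
    relu6 = t_relu6(tape, x),
    hswish = t_hswish(tape, x),
    none = x,
    stop("unknown nonlinearity tag: ", nl)
  )
}

# Full network forward on a tape. `leaves` is the named list of parameter
# nodes (or plain arrays for inference without gradients). `hook`, if given,
# is called as hook(layer_name, dim) on every layer output.
t_net_forward <- function(tape, x, leaves, tab, cfg, hook = NULL) {
  eps <- cfg$eps
  L <- function(nm) leaves[[nm]]
  cur <- x
  cin <- dim4(nd_val(x))[1]
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    nm <- r$layer
    if (r$op == "stem") {
      cur <- t_conv3d(tape, cur, L("stem.w"), stride = c(r$st, r$sh, r$sw))
      cur <- t_chnorm(tape, cur, L("stem.bn.g"), L("stem.bn.b"), eps)
      cur <- t_activation(tape, cur, r$nl)
    } else if (r$op == "eblock") {
      inp <- cur
      cur <- t_pconv(tape, cur, L(paste0(nm, ".pw1.w")))
      cur <- t_chnorm(tape, cur, L(paste0(nm, ".bn1.g")), L(paste0(nm, ".bn1.b")), eps)
      cur <- t_activation(tape, cur, r$nl)
      cur <- t_dwconv3d(tape, cur, L(paste0(nm, ".dw.w")), stride = c(r$st, r$sh, r$sw))
      cur <- t_chnorm(tape, cur, L(paste0(nm, ".bn2.g")), L(paste0(nm, ".bn2.b")), eps)
      cur <- t_activation(tape, cur, r$nl)
      if (r$sa) {
        G <- sa_effective_groups(r$exp, cfg$sa_groups)
        cur <- t_sa_block(tape, cur, list(
          w1 = L(paste0(nm, ".sa.w1")), b1 = L(paste0(nm, ".sa.b1")),
          w2 = L(paste0(nm, ".sa.w2")), b2 = L(paste0(nm, ".sa.b2"))
        ), G, eps)
      }
      cur <- t_pconv(tape, cur, L(paste0(nm, ".pw2.w")))
      cur <- t_chnorm(tape, cur, L(paste0(nm, ".bn3.g")), L(paste0(nm, ".bn3.b")), eps)
      if (r$st == 1L && r$sh == 1L && r$sw == 1L && cin == r$out) {
        cur <- t_add(tape, cur, inp) # inverted-residual skip
      }
    } else if (r$op == "pwconv") {
      cur <- t_pconv(tape, cur, L(paste0(nm, ".w")))
      cur <- t_chnorm(tape, cur, L(paste0(nm, ".bn.g")), L(paste0(nm, ".bn.b")), eps)
      cur <- t_activation(tape, cur, r$nl)
    } else if (r$op == "dcblock") {
      cur <- t_dwtconv_t(tape, cur, L(paste0(nm, ".dw.w")))
      cur <- t_chnorm(tape, cur, L(paste0(nm, ".bn1.g")), L(paste0(nm, ".bn1.b")), eps)
      cur <- t_activation(tape, cur, r$nl)
      cur <- t_pconv(tape, cur, L(paste0(nm, ".pw.w")))
      cur <- t_chnorm(tape, cur, L(paste0(nm, ".bn2.g")), L(paste0(nm, ".bn2.b")), eps)
      cur <- t_activation(tape, cur, r$nl)
    } else if (r$op == "convgru") {
      layers <- lapply(1:3, function(l) {
        fields <- c("wz", "wr", "w", "uz", "ur", "u", "bz", "br", "bh")
        stats::setNames(lapply(fields, function(f) L(sprintf("gru%d.%s", l, f))), fields)
      })
      cur <- t_convgru_stack(tape, cur, layers)
    } else if (r$op == "gap") {
      cur <- t_gap_spatial(tape, cur)
    } else if (r$op == "head") {
      cur <- t_pconv(tape, cur, L("head.w"))
      cur <- t_bias_ch(tape, cur, L("head.b"))
    }
    cin <- r$out
    if (!is.null(hook)) hook(nm, dim4(nd_val(cur)))
  }
  cur
}

#' Run the network forward
#'
#' Maps a facial-video volume to an rPPG trace with one sample per input
#' frame. Deterministic given fixed parameters and input.
#'
#' @param model an [esa_rppgnet()] object.
#' @param video numeric array `(3, T, H, W)`, `T` divisible by 4, `H` and
#'   `W` divisible by 32.
#' @param hook optional `function(layer, dim)` invoked with every
#'   intermediate output shape (used to assert the architecture's shape
#'   contract).
#' @return numeric vector of length `T`.
#' @export
rppg_forward <- function(model, video, hook = NULL) {
  check_input_contract(dim(video))
  tape <- tape_new()
  out <- t_net_forward(tape, tp_leaf(tape, video), model$params,
                       model$table, model$config, hook = hook)
  as.vector(out$val)
}
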