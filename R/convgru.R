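# Convolutional GRU: a gated recurrent unit whose dense transforms are
# replaced by zero-padded 2-D convolutions, preserving feature-map geometry
# over time. A 3-layer stack with elementwise-mean output fusion forms the
# temporal head of the network.

#' Convolutional GRU cell parameters
#'
#' Creates the six convolution kernels and three gate biases of one ConvGRU
#' cell. Update gate `z`, reset gate `r`, and candidate state follow
#' `z = sigmoid(Wz*x + Uz*h)`, `r2 = sigmoid(Wr*x + Ur*h)` (the reset gate),
#' `h~ = tanh(W*x + U*(r2 . h))`, `h' = (1-z).h + z.h~`, where `*` is a
#' spatially zero-padded 2-D convolution and `.` elementwise product.
#'
#' @param in_channels channels of the per-frame input feature map.
#' @param hidden_channels channels of the hidden state.
#' @param kernel odd spatial kernel extent (default 3); zero padding
#'   `kernel %/% 2` keeps the hidden state's spatial size constant over time.
#' @param init_sd standard deviation of the symmetric random kernel
#'   initialization; biases start at zero.
#' @param rng optional function `n -> numeric(n)` drawing the initial kernel
#'   entries (defaults to `rnorm` scaled by `init_sd`).
#' @return an object of class `convgru_params`.
#' @export
convgru_params <- function(in_channels, hidden_channels, kernel = 3L,
                           init_sd = NULL, rng = NULL) {
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) stop("ConvGRU kernel extent must be odd")
  ci <- as.integer(in_channels)
  ch <- as.integer(hidden_channels)
  if (is.null(rng)) rng <- stats::rnorm
  draw <- function(cin) {
    sd <- if (is.null(init_sd)) sqrt(2 / (cin * kernel^2)) else init_sd
    array(rng(ch * cin * kernel * kernel) * sd, c(ch, cin, 1L, kernel, kernel))
  }
  structure(list(
    in_channels = ci, hidden_channels = ch, kernel = kernel,
    wz = draw(ci), wr = draw(ci), w = draw(ci),
    uz = draw(ch), ur = draw(ch), u = draw(ch),
    bz = numeric(ch), br = numeric(ch), bh = numeric(ch)
  ), class = "convgru_params")
}

#' Single ConvGRU step
#'
#' Advances the hidden state by one frame. Input and hidden state must agree
#' spatially; the output spatial size equals the input spatial size.
#'
#' @param x input feature map, array `(C_in, H, W)` or `(C_in, 1, H, W)`.
#' @param h_prev previous hidden state, array `(C_hid, H, W)` or
#'   `(C_hid, 1, H, W)`.
#' @param p a [convgru_params()] object.
#' @return hidden state array `(C_hid, H, W)`.
#' @export
convgru_cell <- function(x, h_prev, p) {
  x <- as_chw4(x)
  h_prev <- as_chw4(h_prev)
  if (!all(dim(x)[3:4] == dim(h_prev)[3:4])) {
    stop("spatial sizes of input and hidden state must agree")
  }
  tape <- tape_new()
  h <- t_convgru_step(tape, tp_leaf(tape, x), tp_leaf(tape, h_prev), p)
  drop_t(h$val)
}

as_chw4 <- function(x) {
  d <- dim(x)
  if (is.null(d) || !length(d) %in% c(3L, 4L)) {
    stop("expected a (C,H,W) or (C,1,H,W) array")
  }
  if (length(d) == 3L) dim(x) <- c(d[1], 1L, d[2], d[3])
  x
}

drop_t <- function(x) {
  d <- dim(x)
  dim(x) <- d[-2]
  x
}

# One cell step on the tape. x, h are (C,1,H,W) nodes; params may be plain
# arrays or nodes (a named list with wz,wr,w,uz,ur,u,bz,br,bh).
t_convgru_step <- function(tape, x, h, p, xz = NULL, xr = NULL, xw = NULL) {
  # Input-side convolutions may be precomputed for a whole sequence and
  # passed in as per-step slices (xz, xr, xw).
  if (is.null(xz)) xz <- t_conv3d(tape, x, p$wz)
  if (is.null(xr)) xr <- t_conv3d(tape, x, p$wr)
  if (is.null(xw)) xw <- t_conv3d(tape, x, p$w)
  z <- t_sigmoid(tape, t_bias_ch(tape, t_add(tape, xz, t_conv3d(tape, h, p$uz)), p$bz))
  r <- t_sigmoid(tape, t_bias_ch(tape, t_add(tape, xr, t_conv3d(tape, h, p$ur)), p$br))
  rh <- t_mul(tape, r, h)
  cand <- t_tanh(tape, t_bias_ch(tape, t_add(tape, xw, t_conv3d(tape, rh, p$u)), p$bh))
  # h' = h + z * (cand - h): convex combination of h_prev and candidate
  t_add(tape, h, t_mul(tape, z, t_sub(tape, cand, h)))
}

#' Run a ConvGRU over a frame sequence
#'
#' Iterates the cell over the `T` frames of `xs`, starting from `h0`
#' (zeros by default), and returns every per-step hidden state.
#'
#' @param xs input sequence, array `(C_in, T, H, W)` with `T >= 1`.
#' @param p a [convgru_params()] object.
#' @param h0 optional initial hidden state `(C_hid, H, W)`.
#' @return array `(C_hid, T, H, W)` of hidden states.
#' @export
convgru_run <- function(xs, p, h0 = NULL) {
  d <- dim4(xs)
  if (d[2] < 1L) stop("empty sequence")
  tape <- tape_new()
  out <- t_convgru_run(tape, tp_leaf(tape, xs), p, h0 = h0)
  out$val
}

t_convgru_run <- function(tape, xs, p, h0 = NULL) {
  d <- dim4(nd_val(xs))
  T_ <- d[2]
  ch <- dim(nd_val(p$uz))[1]
  if (is.null(h0)) h0 <- array(0, c(ch, d[3], d[4]))
  h <- tp_leaf(tape, as_chw4(h0))
  # Precompute the three input-side convolutions over the full sequence
  # (temporal kernel extent 1 makes them per-frame).
  xz <- t_conv3d(tape, xs, p$wz)
  xr <- t_conv3d(tape, xs, p$wr)
  xw <- t_conv3d(tape, xs, p$w)
  steps <- vector("list", T_)
  for (t in seq_len(T_)) {
    h <- t_convgru_step(tape, NULL, h, p,
      xz = t_tslice(tape, xz, t),
      xr = t_tslice(tape, xr, t),
      xw = t_tslice(tape, xw, t)
    )
    steps[[t]] <- h
  }
  t_tstack(tape, steps)
}

#' Stacked ConvGRU with output fusion
#'
#' Runs a stack of ConvGRU layers (each layer consuming the previous layer's
#' hidden-state sequence) and fuses the layers' outputs by elementwise mean.
#' All hidden widths must be equal for the fusion to be defined.
#'
#' @param xs input sequence, array `(C_in, T, H, W)`.
#' @param layers list of [convgru_params()] objects; layer `l`'s input
#'   channels must equal layer `l-1`'s hidden channels.
#' @return array `(C_hid, T, H, W)`: the per-time-step mean of all layers'
#'   hidden states.
#' @export
convgru_stack <- function(xs, layers) {
  tape <- tape_new()
  out <- t_convgru_stack(tape, tp_leaf(tape, xs), layers)
  out$val
}

t_convgru_stack <- function(tape, xs, layers) {
  widths <- vapply(layers, function(p) dim(nd_val(p$uz))[1], numeric(1))
  if (length(unique(widths)) != 1L) {
    stop("all ConvGRU hidden widths must be equal for mean fusion")
  }
  outs <- vector("list", length(layers))
  inp <- xs
  for (l in seq_along(layers)) {
    inp <- t_convgru_run(tape, inp, layers[[l]])
    outs[[l]] <- inp
  }
  if (length(outs) == 1L) outs[[1]] else t_mean_list(tape, outs)
}
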