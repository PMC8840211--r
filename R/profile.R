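# Closed-form complexity accounting: multiplication (MAC) counts per the
# separable-convolution cost model, and trainable parameter counts, walked
# over the layer table without running a forward pass.
#
# Convention: one unit per multiply-accumulate; convolutions, transposed
# convolutions and the six ConvGRU convolutions are counted; normalization,
# nonlinearities, pooling and attention gating are excluded (they are O(NN)
# elementwise against the convolutions' O(NN * k^3 * C)).

#' Convolution complexity descriptor
#'
#' Bundles the quantities of the separable-convolution cost model: input and
#' output spatial extents `df`/`dg`, kernel extent `dk`, input/output channel
#' counts `m`/`n`, and temporal extent `t_len`.
#'
#' @param df,dg spatial extent (square) of input and output feature maps.
#' @param dk kernel extent (cubic).
#' @param m,n input and output channel counts.
#' @param t_len temporal extent.
#' @return an object of class `conv_complexity`.
#' @export
conv_complexity <- function(df, dg, dk, m, n, t_len) {
  v <- c(df = df, dg = dg, dk = dk, m = m, n = n, t_len = t_len)
  if (any(v < 1) || any(v != round(v))) {
    stop("all complexity quantities must be positive integers")
  }
  structure(as.list(v), class = "conv_complexity")
}

#' Multiplication count of a standard 3D convolution
#'
#' `dk^3 * dg^2 * m * n * t_len`: every output voxel of every output channel
#' accumulates a full `dk^3 * m` kernel application.
#'
#' @param cc a [conv_complexity()] descriptor.
#' @return numeric multiplication count.
#' @export
std_conv_macs <- function(cc) {
  stopifnot(inherits(cc, "conv_complexity"))
  cc$dk^3 * cc$dg^2 * cc$m * cc$n * cc$t_len
}

#' Multiplication count of a 3D depthwise-separable convolution
#'
#' Depthwise stage `dk^3 * dg^2 * m * t_len` plus pointwise stage
#' `dg^2 * m * n * t_len`. For unit stride and matched shapes the ratio to
#' [std_conv_macs()] is exactly `1/n + 1/dk^3`.
#'
#' @param cc a [conv_complexity()] descriptor.
#' @return numeric multiplication count.
#' @export
dw_sep_macs <- function(cc) {
  stopifnot(inherits(cc, "conv_complexity"))
  cc$dk^3 * cc$dg^2 * cc$m * cc$t_len + cc$dg^2 * cc$m * cc$n * cc$t_len
}

#' Profile the network's complexity and size
#'
#' Walks the layer table, propagating the input shape and accumulating per
#' layer (i) multiplications, under the multiplications-only convention of
#' the separable-convolution cost model, generalized to anisotropic strides
#' by counting on actual output extents, and (ii) trainable parameters:
#' convolution and transposed-convolution weights and biases, normalization
#' affine pairs, attention scale/shift vectors, and the six convolutions of
#' each ConvGRU layer. The parameter column agrees exactly with the sizes of
#' the instantiated parameter arrays.
#'
#' @param model an [esa_rppgnet()] object (or a layer table data.frame as
#'   returned by [esa_layer_table()]).
#' @param input_shape input volume shape `(C, T, H, W)`; the published
#'   operating point is `c(3, 128, 128, 128)`.
#' @param sa_groups attention group count used when `model` is a bare table.
#' @param gru_kernel ConvGRU kernel extent used when `model` is a bare table.
#' @return an object of class `rppgnet_profile`: list with `layers` (a
#'   data.frame: layer, macs, params), `total_macs`, `total_params`, and the
#'   input shape.
#' @export
profile_network <- function(model, input_shape = c(3L, 128L, 128L, 128L),
                            sa_groups = 4L, gru_kernel = 3L) {
  if (inherits(model, "esa_rppgnet")) {
    tab <- model$table
    sa_groups <- model$config$sa_groups
    gru_kernel <- model$config$gru_kernel
  } else {
    tab <- model
  }
  shp <- as.integer(input_shape) # (C,T,H,W)
  out <- data.frame(layer = character(0), macs = numeric(0), params = numeric(0))
  add <- function(nm, macs, params) {
    out <<- rbind(out, data.frame(layer = nm, macs = macs, params = params))
  }
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    cin <- shp[1]
    tin <- shp[2]
    hin <- shp[3]
    win <- shp[4]
    if (r$op == "stem") {
      toh <- c(tin %/% r$st, hin %/% r$sh, win %/% r$sw)
      macs <- r$kernel^3 * cin * r$out * prod(toh)
      params <- r$kernel^3 * cin * r$out + 2 * r$out
      shp <- c(r$out, toh)
      add(r$layer, macs, params)
    } else if (r$op == "eblock") {
      e <- r$exp
      toh <- c(tin %/% r$st, hin %/% r$sh, win %/% r$sw)
      macs <- cin * e * tin * hin * win + # pointwise expansion
        r$kernel^3 * e * prod(toh) + # depthwise
        e * r$out * prod(toh) # pointwise projection
      params <- cin * e + 2 * e + # expansion + norm
        r$kernel^3 * e + 2 * e + # depthwise + norm
        (if (r$sa) 2 * e else 0) + # attention scale/shift
        e * r$out + 2 * r$out # projection + norm
      shp <- c(r$out, toh)
      add(r$layer, macs, params)
    } else if (r$op == "pwconv") {
      macs <- cin * r$out * tin * hin * win
      params <- cin * r$out + 2 * r$out
      shp <- c(r$out, tin, hin, win)
      add(r$layer, macs, params)
    } else if (r$op == "dcblock") {
      tout <- 2L * tin
      macs <- 4 * cin * tin * hin * win + # depthwise temporal transposed
        cin * r$out * tout * hin * win # pointwise projection
      params <- 4 * cin + 2 * cin + cin * r$out + 2 * r$out
      shp <- c(r$out, tout, hin, win)
      add(r$layer, macs, params)
    } else if (r$op == "convgru") {
      k2 <- gru_kernel^2
      macs <- 0
      params <- 0
      lin <- cin
      for (l in 1:3) {
        macs <- macs + (3 * k2 * lin * r$out + 3 * k2 * r$out^2) * hin * win * tin
        params <- params + 3 * k2 * lin * r$out + 3 * k2 * r$out^2 + 3 * r$out
        lin <- r$out
      }
      shp <- c(r$out, tin, hin, win)
      add(r$layer, macs, params)
    } else if (r$op == "gap") {
      shp <- c(cin, tin, 1L, 1L)
      add(r$layer, 0, 0)
    } else if (r$op == "head") {
      macs <- cin * r$out * tin * hin * win
      params <- cin * r$out + r$out
      shp <- c(r$out, tin, hin, win)
      add(r$layer, macs, params)
    } else {
      stop("unknown operator kind: ", r$op)
    }
  }
  structure(list(layers = out, total_macs = sum(out$macs),
                 total_params = sum(out$params), input_shape = input_shape),
            class = "rppgnet_profile")
}

#' @export
print.rppgnet_profile <- function(x, ...) {
  cat(sprintf("Complexity profile at input %s\n",
              paste(x$input_shape, collapse = "x")))
  df <- x$layers
  df$macs <- sprintf("%12.0f", df$macs)
  df$params <- sprintf("%9.0f", df$params)
  print(df, row.names = FALSE)
  cat(sprintf("total: %.4f G MACs, %.4f M parameters\n",
              x$total_macs / 1e9, x$total_params / 1e6))
  invisible(x)
}

#' Write / read the layer table as plain text
#'
#' Serializes the architecture as a tab-separated table, one layer per line,
#' mirroring the layer columns, so a network variant can be described and
#' rebuilt without code.
#'
#' @param tab a layer table (see [esa_layer_table()]), or an
#'   [esa_rppgnet()] object whose table is taken.
#' @param path file path.
#' @return `read_network_spec` returns the layer table data.frame.
#' @export
write_network_spec <- function(tab, path) {
  if (inherits(tab, "esa_rppgnet")) tab <- tab$table
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab$sa <- as.logical(tab$sa)
  tab
}

#' Save / load all network weights
#'
#' Stores every trainable parameter array of a model in a single archival
#' file (R serialization), together with the layer table and configuration,
#' and restores it.
#'
#' @param model an [esa_rppgnet()] object.
#' @param path file path for the checkpoint.
#' @return `load_checkpoint` returns the restored `esa_rppgnet` object.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "esa_rppgnet"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(obj, class = c(if (!is.null(obj$fit)) "rppgnet_fit", "esa_rppgnet"))
}
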