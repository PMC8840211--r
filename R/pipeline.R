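# End-to-end orchestration: face-region cropping with cached boxes, clip
# slicing, the training loop, whole-video inference with window stitching,
# and HRV agreement evaluation.

#' Built-in face detectors
#'
#' A detector is a function `(frame, t) -> c(row0, col0, row1, col1)`
#' (1-based inclusive pixel box) or `NULL` on failure, where `frame` is a
#' `(3, H, W)` array and `t` the frame index. `detector_full_frame()` always
#' returns the whole frame; `detector_fixed_box(box)` always returns `box`;
#' `detector_from_boxes(boxes)` replays a per-frame box table (e.g. the true
#' boxes from [render_video()]). An external face detector (e.g. an MTCNN
#' wrapper) can be plugged in with the same signature.
#'
#' @param box,boxes a length-4 box / a `T x 4` matrix of boxes.
#' @return a detector function.
#' @export
detector_full_frame <- function() {
  function(frame, t) c(1L, 1L, dim(frame)[2], dim(frame)[3])
}

#' @rdname detector_full_frame
#' @export
detector_fixed_box <- function(box) {
  force(box)
  function(frame, t) box
}

#' @rdname detector_full_frame
#' @export
detector_from_boxes <- function(boxes) {
  force(boxes)
  function(frame, t) boxes[t, ]
}

# Bilinear resize of a (3, h, w) frame to (3, H, W).
bilinear_resize <- function(frame, H, W) {
  d <- dim(frame)
  h <- d[2]
  w <- d[3]
  if (h == H && w == W) return(frame)
  ry <- (seq_len(H) - 0.5) * h / H + 0.5
  rx <- (seq_len(W) - 0.5) * w / W + 0.5
  y0 <- pmin(pmax(floor(ry), 1), h)
  x0 <- pmin(pmax(floor(rx), 1), w)
  y1 <- pmin(y0 + 1, h)
  x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ry - y0, 0), 1)
  fx <- pmin(pmax(rx - x0, 0), 1)
  out <- array(0, c(3, H, W))
  for (ch in 1:3) {
    m <- frame[ch, , ]
    a <- m[y0, x0, drop = FALSE]
    b <- m[y0, x1, drop = FALSE]
    cc <- m[y1, x0, drop = FALSE]
    dd <- m[y1, x1, drop = FALSE]
    wfx <- matrix(fx, H, W, byrow = TRUE)
    wfy <- matrix(fy, H, W)
    out[ch, , ] <- (a * (1 - wfx) + b * wfx) * (1 - wfy) +
      (cc * (1 - wfx) + dd * wfx) * wfy
  }
  out
}

#' Crop the face region with cached boxes
#'
#' Invokes the detector on frames 1, 1+R, 1+2R, ... and reuses each detected
#' box for the following `R - 1` frames, mirroring the cached-detection
#' cadence used on real video. If the detector fails on a refresh frame the
#' last box is reused (with a message); failure on the first frame is fatal.
#' Crops are bilinearly resized to `size x size`.
#'
#' @param video array `(3, T, H, W)`.
#' @param detector a detector function (see [detector_full_frame()]).
#' @param refresh detector refresh period R in frames (default 10).
#' @param size output spatial size (default 128).
#' @return list with `video` (`(3, T, size, size)`), `boxes` (the box used
#'   per frame), and `detector_calls`.
#' @export
crop_faces <- function(video, detector, refresh = 10L, size = 128L) {
  d <- dim4(video)
  T_ <- d[2]
  refresh <- max(1L, as.integer(refresh))
  box <- NULL
  calls <- 0L
  boxes <- matrix(0L, T_, 4)
  out <- array(0, c(3, T_, size, size))
  for (t in seq_len(T_)) {
    if ((t - 1L) %% refresh == 0L) {
      frame <- video[, t, , , drop = FALSE]
      dim(frame) <- d[c(1, 3, 4)]
      calls <- calls + 1L
      nb <- tryCatch(detector(frame, t), error = function(e) NULL)
      if (is.null(nb)) {
        if (is.null(box)) stop("no face found in the first frame")
        message(sprintf("detector failed at frame %d; reusing last box", t))
      } else {
        box <- as.integer(nb)
      }
    }
    boxes[t, ] <- box
    crop <- video[, t, box[1]:box[3], box[2]:box[4], drop = FALSE]
    dim(crop) <- c(3L, box[3] - box[1] + 1L, box[4] - box[2] + 1L)
    out[, t, , ] <- bilinear_resize(crop, size, size)
  }
  list(video = out, boxes = boxes, detector_calls = calls)
}

#' Slice a recording into aligned training clips
#'
#' Cuts the video and its reference PPG (aligned one-to-one at the same
#' rate) into windows of `clip_len` frames advancing by `stride` frames.
#' The reference is band-pass filtered (0.5-4 Hz) once over the whole
#' record, then each window's target is z-normalized.
#'
#' @param video array `(3, T, H, W)`.
#' @param ppg a [pulse_trace()] with one sample per video frame.
#' @param clip_len window length in frames (default 128).
#' @param stride window step in frames (default 8).
#' @param band training-target filter band in Hz.
#' @return list of clips, each a list(video, target, start) where `start`
#'   is the 1-based first frame of the window.
#' @export
slice_clips <- function(video, ppg, clip_len = 128L, stride = 8L,
                        band = c(0.5, 4)) {
  d <- dim4(video)
  T_ <- d[2]
  ppg <- as_pulse_trace(ppg)
  if (length(ppg$samples) != T_) {
    stop("video frames and PPG samples must correspond one-to-one")
  }
  if (T_ < clip_len) stop("recording shorter than one clip")
  filtered <- bandpass(ppg, band[1], band[2])$samples
  starts <- seq(1L, T_ - clip_len + 1L, by = stride)
  lapply(starts, function(s) {
    tgt <- filtered[s:(s + clip_len - 1L)]
    list(
      video = video[, s:(s + clip_len - 1L), , , drop = FALSE],
      target = (tgt - mean(tgt)) / stats::sd(tgt),
      start = s
    )
  })
}

#' Training protocol configuration
#'
#' Defaults follow the published protocol: 30 epochs of Adam at initial
#' learning rate 0.001, decayed by 0.1 every 10 epochs, batch size 8,
#' 128-frame clips advancing by 8 frames, 128 x 128 frames.
#'
#' @param epochs,lr,lr_decay,decay_every,batch_size,clip_len,stride,size
#'   training hyperparameters.
#' @param seed RNG seed for shuffling (and any fresh initialization).
#' @return an object of class `train_control`.
#' @export
train_control <- function(epochs = 30L, lr = 1e-3, lr_decay = 0.1,
                          decay_every = 10L, batch_size = 8L,
                          clip_len = 128L, stride = 8L, size = 128L,
                          seed = 1L) {
  if (clip_len %% 4L != 0L) stop("clip length must be divisible by 4")
  if (lr <= 0 || batch_size < 1L) stop("rates and batch size must be positive")
  structure(as.list(environment()), class = "train_control")
}

#' Train the network
#'
#' Minimizes the mean negative-Pearson loss over clips with Adam under the
#' step-decay learning-rate schedule. `data` is either a list of
#' recordings (`list(video, ppg)`, sliced internally with the control's
#' clip length and stride) or a list of ready clips (`list(video, target)`).
#'
#' @param model an [esa_rppgnet()] object (or `rppgnet_fit` to resume).
#' @param data training data, see above.
#' @param control a [train_control()].
#' @param iterations optional cap on total optimizer steps (one step per
#'   batch), for small-scale convergence runs; `0` returns the
#'   initialization untouched.
#' @param verbose print per-epoch mean loss.
#' @return an object of class `rppgnet_fit` (also `esa_rppgnet`): the model
#'   with trained `params` plus a `fit` element holding `loss_log` (one
#'   entry per optimizer step), `epoch_loss`, and the control used.
#' @export
train_rppgnet <- function(model, data, control = train_control(),
                          iterations = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "esa_rppgnet"))
  clips <- list()
  for (rec in data) {
    if (!is.null(rec$target)) {
      clips[[length(clips) + 1L]] <- rec
    } else {
      clips <- c(clips, slice_clips(rec$video, rec$ppg,
                                    control$clip_len, control$stride))
    }
  }
  if (!length(clips)) stop("no training clips")
  params <- model$params
  opt <- adam_init(params)
  loss_log <- numeric(0)
  epoch_loss <- numeric(0)
  step <- 0L
  done <- FALSE
  with_seed(control$seed, {
    for (ep in seq_len(control$epochs)) {
      lr <- control$lr * control$lr_decay^((ep - 1L) %/% control$decay_every)
      order_ <- sample.int(length(clips))
      ep_losses <- c()
      for (bs in seq(1L, length(order_), by = control$batch_size)) {
        idx <- order_[bs:min(bs + control$batch_size - 1L, length(order_))]
        if (!is.null(iterations) && step >= iterations) {
          done <- TRUE
          break
        }
        gsum <- NULL
        lsum <- 0
        for (ci in idx) {
          tape <- tape_new()
          leaves <- tp_leaves(tape, params)
          out <- t_net_forward(tape, tp_leaf(tape, clips[[ci]]$video),
                               leaves, model$table, model$config)
          loss <- t_neg_pearson(tape, out, clips[[ci]]$target)
          if (!is.finite(loss$val)) {
            stop(sprintf("non-finite loss at step %d (clip %d)", step + 1L, ci))
          }
          lsum <- lsum + loss$val
          g <- tp_leaf_grads(tp_backward(tape, loss), leaves)
          gsum <- if (is.null(gsum)) g else mapply(`+`, gsum, g, SIMPLIFY = FALSE)
        }
        grads <- lapply(gsum, function(x) x / length(idx))
        res <- adam_step(opt, params, grads, lr)
        opt <- res$state
        params <- res$params
        step <- step + 1L
        loss_log <- c(loss_log, lsum / length(idx))
        ep_losses <- c(ep_losses, lsum / length(idx))
      }
      if (length(ep_losses)) epoch_loss <- c(epoch_loss, mean(ep_losses))
      if (verbose && length(ep_losses)) {
        message(sprintf("epoch %d: mean loss %.4f (lr %g)", ep, mean(ep_losses), lr))
      }
      if (done) break
    }
  })
  model$params <- params
  model$fit <- list(loss_log = loss_log, epoch_loss = epoch_loss,
                    steps = step, control = control)
  class(model) <- c("rppgnet_fit", "esa_rppgnet")
  model
}

#' @export
print.rppgnet_fit <- function(x, ...) {
  NextMethod()
  ll <- x$fit$loss_log
  cat(sprintf("  trained %d steps; final neg-Pearson loss %.4f\n",
              x$fit$steps, if (length(ll)) ll[length(ll)] else NA_real_))
  invisible(x)
}

#' @export
plot.rppgnet_fit <- function(x, ...) {
  graphics::plot(x$fit$loss_log, type = "l", xlab = "optimizer step",
                 ylab = "negative Pearson loss", ...)
  invisible(x)
}

#' Whole-video inference with window stitching
#'
#' Runs the network over consecutive non-overlapping `clip_len`-frame
#' windows (with a right-aligned tail window when the length is not a
#' multiple), z-normalizes each window's output — the correlation-based
#' training objective leaves per-window scale arbitrary — and averages any
#' overlap, returning one rPPG sample per input frame.
#'
#' @param model an [esa_rppgnet()] or `rppgnet_fit` object.
#' @param video array `(3, T, H, W)` with `T >= clip_len`.
#' @param fps frame rate carried onto the output trace.
#' @param clip_len window length (default 128).
#' @return a [pulse_trace()] of length `T` at `fps`.
#' @export
rppg_infer <- function(model, video, fps = 30, clip_len = 128L) {
  d <- dim4(video)
  T_ <- d[2]
  if (T_ < clip_len) stop("video shorter than one inference window")
  starts <- seq(1L, T_ - clip_len + 1L, by = clip_len)
  if (starts[length(starts)] + clip_len - 1L < T_) {
    starts <- c(starts, T_ - clip_len + 1L) # right-aligned tail window
  }
  acc <- numeric(T_)
  cnt <- numeric(T_)
  for (s in starts) {
    win <- s:(s + clip_len - 1L)
    y <- rppg_forward(model, video[, win, , , drop = FALSE])
    y <- (y - mean(y)) / stats::sd(y)
    acc[win] <- acc[win] + y
    cnt[win] <- cnt[win] + 1
  }
  pulse_trace(acc / cnt, fps)
}

#' @export
predict.rppgnet_fit <- function(object, video, fps = 30, clip_len = 128L, ...) {
  rppg_infer(object, video, fps = fps, clip_len = clip_len)
}

#' Post-process a trace for HRV analysis
#'
#' The analysis-side conditioning chain: band-pass 0.5-3.5 Hz, z-normalize,
#' cubic-spline interpolation to 256 Hz, peak detection (1-s edge trim for
#' filter transients), and NN-interval extraction.
#'
#' @param trace a [pulse_trace()].
#' @param band analysis filter band in Hz.
#' @param rate peak-timing sample rate in Hz (default 256).
#' @param edge_trim seconds excluded from peak detection at each end.
#' @return list with `trace` (at `rate`), `peaks`, and `nni` (ms).
#' @export
rppg_postprocess <- function(trace, band = c(0.5, 3.5), rate = 256,
                             edge_trim = 1) {
  t2 <- znormalize(bandpass(trace, band[1], band[2]))
  t3 <- resample_uniform(t2, rate)
  pk <- detect_peaks(t3, edge_trim = edge_trim)
  nni <- if (length(pk$indices) >= 2L) peaks_to_nni(pk) else NULL
  list(trace = t3, peaks = pk, nni = nni)
}

#' Evaluate HRV agreement over a recording set
#'
#' For each recording, obtains the predicted rPPG trace (from a fitted
#' model via [rppg_infer()], or from any `function(video) -> pulse_trace`),
#' runs both prediction and reference through the identical post-processing
#' chain ([rppg_postprocess()]), computes HRV metrics for both, and reports
#' per-metric agreement statistics across recordings. Recordings with fewer
#' than 2 detected beats on either side are excluded with a message.
#'
#' @param recordings list of `list(video, ppg)`; `ppg` is the reference
#'   [pulse_trace()].
#' @param predictor a `rppgnet_fit` / `esa_rppgnet` object or a function
#'   `video -> pulse_trace`.
#' @param freq_metrics also compute frequency-domain metrics (requires
#'   records of at least 30 s).
#' @param ... passed to [rppg_postprocess()].
#' @return an object of class `hrv_eval`: list with `per_recording` (a
#'   data.frame of predicted and reference metrics per kept recording),
#'   `agreement` (named list of [hrv_agreement()] per metric), and
#'   `excluded` (indices).
#' @export
evaluate_recordings <- function(recordings, predictor, freq_metrics = TRUE,
                                ...) {
  predict_fun <- if (is.function(predictor)) {
    predictor
  } else {
    function(video) rppg_infer(predictor, video)
  }
  rows <- list()
  excluded <- integer(0)
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    pred <- if (is.null(rec$video)) rec$ppg else predict_fun(rec$video)
    pp <- rppg_postprocess(as_pulse_trace(pred), ...)
    rr <- rppg_postprocess(as_pulse_trace(rec$ppg), ...)
    if (is.null(pp$nni) || is.null(rr$nni)) {
      message(sprintf("recording %d excluded: fewer than 2 detected beats", i))
      excluded <- c(excluded, i)
      next
    }
    ptd <- hrv_time_domain(pp$nni)
    rtd <- hrv_time_domain(rr$nni)
    row <- data.frame(recording = i,
                      avnn_pred = ptd$avnn, avnn_ref = rtd$avnn,
                      sdnn_pred = ptd$sdnn, sdnn_ref = rtd$sdnn,
                      rmssd_pred = ptd$rmssd, rmssd_ref = rtd$rmssd)
    if (freq_metrics) {
      pfd <- tryCatch(hrv_frequency_domain(pp$nni), error = function(e) NULL)
      rfd <- tryCatch(hrv_frequency_domain(rr$nni), error = function(e) NULL)
      if (!is.null(pfd) && !is.null(rfd)) {
        row <- cbind(row, data.frame(
          lfnu_pred = pfd$lfnu, lfnu_ref = rfd$lfnu,
          hfnu_pred = pfd$hfnu, hfnu_ref = rfd$hfnu,
          lf_hf_pred = pfd$lf_hf, lf_hf_ref = rfd$lf_hf))
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no recording survived post-processing")
  per <- do.call(rbind, lapply(rows, function(r) {
    # pad rows missing frequency metrics
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    if (length(miss)) r[miss] <- NA_real_
    r
  }))
  metrics <- intersect(c("avnn", "sdnn", "rmssd", "lfnu", "hfnu", "lf_hf"),
                       sub("_pred$", "", grep("_pred$", names(per), value = TRUE)))
  agreement <- lapply(metrics, function(m) {
    p <- per[[paste0(m, "_pred")]]
    r <- per[[paste0(m, "_ref")]]
    ok <- is.finite(p) & is.finite(r)
    if (sum(ok) >= 2L) hrv_agreement(p[ok], r[ok]) else NULL
  })
  names(agreement) <- metrics
  structure(list(per_recording = per, agreement = agreement,
                 excluded = excluded), class = "hrv_eval")
}

#' @export
print.hrv_eval <- function(x, ...) {
  cat(sprintf("HRV evaluation over %d recordings (%d excluded)\n",
              nrow(x$per_recording), length(x$excluded)))
  for (m in names(x$agreement)) {
    a <- x$agreement[[m]]
    if (is.null(a)) next
    cat(sprintf("  %-6s MAE %8.3f  RMSE %8.3f  R %s\n", m, a$mae, a$rmse,
                if (is.na(a$r)) "NA" else sprintf("%6.3f", a$r)))
  }
  invisible(x)
}
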