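# Shared helpers: numeric differentiation and small reference oracles.

ns <- asNamespace("rppgnet")

# Central-difference gradient of scalar f at selected coordinates of x.
numeric_grad <- function(f, x, coords = seq_along(x), eps = 1e-6) {
  vapply(coords, function(i) {
    xp <- x
    xp[i] <- xp[i] + eps
    xm <- x
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Plain scalar GRU step (dense gates), the 1x1-kernel reference.
scalar_gru_step <- function(x, h, wz, uz, bz, wr, ur, br, w, u, bh) {
  z <- plogis(wz * x + uz * h + bz)
  r <- plogis(wr * x + ur * h + br)
  cand <- tanh(w * x + u * (r * h) + bh)
  (1 - z) * h + z * cand
}

rand_vol <- function(C, T_, H, W) array(stats::rnorm(C * T_ * H * W), c(C, T_, H, W))

# Concatenate (Ci,T,H,W) arrays along the channel axis.
abind_ch <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))), d[2:4]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

# Mean green-channel trace inside a fixed pixel box of a (3,T,H,W) video.
green_trace <- function(video, box) {
  sapply(seq_len(dim(video)[2]), function(t) {
    mean(video[2, t, box[1]:box[3], box[2]:box[4]])
  })
}
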