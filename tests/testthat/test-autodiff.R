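# Reverse-mode tape: analytic gradients must match central differences for
# every operation the network composes, including nested-call construction
# (child nodes created while a parent op's arguments are being evaluated).

test_that("composed conv/norm/activation chain matches numeric gradients", {
  set.seed(101)
  x <- rand_vol(2, 4, 3, 3)
  w <- array(rnorm(3 * 2 * 3 * 3 * 3) * 0.3, c(3, 2, 3, 3, 3))
  dw <- array(rnorm(3 * 1 * 3 * 3) * 0.3, c(3, 1, 3, 3))
  tgt <- rnorm(3 * 2 * 2 * 2)

  run <- function(xv, wv, dwv) {
    tape <- ns$tape_new()
    xn <- ns$tp_leaf(tape, xv)
    wn <- ns$tp_leaf(tape, wv)
    dn <- ns$tp_leaf(tape, dwv)
    h <- ns$t_conv3d(tape, xn, wn) # nested-call construction on purpose
    h <- ns$t_hswish(tape, ns$t_chnorm(tape, h, rep(1.1, 3), rep(0.2, 3)))
    h <- ns$t_dwconv3d(tape, h, dn, stride = c(2L, 2L, 2L))
    loss <- ns$t_neg_pearson(tape, h, tgt)
    list(tape = tape, loss = loss, ids = c(x = xn$id, w = wn$id, d = dn$id))
  }
  r0 <- run(x, w, dw)
  gr <- ns$tp_backward(r0$tape, r0$loss)
  for (nm in c("x", "w", "d")) {
    ref <- switch(nm, x = x, w = w, d = dw)
    coords <- sample(length(ref), 12)
    ng <- numeric_grad(function(v) {
      args <- list(x = x, w = w, d = dw)
      args[[nm]] <- array(v, dim(ref))
      run(args$x, args$w, args$d)$loss$val
    }, as.vector(ref), coords)
    expect_equal(as.vector(gr[[r0$ids[nm]]])[coords], ng, tolerance = 1e-5)
  }
})

test_that("attention block and temporal upsampling gradients are exact", {
  set.seed(102)
  x <- rand_vol(4, 3, 2, 2)
  wt <- matrix(rnorm(16) * 0.4, 4, 4) # (C, 4) temporal transposed kernel
  pars <- list(w1 = rnorm(2), b1 = rnorm(2), w2 = rnorm(2), b2 = rnorm(2))
  tgt <- rnorm(4 * 6 * 2 * 2)

  run <- function(xv, wv, pv) {
    tape <- ns$tape_new()
    xn <- ns$tp_leaf(tape, xv)
    wn <- ns$tp_leaf(tape, wv)
    pn <- lapply(pv, function(p) ns$tp_leaf(tape, p))
    h <- ns$t_sa_block(tape, xn, pn, G = 1L)
    h <- ns$t_dwtconv_t(tape, h, wn)
    loss <- ns$t_neg_pearson(tape, h, tgt)
    list(loss = loss, tape = tape,
         ids = c(x = xn$id, w = wn$id, w1 = pn$w1$id, b2 = pn$b2$id))
  }
  r0 <- run(x, wt, pars)
  gr <- ns$tp_backward(r0$tape, r0$loss)
  checks <- list(
    x = list(x, function(v) run(array(v, dim(x)), wt, pars)),
    w = list(wt, function(v) run(x, matrix(v, 4, 4), pars)),
    w1 = list(pars$w1, function(v) {
      p <- pars; p$w1 <- v; run(x, wt, p)
    }),
    b2 = list(pars$b2, function(v) {
      p <- pars; p$b2 <- v; run(x, wt, p)
    })
  )
  for (nm in names(checks)) {
    ref <- checks[[nm]][[1]]
    coords <- sample(length(ref), min(8, length(ref)))
    ng <- numeric_grad(function(v) checks[[nm]][[2]](v)$loss$val,
                       as.vector(ref), coords)
    expect_equal(as.vector(gr[[r0$ids[nm]]])[coords], ng, tolerance = 1e-5)
  }
})

test_that("ConvGRU sequence gradients match numeric differentiation", {
  set.seed(103)
  p <- convgru_params(3, 2, kernel = 3)
  xs <- rand_vol(3, 3, 2, 2)
  tgt <- rnorm(2 * 3 * 2 * 2)
  fields <- c("wz", "uz", "u", "bz")
  run <- function(xv, pv) {
    tape <- ns$tape_new()
    xn <- ns$tp_leaf(tape, xv)
    pl <- lapply(unclass(pv)[c("wz", "wr", "w", "uz", "ur", "u", "bz", "br", "bh")],
                 function(v) ns$tp_leaf(tape, v))
    out <- ns$t_convgru_run(tape, xn, pl)
    loss <- ns$t_neg_pearson(tape, out, tgt)
    list(loss = loss, tape = tape, xn = xn, pl = pl)
  }
  r0 <- run(xs, p)
  gr <- ns$tp_backward(r0$tape, r0$loss)
  coords <- sample(length(xs), 10)
  ngx <- numeric_grad(function(v) run(array(v, dim(xs)), p)$loss$val,
                      as.vector(xs), coords)
  expect_equal(as.vector(gr[[r0$xn$id]])[coords], ngx, tolerance = 1e-5)
  for (f in fields) {
    ref <- p[[f]]
    coords <- sample(length(ref), min(6, length(ref)))
    ng <- numeric_grad(function(v) {
      p2 <- p
      p2[[f]] <- if (is.null(dim(ref))) v else array(v, dim(ref))
      run(xs, p2)$loss$val
    }, as.vector(ref), coords)
    expect_equal(as.vector(gr[[r0$pl[[f]]$id]])[coords], ng, tolerance = 1e-5)
  }
})

test_that("full-network parameter gradients agree with numeric differences", {
  set.seed(104)
  m <- esa_rppgnet(seed = 5)
  video <- rand_vol(3, 4, 32, 32)
  tgt <- rnorm(4)
  loss_at <- function(params) {
    tape <- ns$tape_new()
    out <- ns$t_net_forward(tape, ns$tp_leaf(tape, video), params,
                            m$table, m$config)
    ns$t_neg_pearson(tape, out, tgt)$val
  }
  tape <- ns$tape_new()
  leaves <- ns$tp_leaves(tape, m$params)
  out <- ns$t_net_forward(tape, ns$tp_leaf(tape, video), leaves,
                          m$table, m$config)
  loss <- ns$t_neg_pearson(tape, out, tgt)
  g <- ns$tp_leaf_grads(ns$tp_backward(tape, loss), leaves)
  picks <- c("stem.w", "eb01.dw.w", "eb04.sa.w1", "pw576.w", "dc1.dw.w",
             "gru1.uz", "head.w")
  for (nm in picks) {
    i <- sample(length(m$params[[nm]]), 1)
    ng <- numeric_grad(function(v) {
      p2 <- m$params
      p2[[nm]][i] <- v
      loss_at(p2)
    }, m$params[[nm]][i], 1, eps = 1e-5)
    expect_equal(as.vector(g[[nm]])[i], ng, tolerance = 1e-3,
                 label = sprintf("gradient of %s", nm))
  }
})
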