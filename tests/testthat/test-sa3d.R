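# 3D shuffle attention: grouping bookkeeping, branch formulas against
# scalar oracles, shuffle permutation, and the block's invariants.

test_that("group split is exact bookkeeping and reassembles the input", {
  x <- rand_vol(4, 2, 2, 2)
  gs <- sa_group_split(x, 2)
  expect_equal(gs[[1]]$xk1, x[1, , , , drop = FALSE])
  expect_equal(gs[[1]]$xk2, x[2, , , , drop = FALSE])
  expect_equal(gs[[2]]$xk1, x[3, , , , drop = FALSE])
  expect_equal(gs[[2]]$xk2, x[4, , , , drop = FALSE])

  # G = 1: branches are the first and last C/2 channels
  gs1 <- sa_group_split(x, 1)
  expect_equal(gs1[[1]]$xk1, x[1:2, , , , drop = FALSE])
  expect_equal(gs1[[1]]$xk2, x[3:4, , , , drop = FALSE])

  # C = 16, G = 8 random values: concatenation reproduces input bitwise
  set.seed(1)
  x <- rand_vol(16, 2, 3, 2)
  parts <- sa_group_split(x, 8)
  rebuilt <- do.call(abind_ch, unlist(lapply(parts, function(p) list(p$xk1, p$xk2)),
                                      recursive = FALSE))
  expect_identical(rebuilt, x)

  expect_error(sa_group_split(x, 3), "invalid grouping")
  expect_error(sa_group_split(rand_vol(2, 1, 1, 1), 2), "invalid grouping")
})

test_that("global average pooling matches brute-force summation", {
  x <- array(3.5, c(4, 2, 2, 2))
  expect_equal(global_avg_pool(x), rep(3.5, 4))
  x1 <- array(7, c(2, 1, 1, 1))
  expect_equal(global_avg_pool(x1), c(7, 7))
  x <- array(1:16, c(2, 2, 2, 2))
  brute <- sapply(1:2, function(c) {
    s <- 0
    for (t in 1:2) for (h in 1:2) for (w in 1:2) s <- s + x[c, t, h, w]
    s / 8
  })
  expect_equal(global_avg_pool(x), brute)
})

test_that("channel branch gates by sigmoid of the scaled global statistic", {
  set.seed(2)
  x <- rand_vol(2, 2, 2, 2)
  expect_equal(sa_channel_branch(x, c(0, 0), c(0, 0)), 0.5 * x)
  # saturation: huge shift drives the gate to 1
  expect_equal(sa_channel_branch(x, c(0, 0), c(50, 50)), x, tolerance = 1e-10)
  # scalar oracle on a single channel
  x1 <- rand_vol(1, 2, 2, 2)
  expected <- plogis(mean(x1)) * x1
  expect_equal(sa_channel_branch(x1, 1, 0), expected)
  expect_error(sa_channel_branch(x, 1, 0), "per channel")
})

test_that("spatial branch normalizes then gates", {
  x <- array(rep(c(2, -1), times = 8), c(2, 2, 2, 2)) # constant per channel
  out <- sa_spatial_branch(x, c(1, 1), c(0.7, -0.3))
  expect_equal(out, plogis(c(0.7, -0.3)) * x, tolerance = 1e-3)
  set.seed(3)
  xr <- rand_vol(2, 2, 2, 2)
  # W2 = 0: gate independent of values
  expect_equal(sa_spatial_branch(xr, c(0, 0), c(1, 1)), plogis(1) * xr)
  # scalar oracle, single channel
  x1 <- rand_vol(1, 2, 2, 2)
  v <- as.vector(x1)
  xhat <- (v - mean(v)) / sqrt(mean(v^2) - mean(v)^2 + 1e-5)
  expected <- array(plogis(xhat) * v, dim(x1))
  expect_equal(sa_spatial_branch(x1, 1, 0), expected)
})

test_that("channel shuffle is the reshape-transpose permutation and inverts", {
  x <- rand_vol(4, 1, 1, 1)
  sh <- channel_shuffle(x, 2)
  expect_equal(as.vector(sh), as.vector(x)[c(1, 3, 2, 4)])
  expect_identical(channel_shuffle(x, 1), x)
  expect_identical(channel_shuffle(x, 4), x)
  set.seed(4)
  for (C in c(6, 12, 16)) {
    for (G in c(2, 3)) {
      if (C %% G != 0) next
      y <- rand_vol(C, 2, 2, 2)
      expect_identical(channel_shuffle(channel_shuffle(y, G), C / G), y)
      expect_setequal(as.vector(channel_shuffle(y, G)[, 1, 1, 1]), y[, 1, 1, 1])
    }
  }
})

test_that("sa_block preserves shape, bounds gates, and composes its parts", {
  set.seed(5)
  for (cfg in list(c(8, 3, 4, 4), c(16, 2, 2, 2), c(24, 5, 3, 2))) {
    x <- do.call(rand_vol, as.list(cfg))
    p <- sa_params(cfg[1], groups = 4)
    p$w1 <- rnorm(cfg[1] / 2)
    p$b1 <- rnorm(cfg[1] / 2)
    p$b2 <- rnorm(cfg[1] / 2)
    y <- sa_block(x, p)
    expect_equal(dim(y), dim(x))
    # gates live in (0,1): undoing the shuffle, no element grows in magnitude
    unshuffled <- channel_shuffle(y, cfg[1] / p$groups)
    expect_true(all(abs(unshuffled) <= abs(x) + 1e-12))
  }

  expect_equal(sa_block(array(0, c(8, 2, 2, 2)), sa_params(8)),
               array(0, c(8, 2, 2, 2)))

  # near-neutral parameters: 0.5 times a channel permutation of the input
  x <- rand_vol(8, 2, 2, 2)
  p0 <- sa_params(8, groups = 2)
  p0$w2 <- rep(0, 4)
  y <- sa_block(x, p0)
  perm <- ns$shuffle_perm(8, 2)
  expect_equal(y, 0.5 * x[perm, , , , drop = FALSE], tolerance = 1e-12)

  # composition oracle: the block equals its four parts composed by hand
  x <- rand_vol(4, 2, 2, 2)
  p <- sa_params(4, groups = 2)
  p$w1 <- rnorm(2); p$b1 <- rnorm(2); p$w2 <- rnorm(2); p$b2 <- rnorm(2)
  manual <- lapply(seq_len(2), function(k) {
    sub <- sa_group_split(x, 2)[[k]]
    ch <- sa_channel_branch(sub$xk1, p$w1[k], p$b1[k])
    sp <- sa_spatial_branch(sub$xk2, p$w2[k], p$b2[k])
    list(ch, sp)
  })
  rebuilt <- do.call(abind_ch, unlist(manual, recursive = FALSE))
  expect_equal(sa_block(x, p), channel_shuffle(rebuilt, 2), tolerance = 1e-12)
})

test_that("effective group count clamps to a valid divisor", {
  expect_equal(ns$sa_effective_groups(16, 4), 4L)
  expect_equal(ns$sa_effective_groups(24, 4), 4L)
  expect_equal(ns$sa_effective_groups(2, 4), 1L)
  expect_equal(ns$sa_effective_groups(6, 4), 3L)
})
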