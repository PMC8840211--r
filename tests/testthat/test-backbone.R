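# Network assembly and the closed-form complexity accounting.

test_that("h-swish hits its breakpoints and closed-form values", {
  expect_equal(h_swish(0), 0)
  expect_equal(h_swish(3), 3)
  expect_equal(h_swish(-3), 0)
  expect_equal(h_swish(10), 10) # saturated gate
  expect_equal(h_swish(1), 2 / 3) # 1 * relu6(4) / 6
  expect_equal(relu6(c(-1, 2, 9)), c(0, 2, 6))
})

test_that("standard and separable multiplication counts follow the cost model", {
  cc <- conv_complexity(df = 8, dg = 4, dk = 3, m = 2, n = 4, t_len = 2)
  expect_equal(std_conv_macs(cc), 27 * 16 * 2 * 4 * 2) # 6912 by loop-nest count
  expect_equal(dw_sep_macs(cc), 1728 + 256) # Eq-by-eq: 27*16*2*2 and 16*2*4*2
  expect_equal(std_conv_macs(conv_complexity(1, 1, 1, 1, 1, 1)), 1)
  cc2 <- conv_complexity(8, 4, 3, 2, 4, 4) # doubled temporal extent
  expect_equal(std_conv_macs(cc2), 2 * std_conv_macs(cc))
  # kernel collapse: dk = 1 gives dg^2 m t (1 + n)
  cc3 <- conv_complexity(4, 4, 1, 3, 5, 2)
  expect_equal(dw_sep_macs(cc3), 16 * 3 * 2 * (1 + 5))
  # exact ratio 1/N + 1/Dk^3 at unit stride and matched shapes
  for (dk in c(1, 3, 5)) {
    for (n in c(1, 8, 16, 64)) {
      cc <- conv_complexity(6, 6, dk, 7, n, 3)
      expect_equal(dw_sep_macs(cc) / std_conv_macs(cc), 1 / n + 1 / dk^3)
    }
  }
  expect_error(conv_complexity(0, 1, 1, 1, 1, 1), "positive")
})

test_that("profiler parameter totals equal the instantiated arrays", {
  m <- esa_rppgnet(seed = 2)
  pr <- profile_network(m)
  expect_equal(pr$total_params, sum(vapply(m$params, length, numeric(1))))
  expect_equal(sum(pr$layers$params), pr$total_params)
  # per-layer agreement too
  for (nm in unique(m$table$layer)) {
    prefix <- if (nm == "convgru") "^gru[123]\\." else paste0("^", nm, "\\.")
    actual <- sum(vapply(m$params[grepl(prefix, names(m$params))], length, numeric(1)))
    expect_equal(pr$layers$params[pr$layers$layer == nm], actual,
                 label = sprintf("parameters of layer %s", nm))
  }
})

test_that("profiler MACs reduce to the closed forms layer by layer", {
  tab <- esa_layer_table()
  pr <- profile_network(tab, input_shape = c(3, 128, 128, 128))
  # stem is one standard conv: Dk^3 M N x output extent
  stem <- std_conv_macs(conv_complexity(df = 128, dg = 64, dk = 3, m = 3,
                                        n = 16, t_len = 128))
  expect_equal(pr$layers$macs[pr$layers$layer == "stem"], stem)
  # a unit-stride Eblock's DW + PW2 equal the separable closed form
  r <- tab[tab$layer == "eb03", ] # 16^2 x 128 x 24, exp 88, out 24, stride 1
  sep <- dw_sep_macs(conv_complexity(16, 16, r$kernel, r$exp, r$out, 128))
  pw1 <- 24 * r$exp * 16 * 16 * 128
  expect_equal(pr$layers$macs[pr$layers$layer == "eb03"], pw1 + sep)
  # pooling costs nothing under the convention
  expect_equal(pr$layers$macs[pr$layers$layer == "gap"], 0)
})

test_that("forward propagates the documented shape contract", {
  m <- esa_rppgnet(seed = 3)
  v <- rand_vol(3, 8, 32, 32)
  shapes <- list()
  y <- rppg_forward(m, v, hook = function(nm, d) shapes[[nm]] <<- d)
  expect_length(y, 8)
  expect_equal(shapes$stem, c(16, 8, 16, 16))
  expect_equal(shapes$eb03, c(24, 8, 4, 4))
  expect_equal(shapes$eb04, c(40, 4, 2, 2)) # temporal halving, 5x5x5 stride 2
  expect_equal(shapes$eb09, c(96, 2, 1, 1))
  expect_equal(shapes$dc1, c(288, 4, 1, 1)) # decoder doubles time
  expect_equal(shapes$dc2, c(144, 8, 1, 1))
  expect_equal(shapes$convgru, c(64, 8, 1, 1))
  expect_equal(shapes$head, c(1, 8, 1, 1))
  # determinism
  expect_identical(y, rppg_forward(m, v))
  # contract errors name the offending dimension
  expect_error(rppg_forward(m, rand_vol(3, 6, 32, 32)), "divisible by 4")
  expect_error(rppg_forward(m, rand_vol(3, 8, 31, 32)), "multiple of 32")
  expect_error(rppg_forward(m, rand_vol(2, 8, 32, 32)), "3, T, H, W")
})

test_that("initialization is seed-reproducible and spec round-trips", {
  m1 <- esa_rppgnet(seed = 7)
  m2 <- esa_rppgnet(seed = 7)
  expect_identical(m1$params, m2$params)
  m3 <- esa_rppgnet(seed = 8)
  expect_false(identical(m1$params$stem.w, m3$params$stem.w))

  tf <- tempfile(fileext = ".tsv")
  write_network_spec(m1, tf)
  tab <- read_network_spec(tf)
  expect_equal(tab, m1$table)

  cp <- tempfile(fileext = ".ckpt")
  save_checkpoint(m1, cp)
  m4 <- load_checkpoint(cp)
  expect_identical(m4$params, m1$params)
  v <- rand_vol(3, 4, 32, 32)
  expect_identical(rppg_forward(m1, v), rppg_forward(m4, v))
})
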