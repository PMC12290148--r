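test_that("receptive-field recursion reproduces the dilated-cascade table", {
  cascade <- lapply(c(1, 2, 4, 1, 2, 4), function(d) conv_layer_spec(d = d))
  expect_identical(receptive_field_sequence(cascade),
                   c(3L, 7L, 15L, 17L, 21L, 29L))
  # a pointwise convolution sees a single pixel
  expect_identical(receptive_field_sequence(conv_layer_spec(ks = 1)), 1L)
  # undilated stack grows by 2 px per 3x3 layer
  plain <- lapply(rep(1, 6), function(d) conv_layer_spec(d = d))
  expect_identical(receptive_field_sequence(plain),
                   c(3L, 5L, 7L, 9L, 11L, 13L))
  # RMS stack (dilations 1,2,4)
  rms <- lapply(c(1, 2, 4), function(d) conv_layer_spec(d = d))
  expect_identical(receptive_field_sequence(rms), c(3L, 7L, 15L))
  # widest RFB branch: pointwise + two stacked 3x3 -> equivalent kernel 5
  b3 <- list(conv_layer_spec(ks = 1), conv_layer_spec(d = 1),
             conv_layer_spec(d = 1))
  expect_identical(receptive_field_sequence(b3)[3], 5L)
})

test_that("conv layer spec validates its geometry", {
  expect_error(conv_layer_spec(ks = 2), "odd")
  expect_error(conv_layer_spec(ks = 3, s = 0), "stride")
  expect_error(conv_layer_spec(d = 0), "dilation")
  expect_identical(conv_layer_spec(d = 4)$p, 4L)  # padding defaults to d
})

test_that("the fused conv unit matches a direct-loop double-precision conv", {
  set.seed(11)
  for (case in list(list(k = 3, s = 1, p = 2, d = 2),
                    list(k = 3, s = 1, p = 4, d = 4),
                    list(k = 1, s = 1, p = 0, d = 1),
                    list(k = 4, s = 2, p = 1, d = 1),
                    list(k = 3, s = 1, p = 0, d = 1))) {
    u <- ns$new_conv_unit(3, 4, k = case$k, stride = case$s, pad = case$p,
                          dil = case$d, bn = FALSE, act = "none")
    x <- rand_tensor(11, 9, 3, 2)
    got <- ns$unit_forward(u, x, training = TRUE)$y
    want <- naive_conv2d(x, u$W, u$b, case$s, case$p, case$d)
    expect_lt(max(abs(got - want)), 1e-4)
  }
})

test_that("all blocks preserve spatial shape over randomized sizes", {
  set.seed(5)
  for (rep in 1:3) {
    h <- sample(6:20, 1); w <- sample(6:20, 1)
    cfg <- tiny_block_cfg()
    for (mk in list(new_cdc_block, new_crac_block, new_msfe_block,
                    new_rms_block, new_plain_block)) {
      blk <- mk(cfg)
      x <- rand_tensor(h, w, cfg$in_channels, 2L)
      y <- block_forward(blk, x)$y
      expect_identical(dim(y)[1:2], c(h, w))
      expect_identical(dim(y)[3], cfg$out_channels)
    }
  }
})

test_that("CRAC with zero conv weights is the identity (residual chain)", {
  for (sz in c(8L, 13L)) {
    blk <- new_crac_block(block_config(3, 3))
    ns$set_zero_weights(blk)
    x <- rand_tensor(sz, sz + 2L, 3, 2, seed = 1)
    expect_equal(block_forward(blk, x)$y, x, tolerance = 1e-6)
  }
})

test_that("RMS skip carries unit 1's output past zeroed units 2-3", {
  blk <- new_rms_block(block_config(2, 2))
  # zero only the later two units; unit 1 keeps its weights
  for (u in ns$collect_units(blk)[2:3]) { u$W[] <- 0; u$b[] <- 0 }
  for (u in ns$collect_units(blk)) u$passthrough <- TRUE
  x <- rand_tensor(9, 9, 2, 1, seed = 2)
  out1 <- ns$unit_forward(blk$units[[1]], x, training = TRUE)$y
  expect_equal(block_forward(blk, x)$y, out1, tolerance = 1e-6)
})

test_that("RFB with zeroed branches reduces to ReLU(x + crac_out)", {
  blk <- new_rfb_block(block_config(2, 2))
  ns$set_zero_weights(blk)
  x <- rand_tensor(7, 7, 2, 2, seed = 3)
  crac_out <- rand_tensor(7, 7, 2, 2, seed = 4)
  got <- rfb_forward(blk, x, crac_out)
  want <- pmax(x + crac_out, 0)
  expect_equal(got, want, tolerance = 1e-6)
  expect_true(all(got >= 0))
})

test_that("MSFE is the composition of CRAC and RFB", {
  blk <- new_msfe_block(block_config(2, 3))
  x <- rand_tensor(10, 10, 2, 1, seed = 6)
  via_parts <- rfb_forward(blk$rfb, x, crac_forward(blk$crac, x))
  expect_equal(msfe_forward(blk, x), via_parts, tolerance = 1e-10)
})

test_that("empirical gradient footprints match the analytic receptive field", {
  # two dilation schedules checked here; the full five-schedule sweep runs
  # in the acceptance suite
  for (d6 in list(c(1L, 2L, 4L, 1L, 2L, 4L), rep(1L, 6))) {
    specs <- lapply(d6, function(d) conv_layer_spec(d = d))
    want <- max(receptive_field_sequence(specs))
    blk <- new_cdc_block(block_config(1, 2, crac_dilations = d6))
    rf <- empirical_receptive_field(blk, input_size = 64L)
    expect_identical(rf$width, as.integer(want))
    expect_identical(rf$height, as.integer(want))
  }
  # CRAC's skips can only widen the support, never shrink it
  blk <- new_crac_block(block_config(1, 2))
  rf <- empirical_receptive_field(blk, input_size = 64L)
  expect_gte(rf$width, 29L)
})

test_that("block backward passes gradient-check against finite differences", {
  set.seed(9)
  blk <- new_msfe_block(block_config(2, 3))
  x <- rand_tensor(8, 8, 2, 2)
  tgt <- rand_tensor(8, 8, 3, 2)
  lossf <- function() {
    o <- block_forward(blk, x, training = TRUE)
    sum((o$y - tgt)^2)
  }
  ns$zero_grads(blk)
  o <- block_forward(blk, x, training = TRUE)
  gx <- block_backward(blk, o$cache, 2 * (o$y - tgt))
  eps <- 1e-3
  for (probe in 1:4) {
    idx <- arrayInd(sample(length(x), 1), dim(x))
    old <- x[idx]
    x[idx] <- old + eps; lp <- lossf()
    x[idx] <- old - eps; lm <- lossf()
    x[idx] <- old
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - gx[idx]) / max(1, abs(fd), abs(gx[idx])), 0.05)
  }
  # weight gradient of the first CRAC unit
  u <- ns$collect_units(blk)[[1]]
  for (i in sample(length(u$W), 3)) {
    old <- u$W[i]
    u$W[i] <- old + eps; lp <- lossf()
    u$W[i] <- old - eps; lm <- lossf()
    u$W[i] <- old
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - u$gW[i]) / max(1, abs(fd), abs(u$gW[i])), 0.05)
  }
})
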