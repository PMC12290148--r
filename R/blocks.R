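# ---------------------------------------------------------------------------
# Architectural building blocks of the segmentation generator:
#   CDC  - cascade dilated convolution (6 dilated 3x3 conv-BN-ReLU units)
#   CRAC - CDC plus two residual skips (units 1->3 and 4->6)
#   RFB  - Inception-style receptive-field block (equivalent kernels 1/3/5)
#   MSFE - CRAC followed by RFB
#   RMS  - residual multi-scale decoder block (dilations 1,2,4, one skip)
# plus the analytic receptive-field recursion for dilated conv stacks.
# ---------------------------------------------------------------------------

#' Specification of a single convolution layer
#'
#' Captures the four quantities that determine a convolution layer's
#' geometry: kernel size, stride, padding and dilation rate.
#'
#' @param ks odd kernel size (pixels).
#' @param s stride.
#' @param p zero padding (pixels); defaults to the dilation rate, which
#'   preserves spatial dimensions for 3x3 kernels.
#' @param d dilation rate.
#' @return an object of class `conv_layer_spec`.
#' @export
#' @examples
#' conv_layer_spec(ks = 3, d = 2)
conv_layer_spec <- function(ks = 3L, s = 1L, p = NULL, d = 1L) {
  ks <- as.integer(ks); s <- as.integer(s); d <- as.integer(d)
  if (ks < 1L || ks %% 2L == 0L) stop("kernel size must be odd and >= 1")
  if (s < 1L) stop("stride must be >= 1")
  if (d < 1L) stop("dilation must be >= 1")
  if (is.null(p)) p <- if (ks == 1L) 0L else d
  p <- as.integer(p)
  if (p < 0L) stop("padding must be >= 0")
  structure(list(ks = ks, s = s, p = p, d = d), class = "conv_layer_spec")
}

#' Cumulative receptive fields of a convolution stack
#'
#' Applies the standard recursion for the receptive field of stacked
#' (dilated) convolutions: the first layer sees
#' `ks + (ks - 1) * (d - 1)` input pixels, and each further layer adds
#' `s * (rf_prev - 1)` to its own dilated kernel extent. For the default
#' six-layer cascade with kernel 3, stride 1 and dilation rates
#' 1, 2, 4, 1, 2, 4 this yields 3, 7, 15, 17, 21, 29.
#'
#' @param stack a list of [conv_layer_spec()] objects, outermost first.
#' @return integer vector of cumulative receptive fields, one per layer.
#' @export
#' @examples
#' specs <- lapply(c(1, 2, 4, 1, 2, 4), function(d) conv_layer_spec(d = d))
#' receptive_field_sequence(specs)
receptive_field_sequence <- function(stack) {
  if (inherits(stack, "conv_layer_spec")) stack <- list(stack)
  if (length(stack) == 0L) stop("stack must contain at least one layer")
  rf <- integer(length(stack))
  prev <- 1L
  for (i in seq_along(stack)) {
    l <- stack[[i]]
    if (!inherits(l, "conv_layer_spec")) stop("stack must hold conv_layer_spec objects")
    ext <- l$ks + (l$ks - 1L) * (l$d - 1L)
    rf[i] <- if (i == 1L) ext else ext + l$s * (prev - 1L)
    prev <- rf[i]
  }
  rf
}

#' Block hyperparameter container
#'
#' @param in_channels,out_channels channel counts entering/leaving the block.
#' @param crac_dilations six dilation rates of the CDC/CRAC cascade.
#' @param rms_dilations three dilation rates of the RMS decoder block.
#' @param rfb_branch_dilations dilation rates of the three RFB trailing convs.
#' @return a list of class `block_config`.
#' @export
block_config <- function(in_channels, out_channels,
                         crac_dilations = c(1L, 2L, 4L, 1L, 2L, 4L),
                         rms_dilations = c(1L, 2L, 4L),
                         rfb_branch_dilations = c(1L, 3L, 5L)) {
  if (length(crac_dilations) != 6L) stop("crac_dilations must have length 6")
  if (length(rms_dilations) != 3L) stop("rms_dilations must have length 3")
  if (length(rfb_branch_dilations) != 3L)
    stop("rfb_branch_dilations must have length 3")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 crac_dilations = as.integer(crac_dilations),
                 rms_dilations = as.integer(rms_dilations),
                 rfb_branch_dilations = as.integer(rfb_branch_dilations)),
            class = "block_config")
}

# dilated 3x3 conv-BN-ReLU cascade shared by CDC and CRAC
cascade_units <- function(in_ch, out_ch, dilations) {
  lapply(seq_along(dilations), function(i) {
    d <- dilations[i]
    new_conv_unit(if (i == 1L) in_ch else out_ch, out_ch, k = 3L,
                  pad = d, dil = d)
  })
}

#' @rdname blocks
#' @export
new_cdc_block <- function(cfg) {
  structure(list(type = "cdc",
                 units = cascade_units(cfg$in_channels, cfg$out_channels,
                                       cfg$crac_dilations),
                 in_ch = cfg$in_channels, out_ch = cfg$out_channels),
            class = "ss_module")
}

#' @rdname blocks
#' @export
new_crac_block <- function(cfg) {
  proj <- if (cfg$in_channels != cfg$out_channels)
    new_conv_unit(cfg$in_channels, cfg$out_channels, k = 1L, pad = 0L,
                  bn = FALSE, act = "none")
  else NULL
  structure(list(type = "crac",
                 units = cascade_units(cfg$in_channels, cfg$out_channels,
                                       cfg$crac_dilations),
                 proj = proj,
                 in_ch = cfg$in_channels, out_ch = cfg$out_channels),
            class = "ss_module")
}

#' @rdname blocks
#' @export
new_rfb_block <- function(cfg) {
  ic <- cfg$in_channels; oc <- cfg$out_channels
  # Branch compositions with equivalent kernels 1, 3, 5: a pointwise conv,
  # pointwise + 3x3, and pointwise + two stacked 3x3 (cheaper than a literal
  # 5x5). Each is followed by a 3x3 dilated conv at rates 1/3/5.
  bd <- cfg$rfb_branch_dilations
  branch1 <- list(new_conv_unit(ic, oc, k = 1L, pad = 0L),
                  new_conv_unit(oc, oc, k = 3L, pad = bd[1], dil = bd[1]))
  branch2 <- list(new_conv_unit(ic, oc, k = 1L, pad = 0L),
                  new_conv_unit(oc, oc, k = 3L, pad = 1L),
                  new_conv_unit(oc, oc, k = 3L, pad = bd[2], dil = bd[2]))
  branch3 <- list(new_conv_unit(ic, oc, k = 1L, pad = 0L),
                  new_conv_unit(oc, oc, k = 3L, pad = 1L),
                  new_conv_unit(oc, oc, k = 3L, pad = 1L),
                  new_conv_unit(oc, oc, k = 3L, pad = bd[3], dil = bd[3]))
  proj <- if (ic != oc)
    new_conv_unit(ic, oc, k = 1L, pad = 0L, bn = FALSE, act = "none")
  else NULL
  structure(list(type = "rfb",
                 branches = list(branch1, branch2, branch3),
                 proj = proj, in_ch = ic, out_ch = oc),
            class = "ss_module")
}

#' Construct segmentation network blocks
#'
#' `new_cdc_block()`, `new_crac_block()`, `new_rfb_block()`,
#' `new_msfe_block()`, `new_rms_block()` and `new_plain_block()` create the
#' building blocks of the generator; all preserve spatial dimensions
#' (stride 1, padding equal to dilation for 3x3 kernels).
#'
#' @param cfg a [block_config()].
#' @return an `ss_module` object usable with [block_forward()].
#' @name blocks
#' @export
new_msfe_block <- function(cfg) {
  structure(list(type = "msfe",
                 crac = new_crac_block(cfg),
                 rfb = new_rfb_block(cfg),
                 in_ch = cfg$in_channels, out_ch = cfg$out_channels),
            class = "ss_module")
}

#' @rdname blocks
#' @export
new_rms_block <- function(cfg) {
  d <- cfg$rms_dilations
  units <- lapply(seq_along(d), function(i) {
    new_conv_unit(if (i == 1L) cfg$in_channels else cfg$out_channels,
                  cfg$out_channels, k = 3L, pad = d[i], dil = d[i])
  })
  structure(list(type = "rms", units = units,
                 in_ch = cfg$in_channels, out_ch = cfg$out_channels),
            class = "ss_module")
}

#' @rdname blocks
#' @export
new_plain_block <- function(cfg) {
  structure(list(type = "plain",
                 units = list(new_conv_unit(cfg$in_channels, cfg$out_channels,
                                            k = 3L, pad = 1L),
                              new_conv_unit(cfg$out_channels, cfg$out_channels,
                                            k = 3L, pad = 1L)),
                 in_ch = cfg$in_channels, out_ch = cfg$out_channels),
            class = "ss_module")
}

seq_forward <- function(units, x, training) {
  caches <- vector("list", length(units))
  h <- x
  for (i in seq_along(units)) {
    out <- unit_forward(units[[i]], h, training)
    h <- out$y
    caches[[i]] <- out$cache
  }
  list(y = h, caches = caches)
}

seq_backward <- function(units, caches, gy) {
  g <- gy
  for (i in rev(seq_along(units))) g <- unit_backward(units[[i]], caches[[i]], g)
  g
}

#' Run a block forward / backward
#'
#' `block_forward()` evaluates a block on a `(H, W, C, N)` array and returns
#' `list(y, cache)`; `block_backward()` backpropagates a gradient of the same
#' shape as `y`, accumulating parameter gradients inside the block and
#' returning the gradient with respect to the block input.
#'
#' @param block an `ss_module` created by one of the block constructors.
#' @param x input array `(H, W, C, N)`.
#' @param training logical; use batch statistics in batch-norm layers.
#' @param cache the cache returned by `block_forward`.
#' @param gy gradient w.r.t. the block output.
#' @return `block_forward`: `list(y, cache)`; `block_backward`: gradient array.
#' @export
block_forward <- function(block, x, training = TRUE) {
  switch(block$type,
    cdc = , plain = {
      out <- seq_forward(block$units, x, training)
      list(y = out$y, cache = out)
    },
    crac = crac_block_forward(block, x, training),
    rms = rms_block_forward(block, x, training),
    rfb = stop("an RFB block needs two inputs; use rfb_forward()"),
    msfe = {
      c1 <- crac_block_forward(block$crac, x, training)
      r1 <- rfb_block_forward(block$rfb, x, c1$y, training)
      list(y = r1$y, cache = list(crac = c1$cache, rfb = r1$cache))
    },
    stop("unknown block type: ", block$type))
}

#' @rdname block_forward
#' @export
block_backward <- function(block, cache, gy) {
  switch(block$type,
    cdc = , plain = seq_backward(block$units, cache$caches, gy),
    crac = crac_block_backward(block, cache, gy),
    rms = rms_block_backward(block, cache, gy),
    msfe = {
      g <- rfb_block_backward(block$rfb, cache$rfb, gy)
      gx_crac <- crac_block_backward(block$crac, cache$crac, g$g_crac)
      g$gx + gx_crac
    },
    stop("unknown block type: ", block$type))
}

crac_block_forward <- function(block, x, training) {
  u <- block$units
  o1 <- unit_forward(u[[1]], x, training)
  o2 <- unit_forward(u[[2]], o1$y, training)
  o3 <- unit_forward(u[[3]], o2$y, training)
  if (is.null(block$proj)) {
    skip <- x; pcache <- NULL
  } else {
    p <- unit_forward(block$proj, x, training)
    skip <- p$y; pcache <- p$cache
  }
  a <- o3$y + skip
  o4 <- unit_forward(u[[4]], a, training)
  o5 <- unit_forward(u[[5]], o4$y, training)
  o6 <- unit_forward(u[[6]], o5$y, training)
  y <- o6$y + a
  list(y = y,
       cache = list(c1 = o1$cache, c2 = o2$cache, c3 = o3$cache,
                    c4 = o4$cache, c5 = o5$cache, c6 = o6$cache,
                    pcache = pcache))
}

crac_block_backward <- function(block, cache, gy) {
  u <- block$units
  g6 <- unit_backward(u[[6]], cache$c6, gy)
  g5 <- unit_backward(u[[5]], cache$c5, g6)
  g4 <- unit_backward(u[[4]], cache$c4, g5)
  ga <- gy + g4
  g3 <- unit_backward(u[[3]], cache$c3, ga)
  g2 <- unit_backward(u[[2]], cache$c2, g3)
  g1 <- unit_backward(u[[1]], cache$c1, g2)
  gskip <- if (is.null(block$proj)) ga
           else unit_backward(block$proj, cache$pcache, ga)
  g1 + gskip
}

rms_block_forward <- function(block, x, training) {
  u <- block$units
  o1 <- unit_forward(u[[1]], x, training)
  o2 <- unit_forward(u[[2]], o1$y, training)
  o3 <- unit_forward(u[[3]], o2$y, training)
  list(y = o3$y + o1$y,
       cache = list(c1 = o1$cache, c2 = o2$cache, c3 = o3$cache))
}

rms_block_backward <- function(block, cache, gy) {
  u <- block$units
  g3 <- unit_backward(u[[3]], cache$c3, gy)
  g2 <- unit_backward(u[[2]], cache$c2, g3)
  unit_backward(u[[1]], cache$c1, g2 + gy)
}

rfb_block_forward <- function(block, x, crac_out, training) {
  if (!all(dim(x)[c(1, 2, 4)] == dim(crac_out)[c(1, 2, 4)]))
    stop("RFB inputs must share spatial dimensions and batch size")
  bouts <- lapply(block$branches, function(br) seq_forward(br, x, training))
  if (is.null(block$proj)) {
    res <- x; pcache <- NULL
  } else {
    p <- unit_forward(block$proj, x, training)
    res <- p$y; pcache <- p$cache
  }
  s <- bouts[[1]]$y + bouts[[2]]$y + bouts[[3]]$y + res + crac_out
  y <- s * (s > 0)
  list(y = y, cache = list(bcaches = lapply(bouts, `[[`, "caches"),
                           pcache = pcache, mask = (s > 0)))
}

rfb_block_backward <- function(block, cache, gy) {
  gs <- gy * cache$mask
  gx <- 0
  for (i in 1:3)
    gx <- gx + seq_backward(block$branches[[i]], cache$bcaches[[i]], gs)
  gres <- if (is.null(block$proj)) gs
          else unit_backward(block$proj, cache$pcache, gs)
  list(gx = gx + gres, g_crac = gs)
}

# --- spec-facing functional wrappers ---------------------------------------

#' Forward passes of the individual block types
#'
#' Thin functional wrappers over [block_forward()] that return only the
#' output feature map. `rfb_forward()` takes both the block input and the
#' CRAC output, which are summed with the branch outputs before the final
#' ReLU; `msfe_forward()` is the composition `rfb(x, crac(x))`.
#'
#' @inheritParams block_forward
#' @param crac_out output of the paired CRAC block (same shape as `x`
#'   spatially).
#' @return output feature map `(H, W, C_out, N)`.
#' @name block_ops
#' @export
cdc_forward <- function(block, x, training = TRUE) {
  stopifnot(block$type == "cdc")
  block_forward(block, x, training)$y
}

#' @rdname block_ops
#' @export
crac_forward <- function(block, x, training = TRUE) {
  stopifnot(block$type == "crac")
  block_forward(block, x, training)$y
}

#' @rdname block_ops
#' @export
rfb_forward <- function(block, x, crac_out, training = TRUE) {
  stopifnot(block$type == "rfb")
  rfb_block_forward(block, x, crac_out, training)$y
}

#' @rdname block_ops
#' @export
msfe_forward <- function(block, x, training = TRUE) {
  stopifnot(block$type == "msfe")
  block_forward(block, x, training)$y
}

#' @rdname block_ops
#' @export
rms_forward <- function(block, x, training = TRUE) {
  stopifnot(block$type == "rms")
  block_forward(block, x, training)$y
}

#' Empirical receptive field of a block
#'
#' Measures the gradient footprint of the centre output unit on the input
#' plane after linearising the block (all-positive weights, zero biases,
#' batch norm in pass-through mode), so that every ReLU is active on a
#' positive input and the footprint equals the linear receptive field.
#' The block is modified in place (its weights are overwritten).
#'
#' @param block an `ss_module`.
#' @param input_size spatial side length of the probe input.
#' @param tol magnitude below which a gradient entry counts as zero.
#' @return `list(height, width)` of the bounding box of nonzero input
#'   gradient.
#' @export
empirical_receptive_field <- function(block, input_size = 64L, tol = 1e-12) {
  linearize_module(block)
  x <- array(1, dim = c(input_size, input_size, block$in_ch, 1L))
  out <- block_forward(block, x, training = TRUE)
  d <- dim(out$y)
  gy <- array(0, dim = d)
  ctr <- floor(d[1:2] / 2) + 1L
  gy[ctr[1], ctr[2], 1L, 1L] <- 1
  gx <- block_backward(block, out$cache, gy)
  support <- apply(abs(gx) > tol, c(1, 2), any)
  rows <- which(apply(support, 1, any))
  cols <- which(apply(support, 2, any))
  list(height = diff(range(rows)) + 1L, width = diff(range(cols)) + 1L)
}
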