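# ---------------------------------------------------------------------------
# The segmentation generator: a 5-level encoder-decoder. Level 1 of the
# encoder is a CDC block, levels 2-5 are MSFE blocks, with 2x2 average
# pooling between levels and an optional input image pyramid (the input
# average-pooled to 1/2, 1/4 and 1/8, channel-concatenated after levels
# 1-3). The decoder upsamples bilinearly, concatenates the same-resolution
# encoder output and applies an RMS block; four deeply supervised sigmoid
# heads emit full-resolution probability maps.
# ---------------------------------------------------------------------------

#' Generator configuration
#'
#' @param levels encoder depth (number of resolution levels).
#' @param base_channels channel count of the first level; doubled per level.
#' @param use_pyramid concatenate average-pooled copies of the input after
#'   encoder levels 1-3.
#' @param use_deep_supervision emit one probability map per decoder level
#'   (4 heads) instead of a single final map.
#' @param encoder_block_types character vector, one of `"cdc"`, `"msfe"`,
#'   `"plain"` per level.
#' @param decoder_block_type `"rms"` or `"plain"`.
#' @param input_normalization `"per_image_max"` (divide by the image's
#'   maximum count; an all-zero image stays zero) or `"fixed_16bit"`
#'   (divide by 65535).
#' @param crac_dilations dilation schedule used by CDC/CRAC cascades.
#' @param seed integer seed controlling weight initialisation.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(levels = 5L, base_channels = 64L,
                             use_pyramid = TRUE, use_deep_supervision = TRUE,
                             encoder_block_types = c("cdc", "msfe", "msfe",
                                                     "msfe", "msfe"),
                             decoder_block_type = c("rms", "plain"),
                             input_normalization = c("per_image_max",
                                                     "fixed_16bit"),
                             crac_dilations = c(1L, 2L, 4L, 1L, 2L, 4L),
                             seed = 42L) {
  decoder_block_type <- match.arg(decoder_block_type)
  input_normalization <- match.arg(input_normalization)
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  if (length(encoder_block_types) != levels)
    stop("encoder_block_types must have one entry per level")
  if (!all(encoder_block_types %in% c("cdc", "msfe", "plain")))
    stop("encoder block types must be cdc, msfe or plain")
  structure(list(levels = levels,
                 base_channels = as.integer(base_channels),
                 use_pyramid = isTRUE(use_pyramid),
                 use_deep_supervision = isTRUE(use_deep_supervision),
                 encoder_block_types = encoder_block_types,
                 decoder_block_type = decoder_block_type,
                 input_normalization = input_normalization,
                 crac_dilations = as.integer(crac_dilations),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Build the segmentation generator
#'
#' @param cfg a [generator_config()].
#' @return an object of class `ss_generator`.
#' @export
build_generator <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    L <- cfg$levels
    # channel widths double per level, capped at 8x base (the usual U-Net
    # style cap; keeps the full-width model near the ~57M-parameter scale
    # of this architecture family)
    ch <- cfg$base_channels * pmin(2L^(seq_len(L) - 1L), 8L)
    make_block <- function(type, ic, oc) {
      bc <- block_config(ic, oc, crac_dilations = cfg$crac_dilations)
      switch(type, cdc = new_cdc_block(bc), msfe = new_msfe_block(bc),
             plain = new_plain_block(bc), rms = new_rms_block(bc))
    }
    enc <- vector("list", L)
    for (l in seq_len(L)) {
      ic <- if (l == 1L) 1L else ch[l - 1L]
      if (cfg$use_pyramid && l >= 2L && l <= min(4L, L)) ic <- ic + 1L
      enc[[l]] <- make_block(cfg$encoder_block_types[l], ic, ch[l])
    }
    n_dec <- L - 1L
    dec <- vector("list", n_dec)
    for (j in seq_len(n_dec)) {
      up_ch <- ch[L - j + 1L]
      skip_ch <- ch[L - j]
      dec[[j]] <- make_block(cfg$decoder_block_type, up_ch + skip_ch,
                             ch[L - j])
    }
    n_heads <- if (cfg$use_deep_supervision) n_dec else 1L
    heads <- lapply(seq_len(n_heads), function(i) {
      j <- if (cfg$use_deep_supervision) i else n_dec
      new_conv_unit(ch[L - j], 1L, k = 1L, pad = 0L, bn = FALSE,
                    act = "none")
    })
    structure(list(cfg = cfg, enc = enc, dec = dec, heads = heads,
                   channels = ch),
              class = c("ss_generator", "ss_module"))
  })
}

check_divisible <- function(H, W, levels) {
  div <- 2L^(levels - 1L)
  if (H %% div != 0L || W %% div != 0L)
    stop("input spatial dimensions must be divisible by ", div,
         " (2^(levels-1)); got ", H, "x", W)
}

#' Forward pass of the generator
#'
#' @param model an `ss_generator`.
#' @param x normalized input array `(H, W, 1, N)` with values in `[0, 1]`.
#' @param training logical; batch-norm mode.
#' @return `list(heads = <list of (H, W, 1, N) probability maps>, cache)`.
#'   With deep supervision the list holds one map per decoder level, ordered
#'   deepest (coarsest) first; the last entry is the final segmentation map.
#' @export
generator_forward <- function(model, x, training = TRUE) {
  cfg <- model$cfg
  d <- dim(x)
  check_divisible(d[1], d[2], cfg$levels)
  L <- cfg$levels
  # image pyramid
  pyr <- NULL
  if (cfg$use_pyramid) {
    pyr <- vector("list", min(3L, L - 1L))
    p <- x
    for (i in seq_along(pyr)) {
      p <- cpp_avgpool2_fwd(p)
      pyr[[i]] <- p
    }
  }
  e <- vector("list", L)
  ecache <- vector("list", L)
  pooled_ch <- integer(L)   # channels of the pooled part of each level input
  h <- x
  for (l in seq_len(L)) {
    if (l > 1L) {
      h <- cpp_avgpool2_fwd(h)
      pooled_ch[l] <- dim(h)[3]
      if (cfg$use_pyramid && l <= min(4L, L))
        h <- concat_ch(h, pyr[[l - 1L]])
    }
    out <- block_forward(model$enc[[l]], h, training)
    ecache[[l]] <- out$cache
    e[[l]] <- out$y
    h <- out$y
  }
  n_dec <- L - 1L
  dcur <- e[[L]]
  dout <- vector("list", n_dec)
  dcache <- vector("list", n_dec)
  up_ch <- integer(n_dec)
  for (j in seq_len(n_dec)) {
    tgt <- dim(e[[L - j]])
    up <- cpp_bilinear_fwd(dcur, tgt[1], tgt[2])
    up_ch[j] <- dim(up)[3]
    cc <- concat_ch(up, e[[L - j]])
    out <- block_forward(model$dec[[j]], cc, training)
    dcache[[j]] <- out$cache
    dout[[j]] <- out$y
    dcur <- out$y
  }
  head_levels <- if (cfg$use_deep_supervision) seq_len(n_dec) else n_dec
  heads <- vector("list", length(head_levels))
  hcache <- vector("list", length(head_levels))
  for (i in seq_along(head_levels)) {
    j <- head_levels[i]
    hu <- unit_forward(model$heads[[i]], dout[[j]], training)
    logits <- hu$y
    if (j < n_dec) logits <- cpp_bilinear_fwd(logits, d[1], d[2])
    heads[[i]] <- sigmoid(logits)
    hcache[[i]] <- list(unit = hu$cache, j = j, y = heads[[i]])
  }
  list(heads = heads,
       cache = list(ecache = ecache, dcache = dcache, hcache = hcache,
                    e_dims = lapply(e, dim), d_dims = lapply(dout, dim),
                    pooled_ch = pooled_ch, up_ch = up_ch,
                    head_levels = head_levels, in_dim = d))
}

#' Backward pass of the generator
#'
#' Accumulates parameter gradients for a list of head-output gradients
#' (`dL/dy_i`, same shapes as the forward head maps).
#'
#' @param model an `ss_generator`.
#' @param cache cache from [generator_forward()].
#' @param ghead list of gradients, one per head.
#' @return invisibly, the gradient with respect to the (normalized) input.
#' @export
generator_backward <- function(model, cache, ghead) {
  cfg <- model$cfg
  L <- cfg$levels
  n_dec <- L - 1L
  gd <- vector("list", n_dec)   # gradient w.r.t. decoder outputs
  for (j in seq_len(n_dec)) gd[[j]] <- 0
  for (i in seq_along(cache$head_levels)) {
    j <- cache$head_levels[i]
    hc <- cache$hcache[[i]]
    y <- hc$y
    glogits <- ghead[[i]] * y * (1 - y)
    if (j < n_dec) {
      dd <- cache$d_dims[[j]]
      glogits <- cpp_bilinear_bwd(glogits, dd[1], dd[2])
    }
    gd[[j]] <- gd[[j]] + unit_backward(model$heads[[i]], hc$unit, glogits)
  }
  ge <- vector("list", L)
  for (l in seq_len(L)) ge[[l]] <- 0
  gnext <- NULL
  for (j in rev(seq_len(n_dec))) {
    g <- gd[[j]]
    if (!is.null(gnext)) g <- g + gnext
    gcc <- block_backward(model$dec[[j]], cache$dcache[[j]], g)
    sp <- split_ch(gcc, cache$up_ch[j])
    ge[[L - j]] <- ge[[L - j]] + sp[[2]]
    src_dim <- if (j == 1L) cache$e_dims[[L]] else cache$d_dims[[j - 1L]]
    gup <- cpp_bilinear_bwd(sp[[1]], src_dim[1], src_dim[2])
    if (j == 1L) ge[[L]] <- ge[[L]] + gup else gnext <- gup
    if (j == 1L) gnext <- NULL
  }
  gdown <- NULL
  for (l in rev(seq_len(L))) {
    g <- ge[[l]]
    if (!is.null(gdown)) g <- g + gdown
    gi <- block_backward(model$enc[[l]], cache$ecache[[l]], g)
    if (l > 1L) {
      if (cfg$use_pyramid && l <= min(4L, L))
        gi <- split_ch(gi, cache$pooled_ch[l])[[1]]
      gdown <- cpp_avgpool2_bwd(gi)
    } else {
      gdown <- gi
    }
  }
  invisible(gdown)
}

#' Normalize a count image for the network
#'
#' @param pixels numeric matrix of nonnegative counts.
#' @param mode `"per_image_max"` or `"fixed_16bit"`.
#' @return numeric matrix in `[0, 1]`.
#' @export
normalize_image <- function(pixels, mode = c("per_image_max", "fixed_16bit")) {
  mode <- match.arg(mode)
  if (mode == "per_image_max") {
    mx <- max(pixels)
    if (mx <= 0) return(pixels * 0)
    pixels / mx
  } else {
    pixels / 65535
  }
}

#' Predict a binary lesion mask
#'
#' Normalizes the image according to the generator configuration, runs the
#' forward pass in evaluation mode and thresholds the final head: pixels
#' with probability greater than or equal to `threshold` become foreground.
#'
#' @param model an `ss_generator`.
#' @param image a [scintigram()] or a numeric count matrix.
#' @param threshold foreground threshold in (0, 1); 0.5 by default.
#' @return a [lesion_mask()].
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single number strictly between 0 and 1")
  px <- if (inherits(image, "scintigram")) image$pixels else image
  xn <- normalize_image(px, model$cfg$input_normalization)
  x <- array(xn, dim = c(dim(xn), 1L, 1L))
  out <- generator_forward(model, x, training = FALSE)
  final <- out$heads[[length(out$heads)]]
  m <- matrix(as.integer(final[, , 1L, 1L] >= threshold), nrow = dim(final)[1])
  lesion_mask(m)
}

#' Save / load a generator checkpoint
#'
#' The configuration is stored alongside the weights so a checkpoint can be
#' restored without external context.
#'
#' @param model an `ss_generator`.
#' @param path file path.
#' @return `load_generator` returns the restored model.
#' @export
save_generator <- function(model, path) {
  saveRDS(list(cfg = model$cfg, state = module_state(model)), path)
  invisible(path)
}

#' @rdname save_generator
#' @export
load_generator <- function(path) {
  obj <- readRDS(path)
  model <- build_generator(obj$cfg)
  load_module_state(model, obj$state)
  model
}
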