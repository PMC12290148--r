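# ---------------------------------------------------------------------------
# The multi-layer convolutional critic. Instead of a scalar real/fake
# probability it emits a multi-scale feature signature: after every strided
# conv stage the feature map is flattened, weighted and mean-normalized,
# and all pieces are concatenated into one vector. The adversarial loss is
# the L1 distance between the signatures of image (x) predicted-mask and
# image (x) ground-truth-mask products.
# ---------------------------------------------------------------------------

#' Critic configuration
#'
#' @param layers number of strided conv stages (each halves resolution).
#' @param base_channels channels of the first stage; the plan is
#'   `base * c(1, 2, 4, 8, 8, 8, ...)` capped at `8 * base`.
#' @param input_mode how image and mask are combined before the critic:
#'   `"product"` (elementwise image x mask, the default), `"concat"`
#'   (2-channel stack), `"sum"`, or `"mask_only"`.
#' @param layer_weights nonnegative per-stage weights of the signature;
#'   all 1 by default.
#' @param seed integer seed for weight initialisation.
#' @return a list of class `critic_config`.
#' @export
critic_config <- function(layers = 6L, base_channels = 64L,
                          input_mode = c("product", "concat", "sum",
                                         "mask_only"),
                          layer_weights = NULL, seed = 42L) {
  input_mode <- match.arg(input_mode)
  layers <- as.integer(layers)
  if (layers < 2L) stop("the critic needs at least 2 stages")
  if (is.null(layer_weights)) layer_weights <- rep(1, layers)
  if (length(layer_weights) != layers)
    stop("layer_weights must have one entry per stage")
  if (any(layer_weights < 0) || all(layer_weights == 0))
    stop("layer_weights must be nonnegative and not all zero")
  structure(list(layers = layers, base_channels = as.integer(base_channels),
                 input_mode = input_mode, layer_weights = layer_weights,
                 seed = as.integer(seed)),
            class = "critic_config")
}

#' Build the critic network
#'
#' Stages are 4x4 convolutions with stride 2 and padding 1 (halving the
#' resolution), leaky-ReLU activations (slope 0.2), batch norm in every
#' stage except the first.
#'
#' @param cfg a [critic_config()].
#' @return an object of class `ss_critic`.
#' @export
build_critic <- function(cfg) {
  stopifnot(inherits(cfg, "critic_config"))
  with_seed(cfg$seed, {
    in_ch <- if (cfg$input_mode == "concat") 2L else 1L
    mult <- pmin(2L^(seq_len(cfg$layers) - 1L), 8L)
    ch <- cfg$base_channels * mult
    stages <- vector("list", cfg$layers)
    for (l in seq_len(cfg$layers)) {
      stages[[l]] <- new_conv_unit(if (l == 1L) in_ch else ch[l - 1L], ch[l],
                                   k = 4L, stride = 2L, pad = 1L,
                                   bn = (l > 1L), act = "leaky", slope = 0.2)
    }
    structure(list(cfg = cfg, stages = stages, channels = ch),
              class = c("ss_critic", "ss_module"))
  })
}

#' Combine an image and a mask into the critic input
#'
#' @param image normalized image array or matrix, values in `[0, 1]`.
#' @param mask probability or binary map of the same spatial shape.
#' @param mode see [critic_config()].
#' @return a `(H, W, C, N)` array (C = 2 for `"concat"`, else 1).
#' @export
critic_input <- function(image, mask,
                         mode = c("product", "concat", "sum", "mask_only")) {
  mode <- match.arg(mode)
  image <- as_nchw(image)
  mask <- as_nchw(mask)
  if (!all(dim(image)[c(1, 2, 4)] == dim(mask)[c(1, 2, 4)]))
    stop("image and mask must share spatial dimensions and batch size")
  if (min(mask) < 0 || max(mask) > 1)
    stop("mask values must lie in [0, 1]")
  switch(mode,
         product = image * mask,
         concat = concat_ch(image, mask),
         sum = image + mask,
         mask_only = mask)
}

critic_forward <- function(model, x, training = TRUE) {
  L <- model$cfg$layers
  w <- model$cfg$layer_weights
  caches <- vector("list", L)
  pieces <- vector("list", L)
  dims <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    if (any(dim(h)[1:2] < 2L))
      stop("input too small to pass through all ", L, " critic stages")
    out <- unit_forward(model$stages[[l]], h, training)
    caches[[l]] <- out$cache
    h <- out$y
    dims[[l]] <- dim(h)
    pieces[[l]] <- as.numeric(h) * (w[l] / length(h))
  }
  list(sig = unlist(pieces), caches = caches, dims = dims,
       piece_len = vapply(pieces, length, integer(1)))
}

critic_backward <- function(model, fwd, gsig, want_gx = TRUE,
                            want_gw = TRUE) {
  L <- model$cfg$layers
  w <- model$cfg$layer_weights
  offs <- cumsum(c(0, fwd$piece_len))
  gnext <- NULL
  for (l in rev(seq_len(L))) {
    gpiece <- gsig[(offs[l] + 1):offs[l + 1]] * (w[l] / fwd$piece_len[l])
    g <- array(gpiece, dim = fwd$dims[[l]])
    if (!is.null(gnext)) g <- g + gnext
    gnext <- unit_backward(model$stages[[l]], fwd$caches[[l]], g,
                           want_gx = (l > 1L || want_gx),
                           want_gw = want_gw)
  }
  gnext
}

#' Multi-scale feature signature of the critic
#'
#' Runs the critic and returns the concatenation of all per-stage feature
#' maps, each flattened and scaled by `layer_weight / n_elements`, so each
#' stage contributes its weighted feature mean structure regardless of
#' resolution.
#'
#' @param model an `ss_critic`.
#' @param x input array from [critic_input()].
#' @param training logical; batch-norm mode.
#' @return an object of class `critic_signature` with fields `vector` and
#'   `n_layers`.
#' @export
critic_signature <- function(model, x, training = TRUE) {
  fwd <- critic_forward(model, as_nchw(x), training)
  structure(list(vector = fwd$sig, n_layers = model$cfg$layers),
            class = "critic_signature")
}

#' Multi-scale L1 distance between two critic signatures
#'
#' The average over critic stages of the weighted mean absolute feature
#' difference: with the per-element normalisation of [critic_signature()],
#' `sum(|a - b|) / n_layers`.
#'
#' @param a,b `critic_signature` objects from the same critic.
#' @return a nonnegative scalar.
#' @export
multiscale_l1 <- function(a, b) {
  stopifnot(inherits(a, "critic_signature"), inherits(b, "critic_signature"))
  if (length(a$vector) != length(b$vector))
    stop("signatures have different lengths")
  sum(abs(a$vector - b$vector)) / a$n_layers
}

#' @rdname save_generator
#' @export
save_critic <- function(model, path) {
  saveRDS(list(cfg = model$cfg, state = module_state(model)), path)
  invisible(path)
}

#' @rdname save_generator
#' @export
load_critic <- function(path) {
  obj <- readRDS(path)
  model <- build_critic(obj$cfg)
  load_module_state(model, obj$state)
  model
}
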