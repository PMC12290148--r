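#' @useDynLib scintiseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois sd
NULL

# ---------------------------------------------------------------------------
# Minimal neural-network core.
#
# Tensors are numeric arrays with dim c(H, W, C, N). A "conv unit" is the
# fused layer conv2d -> batch norm (optional) -> activation, with both passes
# implemented natively (see src/ops.cpp). Parameters live in environments so
# gradients and optimizer state can be accumulated in place; blocks are
# plain lists of units/sub-blocks tagged with class "ss_module".
# ---------------------------------------------------------------------------

ACT_NONE <- 0L
ACT_RELU <- 1L
ACT_LEAKY <- 2L

#' Create a fused convolution unit (conv2d -> batch norm -> activation)
#'
#' The unit holds its weights, batch-norm statistics, gradient accumulators
#' and Adam state in an environment. Kaiming fan-in initialisation is used
#' for the convolution weights.
#'
#' @param in_ch,out_ch input/output channel counts.
#' @param k odd kernel size in pixels.
#' @param stride,pad,dil stride, zero padding and dilation rate.
#' @param bn logical; include a batch-norm layer after the convolution.
#' @param act one of `"none"`, `"relu"`, `"leaky"`.
#' @param slope negative slope for leaky ReLU.
#' @return an environment of class `ss_conv_unit`.
#' @keywords internal
new_conv_unit <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = 1L,
                          dil = 1L, bn = TRUE, act = "relu", slope = 0.2) {
  u <- new.env(parent = emptyenv())
  fan_in <- k * k * in_ch
  u$W <- array(rnorm(k * k * in_ch * out_ch, sd = sqrt(2 / fan_in)),
               dim = c(k, k, in_ch, out_ch))
  u$b <- numeric(out_ch)
  u$gamma <- rep(1, out_ch)
  u$beta <- numeric(out_ch)
  u$rmean <- numeric(out_ch)
  u$rvar <- rep(1, out_ch)
  u$gW <- array(0, dim = dim(u$W)); u$gb <- numeric(out_ch)
  u$ggamma <- numeric(out_ch); u$gbeta <- numeric(out_ch)
  u$stride <- as.integer(stride); u$pad <- as.integer(pad)
  u$dil <- as.integer(dil)
  u$bn <- isTRUE(bn)
  u$passthrough <- FALSE
  u$act <- switch(act, none = ACT_NONE, relu = ACT_RELU, leaky = ACT_LEAKY,
                  stop("unknown activation: ", act))
  u$slope <- slope
  u$in_ch <- as.integer(in_ch); u$out_ch <- as.integer(out_ch)
  u$k <- as.integer(k)
  class(u) <- "ss_conv_unit"
  u
}

unit_bn_mode <- function(u, training) {
  if (!u$bn) 0L
  else if (u$passthrough) 3L
  else if (training) 1L
  else 2L
}

unit_forward <- function(u, x, training = TRUE) {
  mode <- unit_bn_mode(u, training)
  out <- cpp_conv_unit_fwd(x, u$W, u$b, u$stride, u$pad, u$dil, mode,
                           u$gamma, u$beta, u$rmean, u$rvar, 1e-5, 0.1,
                           u$act, u$slope)
  if (mode == 1L) {
    u$rmean <- out$rmean
    u$rvar <- out$rvar
  }
  list(y = out$y,
       cache = list(x = x, y = out$y, z = out$z, mean = out$mean,
                    invstd = out$invstd, bn_mode = mode))
}

unit_backward <- function(u, cache, gy, want_gx = TRUE, want_gw = TRUE) {
  g <- cpp_conv_unit_bwd(cache$x, u$W, gy, cache$y, cache$z, cache$mean,
                         cache$invstd, u$gamma, u$stride, u$pad, u$dil,
                         cache$bn_mode, u$act, u$slope, want_gx, want_gw)
  if (want_gw) {
    u$gW <- u$gW + g$gW
    u$gb <- u$gb + g$gb
    if (u$bn && !u$passthrough) {
      u$ggamma <- u$ggamma + g$ggamma
      u$gbeta <- u$gbeta + g$gbeta
    }
  }
  g$gx
}

# Recursively collect all conv units of a module tree.
collect_units <- function(m) {
  if (inherits(m, "ss_conv_unit")) return(list(m))
  if (is.list(m)) return(do.call(c, lapply(unname(m), collect_units)))
  list()
}

zero_grads <- function(m) {
  for (u in collect_units(m)) {
    u$gW[] <- 0; u$gb[] <- 0; u$ggamma[] <- 0; u$gbeta[] <- 0
  }
  invisible(m)
}

n_parameters <- function(m) {
  sum(vapply(collect_units(m), function(u) {
    length(u$W) + length(u$b) + if (u$bn) 2L * u$out_ch else 0L
  }, numeric(1)))
}

# Named list of parameter array names per unit (used for structural diffs).
parameter_names <- function(m, prefix = "") {
  out <- character(0)
  walk <- function(x, pre) {
    if (inherits(x, "ss_conv_unit")) {
      dims <- paste(dim(x$W), collapse = "x")
      out <<- c(out, paste0(pre, "/W[", dims, "]"), paste0(pre, "/b"))
      if (x$bn) out <<- c(out, paste0(pre, "/gamma"), paste0(pre, "/beta"))
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        tag <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(x[[i]], paste0(pre, "/", tag))
      }
    }
  }
  walk(m, prefix)
  out
}

# Put a module into a linearised probing state: all-positive weights, zero
# bias, batch norm in pass-through mode. With a positive input this makes
# every ReLU active, so the gradient support equals the linear receptive
# field.
linearize_module <- function(m) {
  for (u in collect_units(m)) {
    u$W <- abs(u$W) + 1e-3
    u$b[] <- 0
    u$passthrough <- TRUE
  }
  invisible(m)
}

set_zero_weights <- function(m) {
  for (u in collect_units(m)) {
    u$W[] <- 0; u$b[] <- 0; u$passthrough <- TRUE
  }
  invisible(m)
}

# --- simple array helpers ---------------------------------------------------

as_nchw <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) array(x, dim = c(d, 1L, 1L))
  else if (length(d) == 3L) array(x, dim = c(d, 1L))
  else x
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(g, c1) {
  d <- dim(g)
  list(g[, , seq_len(c1), , drop = FALSE],
       g[, , c1 + seq_len(d[3] - c1), , drop = FALSE])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- Adam -------------------------------------------------------------------

adam_new <- function(module, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$units <- collect_units(module)
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  for (u in opt$units) {
    u$mW <- array(0, dim = dim(u$W)); u$vW <- array(0, dim = dim(u$W))
    u$mb <- numeric(length(u$b)); u$vb <- numeric(length(u$b))
    u$mg <- numeric(length(u$gamma)); u$vg <- numeric(length(u$gamma))
    u$mB <- numeric(length(u$beta)); u$vB <- numeric(length(u$beta))
  }
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (u in opt$units) {
    cpp_adam_update(u$W, u$gW, u$mW, u$vW, opt$lr, b1, b2, c1, c2, opt$eps)
    cpp_adam_update(u$b, u$gb, u$mb, u$vb, opt$lr, b1, b2, c1, c2, opt$eps)
    if (u$bn) {
      cpp_adam_update(u$gamma, u$ggamma, u$mg, u$vg, opt$lr, b1, b2, c1, c2,
                      opt$eps)
      cpp_adam_update(u$beta, u$gbeta, u$mB, u$vB, opt$lr, b1, b2, c1, c2,
                      opt$eps)
    }
  }
  invisible(opt)
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Serialise / restore all parameters of a module tree as a flat list of
# numeric arrays (used by checkpointing).
module_state <- function(m) {
  lapply(collect_units(m), function(u) {
    list(W = u$W, b = u$b, gamma = u$gamma, beta = u$beta,
         rmean = u$rmean, rvar = u$rvar)
  })
}

load_module_state <- function(m, state) {
  units <- collect_units(m)
  if (length(units) != length(state))
    stop("checkpoint does not match the model architecture")
  for (i in seq_along(units)) {
    u <- units[[i]]; s <- state[[i]]
    if (!all(dim(u$W) == dim(s$W)))
      stop("checkpoint weight shape mismatch at unit ", i)
    u$W <- s$W; u$b <- s$b; u$gamma <- s$gamma; u$beta <- s$beta
    u$rmean <- s$rmean; u$rvar <- s$rvar
  }
  invisible(m)
}
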