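# Shared helpers: tiny in-code fixtures so every test runs from a clean
# checkout with no stored data.

ns <- asNamespace("scintiseg")

tiny_block_cfg <- function(ic = 2L, oc = 3L, ...) block_config(ic, oc, ...)

rand_tensor <- function(h, w, c = 1L, n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(h * w * c * n), dim = c(h, w, c, n))
}

rand_mask_tensor <- function(h, w, n = 1L, p = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array((runif(h * w * n) < p) * 1, dim = c(h, w, 1L, n))
}

tiny_generator <- function(base = 4L, seed = 42L, ...) {
  build_generator(generator_config(base_channels = base, seed = seed, ...))
}

tiny_critic <- function(base = 4L, layers = 4L, seed = 42L, ...) {
  build_critic(critic_config(layers = layers, base_channels = base,
                             seed = seed, ...))
}

# independent naive convolution oracle (double precision, direct loops)
naive_conv2d <- function(x, W, b, stride = 1, pad = 1, dil = 1) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(W)[1]; Cout <- dim(W)[4]
  Ho <- (H + 2 * pad - ((k - 1) * dil + 1)) %/% stride + 1
  Wo <- (Wd + 2 * pad - ((k - 1) * dil + 1)) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- b[co]
    for (ci in 1:C) for (kh in 1:k) for (kw in 1:k) {
      hi <- (ho - 1) * stride - pad + (kh - 1) * dil + 1
      wi <- (wo - 1) * stride - pad + (kw - 1) * dil + 1
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= Wd)
        acc <- acc + x[hi, wi, ci, n] * W[kh, kw, ci, co]
    }
    y[ho, wo, co, n] <- acc
  }
  y
}

# phantom dataset on disk in a temp dir, returning the split manifest
make_phantom_dataset <- function(n_patients = 4L, image_size = 32L,
                                 train_fraction = 0.5, seed = 7L) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  cfg <- phantom_config(image_size = image_size, n_patients = n_patients,
                        seed = seed)
  man <- generate_dataset(cfg, dir)
  split_by_patient(man, train_fraction, seed = seed)
}
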