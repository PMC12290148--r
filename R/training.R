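# ---------------------------------------------------------------------------
# Alternating adversarial optimization: one critic step (minimize
# 1 - adv on detached generator outputs) followed by one generator step
# (minimize alpha * seg + beta * adv), both with Adam. Repeated runs use
# seeds seed + run_index and report mean +/- sd metrics.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow common practice for this architecture family: Adam with
#' learning rate 1e-4, batch size 32, 600 epochs, base seed 42 and 5
#' repeated runs. Ablation flags switch off individual components
#' (adversarial loss, image pyramid, deep supervision, MSFE or CDC blocks,
#' the latter two replaced by plain double-conv blocks).
#'
#' @param lr learning rate (> 0) shared by both networks.
#' @param optimizer only `"adam"` is available.
#' @param batch_size images per gradient step.
#' @param epochs passes over the training split.
#' @param seed base seed; run `k` (0-based) uses `seed + k`.
#' @param n_runs repeated training runs for mean +/- sd reporting.
#' @param d_steps_per_g_step critic updates per generator update.
#' @param use_gan,use_pyramid,use_deep_supervision,use_msfe,use_cdc
#'   ablation switches.
#' @return a list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, optimizer = "adam", batch_size = 32L,
                         epochs = 600L, seed = 42L, n_runs = 5L,
                         d_steps_per_g_step = 1L, use_gan = TRUE,
                         use_pyramid = TRUE, use_deep_supervision = TRUE,
                         use_msfe = TRUE, use_cdc = TRUE) {
  if (lr <= 0) stop("lr must be positive")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is available")
  structure(list(lr = lr, optimizer = optimizer,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 n_runs = as.integer(n_runs),
                 d_steps_per_g_step = as.integer(d_steps_per_g_step),
                 use_gan = isTRUE(use_gan), use_pyramid = isTRUE(use_pyramid),
                 use_deep_supervision = isTRUE(use_deep_supervision),
                 use_msfe = isTRUE(use_msfe), use_cdc = isTRUE(use_cdc)),
            class = "train_config")
}

apply_ablations <- function(gen_cfg, cfg) {
  gen_cfg$use_pyramid <- gen_cfg$use_pyramid && cfg$use_pyramid
  gen_cfg$use_deep_supervision <-
    gen_cfg$use_deep_supervision && cfg$use_deep_supervision
  if (!cfg$use_msfe)
    gen_cfg$encoder_block_types[gen_cfg$encoder_block_types == "msfe"] <- "plain"
  if (!cfg$use_cdc)
    gen_cfg$encoder_block_types[gen_cfg$encoder_block_types == "cdc"] <- "plain"
  gen_cfg
}

critic_update <- function(batch, generator_heads, critic, critic_opt) {
  image <- batch$x; gt <- batch$gt
  mode <- critic$cfg$input_mode
  nl <- critic$cfg$layers
  nh <- length(generator_heads)
  zero_grads(critic)
  xg <- critic_input(image, gt, mode)
  fwd_gt <- critic_forward(critic, xg, training = TRUE)
  gsig_gt <- numeric(length(fwd_gt$sig))
  adv <- 0
  for (i in seq_len(nh)) {
    xp <- critic_input(image, generator_heads[[i]], mode)
    fwd_p <- critic_forward(critic, xp, training = TRUE)
    diff <- fwd_p$sig - fwd_gt$sig
    adv <- adv + sum(abs(diff)) / nl / nh
    s <- sign(diff) / (nl * nh)
    # critic minimizes 1 - adv, so push the pred/gt signatures together
    critic_backward(critic, fwd_p, -s, want_gx = FALSE)
    gsig_gt <- gsig_gt + s
  }
  critic_backward(critic, fwd_gt, gsig_gt, want_gx = FALSE)
  adam_step(critic_opt)
  1 - adv
}

#' One adversarial training step
#'
#' Performs (optionally) one critic update on detached generator outputs,
#' then one generator update on the combined segmentation + adversarial
#' objective. With `use_gan = FALSE` the critic is untouched and the
#' reported critic loss is 0.
#'
#' @param batch list with `x` (normalized images, `(H, W, 1, N)`) and `gt`
#'   (binary masks, same shape).
#' @param generator an `ss_generator`.
#' @param critic an `ss_critic` (may be `NULL` when `use_gan = FALSE`).
#' @param w a [loss_weights()].
#' @param cfg a [train_config()].
#' @param gen_opt,critic_opt Adam states from `adam_new()`; created
#'   transiently when omitted (useful for single-step tests).
#' @return `list(gen_loss, disc_loss)`.
#' @export
train_step <- function(batch, generator, critic, w, cfg,
                       gen_opt = NULL, critic_opt = NULL) {
  if (is.null(gen_opt)) gen_opt <- adam_new(generator, lr = cfg$lr)
  use_gan <- cfg$use_gan && w$beta > 0 && !is.null(critic)
  fwd <- generator_forward(generator, batch$x, training = TRUE)
  d_loss <- 0
  if (use_gan) {
    if (is.null(critic_opt)) critic_opt <- adam_new(critic, lr = cfg$lr)
    for (k in seq_len(cfg$d_steps_per_g_step))
      d_loss <- critic_update(batch, fwd$heads, critic, critic_opt)
  }
  zero_grads(generator)
  seg <- seg_loss_with_grad(fwd$heads, batch$gt, w)
  gen_loss <- w$alpha * seg$loss
  ghead <- lapply(seg$grads, function(g) w$alpha * g)
  if (use_gan) {
    adv <- adv_loss_with_grad(fwd$heads, batch$gt, batch$x, critic)
    gen_loss <- gen_loss + w$beta * adv$loss
    for (i in seq_along(ghead))
      ghead[[i]] <- ghead[[i]] + w$beta * adv$grads[[i]]
  }
  generator_backward(generator, fwd$cache, ghead)
  adam_step(gen_opt)
  list(gen_loss = gen_loss, disc_loss = d_loss)
}

load_split_data <- function(manifest, split, normalization) {
  rows <- manifest[manifest$split == split, ]
  if (nrow(rows) == 0L) stop("manifest has no '", split, "' records")
  imgs <- vector("list", nrow(rows))
  gts <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    s <- read_scintigram(rows$image_path[i])
    m <- read_mask(rows$mask_path[i], expected_dim = dim(s$pixels))
    imgs[[i]] <- normalize_image(s$pixels, normalization)
    gts[[i]] <- m$pixels
  }
  list(images = imgs, masks = gts, rows = rows)
}

make_batch <- function(images, masks, idx) {
  d <- dim(images[[idx[1]]])
  x <- array(0, dim = c(d[1], d[2], 1L, length(idx)))
  gt <- array(0, dim = c(d[1], d[2], 1L, length(idx)))
  for (j in seq_along(idx)) {
    x[, , 1L, j] <- images[[idx[j]]]
    gt[, , 1L, j] <- masks[[idx[j]]]
  }
  list(x = x, gt = gt)
}

#' Train the adversarial segmentation model
#'
#' Trains for `cfg$epochs` epochs, repeats the whole procedure
#' `cfg$n_runs` times with seeds `seed + run_index`, and writes per-run
#' artifacts (generator/critic checkpoints, per-epoch loss log CSV) plus an
#' aggregated metrics report computed on the test split.
#'
#' @param manifest a `dataset_manifest` with train and test splits
#'   assigned.
#' @param gen_cfg a [generator_config()].
#' @param critic_cfg a [critic_config()] (ignored when `use_gan = FALSE`).
#' @param w a [loss_weights()].
#' @param cfg a [train_config()].
#' @param out_dir directory for run artifacts; `NULL` to skip writing.
#' @param verbose print per-epoch progress.
#' @return a list with per-run loss logs and metrics, the aggregated
#'   metrics (`aggregate_runs()` result) and checkpoint paths.
#' @export
fit <- function(manifest, gen_cfg, critic_cfg, w, cfg, out_dir = NULL,
                verbose = FALSE) {
  gen_cfg <- apply_ablations(gen_cfg, cfg)
  train_data <- load_split_data(manifest, "train", gen_cfg$input_normalization)
  test_data <- load_split_data(manifest, "test", gen_cfg$input_normalization)
  n_train <- length(train_data$images)
  runs <- vector("list", cfg$n_runs)
  reports <- vector("list", cfg$n_runs)
  for (run in seq_len(cfg$n_runs)) {
    run_seed <- cfg$seed + (run - 1L)
    gcfg <- gen_cfg; gcfg$seed <- run_seed
    generator <- build_generator(gcfg)
    gen_opt <- adam_new(generator, lr = cfg$lr)
    critic <- NULL; critic_opt <- NULL
    if (cfg$use_gan && w$beta > 0) {
      ccfg <- critic_cfg; ccfg$seed <- run_seed + 10000L
      critic <- build_critic(ccfg)
      critic_opt <- adam_new(critic, lr = cfg$lr)
    }
    loss_log <- data.frame(epoch = integer(0), gen_loss = numeric(0),
                           disc_loss = numeric(0))
    with_seed(run_seed, {
      for (epoch in seq_len(cfg$epochs)) {
        ord <- sample(n_train)
        gl <- 0; dl <- 0; nb <- 0L
        for (start in seq(1L, n_train, by = cfg$batch_size)) {
          idx <- ord[start:min(start + cfg$batch_size - 1L, n_train)]
          batch <- make_batch(train_data$images, train_data$masks, idx)
          res <- train_step(batch, generator, critic, w, cfg,
                            gen_opt, critic_opt)
          if (!is.finite(res$gen_loss))
            stop("non-finite generator loss in epoch ", epoch,
                 ", batch starting at index ", start)
          gl <- gl + res$gen_loss; dl <- dl + res$disc_loss; nb <- nb + 1L
        }
        loss_log <- rbind(loss_log,
                          data.frame(epoch = epoch, gen_loss = gl / nb,
                                     disc_loss = dl / nb))
        if (verbose)
          message(sprintf("run %d epoch %d: gen %.4f disc %.4f",
                          run, epoch, gl / nb, dl / nb))
      }
    })
    preds <- lapply(seq_along(test_data$images), function(i) {
      px <- test_data$images[[i]]
      x <- array(px, dim = c(dim(px), 1L, 1L))
      out <- generator_forward(generator, x, training = FALSE)
      final <- out$heads[[length(out$heads)]]
      (final[, , 1L, 1L] >= 0.5) * 1L
    })
    report <- evaluate(preds, test_data$masks)
    reports[[run]] <- report
    ckpt <- NULL
    if (!is.null(out_dir)) {
      run_dir <- file.path(out_dir, sprintf("run_%d", run))
      dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
      ckpt <- file.path(run_dir, "generator.rds")
      save_generator(generator, ckpt)
      if (!is.null(critic))
        save_critic(critic, file.path(run_dir, "critic.rds"))
      utils::write.csv(loss_log, file.path(run_dir, "loss_log.csv"),
                       row.names = FALSE)
    }
    runs[[run]] <- list(loss_log = loss_log, metrics = report,
                        checkpoint = ckpt, seed = run_seed)
  }
  agg <- aggregate_runs(reports)
  if (!is.null(out_dir)) {
    write_metrics_report(agg, out_dir)
    yaml::write_yaml(list(train = unclass(cfg), generator = unclass(gen_cfg),
                          loss = unclass(w)),
                     file.path(out_dir, "resolved_config.yaml"))
  }
  list(runs = runs, metrics = agg)
}
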