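make_tiny_batch <- function(n = 2L, sz = 32L, seed = 41L) {
  set.seed(seed)
  list(x = array(runif(sz * sz * n), c(sz, sz, 1L, n)),
       gt = array((runif(sz * sz * n) < 0.15) * 1, c(sz, sz, 1L, n)))
}

test_that("disabling the adversary leaves the critic bitwise untouched", {
  g <- tiny_generator(base = 2L)
  cr <- tiny_critic()
  before <- ns$module_state(cr)
  cfg <- train_config(batch_size = 2L, epochs = 1L, use_gan = FALSE)
  res <- train_step(make_tiny_batch(), g, cr, loss_weights(), cfg)
  expect_identical(res$disc_loss, 0)
  expect_identical(ns$module_state(cr), before)
})

test_that("a training step returns finite losses and both sum as expected", {
  g <- tiny_generator(base = 2L)
  cr <- tiny_critic()
  cfg <- train_config(batch_size = 2L, epochs = 1L)
  res <- train_step(make_tiny_batch(), g, cr, loss_weights(), cfg)
  expect_true(is.finite(res$gen_loss))
  expect_true(is.finite(res$disc_loss))
  expect_gt(res$gen_loss, 0)
})

test_that("identical seeds give bitwise-identical first-step losses", {
  run_once <- function() {
    g <- tiny_generator(base = 2L, seed = 7L)
    cr <- tiny_critic(seed = 7L)
    cfg <- train_config(batch_size = 2L, epochs = 1L, seed = 7L)
    train_step(make_tiny_batch(seed = 7L), g, cr, loss_weights(), cfg)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$gen_loss, r2$gen_loss)
  expect_identical(r1$disc_loss, r2$disc_loss)
})

test_that("fit writes checkpoints, loss logs and a metrics report per run", {
  man <- make_phantom_dataset(n_patients = 4L, image_size = 32L)
  out <- withr::local_tempdir()
  gcfg <- generator_config(base_channels = 2L, seed = 1L)
  ccfg <- critic_config(layers = 4L, base_channels = 2L, seed = 1L)
  cfg <- train_config(batch_size = 4L, epochs = 2L, n_runs = 2L, seed = 1L)
  res <- fit(man, gcfg, ccfg, loss_weights(), cfg, out_dir = out)
  expect_length(res$runs, 2L)
  for (k in 1:2) {
    expect_true(file.exists(file.path(out, paste0("run_", k),
                                      "generator.rds")))
    expect_true(file.exists(file.path(out, paste0("run_", k),
                                      "loss_log.csv")))
    expect_identical(nrow(res$runs[[k]]$loss_log), 2L)
  }
  expect_true(file.exists(file.path(out, "metrics_summary.json")))
  expect_true(file.exists(file.path(out, "resolved_config.yaml")))
  expect_identical(nrow(res$metrics$per_run), 2L)
  expect_true(all(c("dsc_sd", "precision_sd") %in%
                    names(res$metrics$summary)))
  # the two runs used different seeds, so their losses differ
  expect_false(identical(res$runs[[1]]$loss_log$gen_loss,
                         res$runs[[2]]$loss_log$gen_loss))
})

test_that("ablation flags change only their designated subgraph", {
  base_names <- ns$parameter_names(
    build_generator(ns$apply_ablations(
      generator_config(base_channels = 2L), train_config())))
  no_msfe <- ns$parameter_names(
    build_generator(ns$apply_ablations(
      generator_config(base_channels = 2L),
      train_config(use_msfe = FALSE))))
  # removing MSFE rewires only encoder levels 2-5
  expect_true(all(grepl("/enc/", symdiff <- union(
    setdiff(base_names, no_msfe), setdiff(no_msfe, base_names)))))
  no_cdc <- ns$parameter_names(
    build_generator(ns$apply_ablations(
      generator_config(base_channels = 2L),
      train_config(use_cdc = FALSE))))
  expect_true(all(grepl("/enc/1/", union(setdiff(base_names, no_cdc),
                                         setdiff(no_cdc, base_names)))))
  no_ds <- build_generator(ns$apply_ablations(
    generator_config(base_channels = 2L),
    train_config(use_deep_supervision = FALSE)))
  expect_length(no_ds$heads, 1L)
})

test_that("an empty training split is a configuration error", {
  man <- make_phantom_dataset(n_patients = 4L, image_size = 32L)
  man$split <- "test"
  gcfg <- generator_config(base_channels = 2L)
  expect_error(fit(man, gcfg, critic_config(), loss_weights(),
                   train_config(epochs = 1L)), "no 'train' records")
})
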