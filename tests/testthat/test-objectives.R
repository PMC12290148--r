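test_that("Dice coefficient handles perfect, disjoint and counted overlaps", {
  m <- matrix(0, 6, 6); m[2:3, 2:3] <- 1
  expect_equal(dice_coefficient(m, m, smooth = 0), 1)
  disj <- matrix(0, 6, 6); disj[5:6, 5:6] <- 1
  expect_equal(dice_coefficient(m, disj, smooth = 1e-12), 0, tolerance = 1e-6)
  # TP=3, FP=1, FN=2 -> 2*3/(2*3+1+2) = 0.6667
  gt <- matrix(0, 4, 4); gt[cbind(c(1, 1, 2, 2, 3), c(1, 2, 1, 2, 3))] <- 1
  pr <- matrix(0, 4, 4); pr[cbind(c(1, 1, 2, 4), c(1, 2, 1, 4))] <- 1
  cc <- confusion_counts(pr, gt)
  expect_identical(unlist(cc[c("tp", "fp", "fn")]),
                   c(tp = 3L, fp = 1L, fn = 2L))
  expect_equal(dice_coefficient(pr, gt, smooth = 1e-12), 2 * 3 / (2 * 3 + 1 + 2),
               tolerance = 1e-9)
})

test_that("binarized soft Dice equals the confusion-count Dice", {
  set.seed(21)
  for (i in 1:200) {
    a <- matrix((runif(64) < 0.4) * 1, 8, 8)
    b <- matrix((runif(64) < 0.4) * 1, 8, 8)
    cc <- confusion_counts(a, b)
    denom <- 2 * cc$tp + cc$fp + cc$fn
    want <- if (denom == 0) 1 else 2 * cc$tp / denom
    expect_equal(dice_coefficient(a, b, smooth = 1e-12), want,
                 tolerance = 1e-6)
  }
})

test_that("seg loss averages per-head Dice complements", {
  gt <- matrix(0, 8, 8); gt[3:5, 3:5] <- 1
  w <- loss_weights()
  perfect <- replicate(4, gt, simplify = FALSE)
  expect_equal(seg_loss(perfect, gt, w), 0)
  disj <- matrix(0, 8, 8); disj[7:8, 7:8] <- 1
  expect_equal(seg_loss(replicate(4, disj, simplify = FALSE), gt, w,
                        smooth = 1e-12), 1, tolerance = 1e-6)
  # heads with Dice {1, 1, 0, 0} and equal weights -> loss 0.5
  mixed <- list(gt, gt, disj, disj)
  expect_equal(seg_loss(mixed, gt, w, smooth = 1e-12), 0.5, tolerance = 1e-6)
  expect_error(seg_loss(perfect, gt * 0.5, w), "binary")
})

test_that("bce and dice_plus_bce loss kinds behave as documented", {
  gt <- matrix(0, 8, 8); gt[2:4, 2:4] <- 1
  heads <- replicate(4, pmin(pmax(gt, 1e-7), 1 - 1e-7), simplify = FALSE)
  wb <- loss_weights(seg_loss_kind = "bce")
  expect_lt(seg_loss(heads, gt, wb), 1e-5)
  wdb <- loss_weights(seg_loss_kind = "dice_plus_bce")
  wd <- loss_weights(seg_loss_kind = "dice")
  expect_gte(seg_loss(heads, gt, wdb), seg_loss(heads, gt, wd))
})

test_that("generator and critic adversarial losses sum to one", {
  cr <- tiny_critic()
  set.seed(22)
  img <- array(runif(16 * 16), c(16, 16, 1, 1))
  gt <- array((runif(16 * 16) < 0.3) * 1, c(16, 16, 1, 1))
  heads <- replicate(4, array(runif(16 * 16), c(16, 16, 1, 1)),
                     simplify = FALSE)
  a <- adv_loss_G(heads, gt, img, cr)
  d <- disc_loss(heads, gt, img, cr)
  expect_equal(a + d, 1, tolerance = 1e-14)
  # perfect heads: adv 0, disc 1
  perfect <- replicate(4, gt, simplify = FALSE)
  expect_equal(adv_loss_G(perfect, gt, img, cr), 0)
  expect_equal(disc_loss(perfect, gt, img, cr), 1)
  # symmetric under swapping pred and gt
  pred_bin <- array((runif(16 * 16) < 0.3) * 1, c(16, 16, 1, 1))
  a1 <- adv_loss_G(replicate(4, pred_bin, simplify = FALSE), gt, img, cr)
  a2 <- adv_loss_G(replicate(4, gt, simplify = FALSE), pred_bin, img, cr)
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("total generator loss reduces to its parts at extreme weights", {
  cr <- tiny_critic()
  set.seed(23)
  img <- array(runif(16 * 16), c(16, 16, 1, 1))
  gt <- array((runif(16 * 16) < 0.3) * 1, c(16, 16, 1, 1))
  heads <- replicate(4, array(runif(16 * 16), c(16, 16, 1, 1)),
                     simplify = FALSE)
  w10 <- loss_weights(alpha = 1, beta = 0)
  expect_equal(total_gen_loss(heads, gt, img, cr, w10),
               seg_loss(heads, gt, w10))
  w01 <- loss_weights(alpha = 0, beta = 1)
  expect_equal(total_gen_loss(heads, gt, img, cr, w01),
               adv_loss_G(heads, gt, img, cr))
  perfect <- replicate(4, gt, simplify = FALSE)
  expect_equal(total_gen_loss(perfect, gt, img, cr, loss_weights()), 0)
})

test_that("corrupting a perfect prediction never decreases the Dice loss", {
  set.seed(24)
  gt <- matrix((runif(100) < 0.3) * 1, 10, 10)
  w <- loss_weights()
  prev <- seg_loss(replicate(4, gt, simplify = FALSE), gt, w)
  pred <- gt
  fg <- which(pred == 1)
  for (i in sample(fg, min(5, length(fg)))) {
    pred[i] <- 0
    cur <- seg_loss(replicate(4, pred, simplify = FALSE), gt, w)
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})

test_that("evaluate macro-averages per-image metrics, order-invariantly", {
  gt1 <- matrix(0, 4, 4); gt1[cbind(c(1, 1, 2, 2, 3), c(1, 2, 1, 2, 3))] <- 1
  pr1 <- matrix(0, 4, 4); pr1[cbind(c(1, 1, 2, 4), c(1, 2, 1, 4))] <- 1
  gt2 <- matrix(0, 4, 4); gt2[1, 1] <- 1
  pr2 <- gt2
  rep12 <- evaluate(list(pr1, pr2), list(gt1, gt2))
  rep21 <- evaluate(list(pr2, pr1), list(gt2, gt1))
  expect_equal(rep12$dsc, rep21$dsc)
  expect_equal(rep12$per_image$precision[1], 0.75)
  expect_equal(rep12$per_image$recall[1], 0.6)
  expect_equal(rep12$per_image$dsc[1], 2 * 0.75 * 0.6 / (0.75 + 0.6))
  # all-background prediction with nonempty gt has zero recall
  rep0 <- evaluate(list(matrix(0, 4, 4)), list(gt1))
  expect_equal(rep0$recall, 0)
  # both empty counts as a correct rejection by default
  repe <- evaluate(list(matrix(0, 4, 4)), list(matrix(0, 4, 4)))
  expect_equal(repe$dsc, 1)
  expect_equal(evaluate(list(matrix(0, 4, 4)), list(matrix(0, 4, 4)),
                        empty_value = 0)$dsc, 0)
  expect_error(evaluate(list(pr1), list(gt1, gt2)), "same length")
})

test_that("run aggregation reports mean and standard deviation", {
  r1 <- evaluate(list(matrix(1, 2, 2)), list(matrix(1, 2, 2)))
  gt <- matrix(0, 2, 2); gt[1, 1] <- 1
  r2 <- evaluate(list(matrix(1, 2, 2)), list(gt))
  agg <- aggregate_runs(list(r1, r2))
  expect_equal(nrow(agg$per_run), 2)
  expect_equal(agg$summary$dsc, mean(agg$per_run$dsc))
  expect_equal(agg$summary$dsc_sd, sd(agg$per_run$dsc))
  dir <- withr::local_tempdir()
  write_metrics_report(agg, dir)
  expect_true(file.exists(file.path(dir, "metrics_per_run.csv")))
  expect_true(file.exists(file.path(dir, "metrics_summary.json")))
})
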