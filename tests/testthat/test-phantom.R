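# flood-fill connected-component count: an independent oracle for the
# clustering behaviour (4-connectivity)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] == 1L && lab[i, j] == 0L) {
      comp <- comp + 1L
      queue <- list(c(i, j)); lab[i, j] <- comp
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] == 1L &&
              lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- comp
            queue <- c(queue, list(q))
          }
        }
      }
    }
  }
  comp
}

test_that("phantom pairs are bit-identical for a fixed (seed, patient)", {
  cfg <- phantom_config(image_size = 32L, n_patients = 2L, seed = 5L)
  a <- generate_phantom_pair(cfg, 1L)
  b <- generate_phantom_pair(cfg, 1L)
  expect_identical(a$anterior$pixels, b$anterior$pixels)
  expect_identical(a$posterior$pixels, b$posterior$pixels)
  expect_identical(a$mask_anterior$pixels, b$mask_anterior$pixels)
  c2 <- generate_phantom_pair(cfg, 2L)
  expect_false(identical(a$anterior$pixels, c2$anterior$pixels))
})

test_that("posterior view is the mirrored anterior with independent noise", {
  cfg <- phantom_config(image_size = 32L, n_patients = 1L, seed = 8L)
  p <- generate_phantom_pair(cfg, 1L)
  expect_identical(p$mask_posterior$pixels,
                   p$mask_anterior$pixels[, 32:1])
  expect_false(identical(p$posterior$pixels, p$anterior$pixels[, 32:1]))
})

test_that("zero lesions yield empty masks but a visible spine band", {
  cfg <- phantom_config(image_size = 32L, n_patients = 1L,
                        lesions_per_image = c(0L, 0L),
                        n_confounders = c(0L, 0L), seed = 2L)
  p <- generate_phantom_pair(cfg, 1L)
  expect_true(all(p$mask_anterior$pixels == 0L))
  px <- p$anterior$pixels
  spine_cols <- 14:19
  expect_gt(mean(px[, spine_cols]), 2 * mean(px[, 1:6]))
})

test_that("forced clustering keeps lesion centers within one cluster diameter", {
  cfg <- phantom_config(image_size = 64L, n_patients = 1L,
                        lesions_per_image = c(3L, 3L), cluster_prob = 1,
                        small_lesion_prob = 1, n_confounders = c(0L, 0L),
                        seed = 11L)
  for (i in 1:5) {
    p <- generate_phantom_pair(cfg, i)
    centers <- p$lesions[, c("cy", "cx")]
    dists <- as.matrix(dist(centers))
    expect_lte(max(dists), 2 * max(cfg$large_radius_px))
    expect_lte(count_components(p$mask_anterior$pixels), 3L)
  }
})

test_that("the mask is exactly the union of the logged lesion ellipses", {
  cfg <- phantom_config(image_size = 48L, n_patients = 1L, seed = 13L)
  for (i in 1:4) {
    p <- generate_phantom_pair(cfg, i)
    size <- cfg$image_size
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    rebuilt <- matrix(0L, size, size)
    for (j in seq_len(nrow(p$lesions))) {
      l <- p$lesions[j, ]
      sup <- ((rows - l$cy) / l$ry)^2 + ((cols - l$cx) / l$rx)^2 <= 1
      rebuilt[sup] <- 1L
    }
    expect_identical(p$mask_anterior$pixels, rebuilt)
  }
})

test_that("count statistics honour lesion > spine > background ordering", {
  cfg <- phantom_config(image_size = 64L, n_patients = 1L,
                        lesions_per_image = c(2L, 3L),
                        n_confounders = c(0L, 0L), seed = 17L)
  les <- c(); spine <- c(); bg <- c()
  for (i in 1:5) {
    p <- generate_phantom_pair(cfg, i)
    px <- p$anterior$pixels
    m <- p$mask_anterior$pixels
    spine_band <- matrix(FALSE, 64, 64); spine_band[, 28:37] <- TRUE
    les <- c(les, px[m == 1L])
    spine <- c(spine, px[spine_band & m == 0L])
    bg <- c(bg, px[!spine_band & m == 0L & col(px) < 20])
  }
  expect_gt(mean(les), mean(spine))
  expect_gt(mean(spine), mean(bg))
})

test_that("all phantom images satisfy the 16-bit count invariants", {
  cfg <- phantom_config(image_size = 32L, n_patients = 3L, seed = 19L)
  for (i in 1:3) {
    p <- generate_phantom_pair(cfg, i)
    for (img in list(p$anterior$pixels, p$posterior$pixels)) {
      expect_true(all(img >= 0L))
      expect_true(all(img <= 65535L))
      expect_true(is.integer(img))
    }
  }
})

test_that("generate_dataset writes two records per patient plus a manifest", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(image_size = 32L, n_patients = 3L, seed = 23L)
  man <- generate_dataset(cfg, dir)
  expect_identical(nrow(man), 6L)
  expect_true(all(table(man$patient_id) == 2L))
  expect_setequal(unique(man$view), c("anterior", "posterior"))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))
  # written pair matches the in-memory pair
  p <- generate_phantom_pair(cfg, 1L)
  r <- read_scintigram(man$image_path[man$patient_id == "P0001" &
                                        man$view == "anterior"])
  expect_identical(r$pixels, p$anterior$pixels)
})

test_that("small-lesion foreground fraction matches the expected ellipse area", {
  cfg <- phantom_config(image_size = 64L, n_patients = 50L,
                        lesions_per_image = c(1L, 1L), small_lesion_prob = 1,
                        n_confounders = c(0L, 0L), cluster_prob = 0,
                        seed = 29L)
  fracs <- vapply(1:50, function(i) {
    mean(generate_phantom_pair(cfg, i)$mask_anterior$pixels)
  }, numeric(1))
  # expected area of an axis-aligned ellipse with r ~ U(1.5, 3) and
  # eccentricity ~ U(0.5, 1): E[pi r^2 ecc] = pi E[r^2] E[ecc]
  r <- cfg$small_radius_px
  e_r2 <- (r[2]^3 - r[1]^3) / (3 * (r[2] - r[1]))
  expected <- pi * e_r2 * 0.75 / 64^2
  expect_lt(abs(mean(fracs) - expected) / expected, 0.2)
})
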