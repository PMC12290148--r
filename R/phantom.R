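# ---------------------------------------------------------------------------
# Synthetic bone-scintigram phantoms. Each synthetic patient yields an
# anterior/posterior image pair: a Poisson draw around a rate map composed
# of a uniform soft-tissue background, a high-uptake vertical spine band,
# hard-edged elliptical metastatic lesions spanning small (few-pixel) to
# large scales, and benign hot-spot confounders (soft Gaussian blobs near
# the image border, sharing the lesion intensity range) that are never part
# of the lesion mask. The posterior view is the mirrored anterior rate map
# with independently redrawn noise.
# ---------------------------------------------------------------------------

#' Phantom generator configuration
#'
#' Defaults emulate a thoracic bone-scan crop: counts of a few hundred in
#' hot regions, a spine band about one sixth of the image width, and lesion
#' radii from under 2 px ("few-pixel" lesions) up to ~9 px.
#'
#' @param image_size square image side in pixels (>= 32).
#' @param n_patients number of synthetic patients (2 images each).
#' @param lesions_per_image integer range `c(lo, hi)` of lesions per image.
#' @param small_radius_px,large_radius_px radius ranges (px) of the two
#'   lesion scales.
#' @param small_lesion_prob probability that a lesion is small-scale.
#' @param background_rate,spine_rate,lesion_rate expected counts of
#'   background, spine band and lesion interior; must satisfy
#'   `lesion_rate > spine_rate > background_rate > 0`.
#' @param confounder_rate peak added counts of a benign confounder blob
#'   (defaults to the lesion rate so intensity alone cannot separate them).
#' @param n_confounders integer range of confounder blobs per image.
#' @param cluster_prob probability that an image's lesions are clustered
#'   (centers drawn near one seed point).
#' @param seed base seed; patient `i` uses `seed + i` so every pair is
#'   reproducible in isolation.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64L, n_patients = 171L,
                           lesions_per_image = c(1L, 4L),
                           small_radius_px = c(1.5, 3),
                           large_radius_px = c(5, 9),
                           small_lesion_prob = 0.6,
                           background_rate = 20, spine_rate = 120,
                           lesion_rate = 300, confounder_rate = 300,
                           n_confounders = c(0L, 2L), cluster_prob = 0.15,
                           seed = 42L) {
  if (image_size < 32L) stop("image_size must be >= 32")
  if (!(lesion_rate > spine_rate && spine_rate > background_rate &&
        background_rate > 0))
    stop("rates must satisfy lesion_rate > spine_rate > background_rate > 0")
  if (any(small_radius_px <= 0) || any(large_radius_px <= 0))
    stop("radius ranges must be positive")
  structure(list(image_size = as.integer(image_size),
                 n_patients = as.integer(n_patients),
                 lesions_per_image = as.integer(lesions_per_image),
                 small_radius_px = small_radius_px,
                 large_radius_px = large_radius_px,
                 small_lesion_prob = small_lesion_prob,
                 background_rate = background_rate,
                 spine_rate = spine_rate, lesion_rate = lesion_rate,
                 confounder_rate = confounder_rate,
                 n_confounders = as.integer(n_confounders),
                 cluster_prob = cluster_prob, seed = as.integer(seed)),
            class = "phantom_config")
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else runif(1, r[1], r[2])
sample_int_range <- function(r) {
  if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)
}

ellipse_support <- function(size, cy, cx, ry, rx) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1
}

# Draw one anterior rate map + mask + lesion log for the current RNG state.
draw_rate_map <- function(cfg) {
  size <- cfg$image_size
  rate <- matrix(cfg$background_rate, size, size)
  # vertical spine band, one sixth of the width, centred
  half_band <- max(2L, round(size / 12))
  mid <- size / 2
  spine_cols <- max(1L, floor(mid - half_band)):min(size, ceiling(mid + half_band))
  rate[, spine_cols] <- cfg$spine_rate

  n_lesions <- sample_int_range(cfg$lesions_per_image)
  mask <- matrix(0L, size, size)
  lesions <- NULL
  margin <- 2
  clustered <- n_lesions > 1 && runif(1) < cfg$cluster_prob
  cluster_radius <- max(cfg$large_radius_px)
  if (clustered) {
    ccy <- runif(1, cluster_radius + margin, size - cluster_radius - margin)
    ccx <- runif(1, cluster_radius + margin, size - cluster_radius - margin)
  }
  if (n_lesions > 0) {
    for (i in seq_len(n_lesions)) {
      small <- runif(1) < cfg$small_lesion_prob
      r <- sample_range(if (small) cfg$small_radius_px else cfg$large_radius_px)
      ecc <- runif(1, 0.5, 1)
      if (runif(1) < 0.5) { ry <- r; rx <- r * ecc } else { ry <- r * ecc; rx <- r }
      placed <- FALSE
      for (try in 1:100) {
        if (clustered) {
          repeat {
            dy <- rnorm(1, sd = cluster_radius / 2)
            dx <- rnorm(1, sd = cluster_radius / 2)
            if (sqrt(dy^2 + dx^2) <= cluster_radius) break
          }
          cy <- ccy + dy; cx <- ccx + dx
        } else {
          cy <- runif(1, ry + margin, size - ry - margin)
          cx <- runif(1, rx + margin, size - rx - margin)
        }
        if (cy - ry >= 1 && cy + ry <= size && cx - rx >= 1 &&
            cx + rx <= size) { placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place a lesion of radius ", round(r, 1),
             " inside a ", size, "px frame after 100 tries")
      sup <- ellipse_support(size, cy, cx, ry, rx)
      mask[sup] <- 1L
      rate[sup] <- pmax(rate[sup], cfg$lesion_rate)
      lesions <- rbind(lesions,
                       data.frame(cy = cy, cx = cx, ry = ry, rx = rx,
                                  small = small))
    }
  }

  # benign confounders: soft Gaussian hot spots near the border, never
  # overlapping the lesion mask
  n_conf <- sample_int_range(cfg$n_confounders)
  border <- max(6, round(size / 8))
  if (n_conf > 0) {
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    for (i in seq_len(n_conf)) {
      for (try in 1:100) {
        sigma <- runif(1, 1.5, 3)
        cy <- runif(1, 1, size); cx <- runif(1, 1, size)
        near_border <- min(cy, size - cy + 1, cx, size - cx + 1) <= border
        if (!near_border) next
        core <- (rows - cy)^2 + (cols - cx)^2 <= (2 * sigma)^2
        if (!any(mask[core] == 1L)) {
          d2 <- (rows - cy)^2 + (cols - cx)^2
          rate <- rate + cfg$confounder_rate * exp(-d2 / (2 * sigma^2))
          break
        }
      }
    }
  }
  list(rate = rate, mask = mask, lesions = lesions)
}

poisson_image <- function(rate) {
  px <- matrix(rpois(length(rate), lambda = rate), nrow(rate), ncol(rate))
  px[px > 65535L] <- 65535L
  px
}

#' Generate one synthetic patient (anterior + posterior pair)
#'
#' Fully deterministic given `(config$seed, patient_index)`: the effective
#' seed is `seed + patient_index`. The posterior view mirrors the anterior
#' rate map horizontally and redraws the Poisson noise independently.
#'
#' @param config a [phantom_config()].
#' @param patient_index positive integer.
#' @return a list with fields `anterior`, `posterior` ([scintigram()]s),
#'   `mask_anterior`, `mask_posterior` ([lesion_mask()]s) and `lesions`
#'   (data frame of the anterior lesion ellipse parameters).
#' @export
generate_phantom_pair <- function(config, patient_index) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed + as.integer(patient_index), {
    dr <- draw_rate_map(config)
    ant <- poisson_image(dr$rate)
    rate_post <- dr$rate[, ncol(dr$rate):1]
    post <- poisson_image(rate_post)
    list(anterior = scintigram(ant),
         posterior = scintigram(post),
         mask_anterior = lesion_mask(dr$mask),
         mask_posterior = lesion_mask(dr$mask[, ncol(dr$mask):1]),
         lesions = dr$lesions)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `2 * n_patients` image/mask pairs (16-bit TIFF images, 8-bit PNG
#' masks) and a CSV manifest; every patient has exactly one anterior and
#' one posterior record, both initially unassigned.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if needed).
#' @return the `dataset_manifest`, invisibly also written to
#'   `<out_dir>/manifest.csv`.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  rows <- vector("list", 2L * config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    pair <- generate_phantom_pair(config, i)
    for (view in c("anterior", "posterior")) {
      img_path <- file.path(out_dir, sprintf("%s_%s.tif", pid, view))
      msk_path <- file.path(out_dir, sprintf("%s_%s_mask.png", pid, view))
      write_scintigram(pair[[view]], img_path)
      write_mask(pair[[paste0("mask_", view)]], msk_path)
      rows[[2L * (i - 1L) + (view == "posterior") + 1L]] <-
        data.frame(patient_id = pid, view = view, image_path = img_path,
                   mask_path = msk_path, split = "unassigned")
    }
  }
  manifest <- dataset_manifest(do.call(rbind, rows))
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
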