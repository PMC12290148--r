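test_that("scintigram and mask constructors enforce their invariants", {
  expect_error(scintigram(matrix(0L, 4, 4)), "8x8")
  expect_error(scintigram(matrix(-1L, 8, 8)), "nonnegative")
  expect_error(scintigram(matrix(70000L, 8, 8)), "16 bits")
  expect_error(lesion_mask(matrix(2L, 8, 8)), "0 or 1")
  s <- scintigram(matrix(5L, 8, 9))
  expect_identical(c(s$height, s$width), c(8L, 9L))
  expect_equal(s$pixel_pitch_mm, 2.26)
})

test_that("16-bit TIFF round-trip preserves counts exactly", {
  set.seed(31)
  px <- matrix(as.integer(sample(0:65535, 256, replace = TRUE)), 16, 16)
  px[1, 1] <- 65535L; px[2, 2] <- 0L
  s <- scintigram(px)
  p <- withr::local_tempfile(fileext = ".tif")
  write_scintigram(s, p)
  r <- read_scintigram(p)
  expect_identical(r$pixels, px)
  # all-zero image round-trips to all zeros
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_scintigram(scintigram(matrix(0L, 16, 16)), p2)
  expect_true(all(read_scintigram(p2)$pixels == 0L))
})

test_that("masks binarize on read: any positive value becomes 1", {
  m <- matrix(0L, 10, 10); m[3:4, 3:4] <- 1L
  p <- withr::local_tempfile(fileext = ".png")
  write_mask(lesion_mask(m), p)
  r <- read_mask(p)
  expect_identical(r$pixels, m)
  # a gray-valued raster maps >0 to 1
  p2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(c(0, 1 / 255, 2 / 255, 0), 2, 2), p2)
  r2 <- read_mask(p2)
  expect_identical(r2$pixels, matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_error(read_mask(p, expected_dim = c(4, 4)), "do not match")
})

test_that("read errors name the offending property", {
  expect_error(read_scintigram("no/such/file.tif"), "not found")
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(32 * 32 * 3), c(32, 32, 3)), p)  # RGB raster
  expect_error(read_scintigram(p), "channel")
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", p2)
  expect_error(read_scintigram(p2), "unsupported raster format")
})

test_that("manifests round-trip through CSV and validate split coherence", {
  man <- dataset_manifest(data.frame(
    patient_id = rep(c("P1", "P2"), each = 2),
    view = rep(c("anterior", "posterior"), 2),
    image_path = paste0("img", 1:4, ".tif"),
    mask_path = paste0("msk", 1:4, ".png")))
  p <- withr::local_tempfile(fileext = ".csv")
  write_manifest(man, p)
  r <- read_manifest(p)
  expect_identical(as.data.frame(r), as.data.frame(man))
  bad <- as.data.frame(man)
  bad$split <- c("train", "test", "train", "train")
  expect_error(dataset_manifest(bad), "share one split")
})

test_that("patient-grouped splitting reproduces the clinical cohort counts", {
  # 171 patients at a 118-patient training fraction -> 118 / 53
  man <- dataset_manifest(data.frame(
    patient_id = rep(sprintf("P%03d", 1:171), each = 2),
    view = rep(c("anterior", "posterior"), 171),
    image_path = sprintf("i%d.tif", 1:342),
    mask_path = sprintf("m%d.png", 1:342)))
  sp <- split_by_patient(man, 118 / 171, seed = 1)
  expect_identical(length(unique(sp$patient_id[sp$split == "train"])), 118L)
  expect_identical(length(unique(sp$patient_id[sp$split == "test"])), 53L)
  # two patients at 0.5 -> one each, views kept together
  man2 <- dataset_manifest(data.frame(
    patient_id = rep(c("A", "B"), each = 2),
    view = rep(c("anterior", "posterior"), 2),
    image_path = sprintf("i%d.tif", 1:4),
    mask_path = sprintf("m%d.png", 1:4)))
  sp2 <- split_by_patient(man2, 0.5, seed = 3)
  expect_identical(sum(sp2$split == "train"), 2L)
  expect_identical(length(unique(sp2$split[sp2$patient_id == "A"])), 1L)
  # deterministic for a fixed seed
  expect_identical(split_by_patient(man, 118 / 171, seed = 9)$split,
                   split_by_patient(man, 118 / 171, seed = 9)$split)
  expect_error(split_by_patient(man, 1e-9, seed = 1), "empty split")
  expect_error(split_by_patient(sp, 0.5, seed = 1), "already contains")
})

test_that("no patient leaks and no view is separated over 100 random seeds", {
  man <- dataset_manifest(data.frame(
    patient_id = rep(sprintf("P%02d", 1:20), each = 2),
    view = rep(c("anterior", "posterior"), 20),
    image_path = sprintf("i%d.tif", 1:40),
    mask_path = sprintf("m%d.png", 1:40)))
  for (seed in 1:100) {
    sp <- split_by_patient(man, 0.7, seed = seed)
    tr <- unique(sp$patient_id[sp$split == "train"])
    te <- unique(sp$patient_id[sp$split == "test"])
    expect_length(intersect(tr, te), 0)
    expect_true(all(tapply(sp$split, sp$patient_id,
                           function(s) length(unique(s))) == 1L))
  }
})
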