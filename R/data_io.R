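# ---------------------------------------------------------------------------
# Reading and writing scintigrams (16-bit count images), lesion masks and
# dataset manifests, plus patient-grouped train/test splitting. Planar bone
# scans come in anterior/posterior pairs per patient; the two views of a
# patient must never be separated across splits.
# ---------------------------------------------------------------------------

#' Scintigram: a planar nuclear-medicine count image
#'
#' A 2-D matrix of nonnegative integer radiotracer counts (16-bit range)
#' with pixel-pitch metadata. Typical whole-body gamma-camera acquisitions
#' use a 2.26 mm pixel pitch.
#'
#' @param pixels integer matrix of counts, all in `[0, 65535]`.
#' @param pixel_pitch_mm physical pixel spacing in millimetres.
#' @return an object of class `scintigram`.
#' @export
#' @examples
#' s <- scintigram(matrix(0L, 16, 16))
#' dim(s$pixels)
scintigram <- function(pixels, pixel_pitch_mm = 2.26) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("scintigrams must be at least 8x8 pixels")
  if (any(pixels < 0)) stop("counts must be nonnegative")
  if (any(pixels > 65535)) stop("counts must be representable in 16 bits")
  if (any(pixels != round(pixels))) stop("counts must be integers")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, height = nrow(pixels),
                 width = ncol(pixels), pixel_pitch_mm = pixel_pitch_mm),
            class = "scintigram")
}

#' Binary lesion mask paired with a scintigram
#'
#' @param pixels matrix with values in `{0, 1}`.
#' @return an object of class `lesion_mask`.
#' @export
lesion_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (!all(pixels %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels), class = "lesion_mask")
}

raster_ext <- function(path) tolower(tools::file_ext(path))

read_raster_16 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- raster_ext(path)
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L)
      stop("expected a single-channel raster, got ", dim(img)[3],
           " channels: ", path)
    if (is.double(img) && any(img != round(img)))
      stop("expected an integer (not floating-point) raster: ", path)
    storage.mode(img) <- "integer"
    img
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (length(dim(img)) != 2L)
      stop("expected a single-channel raster, got ", dim(img)[3],
           " channels: ", path)
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    m <- round(img * (2^depth - 1))
    storage.mode(m) <- "integer"
    m
  } else {
    stop("unsupported raster format '", ext, "' (use TIFF or PNG): ", path)
  }
}

#' Read a scintigram from a 16-bit grayscale raster
#'
#' Counts are returned exactly as stored; no rescaling is applied.
#' TIFF and PNG are accepted.
#'
#' @param path file path.
#' @param pixel_pitch_mm pixel spacing metadata to attach.
#' @return a [scintigram()].
#' @export
read_scintigram <- function(path, pixel_pitch_mm = 2.26) {
  scintigram(read_raster_16(path), pixel_pitch_mm = pixel_pitch_mm)
}

#' Write a scintigram as 16-bit grayscale TIFF
#'
#' TIFF is the canonical on-disk format: lossless and natively 16-bit, it
#' round-trips count matrices exactly.
#'
#' @param s a [scintigram()].
#' @param path output path (`.tif`/`.tiff`).
#' @return invisibly, `path`.
#' @export
write_scintigram <- function(s, path) {
  stopifnot(inherits(s, "scintigram"))
  tiff::writeTIFF(s$pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a lesion mask from a raster
#'
#' Any pixel greater than zero becomes foreground (1).
#'
#' @param path file path (PNG or TIFF).
#' @param expected_dim optional `c(height, width)` of the paired image;
#'   a mismatch raises a pairing error.
#' @return a [lesion_mask()].
#' @export
read_mask <- function(path, expected_dim = NULL) {
  m <- read_raster_16(path)
  if (!is.null(expected_dim) && !all(dim(m) == expected_dim))
    stop("mask dimensions ", paste(dim(m), collapse = "x"),
         " do not match the paired image ",
         paste(expected_dim, collapse = "x"), ": ", path)
  lesion_mask((m > 0) * 1L)
}

#' Write a lesion mask as 8-bit PNG with values \{0, 255\}
#'
#' @param m a [lesion_mask()].
#' @param path output path (`.png`).
#' @return invisibly, `path`.
#' @export
write_mask <- function(m, path) {
  stopifnot(inherits(m, "lesion_mask"))
  png::writePNG(m$pixels * 1.0, path)
  invisible(path)
}

manifest_cols <- c("patient_id", "view", "image_path", "mask_path", "split")

#' Dataset manifest
#'
#' A data frame with columns `patient_id`, `view` (anterior/posterior),
#' `image_path`, `mask_path` and `split` (train/test/unassigned). All
#' records of a patient must share one split value.
#'
#' @param records data frame with the columns above (`split` optional,
#'   defaulting to "unassigned").
#' @return a validated `dataset_manifest` data frame.
#' @export
dataset_manifest <- function(records) {
  if (!("split" %in% names(records))) records$split <- "unassigned"
  missing <- setdiff(manifest_cols, names(records))
  if (length(missing) > 0)
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  records <- records[, manifest_cols]
  if (!all(records$view %in% c("anterior", "posterior")))
    stop("view must be 'anterior' or 'posterior'")
  if (!all(records$split %in% c("train", "test", "unassigned")))
    stop("split must be 'train', 'test' or 'unassigned'")
  splits <- tapply(records$split, records$patient_id,
                   function(s) length(unique(s)))
  if (any(splits > 1))
    stop("all records of a patient must share one split value")
  class(records) <- c("dataset_manifest", "data.frame")
  records
}

#' Read / write a manifest CSV
#'
#' @param path CSV path with header
#'   `patient_id,view,image_path,mask_path,split`.
#' @return `read_manifest` returns a `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  dataset_manifest(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_manifest
#' @param manifest a `dataset_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' Patient-grouped train/test split
#'
#' Patients (not images) are shuffled with the given seed and partitioned
#' so that `round(train_fraction * n_patients)` patients form the training
#' set; all records of a patient (anterior and posterior view) are always
#' co-assigned, so no patient can leak across splits.
#'
#' @param manifest a `dataset_manifest` with all records unassigned.
#' @param train_fraction fraction of patients assigned to training,
#'   in (0, 1).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return the manifest with `split` filled in.
#' @export
split_by_patient <- function(manifest, train_fraction, seed) {
  if (!all(manifest$split == "unassigned"))
    stop("manifest already contains split assignments")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be strictly between 0 and 1")
  patients <- unique(manifest$patient_id)
  if (length(patients) < 2L) stop("need at least 2 distinct patients")
  n_train <- round(train_fraction * length(patients))
  if (n_train == 0L || n_train == length(patients))
    stop("train_fraction ", train_fraction, " produces an empty split for ",
         length(patients), " patients")
  shuffled <- with_seed(seed, sample(patients))
  train_ids <- shuffled[seq_len(n_train)]
  manifest$split <- ifelse(manifest$patient_id %in% train_ids,
                           "train", "test")
  dataset_manifest(as.data.frame(manifest))
}
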