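# Reading and writing: multi-channel TIFF + JSON sidecar, mask TIFFs,
# truth JSON. The tiff writer stores float samples in [0, 1], so channels
# are scaled by a recorded per-file factor; channel names and the scale
# live in a JSON sidecar next to the image (the TIFF container used here
# cannot carry per-page description strings).

#' Write a multi-channel image as a multi-page TIFF
#'
#' One 32-bit float page per channel. Intensities are divided by a common
#' scale factor (the overall maximum) to fit the writer's `[0, 1]` range;
#' the scale, the channel names, and the pixel size are recorded in a JSON
#' sidecar `<path>.json` which [read_image_tiff()] uses to restore the
#' original values.
#'
#' @param image a [microscopy_image()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "microscopy_image"))
  mx <- max(1e-12, max(vapply(image$channels, max, numeric(1))))
  pages <- lapply(image$channels, function(m) m / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(channels = names(image$channels), intensity_scale = mx,
               pixel_size_nm = image$pixel_size_nm)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-channel TIFF written by [write_image_tiff()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must exist.
#' @return a [microscopy_image()].
#' @export
read_image_tiff <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    abort(sprintf("sidecar %s not found; cannot recover channel names", meta_path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$channels)) {
    abort("page count does not match sidecar channel list")
  }
  channels <- lapply(pages, function(p) p * meta$intensity_scale)
  names(channels) <- meta$channels
  microscopy_image(channels, meta$pixel_size_nm)
}

#' Write a boolean mask as an 8-bit single-channel TIFF
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  m <- matrix(as.numeric(as_logical_mask(mask)), nrow(mask), ncol(mask))
  tiff::writeTIFF(m, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a mask TIFF back as a logical matrix
#'
#' @param path TIFF path.
#' @return logical matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Write simulation ground truth as JSON
#'
#' Masks are stored as run-length-free index lists (1-based linear pixel
#' indices) with the grid dimensions, keeping the file plain text.
#'
#' @param truth a `sim_truth` from [simulate_cell()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  obj <- list(
    dim = dim(truth$cell_mask),
    pixel_size_nm = truth$pixel_size_nm,
    enrichment_rho = truth$enrichment_rho,
    nuclear_fraction_tf = truth$nuclear_fraction_tf,
    seed = truth$seed,
    cell_mask_idx = which(truth$cell_mask),
    nucleus_mask_idx = which(truth$nucleus_mask),
    organelle_mask_idx = which(truth$organelle_mask_true),
    puncta = truth$puncta_true
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read simulation ground truth from JSON
#'
#' @param path `.json` path written by [write_truth_json()].
#' @return a `sim_truth`-like list with masks restored to logical matrices.
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.integer(obj$dim)
  mk <- function(idx) {
    m <- matrix(FALSE, d[1], d[2])
    m[as.integer(idx)] <- TRUE
    m
  }
  structure(list(cell_mask = mk(obj$cell_mask_idx),
                 nucleus_mask = mk(obj$nucleus_mask_idx),
                 organelle_mask_true = mk(obj$organelle_mask_idx),
                 puncta_true = as_tibble(obj$puncta),
                 enrichment_rho = obj$enrichment_rho,
                 nuclear_fraction_tf = obj$nuclear_fraction_tf,
                 pixel_size_nm = obj$pixel_size_nm,
                 seed = obj$seed),
            class = "sim_truth")
}
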