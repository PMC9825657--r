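#' Mask-building parameters
#'
#' Controls the contrast-enhancement, smoothing, and thresholding steps used
#' by [build_organelle_mask()]. Contrast enhancement is percentile rescaling:
#' intensities at or below the low percentile (within the cell) map to 0,
#' at or above the high percentile map to 1. Smoothing is a mean filter with
#' a disc kernel. Thresholding is Otsu's method computed only from pixels
#' inside the cell mask (background outside the cell would otherwise
#' dominate the histogram), or a fixed cutoff on the rescaled image.
#'
#' @param contrast_percentiles `(low, high)` percentiles in `[0, 100]`,
#'   `low < high`.
#' @param mean_filter_radius_px disc radius of the mean filter in pixels;
#'   0 disables smoothing.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold cutoff on the rescaled `[0, 1]` image when
#'   `threshold_method = "fixed"`.
#' @return an object of class `mask_params`.
#' @export
mask_params <- function(contrast_percentiles = c(1, 99),
                        mean_filter_radius_px = 1,
                        threshold_method = c("otsu", "fixed"),
                        fixed_threshold = 0.5) {
  threshold_method <- match.arg(threshold_method)
  lo <- contrast_percentiles[1]; hi <- contrast_percentiles[2]
  if (lo < 0 || hi > 100 || lo >= hi) {
    abort("contrast_percentiles must satisfy 0 <= low < high <= 100")
  }
  if (mean_filter_radius_px < 0) abort("mean_filter_radius_px must be >= 0")
  structure(list(contrast_percentiles = as.numeric(contrast_percentiles),
                 mean_filter_radius_px = as.numeric(mean_filter_radius_px),
                 threshold_method = threshold_method,
                 fixed_threshold = as.numeric(fixed_threshold)),
            class = "mask_params")
}

#' Segment cells and nuclei from a multi-channel image
#'
#' Nuclei are thresholded (Otsu) from the nucleus channel; the cell
#' footprint is thresholded at a low cutoff from the cell channel and
#' hole-filled. Each connected cell region containing at least one nucleus
#' becomes one [cell_roi()]. When `roi_override` is supplied (a list of
#' `cell_roi` objects, e.g. read from files), it is returned unchanged and
#' no segmentation runs.
#'
#' @param image a [microscopy_image()].
#' @param nucleus_channel,cell_channel channel names; the cell channel
#'   should fill the whole cell (a cytosolic + nuclear stain).
#' @param params a [mask_params()] for the nucleus threshold.
#' @param cell_threshold_factor the cell footprint keeps pixels above this
#'   fraction of the Otsu threshold of the cell channel; below 1 it is a
#'   deliberately low cutoff that tolerates dim cytosol at the cell rim.
#' @param roi_override optional externally supplied ROIs; passed through.
#' @return list of [cell_roi()] objects (possibly empty, with a warning,
#'   when no nucleus is found).
#' @export
segment_cells <- function(image, nucleus_channel = "nucleus",
                          cell_channel = "tf", params = mask_params(),
                          cell_threshold_factor = 0.75,
                          roi_override = NULL) {
  if (!is.null(roi_override)) {
    stopifnot(all(vapply(roi_override, inherits, logical(1), "cell_roi")))
    return(roi_override)
  }
  nuc_ch <- get_channel(image, nucleus_channel)
  cell_ch <- get_channel(image, cell_channel)
  if (all(nuc_ch == 0) && all(cell_ch == 0)) {
    warn("blank image: no cells found")
    return(list())
  }
  thr_n <- otsu_threshold(as.numeric(nuc_ch))
  if (is.na(thr_n)) {
    warn("constant nucleus channel: no nucleus found")
    return(list())
  }
  nuc_mask <- nuc_ch > thr_n
  nuc_lab <- label_components_8(nuc_mask)
  if (max(nuc_lab) == 0) {
    warn("no nucleus found")
    return(list())
  }
  thr_c <- otsu_threshold(as.numeric(cell_ch)) * cell_threshold_factor
  cell_mask <- cell_ch >= thr_c
  cell_mask <- as_logical_mask(
    EBImage::imageData(EBImage::fillHull(EBImage::Image(cell_mask * 1))))
  dim(cell_mask) <- dim(cell_ch)
  cell_lab <- label_components_8(cell_mask)

  rois <- list()
  for (cid in seq_len(max(cell_lab))) {
    cm <- cell_lab == cid
    nuc_ids <- setdiff(unique(nuc_lab[cm]), 0L)
    if (length(nuc_ids) == 0) next
    nm <- (nuc_lab %in% nuc_ids)
    dim(nm) <- dim(cm)
    nm <- nm & cm
    if (!any(cm & !nm)) next   # no cytosol
    rois[[length(rois) + 1]] <-
      cell_roi(paste0("cell_", length(rois) + 1), cm, nm)
  }
  if (length(rois) == 0) warn("no cell containing a nucleus was found")
  rois
}

#' Build the organelle (inner) mask from an intensity channel
#'
#' Reproduces a contrast-enhance / mean-filter / threshold mask recipe:
#' (1) rescale so the low/high percentiles of the in-cell intensities map
#' to `[0, 1]` (clipping outside); (2) mean-filter with a disc of the given
#' radius; (3) threshold by Otsu (computed within the cell mask) or a fixed
#' cutoff; (4) intersect with the cytosol. Returns the inner mask `M` used
#' by [build_ring_mask()].
#'
#' @param organelle_channel numeric matrix, same grid as the ROI masks.
#' @param roi a [cell_roi()].
#' @param params a [mask_params()].
#' @return logical matrix; empty (all `FALSE`, with a warning) when the
#'   channel is constant inside the cell so Otsu is undefined.
#' @export
build_organelle_mask <- function(organelle_channel, roi,
                                 params = mask_params()) {
  stopifnot(inherits(roi, "cell_roi"), inherits(params, "mask_params"))
  stopifnot_same_dim(organelle_channel, roi$cell_mask,
                     "channel and ROI masks")
  inside <- organelle_channel[roi$cell_mask]
  qs <- quantile(inside, params$contrast_percentiles / 100, names = FALSE)
  if (qs[2] - qs[1] <= .Machine$double.eps * max(1, abs(qs[2]))) {
    warn("constant channel within the cell: organelle mask is empty")
    return(matrix(FALSE, nrow(organelle_channel), ncol(organelle_channel)))
  }
  scaled <- (organelle_channel - qs[1]) / (qs[2] - qs[1])
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  r <- params$mean_filter_radius_px
  if (r > 0) {
    side <- 2 * floor(r) + 1
    brush <- EBImage::makeBrush(side, shape = "disc")
    brush <- brush / sum(brush)
    scaled <- EBImage::imageData(EBImage::filter2(scaled, brush))
    dim(scaled) <- dim(organelle_channel)
  }
  thr <- if (params$threshold_method == "otsu") {
    otsu_threshold(scaled[roi$cell_mask])
  } else params$fixed_threshold
  if (is.na(thr)) {
    warn("Otsu threshold undefined (constant smoothed channel): empty mask")
    return(matrix(FALSE, nrow(organelle_channel), ncol(organelle_channel)))
  }
  mask <- scaled >= thr
  # fixed threshold at t on a binary-rendered channel must keep the
  # rendered pixels themselves (values == 1 >= t), so >= not >
  mask & roi$cytosol_mask
}

#' Build the dilated ring-mask geometry around an inner mask
#'
#' The inner mask `M` is dilated twice by `dilation_radius_nm`, with
#' dilation defined through the exact Euclidean distance transform:
#' `D1 = {d(p, M) <= r}`, `D2 = {d(p, M) <= 2r}` with `r` in pixels. The
#' first shell (`D1 \ M`) is an excluded buffer immediately surrounding the
#' organelle; the second shell (`D2 \ D1`) is the measured ring, spanning
#' `(r, 2r]` nm from the mask boundary. Both shells are clipped to the
#' cytosol. When the ring is empty after clipping (for example when the
#' inner mask fills the cytosol), the result is flagged and the cell should
#' be excluded downstream.
#'
#' @param inner_mask non-empty logical matrix (the organelle mask `M`).
#' @param roi a [cell_roi()] on the same grid.
#' @param dilation_radius_nm radius of each of the two dilations, default
#'   300 nm.
#' @param pixel_size_nm physical pixel size; the radius must be at least
#'   one pixel.
#' @return a [ring_mask_set()].
#' @examples
#' m <- matrix(FALSE, 13, 13); m[7, 7] <- TRUE
#' cellm <- matrix(TRUE, 13, 13); nucm <- matrix(FALSE, 13, 13); nucm[1, 1] <- TRUE
#' rs <- build_ring_mask(m, cell_roi("c1", cellm, nucm),
#'                       dilation_radius_nm = 300, pixel_size_nm = 100)
#' sum(rs$inner_mask | rs$buffer_mask)  # |D1| = 29
#' sum(rs$ring_mask)                    # 84
#' @export
build_ring_mask <- function(inner_mask, roi, dilation_radius_nm = 300,
                            pixel_size_nm) {
  stopifnot(inherits(roi, "cell_roi"))
  inner_mask <- as_logical_mask(inner_mask)
  stopifnot_same_dim(inner_mask, roi$cell_mask, "inner mask and ROI")
  if (!any(inner_mask)) abort("inner_mask is empty")
  r_px <- nm_to_px(dilation_radius_nm, pixel_size_nm)
  if (r_px < 1) {
    abort(sprintf(
      "dilation radius %g nm is < 1 pixel at %g nm/px; needs pixel_size_nm <= %g",
      dilation_radius_nm, pixel_size_nm, dilation_radius_nm))
  }
  eps <- 1e-7
  d <- distance_to_mask(inner_mask)
  d1 <- d <= r_px + eps
  d2 <- d <= 2 * r_px + eps
  buffer <- d1 & !inner_mask & roi$cytosol_mask
  ring <- d2 & !d1 & roi$cytosol_mask
  ring_mask_set(inner_mask, buffer, ring,
                dilation_radius_nm = dilation_radius_nm,
                pixel_size_nm = pixel_size_nm)
}
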