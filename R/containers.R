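#' Multi-channel microscopy image
#'
#' A set of named 2D intensity channels on a common pixel grid with a known
#' physical pixel size. Channels are plain numeric matrices indexed
#' `[row, col]` (0-based coordinates are never used in the API; all
#' functions take and return 1-based R indices, while physical positions
#' are in micrometres).
#'
#' @param channels named list of numeric matrices, all the same dimension.
#' @param pixel_size_nm physical size of one pixel edge, in nanometres.
#' @return an object of class `microscopy_image`.
#' @examples
#' img <- microscopy_image(list(receptor = matrix(1, 8, 8)), pixel_size_nm = 100)
#' channel_names(img)
#' @export
microscopy_image <- function(channels, pixel_size_nm) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("all channels must be matrices of identical dimensions")
  }
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    abort("`pixel_size_nm` must be a positive number")
  }
  structure(
    list(channels = lapply(channels, function(m) {
      storage.mode(m) <- "double"; m
    }),
    pixel_size_nm = as.numeric(pixel_size_nm)),
    class = "microscopy_image"
  )
}

#' @rdname microscopy_image
#' @param x a `microscopy_image`.
#' @export
channel_names <- function(x) names(x$channels)

#' Extract one channel as a numeric matrix
#'
#' @param x a `microscopy_image`.
#' @param name channel name.
#' @return numeric matrix.
#' @export
get_channel <- function(x, name) {
  if (!name %in% names(x$channels)) {
    abort(sprintf("channel '%s' not found (have: %s)", name,
                  paste(names(x$channels), collapse = ", ")))
  }
  x$channels[[name]]
}

#' @export
print.microscopy_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<microscopy_image> %d x %d px (%.0f nm/px), channels: %s\n",
              d[1], d[2], x$pixel_size_nm,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Per-cell region of interest
#'
#' Boolean masks for one cell: the whole cell, its nucleus, and the cytosol
#' (cell minus nucleus). The cytosol is derived, never supplied, so the
#' invariant `cytosol == cell & !nucleus` always holds.
#'
#' @param cell_id identifier for the cell.
#' @param cell_mask,nucleus_mask logical matrices of identical dimension;
#'   `nucleus_mask` must be contained in `cell_mask`.
#' @return an object of class `cell_roi`.
#' @export
cell_roi <- function(cell_id, cell_mask, nucleus_mask) {
  cell_mask <- as_logical_mask(cell_mask)
  nucleus_mask <- as_logical_mask(nucleus_mask)
  stopifnot_same_dim(cell_mask, nucleus_mask, "cell and nucleus masks")
  if (any(nucleus_mask & !cell_mask)) {
    abort("nucleus_mask must be contained in cell_mask")
  }
  cytosol <- cell_mask & !nucleus_mask
  if (!any(cytosol)) abort("cytosol (cell minus nucleus) is empty")
  structure(list(cell_id = cell_id, cell_mask = cell_mask,
                 nucleus_mask = nucleus_mask, cytosol_mask = cytosol),
            class = "cell_roi")
}

#' @export
print.cell_roi <- function(x, ...) {
  cat(sprintf("<cell_roi '%s'> cell %d px, nucleus %d px, cytosol %d px\n",
              as.character(x$cell_id), sum(x$cell_mask), sum(x$nucleus_mask),
              sum(x$cytosol_mask)))
  invisible(x)
}

#' Ring mask set around an organelle mask
#'
#' Holds the inner organelle mask `M`, the excluded buffer (first dilation
#' shell, `D1 \ M`) and the measured ring (second shell, `D2 \ D1`), as
#' produced by [build_ring_mask()]. The three masks are pairwise disjoint.
#'
#' @param inner_mask,buffer_mask,ring_mask logical matrices.
#' @param dilation_radius_nm,pixel_size_nm geometry parameters.
#' @param flagged `TRUE` when the ring is empty after clipping; such cells
#'   are excluded from downstream statistics.
#' @return an object of class `ring_mask_set`.
#' @export
ring_mask_set <- function(inner_mask, buffer_mask, ring_mask,
                          dilation_radius_nm, pixel_size_nm,
                          flagged = !any(ring_mask)) {
  inner_mask <- as_logical_mask(inner_mask)
  buffer_mask <- as_logical_mask(buffer_mask)
  ring_mask <- as_logical_mask(ring_mask)
  stopifnot_same_dim(inner_mask, buffer_mask, "ring masks")
  stopifnot_same_dim(inner_mask, ring_mask, "ring masks")
  if (any(inner_mask & buffer_mask) || any(inner_mask & ring_mask) ||
      any(buffer_mask & ring_mask)) {
    abort("inner, buffer and ring masks must be pairwise disjoint")
  }
  structure(list(inner_mask = inner_mask, buffer_mask = buffer_mask,
                 ring_mask = ring_mask,
                 dilation_radius_nm = as.numeric(dilation_radius_nm),
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 flagged = isTRUE(flagged)),
            class = "ring_mask_set")
}

#' @export
print.ring_mask_set <- function(x, ...) {
  cat(sprintf(
    "<ring_mask_set> inner %d px, buffer %d px, ring %d px (r = %.0f nm, %.0f nm/px)%s\n",
    sum(x$inner_mask), sum(x$buffer_mask), sum(x$ring_mask),
    x$dilation_radius_nm, x$pixel_size_nm,
    if (x$flagged) " [flagged: empty ring]" else ""))
  invisible(x)
}
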