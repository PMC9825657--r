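#' Extract a line profile across an image
#'
#' Samples one or more channels along the segment from `from` to `to`
#' (1-based, possibly fractional `(row, col)` coordinates) at `n_samples`
#' evenly spaced points using bilinear interpolation, the standard
#' behaviour for plot profiles over non-integer lines. With `width_px > 1`
#' each sample is the mean over `width_px` parallel offsets perpendicular
#' to the line, emulating a wide profile arrow.
#'
#' @param image a [microscopy_image()].
#' @param channels channel names to sample.
#' @param from,to numeric `(row, col)` endpoints, inside the image.
#' @param n_samples number of samples (>= 2), default 100.
#' @param width_px odd-ish averaging width in pixels, default 1.
#' @return an object of class `line_profile`: a list with `samples` (a
#'   long tibble `distance_um`, `channel`, `intensity`), `from`, `to`,
#'   `n_samples`, `sample_spacing_um`.
#' @export
line_profile <- function(image, channels, from, to, n_samples = 100,
                         width_px = 1) {
  stopifnot(inherits(image, "microscopy_image"))
  if (n_samples < 2) abort("n_samples must be >= 2")
  d <- dim(image$channels[[1]])
  inside <- function(p) all(p >= 1) && p[1] <= d[1] && p[2] <= d[2]
  if (!inside(from) || !inside(to)) abort("profile endpoints must lie inside the image")
  t <- seq(0, 1, length.out = n_samples)
  r <- from[1] + t * (to[1] - from[1])
  c <- from[2] + t * (to[2] - from[2])
  seg_len <- sqrt(sum((to - from)^2))
  # unit normal for perpendicular averaging
  nvec <- if (seg_len > 0) c(-(to[2] - from[2]), to[1] - from[1]) / seg_len else c(0, 0)
  offsets <- if (width_px > 1) seq(-(width_px - 1) / 2, (width_px - 1) / 2) else 0
  px_um <- image$pixel_size_nm / 1000
  samples <- purrr::map_dfr(channels, function(ch) {
    m <- get_channel(image, ch)
    vals <- rowMeans(vapply(offsets, function(o) {
      rr <- pmin(pmax(r + o * nvec[1], 1), d[1])
      cc <- pmin(pmax(c + o * nvec[2], 1), d[2])
      bilinear_interp(m, rr, cc)
    }, numeric(n_samples)))
    tibble(distance_um = t * seg_len * px_um, channel = ch, intensity = vals)
  })
  structure(list(samples = samples, from = from, to = to,
                 n_samples = as.integer(n_samples),
                 sample_spacing_um = seg_len * px_um / (n_samples - 1)),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples, %.3f um spacing, channels: %s\n",
              x$n_samples, x$sample_spacing_um,
              paste(unique(x$samples$channel), collapse = ", ")))
  invisible(x)
}

#' Plot a line profile
#'
#' @param object a `line_profile`.
#' @param ... unused.
#' @return a ggplot of intensity against distance, one line per channel.
#' @export
autoplot.line_profile <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$distance_um, y = .data$intensity,
                               colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (µm)", y = "intensity (AU)") +
    ggplot2::theme_classic()
}

#' Coefficient of variation of a sampled profile
#'
#' Quantifies how uniform a channel is along a profile: 0 for a perfectly
#' flat profile, larger for punctate distributions. Uses the population
#' (divide-by-n) standard deviation, since the profile is a full sampling
#' of the chosen segment. Invariant under intensity rescaling.
#'
#' @param profile a [line_profile()].
#' @param channel channel name to score.
#' @return CV (SD / mean), dimensionless.
#' @export
uniformity_cv <- function(profile, channel) {
  stopifnot(inherits(profile, "line_profile"))
  v <- profile$samples$intensity[profile$samples$channel == channel]
  if (length(v) < 2) abort(sprintf("channel '%s' not sampled in this profile", channel))
  m <- mean(v)
  if (m <= 0) abort("profile mean must be > 0 for a CV")
  sqrt(mean((v - m)^2)) / m
}

#' Nuclear-translocation index for a transcription factor
#'
#' The mean signal over the nucleus divided by the mean over the cytosol.
#' An index well below 1 indicates nuclear exclusion (inactive signaling);
#' an increase upon stimulation indicates translocation into the nucleus
#' (signaling completed).
#'
#' @param tf_channel numeric matrix of the transcription-factor channel.
#' @param roi a [cell_roi()].
#' @param condition condition label.
#' @return one-row tibble: `cell_id`, `condition`, `mean_nuclear`,
#'   `mean_cytosolic`, `index`, `valid` (FALSE when the cytosolic mean is
#'   zero).
#' @export
nuclear_translocation_index <- function(tf_channel, roi,
                                        condition = "unknown") {
  stopifnot(inherits(roi, "cell_roi"))
  stopifnot_same_dim(tf_channel, roi$cell_mask, "channel and ROI")
  if (!any(roi$nucleus_mask) || !any(roi$cytosol_mask)) {
    abort("nucleus and cytosol masks must be non-empty")
  }
  mn <- mean(tf_channel[roi$nucleus_mask])
  mc <- mean(tf_channel[roi$cytosol_mask])
  valid <- is.finite(mc) && mc > 0
  tibble(cell_id = as.character(roi$cell_id),
         condition = as.character(condition),
         mean_nuclear = mn, mean_cytosolic = mc,
         index = if (valid) mn / mc else NA_real_,
         valid = valid)
}
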