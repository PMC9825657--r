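#' Detect bright receptor bodies (puncta) in one cell
#'
#' A punctum is a connected bright region at least `min_diameter_um` in
#' equivalent circular diameter and at least `fold_threshold` times
#' brighter than the mean signal over the whole cytosol. The cytosolic
#' mean is computed in a single pass with puncta pixels included ("the mean
#' signal throughout the cytosol"); `refine_background = TRUE` applies one
#' refinement iteration that recomputes the mean after excluding the
#' detected pixels and re-detects. Components are 8-connected, so
#' diagonally touching blobs merge, matching common particle-analysis
#' behaviour. "Diameter" is the equivalent circular diameter
#' `2 * sqrt(area / pi) * pixel_size`, since no shape is assumed.
#'
#' Because the threshold is relative to the cytosolic mean, detection is
#' invariant under any positive rescaling of the intensities.
#'
#' @param signal_channel numeric matrix.
#' @param roi a [cell_roi()]; detection is restricted to its cytosol.
#' @param pixel_size_nm physical pixel size (required).
#' @param min_diameter_um minimum equivalent diameter, default 1 um.
#' @param fold_threshold minimum brightness over the cytosolic mean,
#'   default 10.
#' @param refine_background recompute the cytosolic mean once with
#'   detected pixels excluded? Off by default.
#' @return tibble of puncta (`cell_id`, `label`, `centroid_row`,
#'   `centroid_col`, `area_px`, `equivalent_diameter_um`,
#'   `mean_intensity`, `fold_over_cytosol`, `pixels` list-column of linear
#'   pixel indices), with attributes `image_dim`, `pixel_size_nm` and
#'   `mu_cytosol`.
#' @export
detect_puncta <- function(signal_channel, roi, pixel_size_nm,
                          min_diameter_um = 1.0, fold_threshold = 10,
                          refine_background = FALSE) {
  stopifnot(inherits(roi, "cell_roi"))
  stopifnot_same_dim(signal_channel, roi$cell_mask, "signal and ROI")
  if (missing(pixel_size_nm) || is.null(pixel_size_nm) ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    abort("pixel_size_nm is required and must be > 0")
  }
  cyt <- roi$cytosol_mask
  if (!any(cyt)) abort("cytosol mask is empty")
  mu_cyt <- mean(signal_channel[cyt])
  if (mu_cyt <= 0) abort("mean cytosolic signal is zero: nothing to detect")

  run_pass <- function(mu) {
    candidate <- (signal_channel >= fold_threshold * mu) & cyt
    lab <- label_components_8(candidate)
    list(candidate = candidate, lab = lab)
  }
  pass <- run_pass(mu_cyt)
  if (refine_background && any(pass$candidate)) {
    keep <- cyt & !pass$candidate
    if (any(keep)) {
      mu_cyt <- mean(signal_channel[keep])
      pass <- run_pass(mu_cyt)
    }
  }

  lab <- pass$lab
  n_comp <- max(lab)
  empty <- tibble(cell_id = character(), label = integer(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  area_px = integer(), equivalent_diameter_um = numeric(),
                  mean_intensity = numeric(), fold_over_cytosol = numeric(),
                  pixels = list())
  res <- if (n_comp == 0) empty else {
    nr <- nrow(signal_channel)
    purrr::map_dfr(seq_len(n_comp), function(k) {
      px <- which(lab == k)
      area <- length(px)
      eq_d <- 2 * sqrt(area / pi) * pixel_size_nm / 1000
      rows <- ((px - 1L) %% nr) + 1L
      cols <- ((px - 1L) %/% nr) + 1L
      mi <- mean(signal_channel[px])
      tibble(cell_id = as.character(roi$cell_id), label = k,
             centroid_row = mean(rows), centroid_col = mean(cols),
             area_px = area, equivalent_diameter_um = eq_d,
             mean_intensity = mi, fold_over_cytosol = mi / mu_cyt,
             pixels = list(px))
    }) %>%
      filter(.data$equivalent_diameter_um >= min_diameter_um - 1e-9) %>%
      mutate(label = seq_len(n()))
  }
  attr(res, "image_dim") <- dim(signal_channel)
  attr(res, "pixel_size_nm") <- pixel_size_nm
  attr(res, "mu_cytosol") <- mu_cyt
  res
}

#' Fraction of puncta colocalized with a second channel's puncta
#'
#' A punctum from list A counts as colocalized when its centroid falls
#' inside any component of list B, or when its pixel overlap with a single
#' B component covers at least half of its own area. Both tibbles must
#' come from the same image grid. When A is empty the fraction is 0 by
#' convention and the result is flagged.
#'
#' @param puncta_a,puncta_b tibbles from [detect_puncta()] on two channels
#'   of the same cell.
#' @return one-row tibble: `n_a`, `n_b`, `n_colocalized`, `fraction`,
#'   `flagged`.
#' @export
puncta_colocalization <- function(puncta_a, puncta_b) {
  dim_a <- attr(puncta_a, "image_dim")
  dim_b <- attr(puncta_b, "image_dim")
  if (is.null(dim_a) || is.null(dim_b) || !identical(dim_a, dim_b)) {
    abort("puncta lists come from different image grids")
  }
  n_a <- nrow(puncta_a)
  if (n_a == 0) {
    return(tibble(n_a = 0L, n_b = nrow(puncta_b), n_colocalized = 0L,
                  fraction = 0, flagged = TRUE))
  }
  nr <- dim_a[1]
  b_pixels <- unlist(puncta_b$pixels)
  b_set <- unique(b_pixels)
  coloc <- vapply(seq_len(n_a), function(i) {
    ctr_idx <- (round(puncta_a$centroid_col[i]) - 1L) * nr +
      round(puncta_a$centroid_row[i])
    if (ctr_idx %in% b_set) return(TRUE)
    a_px <- puncta_a$pixels[[i]]
    if (nrow(puncta_b) == 0) return(FALSE)
    any(vapply(puncta_b$pixels, function(bp) {
      length(intersect(a_px, bp)) >= 0.5 * length(a_px)
    }, logical(1)))
  }, logical(1))
  tibble(n_a = n_a, n_b = nrow(puncta_b),
         n_colocalized = sum(coloc),
         fraction = sum(coloc) / n_a, flagged = FALSE)
}

#' Summarize per-cell puncta counts by condition
#'
#' Mean, SD and n of per-cell body counts per condition, with a two-sample
#' t-test p-value for one named pair of conditions (the usual "mean number
#' of bodies per cell at time A vs time B" comparison). Empty conditions
#' are excluded with a warning.
#'
#' @param counts data frame with columns `cell_id`, `condition`,
#'   `n_puncta` (one row per cell).
#' @param comparison length-2 character vector naming the pair to test;
#'   `NULL` skips the test.
#' @return an object of class `puncta_summary` with fields `summary`
#'   (condition, n_cells, mean_bodies_per_cell, sd), `comparison`,
#'   `p_value`.
#' @export
summarize_puncta <- function(counts, comparison = NULL) {
  counts <- as_tibble(counts)
  if (!all(c("condition", "n_puncta") %in% names(counts))) {
    abort("counts need `condition` and `n_puncta` columns")
  }
  if (any(counts$n_puncta < 0)) abort("puncta counts must be >= 0")
  smry <- counts %>%
    group_by(.data$condition) %>%
    summarise(n_cells = n(), mean_bodies_per_cell = mean(.data$n_puncta),
              sd = sd(.data$n_puncta)) %>%
    ungroup()
  p_value <- NA_real_
  if (!is.null(comparison)) {
    if (length(comparison) != 2) abort("comparison must name two conditions")
    miss <- setdiff(comparison, smry$condition)
    if (length(miss) > 0) {
      warn(paste("comparison condition(s) absent:", paste(miss, collapse = ", ")))
    } else {
      a <- counts$n_puncta[counts$condition == comparison[1]]
      b <- counts$n_puncta[counts$condition == comparison[2]]
      if (length(a) >= 2 && length(b) >= 2) {
        p_value <- if (sd(a) == 0 && sd(b) == 0) {
          # t statistic degenerate: identical constants carry no evidence
          if (mean(a) == mean(b)) 1 else 0
        } else t.test(a, b, var.equal = TRUE)$p.value
      } else {
        warn("need >= 2 cells per condition for the t-test")
      }
    }
  }
  structure(list(summary = smry, comparison = comparison, p_value = p_value),
            class = "puncta_summary")
}

#' @export
print.puncta_summary <- function(x, ...) {
  cat("<puncta_summary>\n")
  print(x$summary)
  if (!is.null(x$comparison)) {
    cat(sprintf("t-test %s vs %s: p = %.4g\n", x$comparison[1],
                x$comparison[2], x$p_value))
  }
  invisible(x)
}

#' @rdname summarize_puncta
#' @param x a `puncta_summary`.
#' @param ... unused.
#' @export
tidy.puncta_summary <- function(x, ...) x$summary

#' @rdname summarize_puncta
#' @export
glance.puncta_summary <- function(x, ...) {
  tibble(p_value = x$p_value,
         comparison = if (is.null(x$comparison)) NA_character_ else
           paste(x$comparison, collapse = " vs "),
         n_conditions = nrow(x$summary))
}
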