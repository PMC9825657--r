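#' Per-cell inner/ring colocalization ratio
#'
#' The core localization statistic: the arithmetic mean of the signal over
#' the inner organelle mask divided by its mean over the cytosolic ring a
#' fixed physical distance away (the "Mito / Outer mito" ratio). A ratio of
#' 1 means the signal is as concentrated on the organelle as in nearby
#' cytosol; values above 1 indicate enrichment. Cells whose ring is empty
#' or has zero mean are returned flagged invalid and are excluded (with a
#' logged count) by [compare_groups()].
#'
#' @param signal_channel numeric matrix of the signal to quantify
#'   (receptor channel).
#' @param rings a [ring_mask_set()] from [build_ring_mask()].
#' @param roi the matching [cell_roi()]; supplies the cell id.
#' @param condition label for the experimental condition (e.g. `"mock"`,
#'   `"SLR14"`, `"SeV"`).
#' @return one-row tibble: `cell_id`, `condition`, `mean_inner`,
#'   `mean_ring`, `ratio`, `valid`.
#' @examples
#' sig <- matrix(5, 13, 13)
#' m <- matrix(FALSE, 13, 13); m[7, 7] <- TRUE
#' cellm <- matrix(TRUE, 13, 13); nucm <- matrix(FALSE, 13, 13); nucm[1, 1] <- TRUE
#' roi <- cell_roi("c1", cellm, nucm)
#' rs <- build_ring_mask(m, roi, 300, 100)
#' coloc_ratio(sig, rs, roi, "mock")$ratio  # 1: uniform signal
#' @export
coloc_ratio <- function(signal_channel, rings, roi, condition = "unknown") {
  stopifnot(inherits(rings, "ring_mask_set"), inherits(roi, "cell_roi"))
  stopifnot_same_dim(signal_channel, rings$inner_mask, "signal and masks")
  mean_inner <- if (any(rings$inner_mask)) {
    mean(signal_channel[rings$inner_mask])
  } else NA_real_
  mean_ring <- if (any(rings$ring_mask)) {
    mean(signal_channel[rings$ring_mask])
  } else NA_real_
  valid <- !rings$flagged && is.finite(mean_inner) && is.finite(mean_ring) &&
    mean_ring > 0
  tibble(cell_id = as.character(roi$cell_id),
         condition = as.character(condition),
         mean_inner = mean_inner, mean_ring = mean_ring,
         ratio = if (valid) mean_inner / mean_ring else NA_real_,
         valid = valid)
}

#' Compare colocalization ratios across conditions
#'
#' One-way ANOVA omnibus test of the per-cell ratio across conditions,
#' plus unadjusted equal-variance two-sample t-tests of every non-reference
#' condition against the reference (per-comparison p-values, as reported
#' alongside such figures; an optional Dunnett correction against the
#' reference is available via `dunnett = TRUE`). Invalid records are
#' dropped with a logged count; conditions with fewer than two valid
#' records are excluded with a warning.
#'
#' @param records tibble of per-cell records as returned by
#'   [coloc_ratio()] (columns `condition`, `ratio`, optionally `valid`),
#'   or any data frame with a numeric `ratio` and a `condition` column.
#' @param reference reference condition label (default `"mock"`).
#' @param dunnett apply Dunnett's many-to-one adjustment to the pairwise
#'   p-values instead of unadjusted t-tests?
#' @return an object of class `group_comparison` with fields `summary`
#'   (per-condition n, mean, sd), `omnibus_F`, `omnibus_p`, `pairwise`
#'   (condition, estimate difference, p), `reference`, `n_excluded`.
#' @seealso [tidy.group_comparison()], [glance.group_comparison()],
#'   [autoplot.group_comparison()]
#' @export
compare_groups <- function(records, reference = "mock", dunnett = FALSE) {
  records <- as_tibble(records)
  if (!all(c("condition", "ratio") %in% names(records))) {
    abort("records need `condition` and `ratio` columns")
  }
  if (!"valid" %in% names(records)) records$valid <- is.finite(records$ratio)
  n_excluded <- sum(!records$valid | !is.finite(records$ratio))
  if (n_excluded > 0) {
    rlang::inform(sprintf("excluding %d invalid cell(s) from group statistics",
                          n_excluded))
  }
  rec <- filter(records, .data$valid, is.finite(.data$ratio))
  counts <- rec %>% group_by(.data$condition) %>% summarise(n = n())
  small <- counts$condition[counts$n < 2]
  if (length(small) > 0) {
    warn(paste("dropping condition(s) with < 2 valid cells:",
               paste(small, collapse = ", ")))
    rec <- filter(rec, !.data$condition %in% small)
  }
  conds <- unique(rec$condition)
  if (length(conds) < 2) abort("need at least 2 conditions with >= 2 valid cells")
  if (!reference %in% conds) {
    abort(sprintf("reference condition '%s' not present", reference))
  }
  rec$condition <- factor(rec$condition,
                          levels = c(reference, setdiff(conds, reference)))
  fit <- aov(ratio ~ condition, data = rec)
  an <- summary(fit)[[1]]
  omnibus_F <- an[["F value"]][1]
  omnibus_p <- an[["Pr(>F)"]][1]
  summary_tbl <- rec %>%
    group_by(condition = as.character(.data$condition)) %>%
    summarise(n = n(), mean_ratio = mean(.data$ratio),
              sd_ratio = sd(.data$ratio)) %>%
    ungroup()
  ref_vals <- rec$ratio[rec$condition == reference]
  others <- setdiff(levels(rec$condition), reference)
  pairwise <- purrr::map_dfr(others, function(cond) {
    v <- rec$ratio[rec$condition == cond]
    tt <- t.test(v, ref_vals, var.equal = TRUE)
    tibble(condition = cond, estimate = mean(v) - mean(ref_vals),
           statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  if (dunnett) {
    if (!requireNamespace("multcomp", quietly = TRUE)) {
      abort("dunnett = TRUE requires the multcomp package")
    }
    gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(
      condition = "Dunnett")))
    pairwise$p_value <- as.numeric(gl$test$pvalues)
  }
  structure(list(summary = summary_tbl, omnibus_F = omnibus_F,
                 omnibus_p = omnibus_p, pairwise = pairwise,
                 reference = reference, n_excluded = n_excluded,
                 data = rec),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> one-way ANOVA F = %.4g, p = %.4g (ref: %s)\n",
              x$omnibus_F, x$omnibus_p, x$reference))
  print(x$summary)
  cat("pairwise vs reference:\n")
  print(x$pairwise)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return tibble of pairwise contrasts against the reference condition.
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' One-row summary of a group comparison
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return one-row tibble with the omnibus ANOVA statistics.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(statistic = x$omnibus_F, p_value = x$omnibus_p,
         n_conditions = nrow(x$summary), n_cells = sum(x$summary$n),
         n_excluded = x$n_excluded, reference = x$reference)
}

#' Plot per-cell ratios by condition
#'
#' Jittered per-cell ratios with a bar at each condition mean, the usual
#' presentation for per-cell colocalization ratios.
#'
#' @param object a `group_comparison`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$condition, y = .data$ratio)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red", linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "inner / ring mean signal ratio") +
    ggplot2::theme_classic()
}
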