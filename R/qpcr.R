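#' Delta-delta-Ct fold induction
#'
#' Relative quantification: per condition, `delta_Ct = mean Ct(target) -
#' mean Ct(reference gene)`; `delta_delta_Ct = delta_Ct(condition) -
#' delta_Ct(reference condition)`; `fold = 2^(-delta_delta_Ct)`.
#' Per-condition mean Ct is used for the headline fold; per-replicate
#' folds (each replicate's target Ct against the condition-mean reference
#' Ct) are also emitted so an SD can be shown as error bars. The fold is
#' invariant to adding any constant to all Ct values (machine offset).
#' Non-detect target wells are excluded with a warning; a missing
#' reference gene or condition is an error.
#'
#' @param ct_table long-format data frame with columns `condition`,
#'   `gene`, `replicate`, `ct` and optionally `detected` (as produced by
#'   [simulate_qpcr_plate()] or read from CSV).
#' @param target_gene gene whose induction is quantified.
#' @param reference_gene housekeeping gene, default `"ACTB"`.
#' @param reference_condition baseline condition, default `"Mock"`.
#' @return an object of class `ddct_result`: tibble-like `by_condition`
#'   (condition, delta_ct, delta_delta_ct, fold) plus `replicates`
#'   (condition, replicate, fold) and the settings used.
#' @examples
#' ct <- tibble::tibble(
#'   condition = rep(c("Mock", "SLR14"), each = 2),
#'   gene = rep(c("IFNB", "ACTB"), 2),
#'   replicate = 1, ct = c(28, 18, 21, 18))
#' delta_delta_ct(ct, "IFNB")$by_condition  # fold = 2^7 = 128
#' @export
delta_delta_ct <- function(ct_table, target_gene, reference_gene = "ACTB",
                           reference_condition = "Mock") {
  tbl <- as_tibble(ct_table)
  need <- c("condition", "gene", "replicate", "ct")
  if (!all(need %in% names(tbl))) {
    abort(paste("ct_table needs columns:", paste(need, collapse = ", ")))
  }
  if (!"detected" %in% names(tbl)) tbl$detected <- !is.na(tbl$ct)
  if (!reference_gene %in% tbl$gene) {
    abort(sprintf("reference gene '%s' absent from the table", reference_gene))
  }
  if (!target_gene %in% tbl$gene) {
    abort(sprintf("target gene '%s' absent from the table", target_gene))
  }
  if (!reference_condition %in% tbl$condition) {
    abort(sprintf("reference condition '%s' absent", reference_condition))
  }
  nd <- sum(tbl$gene == target_gene & !tbl$detected)
  if (nd > 0) {
    warn(sprintf("excluding %d non-detect target well(s)", nd))
  }
  tbl <- filter(tbl, .data$detected, is.finite(.data$ct))
  conds <- unique(tbl$condition)
  mean_ct <- function(cond, gene) {
    v <- tbl$ct[tbl$condition == cond & tbl$gene == gene]
    if (length(v) == 0) {
      abort(sprintf("no detected '%s' wells for condition '%s'", gene, cond))
    }
    mean(v)
  }
  dct <- vapply(conds, function(cn) {
    mean_ct(cn, target_gene) - mean_ct(cn, reference_gene)
  }, numeric(1))
  ddct <- dct - dct[match(reference_condition, conds)]
  by_condition <- tibble(condition = conds, delta_ct = unname(dct),
                         delta_delta_ct = unname(ddct),
                         fold = 2^(-unname(ddct)))
  dct_ref_cond <- dct[match(reference_condition, conds)]
  replicates <- tbl %>%
    filter(.data$gene == target_gene) %>%
    group_by(.data$condition, .data$replicate) %>%
    summarise(ct_target = mean(.data$ct), .groups = "drop") %>%
    mutate(
      delta_ct = .data$ct_target - vapply(.data$condition, mean_ct,
                                          numeric(1), gene = reference_gene),
      fold = 2^(-(.data$delta_ct - dct_ref_cond))) %>%
    select("condition", "replicate", "fold")
  structure(list(by_condition = by_condition, replicates = replicates,
                 target_gene = target_gene, reference_gene = reference_gene,
                 reference_condition = reference_condition),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result> %s normalized to %s, relative to %s\n",
              x$target_gene, x$reference_gene, x$reference_condition))
  print(x$by_condition)
  invisible(x)
}

#' @rdname delta_delta_ct
#' @param x a `ddct_result`.
#' @param ... unused.
#' @return `tidy()`: per-replicate folds; `glance()`: condition-level folds
#'   with replicate SD.
#' @export
tidy.ddct_result <- function(x, ...) x$replicates

#' @rdname delta_delta_ct
#' @export
glance.ddct_result <- function(x, ...) {
  sds <- x$replicates %>%
    group_by(.data$condition) %>%
    summarise(fold_sd = sd(.data$fold), n_replicates = n())
  left_join(x$by_condition, sds, by = "condition")
}

#' Fit a log-linear qPCR standard curve
#'
#' Least-squares fit of `Ct ~ log10(copies)` over a dilution series of
#' standards with known copy number (e.g. an in vitro transcribed
#' fragment). Amplification efficiency is `10^(-1/slope) - 1` (1.0 means
#' perfect doubling per cycle, slope -3.3219). The limit of detection is
#' the smallest standard level at which every replicate was detected.
#'
#' @param standards data frame with columns `copies` (> 0) and `ct`, one
#'   row per standard well; an optional `detected` column marks
#'   non-detects (default: `!is.na(ct)`).
#' @return an object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `lod_copies`, `n_levels` and the data.
#' @examples
#' s <- tibble::tibble(copies = 10^(4:8),
#'                     ct = 43.2877 - 3.3219 * log10(10^(4:8)))
#' fit_standard_curve(s)
#' @export
fit_standard_curve <- function(standards) {
  s <- as_tibble(standards)
  if (!all(c("copies", "ct") %in% names(s))) {
    abort("standards need `copies` and `ct` columns")
  }
  if (!"detected" %in% names(s)) s$detected <- !is.na(s$ct)
  if (any(s$copies <= 0)) abort("standard copies must all be > 0")
  det <- filter(s, .data$detected, is.finite(.data$ct))
  n_levels <- length(unique(det$copies))
  if (n_levels < 3) abort("need >= 3 distinct detected standard levels")
  fit <- lm(ct ~ log10(copies), data = det)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope >= 0) {
    abort("fitted slope is non-negative: assay failure (Ct must fall with copies)")
  }
  # direct R^2: summary.lm() warns on the (legitimate) exact fit
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((det$ct - mean(det$ct))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  all_det <- s %>%
    group_by(.data$copies) %>%
    summarise(all_detected = all(.data$detected)) %>%
    filter(.data$all_detected)
  lod <- if (nrow(all_det) > 0) min(all_det$copies) else NA_real_
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1, lod_copies = lod,
                 n_levels = n_levels, data = s),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Ct = %.4f %+.4f log10(copies); eff = %.3f, R^2 = %.4f, LOD = %g copies\n",
    x$intercept, x$slope, x$efficiency, x$r_squared, x$lod_copies))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x a `standard_curve`.
#' @param ... unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         efficiency = x$efficiency, r_squared = x$r_squared,
         lod_copies = x$lod_copies, n_levels = x$n_levels)
}

#' Plot a standard curve with its fit
#'
#' @param object a `standard_curve`.
#' @param ... unused.
#' @return a ggplot of Ct against log10 copies with the fitted line.
#' @export
autoplot.standard_curve <- function(object, ...) {
  d <- filter(object$data, .data$detected)
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$copies), y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = "log10 copies", y = "Ct") +
    ggplot2::theme_classic()
}

#' Absolute copies per cell from Ct values and a standard curve
#'
#' Inverts the standard curve — `copies = 10^((Ct - intercept) / slope)` —
#' then scales the copies measured in the RT input to per-cell units:
#' `copies_per_cell = copies / extract_fraction_used / cells_per_sample`.
#' Wells are summarised per sample by the mean Ct over detected
#' replicates. Samples whose copies fall below the curve's limit of
#' detection, or that are entirely non-detect, are flagged `below_lod`
#' (non-detects get no copy estimate; they are never imputed a Ct).
#'
#' @param ct_table data frame with columns `sample_id`, `ct` and
#'   optionally `detected`, `condition`, `replicate`.
#' @param curve a [fit_standard_curve()] result.
#' @param extract_fraction_used fraction of the RNA extract that entered
#'   the RT reaction, in `(0, 1]`.
#' @param cells_per_sample number of cells the extract came from (> 0).
#' @return tibble: `sample_id`, `mean_ct`, `copies_in_rt_input`,
#'   `copies_per_cell`, `below_lod`, plus the per-cell LOD implied by the
#'   curve (`lod_copies_per_cell` attribute).
#' @examples
#' s <- tibble::tibble(copies = 10^(4:8),
#'                     ct = 43.2877 - 3.3219 * log10(10^(4:8)))
#' curve <- fit_standard_curve(s)
#' wells <- tibble::tibble(sample_id = "a", ct = 30, detected = TRUE)
#' copies_per_cell(wells, curve, extract_fraction_used = 0.1,
#'                 cells_per_sample = 2e4)  # 5 copies/cell
#' @export
copies_per_cell <- function(ct_table, curve, extract_fraction_used,
                            cells_per_sample) {
  stopifnot(inherits(curve, "standard_curve"))
  if (extract_fraction_used <= 0 || extract_fraction_used > 1) {
    abort("extract_fraction_used must lie in (0, 1]")
  }
  if (cells_per_sample <= 0) abort("cells_per_sample must be > 0")
  tbl <- as_tibble(ct_table)
  if (!all(c("sample_id", "ct") %in% names(tbl))) {
    abort("ct_table needs `sample_id` and `ct` columns")
  }
  if (!"detected" %in% names(tbl)) tbl$detected <- !is.na(tbl$ct)
  res <- tbl %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_detected = sum(.data$detected & is.finite(.data$ct)),
      mean_ct = if (n_detected > 0)
        mean(.data$ct[.data$detected & is.finite(.data$ct)]) else NA_real_,
      .groups = "drop") %>%
    mutate(
      copies_in_rt_input = ifelse(
        .data$n_detected > 0,
        10^((.data$mean_ct - curve$intercept) / curve$slope), NA_real_),
      copies_per_cell = .data$copies_in_rt_input / extract_fraction_used /
        cells_per_sample,
      below_lod = .data$n_detected == 0 |
        (!is.na(curve$lod_copies) &
           .data$copies_in_rt_input < curve$lod_copies)) %>%
    select("sample_id", "mean_ct", "copies_in_rt_input", "copies_per_cell",
           "below_lod")
  attr(res, "lod_copies_per_cell") <-
    curve$lod_copies / extract_fraction_used / cells_per_sample
  res
}
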