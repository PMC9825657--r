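# Shared fixture builders. All scenes are generated in code at test time;
# small grids keep the suite fast.

suppressMessages(library(dplyr))

# compact single-cell geometry used throughout the suite
small_params <- function(...) {
  args <- modifyList(list(image_shape = c(96L, 96L), cell_radius_um = 3.5,
                          nucleus_radius_um = 1.3, organelle_filaments = 3),
                     list(...))
  do.call(sim_params, args)
}

# identical geometry with blur and noise disabled
clean_params <- function(...) {
  small_params(psf_sigma_um = 0, shot_noise = FALSE, read_noise_sd = 0, ...)
}

# roomier geometry for puncta scenes: the detection threshold is relative
# to the whole-cytosol mean (puncta included), so the cytosol must be
# large relative to the painted disks
puncta_params <- function(...) {
  clean_params(image_shape = c(224L, 224L), cell_radius_um = 10,
               nucleus_radius_um = 3, organelle_filaments = 0, ...)
}

truth_roi <- function(truth, id = "cell") {
  cell_roi(id, truth$cell_mask, truth$nucleus_mask)
}

# full measurement path: simulate -> organelle mask -> ring -> ratio
measure_ratio <- function(rho, seed,
                          mp = mask_params(mean_filter_radius_px = 1),
                          params_fun = small_params) {
  p <- params_fun(enrichment_rho = rho, seed = seed)
  s <- simulate_cell(p, channels = c("receptor", "organelle"))
  roi <- truth_roi(s$truth)
  inner <- build_organelle_mask(get_channel(s$image, "organelle"), roi, mp)
  rings <- build_ring_mask(inner, roi, 300, p$pixel_size_nm)
  coloc_ratio(get_channel(s$image, "receptor"), rings, roi, "x")$ratio
}

# brute-force Euclidean dilation oracle: pixels whose exact all-pairs
# distance to the mask is <= r
brute_force_dilation <- function(mask, r) {
  stopifnot(any(mask))
  dm <- dim(mask)
  idx <- which(mask)
  mr <- ((idx - 1L) %% dm[1]) + 1L
  mc <- ((idx - 1L) %/% dm[1]) + 1L
  pr <- matrix(rep(seq_len(dm[1]), dm[2]), ncol = 1)
  pc <- matrix(rep(seq_len(dm[2]), each = dm[1]), ncol = 1)
  d2 <- outer(as.numeric(pr), as.numeric(mr), function(a, b) (a - b)^2) +
    outer(as.numeric(pc), as.numeric(mc), function(a, b) (a - b)^2)
  dmin <- sqrt(apply(d2, 1, min))
  out <- dmin <= r + 1e-9
  dim(out) <- dm
  out
}

# textbook one-way ANOVA from sums of squares
anova_oracle <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}
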