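# canonical scene: cytosol baseline 100 AU with three qualifying 1.5 um
# disks at 1500 AU, one sub-diameter 0.8 um disk at 1500 AU, and one
# sub-brightness 1.5 um disk at 800 AU
canonical_puncta_scene <- function(seed = 5) {
  p <- puncta_params(puncta_spec = list(c(1.5, 15, 3), c(0.8, 15, 1),
                                        c(1.5, 8, 1)),
                     seed = seed)
  s <- simulate_cell(p, channels = "receptor")
  list(signal = get_channel(s$image, "receptor"), truth = s$truth,
       roi = truth_roi(s$truth), pixel_size_nm = p$pixel_size_nm)
}

test_that("the diameter and fold criteria keep exactly the qualifying disks", {
  fx <- canonical_puncta_scene()
  pts <- detect_puncta(fx$signal, fx$roi, fx$pixel_size_nm)
  expect_equal(nrow(pts), 3)
  expect_true(all(pts$equivalent_diameter_um >= 1.0))
  expect_true(all(pts$fold_over_cytosol >= 10))
  # brute-force check of the filters: the dim disk fails the recomputed
  # 10 x mu_cyt pixel threshold, the small disk fails the diameter rule
  mu <- mean(fx$signal[fx$roi$cytosol_mask])
  expect_lt(800, 10 * mu)
  small <- fx$truth$puncta_true[fx$truth$puncta_true$diameter_um == 0.8 &
                                  fx$truth$puncta_true$channel == "receptor", ]
  area_small <- sum((row(fx$signal) - small$row)^2 +
                      (col(fx$signal) - small$col)^2 <= small$radius_px^2)
  expect_lt(2 * sqrt(area_small / pi) * fx$pixel_size_nm / 1000, 1.0)
})

test_that("detection is invariant under intensity scaling", {
  fx <- canonical_puncta_scene()
  a <- detect_puncta(fx$signal, fx$roi, fx$pixel_size_nm)
  b <- detect_puncta(2 * fx$signal, fx$roi, fx$pixel_size_nm)
  c <- detect_puncta(0.01 * fx$signal, fx$roi, fx$pixel_size_nm)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$pixels, c$pixels)
})

test_that("uniform cytosol yields no puncta and zero signal errors", {
  s <- simulate_cell(puncta_params(seed = 2), channels = "receptor")
  roi <- truth_roi(s$truth)
  sig <- get_channel(s$image, "receptor")
  expect_equal(nrow(detect_puncta(sig, roi, 100)), 0)
  expect_error(detect_puncta(matrix(0, 224, 224), roi, 100), "zero")
  expect_error(detect_puncta(sig, roi, pixel_size_nm = NULL), "pixel_size_nm")
})

test_that("detection recall and precision are exact on clean margin scenes", {
  # all true puncta satisfy both criteria with ample margin
  p <- puncta_params(puncta_spec = list(c(1.4, 20, 4)), seed = 9)
  s <- simulate_cell(p, channels = "receptor")
  roi <- truth_roi(s$truth)
  pts <- detect_puncta(get_channel(s$image, "receptor"), roi, 100)
  expect_equal(nrow(pts), 4)
  # each detection sits on a distinct true punctum
  d <- outer(pts$centroid_row, s$truth$puncta_true$row, "-")^2 +
    outer(pts$centroid_col, s$truth$puncta_true$col, "-")^2
  expect_true(all(apply(sqrt(d), 1, min) < 2))
  expect_equal(length(unique(apply(d, 1, which.min))), 4)
})

test_that("diameter filter boundary: exact-size disks kept, one row smaller rejected", {
  # lattice disk of radius 5 px has 81 px -> equivalent diameter 1.016 um;
  # radius 4 px has 49 px -> 0.790 um (brute-force counts)
  sig <- matrix(100, 64, 64)
  cellm <- matrix(TRUE, 64, 64)
  nucm <- matrix(FALSE, 64, 64); nucm[1, 1] <- TRUE
  roi <- cell_roi("c", cellm, nucm)
  mk <- function(r0, ctr) (row(sig) - ctr[1])^2 + (col(sig) - ctr[2])^2 <= r0^2
  big <- mk(5, c(16, 16)); small <- mk(4, c(48, 48))
  expect_equal(sum(big), 81); expect_equal(sum(small), 49)
  sig[big] <- 5000; sig[small] <- 5000
  pts <- detect_puncta(sig, roi, 100, min_diameter_um = 1.0)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$area_px, 81)
})

test_that("diagonally touching blobs merge under 8-connectivity", {
  sig <- matrix(10, 32, 32)
  cellm <- matrix(TRUE, 32, 32)
  nucm <- matrix(FALSE, 32, 32); nucm[1, 1] <- TRUE
  roi <- cell_roi("c", cellm, nucm)
  # two 5x5 squares meeting only at a corner: one 8-connected component
  sig[10:14, 10:14] <- 1000
  sig[15:19, 15:19] <- 1000
  pts <- detect_puncta(sig, roi, 100, min_diameter_um = 0.5)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$area_px, 50)
})

test_that("puncta colocalization follows the centroid/overlap rule", {
  fx <- canonical_puncta_scene()
  pts <- detect_puncta(fx$signal, fx$roi, fx$pixel_size_nm)
  self <- puncta_colocalization(pts, pts)
  expect_equal(self$fraction, 1.0)
  empty <- pts[0, ]
  attr(empty, "image_dim") <- attr(pts, "image_dim")
  flagged <- puncta_colocalization(empty, pts)
  expect_equal(flagged$fraction, 0)
  expect_true(flagged$flagged)
  none <- puncta_colocalization(pts, empty)
  expect_equal(none$fraction, 0)
  wrong <- pts
  attr(wrong, "image_dim") <- c(10L, 10L)
  expect_error(puncta_colocalization(pts, wrong), "grid")
})

test_that("seeded RNA colocalization fraction is recovered from images", {
  fractions <- vapply(1:25, function(i) {
    p <- puncta_params(puncta_spec = list(c(1.3, 15, 5)),
                       rna_coloc_fraction = 0.6, seed = 400 + i)
    s <- simulate_cell(p, channels = c("receptor", "rna"))
    roi <- truth_roi(s$truth)
    a <- detect_puncta(get_channel(s$image, "receptor"), roi, 100)
    b <- detect_puncta(get_channel(s$image, "rna"), roi, 100)
    puncta_colocalization(a, b)$fraction
  }, numeric(1))
  expect_lt(abs(mean(fractions) - 0.6), 0.1)
})

test_that("per-condition puncta summaries and t-test behave", {
  counts <- tibble::tibble(cell_id = as.character(1:6),
                           condition = rep(c("3h", "24h"), each = 3),
                           n_puncta = c(0, 1, 2, 2, 2, 2))
  ps <- summarize_puncta(counts, comparison = c("3h", "24h"))
  s3 <- ps$summary[ps$summary$condition == "3h", ]
  expect_equal(s3$mean_bodies_per_cell, 1.0)
  expect_equal(s3$sd, 1.0)
  expect_true(ps$p_value > 0 && ps$p_value <= 1)

  same <- tibble::tibble(cell_id = as.character(1:6),
                         condition = rep(c("a", "b"), each = 3),
                         n_puncta = rep(2, 6))
  expect_equal(summarize_puncta(same, c("a", "b"))$p_value, 1)
  expect_warning(summarize_puncta(counts, c("3h", "missing")), "absent")
})

test_that("simulated per-cell counts are recovered across a cohort", {
  counts <- purrr::map_dfr(1:12, function(i) {
    truth_n <- if (i <= 6) 3 else 5
    p <- puncta_params(puncta_spec = list(c(1.3, 15, truth_n)),
                       seed = 900 + i)
    s <- simulate_cell(p, channels = "receptor")
    pts <- detect_puncta(get_channel(s$image, "receptor"),
                         truth_roi(s$truth), 100)
    tibble::tibble(cell_id = as.character(i),
                   condition = if (i <= 6) "low" else "high",
                   n_puncta = nrow(pts))
  })
  ps <- summarize_puncta(counts, comparison = c("low", "high"))
  expect_lt(abs(ps$summary$mean_bodies_per_cell[ps$summary$condition == "low"] - 3), 0.2)
  expect_lt(abs(ps$summary$mean_bodies_per_cell[ps$summary$condition == "high"] - 5), 0.2)
})
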