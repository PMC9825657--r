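ramp_image <- function(n = 32) {
  # I(r, c) = c: linear in the column index
  microscopy_image(list(sig = matrix(rep(1:n, each = n), n, n)),
                   pixel_size_nm = 100)
}

test_that("profiles of constant images are constant", {
  img <- microscopy_image(list(sig = matrix(7, 16, 16)), 100)
  pr <- line_profile(img, "sig", from = c(2, 2), to = c(14, 14), n_samples = 25)
  expect_true(all(pr$samples$intensity == 7))
  expect_equal(uniformity_cv(pr, "sig"), 0)
})

test_that("bilinear sampling along a row matches the closed form", {
  img <- ramp_image()
  pr <- line_profile(img, "sig", from = c(10, 3), to = c(10, 27),
                     n_samples = 25)
  expect_equal(pr$samples$intensity, seq(3, 27, length.out = 25),
               tolerance = 1e-12)
  # spacing in physical units: 24 px * 0.1 um / 24 intervals
  expect_equal(pr$sample_spacing_um, 0.1, tolerance = 1e-12)
  # fractional endpoints interpolate linearly too
  pr2 <- line_profile(img, "sig", from = c(10.5, 3.25), to = c(10.5, 26.75),
                      n_samples = 10)
  expect_equal(pr2$samples$intensity, seq(3.25, 26.75, length.out = 10),
               tolerance = 1e-12)
})

test_that("reversing the endpoints reverses the samples", {
  img <- ramp_image()
  a <- line_profile(img, "sig", c(5, 2), c(20, 30), n_samples = 40)
  b <- line_profile(img, "sig", c(20, 30), c(5, 2), n_samples = 40)
  expect_equal(a$samples$intensity, rev(b$samples$intensity),
               tolerance = 1e-12)
})

test_that("profiles are equivariant under integer translation", {
  withr::with_seed(3, base <- matrix(stats::runif(40 * 40), 40, 40))
  shifted <- matrix(0, 40, 40)
  shifted[4:40, 6:40] <- base[1:37, 1:35]
  i1 <- microscopy_image(list(s = base), 100)
  i2 <- microscopy_image(list(s = shifted), 100)
  p1 <- line_profile(i1, "s", c(5, 5), c(30, 25), n_samples = 20)
  p2 <- line_profile(i2, "s", c(8, 10), c(33, 30), n_samples = 20)
  expect_equal(p1$samples$intensity, p2$samples$intensity, tolerance = 1e-12)
})

test_that("wide profiles average perpendicular offsets", {
  img <- ramp_image()
  narrow <- line_profile(img, "sig", c(10, 3), c(10, 27), n_samples = 25)
  wide <- line_profile(img, "sig", c(10, 3), c(10, 27), n_samples = 25,
                       width_px = 3)
  # offsets move along rows; the ramp only varies along columns
  expect_equal(narrow$samples$intensity, wide$samples$intensity,
               tolerance = 1e-12)
  expect_error(line_profile(img, "sig", c(0, 3), c(10, 27)), "inside")
})

test_that("uniformity CV is scale-invariant and ranks puncta above diffuse", {
  m <- matrix(c(90, 90, 110, 110), 2, 2)   # columns 90 | 110
  img <- microscopy_image(list(s = m), 100)
  pr <- line_profile(img, "s", c(1, 1), c(1, 2), n_samples = 2)
  expect_equal(uniformity_cv(pr, "s"), 0.1)  # population SD 10 / mean 100
  pr2 <- line_profile(microscopy_image(list(s = 5 * m), 100), "s",
                      c(1, 1), c(1, 2), n_samples = 2)
  expect_equal(uniformity_cv(pr2, "s"), 0.1, tolerance = 1e-12)

  # a nucleus-to-membrane trace through a receptor body is less uniform
  # than the same trace in a diffuse cell, at matched noise
  noisy_puncta <- function(...) {
    args <- modifyList(list(image_shape = c(224L, 224L), cell_radius_um = 10,
                            nucleus_radius_um = 3, organelle_filaments = 0),
                       list(...))
    do.call(sim_params, args)
  }
  diffuse <- simulate_cell(noisy_puncta(seed = 61), channels = "receptor")
  laden <- simulate_cell(noisy_puncta(puncta_spec = list(c(1.3, 15, 4)),
                                      seed = 61), channels = "receptor")
  cv_of <- function(sim, through) {
    ctr <- c(112.5, 112.5)
    d_p <- sqrt(sum((through - ctr)^2))
    dir <- (through - ctr) / d_p
    # from just outside the nucleus to just past the punctum position,
    # staying inside the cell for both scenes
    uniformity_cv(line_profile(sim$image, "receptor",
                               ctr + 32 * dir, ctr + (d_p + 6) * dir,
                               n_samples = 60), "receptor")
  }
  pt <- c(laden$truth$puncta_true$row[1], laden$truth$puncta_true$col[1])
  expect_lt(cv_of(diffuse, pt), cv_of(laden, pt))
})

test_that("nuclear translocation index is the ratio of mask means", {
  cellm <- matrix(FALSE, 20, 20); cellm[3:18, 3:18] <- TRUE
  nucm <- matrix(FALSE, 20, 20); nucm[8:12, 8:12] <- TRUE
  roi <- cell_roi("c", cellm, nucm)
  tf <- matrix(0, 20, 20); tf[cellm] <- 200; tf[nucm] <- 50
  rec <- nuclear_translocation_index(tf, roi, "mock")
  expect_equal(rec$index, 0.25)

  tf0 <- matrix(0, 20, 20); tf0[nucm] <- 50
  rec0 <- nuclear_translocation_index(tf0, roi)
  expect_false(rec0$valid)
  expect_true(is.na(rec0$index))
})

test_that("truth masks recover the simulated nuclear fraction exactly", {
  p <- clean_params(nuclear_fraction_tf = 3, seed = 19)
  s <- simulate_cell(p, channels = "tf")
  rec <- nuclear_translocation_index(get_channel(s$image, "tf"),
                                     truth_roi(s$truth), "stim")
  expect_equal(rec$index, 3.0, tolerance = 1e-9)
})

test_that("mock and stimulated cohorts separate on the translocation index", {
  idx <- function(eta, seed) {
    p <- small_params(nuclear_fraction_tf = eta, seed = seed)
    s <- simulate_cell(p, channels = "tf")
    nuclear_translocation_index(get_channel(s$image, "tf"),
                                truth_roi(s$truth))$index
  }
  mock <- vapply(1:10, function(i) idx(0.1, 500 + i), numeric(1))
  stim <- vapply(1:10, function(i) idx(2.0, 600 + i), numeric(1))
  expect_lt(t.test(mock, stim)$p.value, 0.01)
  expect_lt(mean(mock), mean(stim))
})
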