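worked_ct_table <- function() {
  tibble::tibble(
    condition = rep(c("Mock", "treated"), each = 2),
    gene = rep(c("IFNB", "ACTB"), 2),
    replicate = 1,
    ct = c(28, 18, 21, 18))
}

test_that("delta-delta-Ct reproduces the closed-form worked example", {
  dd <- delta_delta_ct(worked_ct_table(), "IFNB")
  treated <- dd$by_condition[dd$by_condition$condition == "treated", ]
  expect_equal(treated$fold, 128)  # 2^(28 - 21)
  mock <- dd$by_condition[dd$by_condition$condition == "Mock", ]
  expect_equal(mock$fold, 1)
})

test_that("identical Ct values give fold 1 and machine offsets cancel", {
  tbl <- worked_ct_table()
  tbl$ct[tbl$condition == "treated"] <- tbl$ct[tbl$condition == "Mock"]
  dd <- delta_delta_ct(tbl, "IFNB")
  expect_true(all(dd$by_condition$fold == 1))

  shifted <- worked_ct_table()
  shifted$ct <- shifted$ct + 4.7
  expect_equal(delta_delta_ct(shifted, "IFNB")$by_condition$fold,
               delta_delta_ct(worked_ct_table(), "IFNB")$by_condition$fold,
               tolerance = 1e-12)
})

test_that("missing genes or conditions error; non-detects warn", {
  expect_error(delta_delta_ct(worked_ct_table(), "IFNB", "GAPDH"), "GAPDH")
  expect_error(delta_delta_ct(worked_ct_table(), "IL6"), "IL6")
  expect_error(delta_delta_ct(worked_ct_table(), "IFNB",
                              reference_condition = "PBS"), "PBS")
  tbl <- worked_ct_table()
  tbl <- rbind(tbl, tibble::tibble(condition = "treated", gene = "IFNB",
                                   replicate = 2, ct = NA_real_))
  expect_warning(dd <- delta_delta_ct(tbl, "IFNB"), "non-detect")
  expect_equal(dd$by_condition$fold[dd$by_condition$condition == "treated"], 128)
})

test_that("simulated plates recover a known fold induction", {
  # true fold 100 via target copies; reference gene constant
  folds <- vapply(1:60, function(i) {
    wells <- dplyr::bind_rows(
      tidyr::crossing(condition = c("Mock", "stim"), replicate = 1:3) %>%
        dplyr::mutate(sample_id = condition, gene = "IFNB",
                      copies = ifelse(condition == "Mock", 1e3, 1e5)),
      tidyr::crossing(condition = c("Mock", "stim"), replicate = 1:3) %>%
        dplyr::mutate(sample_id = condition, gene = "ACTB", copies = 1e7))
    plate <- simulate_qpcr_plate(qpcr_truth(wells, ct_noise_sd = 0.2,
                                            seed = 3000 + i))
    dd <- delta_delta_ct(plate, "IFNB")
    dd$by_condition$fold[dd$by_condition$condition == "stim"]
  }, numeric(1))
  expect_gte(median(folds), 80)
  expect_lte(median(folds), 125)
})

test_that("standard curve recovers exact parameters from noise-free points", {
  s <- tibble::tibble(copies = 10^(4:8),
                      ct = 43.2877 - 3.3219 * log10(10^(4:8)))
  curve <- fit_standard_curve(s)
  expect_equal(curve$slope, -3.3219, tolerance = 1e-6)
  expect_equal(curve$intercept, 43.2877, tolerance = 1e-6)
  expect_equal(curve$efficiency, 1.00, tolerance = 1e-4)
  expect_equal(curve$r_squared, 1.0, tolerance = 1e-9)
  expect_equal(curve$lod_copies, 1e4)
  expect_equal(tidy(curve)$estimate, c(43.2877, -3.3219), tolerance = 1e-6)
})

test_that("standard curve validates inputs and flags assay failure", {
  two <- tibble::tibble(copies = c(1e4, 1e5), ct = c(30, 27))
  expect_error(fit_standard_curve(two), ">= 3")
  bad <- tibble::tibble(copies = 10^(4:6), ct = c(20, 25, 30))
  expect_error(fit_standard_curve(bad), "assay failure")
  neg <- tibble::tibble(copies = c(0, 1e4, 1e5), ct = c(40, 30, 27))
  expect_error(fit_standard_curve(neg), "> 0")
})

test_that("noisy dilution series recovers the slope within 0.1", {
  wells <- tidyr::crossing(level = 4:8, replicate = 1:3) %>%
    dplyr::mutate(sample_id = paste0("s", level), condition = "std",
                  gene = "DI", copies = 10^level)
  plate <- simulate_qpcr_plate(qpcr_truth(wells, ct_noise_sd = 0.15, seed = 77))
  curve <- fit_standard_curve(
    dplyr::tibble(copies = wells$copies, ct = plate$ct,
                  detected = plate$detected))
  expect_lt(abs(curve$slope - (-3.3219)), 0.1)
})

test_that("copies per cell follows the arithmetic chain and flags non-detects", {
  s <- tibble::tibble(copies = 10^(4:8),
                      ct = 43.2877 - 3.3219 * log10(10^(4:8)))
  curve <- fit_standard_curve(s)
  wells <- tibble::tibble(sample_id = c("a", "nd"), ct = c(30, NA),
                          detected = c(TRUE, FALSE))
  res <- copies_per_cell(wells, curve, extract_fraction_used = 0.1,
                         cells_per_sample = 2e4)
  a <- res[res$sample_id == "a", ]
  # the textbook constants are printed to 4-5 digits, so inversion is
  # exact only to ~1e-4 relative
  expect_equal(a$copies_in_rt_input, 1e4, tolerance = 2e-4)
  expect_equal(a$copies_per_cell, 5.0, tolerance = 2e-4)
  expect_false(a$below_lod)
  nd <- res[res$sample_id == "nd", ]
  expect_true(nd$below_lod)
  expect_true(is.na(nd$copies_per_cell))
  expect_error(copies_per_cell(wells, curve, 1.5, 100), "\\(0, 1\\]")
})

test_that("simulate -> fit -> invert round-trips copies per cell", {
  # 10 copies/cell, 2e4 cells, 10% of extract into RT -> 2e4 copies in input
  recovered <- vapply(1:20, function(i) {
    seed <- 5000 + i
    std_wells <- tidyr::crossing(level = 4:8, replicate = 1:3) %>%
      dplyr::mutate(sample_id = paste0("s", level), condition = "std",
                    gene = "DI", copies = 10^level)
    unk_wells <- tibble::tibble(sample_id = "unk", condition = "SeV",
                                gene = "DI", replicate = 1:3, copies = 2e4)
    plate <- simulate_qpcr_plate(
      qpcr_truth(dplyr::bind_rows(std_wells, unk_wells),
                 ct_noise_sd = 0.2, seed = seed))
    curve <- fit_standard_curve(tibble::tibble(
      copies = std_wells$copies,
      ct = plate$ct[plate$condition == "std"],
      detected = plate$detected[plate$condition == "std"]))
    res <- copies_per_cell(plate[plate$condition == "SeV", ], curve,
                           extract_fraction_used = 0.1,
                           cells_per_sample = 2e4)
    res$copies_per_cell
  }, numeric(1))
  # 0.2 Ct noise on triplicates propagates to ~8% (1 sigma) in copies, so
  # the central recovery must sit within the 20% band
  expect_lte(abs(median(recovered) - 10) / 10, 0.2)
  expect_gt(mean(abs(recovered - 10) / 10 <= 0.2), 0.8)
})

test_that("round-trip holds across a full 5-log dilution series", {
  std_wells <- tidyr::crossing(level = 4:8, replicate = 1:3) %>%
    dplyr::mutate(sample_id = paste0("s", level), condition = "std",
                  gene = "DI", copies = 10^level)
  plate <- simulate_qpcr_plate(qpcr_truth(std_wells, ct_noise_sd = 0.1,
                                          seed = 123))
  curve <- fit_standard_curve(tibble::tibble(
    copies = std_wells$copies, ct = plate$ct, detected = plate$detected))
  res <- copies_per_cell(plate, curve, 1, 1)
  truth <- std_wells %>% dplyr::distinct(sample_id, copies)
  m <- merge(res, truth, by = "sample_id")
  # noise of 0.1 Ct propagates to ~ +-10% in copies (2^(3 * 0.1 / sqrt(3)))
  expect_true(all(abs(log10(m$copies_in_rt_input) - log10(m$copies)) < 0.12))
})

test_that("replicate-level folds supply a spread around the condition fold", {
  tbl <- tibble::tibble(
    condition = rep(rep(c("Mock", "stim"), each = 3), 2),
    gene = rep(c("IFNB", "ACTB"), each = 6),
    replicate = rep(1:3, 4),
    ct = c(28.1, 28.0, 27.9, 21.1, 21.0, 20.9, rep(18, 6)))
  dd <- delta_delta_ct(tbl, "IFNB")
  reps <- tidy(dd)
  expect_equal(nrow(reps), 6)
  gl <- glance(dd)
  stim_fold <- gl$fold[gl$condition == "stim"]
  stim_reps <- reps$fold[reps$condition == "stim"]
  expect_true(min(stim_reps) < stim_fold && stim_fold < max(stim_reps))
  expect_true(all(is.finite(gl$fold_sd)))
})
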