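#' Build and validate a pipeline run configuration
#'
#' A run simulates cells for a set of labelled conditions, measures them
#' (colocalization ratios and/or puncta counts), and computes group
#' statistics, writing per-cell and group-level CSVs plus a JSON manifest.
#' One root seed reproduces the whole run: every cell derives its own
#' substream from `(seed, condition, cell index)`.
#'
#' @param conditions named list: one entry per condition label, each a
#'   list of [sim_params()] overrides (e.g. `list(enrichment_rho = 3)`).
#' @param n_cells cells per condition.
#' @param stages subset of `c("simulate", "coloc", "puncta", "stats")`.
#' @param base_params [sim_params()] overrides shared by all conditions.
#' @param channels channels rendered per cell; every channel a stage needs
#'   must be listed here (validated before any stage runs).
#' @param dilation_radius_nm ring geometry for the coloc stage.
#' @param mask_params a [mask_params()] for the organelle mask.
#' @param min_diameter_um,fold_threshold puncta criteria.
#' @param reference reference condition for the statistics stage.
#' @param use_truth_rois use the simulator's true cell/nucleus masks as
#'   ROIs instead of re-segmenting each image (faster; segmentation is
#'   validated separately).
#' @param seed root seed.
#' @param out_dir output directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(conditions, n_cells = 20,
                       stages = c("simulate", "coloc", "puncta", "stats"),
                       base_params = list(),
                       channels = c("receptor", "organelle", "rna", "tf",
                                    "nucleus"),
                       dilation_radius_nm = 300,
                       mask_params = riglocate::mask_params(),
                       min_diameter_um = 1.0, fold_threshold = 10,
                       reference = NULL, use_truth_rois = TRUE,
                       seed = 1L, out_dir = tempfile("riglocate_run_")) {
  if (!is.list(conditions) || length(conditions) == 0 ||
      is.null(names(conditions)) || any(names(conditions) == "")) {
    abort("`conditions` must be a non-empty named list of parameter overrides")
  }
  stages <- match.arg(stages, c("simulate", "coloc", "puncta", "stats"),
                      several.ok = TRUE)
  all_channels <- c("receptor", "organelle", "rna", "tf", "nucleus")
  bad <- setdiff(channels, all_channels)
  if (length(bad) > 0) {
    abort(paste("undeclared channel(s):", paste(bad, collapse = ", ")))
  }
  needed <- c(if ("coloc" %in% stages) c("receptor", "organelle"),
              if ("puncta" %in% stages) "receptor")
  miss <- setdiff(needed, channels)
  if (length(miss) > 0) {
    abort(paste("stages reference channel(s) not in `channels`:",
                paste(miss, collapse = ", ")))
  }
  if (is.null(reference)) reference <- names(conditions)[1]
  if (!reference %in% names(conditions)) {
    abort(sprintf("reference '%s' is not a declared condition", reference))
  }
  cfg <- structure(list(conditions = conditions, n_cells = as.integer(n_cells),
                        stages = stages, base_params = base_params,
                        channels = channels,
                        dilation_radius_nm = as.numeric(dilation_radius_nm),
                        mask_params = mask_params,
                        min_diameter_um = as.numeric(min_diameter_um),
                        fold_threshold = as.numeric(fold_threshold),
                        reference = reference,
                        use_truth_rois = isTRUE(use_truth_rois),
                        seed = as.integer(seed), out_dir = out_dir),
                   class = "run_config")
  # every condition's overrides must build valid sim params
  for (cn in names(conditions)) cell_params(cfg, cn, 1L)
  cfg
}

cell_params <- function(cfg, condition, i) {
  args <- modifyList(cfg$base_params, cfg$conditions[[condition]])
  args$seed <- derive_seed(cfg$seed, "cell", condition, i)
  do.call(sim_params, args)
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]; `mask_params` is
#' given as a mapping of [mask_params()] arguments.
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$mask_params)) y$mask_params <- do.call(mask_params, y$mask_params)
  for (fld in c("conditions", "base_params")) {
    if (!is.null(y[[fld]])) y[[fld]] <- lapply(y[[fld]], as.list)
  }
  do.call(run_config, y)
}

measure_one_cell <- function(cfg, condition, i) {
  p <- cell_params(cfg, condition, i)
  sim <- simulate_cell(p, channels = cfg$channels)
  roi <- if (cfg$use_truth_rois) {
    cell_roi(sprintf("%s_%03d", condition, i), sim$truth$cell_mask,
             sim$truth$nucleus_mask)
  } else {
    rois <- segment_cells(sim$image)
    if (length(rois) == 0) return(list(excluded = "segmentation_failed"))
    r <- rois[[1]]
    r$cell_id <- sprintf("%s_%03d", condition, i)
    r
  }
  if (inherits(roi, "list") && !is.null(roi$excluded)) return(roi)
  out <- list()
  if ("coloc" %in% cfg$stages) {
    inner <- build_organelle_mask(get_channel(sim$image, "organelle"), roi,
                                  cfg$mask_params)
    if (!any(inner)) return(list(excluded = "empty_organelle_mask"))
    rings <- build_ring_mask(inner, roi, cfg$dilation_radius_nm,
                             p$pixel_size_nm)
    rec <- coloc_ratio(get_channel(sim$image, "receptor"), rings, roi,
                       condition)
    if (!rec$valid) return(list(excluded = "empty_ring"))
    out$coloc <- rec
  }
  if ("puncta" %in% cfg$stages) {
    pts <- detect_puncta(get_channel(sim$image, "receptor"), roi,
                         p$pixel_size_nm, cfg$min_diameter_um,
                         cfg$fold_threshold)
    out$puncta <- tibble(cell_id = roi$cell_id, condition = condition,
                         n_puncta = nrow(pts))
  }
  out
}

#' Run the simulate/measure/stats pipeline
#'
#' Executes the configured stages for every condition and cell, writes
#' per-cell and group-level CSVs into `cfg$out_dir`, and writes a JSON
#' manifest last. The manifest records the config hash, package version,
#' per-file MD5 checksums, and a per-cell exclusion log (reason + count);
#' it carries no timestamps, so re-running an identical config + seed
#' reproduces a byte-identical manifest.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly (class `run_manifest`), with
#'   `$coloc`, `$puncta`, `$comparison`, `$puncta_summary` results
#'   attached where the corresponding stage ran.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  exclusions <- tibble(cell_id = character(), reason = character())
  coloc_records <- list()
  puncta_records <- list()
  for (condition in names(cfg$conditions)) {
    for (i in seq_len(cfg$n_cells)) {
      res <- tryCatch(
        measure_one_cell(cfg, condition, i),
        error = function(e) {
          abort(sprintf("stage failure for condition '%s', cell %d: %s",
                        condition, i, conditionMessage(e)))
        })
      if (!is.null(res$excluded)) {
        exclusions <- bind_rows(exclusions, tibble(
          cell_id = sprintf("%s_%03d", condition, i), reason = res$excluded))
        next
      }
      if (!is.null(res$coloc)) coloc_records[[length(coloc_records) + 1]] <- res$coloc
      if (!is.null(res$puncta)) puncta_records[[length(puncta_records) + 1]] <- res$puncta
    }
  }
  files <- character()
  results <- list()
  if (length(coloc_records) > 0) {
    coloc_tbl <- bind_rows(coloc_records)
    f <- file.path(cfg$out_dir, "coloc_cells.csv")
    write.csv(coloc_tbl, f, row.names = FALSE)
    files <- c(files, f)
    results$coloc <- coloc_tbl
    if ("stats" %in% cfg$stages && length(unique(coloc_tbl$condition)) >= 2) {
      cmp <- compare_groups(coloc_tbl, reference = cfg$reference)
      f <- file.path(cfg$out_dir, "coloc_groups.csv")
      write.csv(left_join(cmp$summary, cmp$pairwise, by = "condition"), f,
                row.names = FALSE)
      files <- c(files, f)
      results$comparison <- cmp
    }
  }
  if (length(puncta_records) > 0) {
    puncta_tbl <- bind_rows(puncta_records)
    f <- file.path(cfg$out_dir, "puncta_cells.csv")
    write.csv(puncta_tbl, f, row.names = FALSE)
    files <- c(files, f)
    results$puncta <- puncta_tbl
    if ("stats" %in% cfg$stages) {
      conds <- unique(puncta_tbl$condition)
      cmp_pair <- if (length(conds) >= 2) {
        c(cfg$reference, setdiff(conds, cfg$reference)[1])
      } else NULL
      ps <- summarize_puncta(puncta_tbl, comparison = cmp_pair)
      f <- file.path(cfg$out_dir, "puncta_summary.csv")
      write.csv(ps$summary, f, row.names = FALSE)
      files <- c(files, f)
      results$puncta_summary <- ps
    }
  }
  f <- file.path(cfg$out_dir, "exclusions.csv")
  write.csv(exclusions, f, row.names = FALSE)
  files <- c(files, f)

  manifest <- list(
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
    package_version = as.character(utils::packageVersion("riglocate")),
    seed = cfg$seed,
    stages = cfg$stages,
    files = lapply(setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))),
    exclusions = as.list(table(exclusions$reason))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out <- c(manifest, results,
           list(manifest_path = manifest_path, out_dir = cfg$out_dir,
                exclusion_log = exclusions))
  invisible(structure(out, class = "run_manifest"))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> config %s, seed %d, %d file(s), %d exclusion(s)\n",
              substr(x$config_hash, 1, 8), x$seed, length(x$files),
              nrow(x$exclusion_log)))
  invisible(x)
}

#' Generate the canonical small test scenes
#'
#' Writes the fixture set used throughout the test suite: a uniform cell
#' (no enrichment, no noise), enrichment scenes at rho 1/2/3, the
#' canonical puncta scene (three qualifying disks, one sub-diameter disk,
#' one sub-brightness disk), and a synthetic qPCR plate with its standard
#' dilution series — each with its ground truth as JSON. All files are
#' deterministic in `seed`.
#'
#' @param out_dir writable directory (created if needed).
#' @param seed root seed.
#' @return named character vector of file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  save_scene <- function(name, params) {
    sim <- simulate_cell(params)
    ip <- file.path(out_dir, paste0(name, ".tif"))
    tp <- file.path(out_dir, paste0(name, "_truth.json"))
    write_image_tiff(sim$image, ip)
    write_truth_json(sim$truth, tp)
    files[[length(files) + 1]] <<- ip
    files[[length(files) + 1]] <<- tp
  }
  small <- function(...) {
    args <- modifyList(list(image_shape = c(128L, 128L), cell_radius_um = 5,
                            nucleus_radius_um = 1.8,
                            organelle_filaments = 4),
                       list(...))
    do.call(sim_params, args)
  }
  save_scene("uniform_cell",
             small(enrichment_rho = 1, psf_sigma_um = 0, shot_noise = FALSE,
                   read_noise_sd = 0, seed = derive_seed(seed, "uniform")))
  for (rho in c(1, 2, 3)) {
    save_scene(sprintf("rho%g_cell", rho),
               small(enrichment_rho = rho,
                     seed = derive_seed(seed, "rho", rho)))
  }
  # the puncta scene needs a large cytosol so that the bright disks leave
  # the (single-pass) cytosolic mean low enough for the 10x criterion
  save_scene("puncta_scene",
             small(image_shape = c(224L, 224L), cell_radius_um = 10,
                   nucleus_radius_um = 3, organelle_filaments = 0,
                   psf_sigma_um = 0, shot_noise = FALSE, read_noise_sd = 0,
                   puncta_spec = list(c(1.5, 15, 3), c(0.8, 15, 1),
                                      c(1.5, 8, 1)),
                   seed = derive_seed(seed, "puncta-scene")))
  # qPCR plate: standards 10^4..10^8 in triplicate + unknowns
  wells <- bind_rows(
    tidyr::crossing(level = 4:8, replicate = 1:3) %>%
      mutate(sample_id = sprintf("std_1e%d", .data$level),
             condition = "standard", gene = "DI",
             copies = 10^.data$level) %>%
      select(-"level"),
    tibble(sample_id = "unknown_a", condition = "SeV", gene = "DI",
           replicate = 1:3, copies = 2e5),
    tibble(sample_id = "mock", condition = "Mock", gene = "DI",
           replicate = 1:3, copies = 0))
  plate <- simulate_qpcr_plate(qpcr_truth(wells, seed = derive_seed(seed, "plate")))
  truth_csv <- file.path(out_dir, "qpcr_truth.csv")
  plate_csv <- file.path(out_dir, "qpcr_plate.csv")
  write.csv(wells, truth_csv, row.names = FALSE)
  write.csv(plate, plate_csv, row.names = FALSE)
  files <- c(unlist(files), truth_csv, plate_csv)
  invisible(setNames(files, basename(files)))
}
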