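#' Parameters for the synthetic-cell simulator
#'
#' All geometric parameters are given in physical units (micrometres) and
#' converted to pixels through `pixel_size_nm`; a length that converts to
#' less than one pixel is rejected. The defaults describe a single
#' epithelial-like cell imaged at high magnification: an elliptical cell of
#' ~8 um radius with a ~3 um nucleus, a filamentous organelle
#' (mitochondria-like) network in the cytosol, a diffuse cytosolic receptor
#' pool whose mean on the organelle is `enrichment_rho` times its mean in
#' free cytosol, optional bright puncta, a transcription-factor channel
#' partitioned between nucleus and cytosol, isotropic Gaussian PSF blur,
#' and Poisson shot noise plus Gaussian read noise.
#'
#' @param image_shape integer vector `(rows, cols)` in pixels.
#' @param pixel_size_nm physical pixel size; default 100 nm.
#' @param cell_radius_um,nucleus_radius_um semi-major axis of the cell
#'   ellipse and radius of the circular nucleus; the nucleus must be
#'   strictly smaller than the cell.
#' @param organelle_filaments number of filament polylines.
#' @param filament_width_um full width of each filament.
#' @param enrichment_rho receptor mean on the organelle divided by receptor
#'   mean in free cytosol (>= 0); `1` means no enrichment.
#' @param baseline_intensity pre-noise receptor intensity in free cytosol
#'   (arbitrary units, > 0).
#' @param puncta_spec list of `c(diameter_um, fold_brightness, count)`
#'   triples; each punctum is a disk of the given diameter rendered at
#'   `fold_brightness * baseline_intensity` in the receptor channel.
#' @param rna_coloc_fraction fraction of RNA-channel puncta co-placed with
#'   receptor puncta (in `[0, 1]`).
#' @param nuclear_fraction_tf transcription-factor nuclear mean divided by
#'   its cytosolic mean (>= 0).
#' @param psf_sigma_um standard deviation of the Gaussian PSF (0 disables
#'   blur).
#' @param shot_noise apply Poisson noise with mean equal to the pre-noise
#'   intensity?
#' @param read_noise_sd standard deviation of additive Gaussian read noise
#'   (applied after shot noise; the result is clipped at 0).
#' @param puncta_clearance_um minimum clearance kept between a punctum rim
#'   and the organelle network, so puncta do not contaminate the organelle
#'   mask or its immediate surround.
#' @param seed integer root seed; every random stage derives its own
#'   substream from it, so identical parameters give bitwise-identical
#'   output.
#' @return an object of class `sim_params`.
#' @seealso [simulate_cell()]
#' @export
sim_params <- function(image_shape = c(192L, 192L),
                       pixel_size_nm = 100,
                       cell_radius_um = 8,
                       nucleus_radius_um = 3,
                       organelle_filaments = 6,
                       filament_width_um = 0.4,
                       enrichment_rho = 1,
                       baseline_intensity = 100,
                       puncta_spec = list(),
                       rna_coloc_fraction = 0,
                       nuclear_fraction_tf = 1,
                       psf_sigma_um = 0.15,
                       shot_noise = TRUE,
                       read_noise_sd = 2,
                       puncta_clearance_um = 0.7,
                       seed = 1L) {
  p <- list(image_shape = as.integer(image_shape),
            pixel_size_nm = as.numeric(pixel_size_nm),
            cell_radius_um = as.numeric(cell_radius_um),
            nucleus_radius_um = as.numeric(nucleus_radius_um),
            organelle_filaments = as.integer(organelle_filaments),
            filament_width_um = as.numeric(filament_width_um),
            enrichment_rho = as.numeric(enrichment_rho),
            baseline_intensity = as.numeric(baseline_intensity),
            puncta_spec = puncta_spec,
            rna_coloc_fraction = as.numeric(rna_coloc_fraction),
            nuclear_fraction_tf = as.numeric(nuclear_fraction_tf),
            psf_sigma_um = as.numeric(psf_sigma_um),
            shot_noise = isTRUE(shot_noise),
            read_noise_sd = as.numeric(read_noise_sd),
            puncta_clearance_um = as.numeric(puncta_clearance_um),
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (length(p$image_shape) != 2 || any(p$image_shape < 16)) {
    abort("image_shape must be (rows, cols), each >= 16 pixels")
  }
  if (p$pixel_size_nm <= 0) abort("pixel_size_nm must be > 0")
  if (p$nucleus_radius_um >= p$cell_radius_um) {
    abort("nucleus_radius_um must be smaller than cell_radius_um")
  }
  px <- function(um) um_to_px(um, p$pixel_size_nm)
  if (px(p$nucleus_radius_um) < 1 || px(p$cell_radius_um) < 1) {
    abort("cell and nucleus radii must each span at least one pixel")
  }
  if (p$organelle_filaments > 0 && px(p$filament_width_um) < 1) {
    abort(sprintf(
      "filament_width_um = %g spans < 1 pixel at %g nm/px; use a width >= %g um",
      p$filament_width_um, p$pixel_size_nm, p$pixel_size_nm / 1000))
  }
  if (p$enrichment_rho < 0) abort("enrichment_rho must be >= 0")
  if (p$baseline_intensity <= 0) abort("baseline_intensity must be > 0")
  if (p$rna_coloc_fraction < 0 || p$rna_coloc_fraction > 1) {
    abort("rna_coloc_fraction must lie in [0, 1]")
  }
  if (p$nuclear_fraction_tf < 0) abort("nuclear_fraction_tf must be >= 0")
  if (p$psf_sigma_um < 0 || p$read_noise_sd < 0) {
    abort("psf_sigma_um and read_noise_sd must be >= 0")
  }
  for (spec in p$puncta_spec) {
    if (length(spec) != 3 || spec[1] <= 0 || spec[2] <= 0 || spec[3] < 0) {
      abort("each puncta_spec entry must be c(diameter_um, fold, count)")
    }
    if (px(spec[1]) / 2 < 1) {
      abort(sprintf("punctum diameter %g um spans < 2 pixels at %g nm/px",
                    spec[1], p$pixel_size_nm))
    }
  }
  invisible(p)
}

ellipse_mask <- function(shape, center, semi_r, semi_c) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / semi_r)^2 + ((c - center[2]) / semi_c)^2 <= 1
}

disk_mask <- function(shape, center, radius_px) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius_px^2
}

# Filamentous organelle network: random-walk polylines of a given width,
# clipped to the cytosol. Walks reflect when they would leave the cell,
# which keeps them inside without modelling true mitochondrial morphology.
draw_filaments <- function(p, cytosol, cell) {
  shape <- p$image_shape
  width_px <- um_to_px(p$filament_width_um, p$pixel_size_nm)
  step_px <- max(2, um_to_px(0.5, p$pixel_size_nm))
  n_steps <- max(6L, ceiling(um_to_px(2.2 * p$cell_radius_um, p$pixel_size_nm) / step_px))
  centerline <- matrix(FALSE, shape[1], shape[2])
  starts <- which(cytosol)
  nr <- shape[1]
  for (f in seq_len(p$organelle_filaments)) {
    s <- starts[sample.int(length(starts), 1)]
    pt <- c(((s - 1) %% nr) + 1, ((s - 1) %/% nr) + 1)
    theta <- stats::runif(1, 0, 2 * pi)
    pts <- matrix(pt, 1, 2)
    for (k in seq_len(n_steps)) {
      theta <- theta + rnorm(1, 0, 0.45)
      cand <- pt + step_px * c(cos(theta), sin(theta))
      ri <- round(cand[1]); ci <- round(cand[2])
      inside <- ri >= 1 && ri <= nr && ci >= 1 && ci <= shape[2] && cell[ri, ci]
      if (!inside) {              # reflect back toward the cell interior
        theta <- theta + pi + rnorm(1, 0, 0.3)
        next
      }
      pt <- cand
      pts <- rbind(pts, pt)
    }
    if (nrow(pts) < 2) next
    # rasterize the polyline densely
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      n <- max(2L, ceiling(sqrt(sum((b - a)^2)) * 2))
      t <- seq(0, 1, length.out = n)
      rr <- round(a[1] + t * (b[1] - a[1]))
      cc <- round(a[2] + t * (b[2] - a[2]))
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= shape[2]
      centerline[cbind(rr[ok], cc[ok])] <- TRUE
    }
  }
  centerline <- centerline & cytosol
  if (!any(centerline)) return(centerline)
  thick <- distance_to_mask(centerline) <= width_px / 2
  thick & cytosol
}

# Rejection-sample non-overlapping punctum centres whose disks fit in the
# cytosol and keep a clearance from the organelle network.
place_puncta <- function(spec_list, cytosol, organelle, p,
                         avoid = NULL, max_tries = 2000L) {
  if (length(spec_list) == 0) {
    return(tibble(row = numeric(), col = numeric(), radius_px = numeric(),
                  diameter_um = numeric(), fold = numeric(), spec_id = integer()))
  }
  shape <- dim(cytosol)
  dist_out <- distance_to_mask(!cytosol)
  dist_org <- if (any(organelle)) distance_to_mask(organelle) else
    matrix(Inf, shape[1], shape[2])
  clear_px <- um_to_px(p$puncta_clearance_um, p$pixel_size_nm)
  placed <- if (is.null(avoid)) {
    tibble(row = numeric(), col = numeric(), radius_px = numeric(),
           diameter_um = numeric(), fold = numeric(), spec_id = integer())
  } else avoid
  out <- list()
  nr <- shape[1]
  for (si in seq_along(spec_list)) {
    spec <- spec_list[[si]]
    radius_px <- um_to_px(spec[1], p$pixel_size_nm) / 2
    allowed <- which(dist_out > radius_px + 0.5 &
                     dist_org > radius_px + clear_px)
    if (length(allowed) == 0 && spec[3] > 0) {
      abort(sprintf("no room for a %g um punctum inside the cytosol", spec[1]))
    }
    for (k in seq_len(spec[3])) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- allowed[sample.int(length(allowed), 1)]
        ctr <- c(((s - 1) %% nr) + 1, ((s - 1) %/% nr) + 1)
        sep <- TRUE
        if (nrow(placed) > 0) {
          d <- sqrt((placed$row - ctr[1])^2 + (placed$col - ctr[2])^2)
          sep <- all(d > placed$radius_px + radius_px + 2)
        }
        if (sep) { ok <- TRUE; break }
      }
      if (!ok) abort("could not place a punctum without overlap; reduce counts or sizes")
      rec <- tibble(row = ctr[1], col = ctr[2], radius_px = radius_px,
                    diameter_um = spec[1], fold = spec[2], spec_id = si)
      placed <- bind_rows(placed, rec)
      out[[length(out) + 1]] <- rec
    }
  }
  if (length(out) == 0) {
    tibble(row = numeric(), col = numeric(), radius_px = numeric(),
           diameter_um = numeric(), fold = numeric(), spec_id = integer())
  } else bind_rows(out)
}

paint_puncta <- function(img, puncta, value_fun) {
  for (i in seq_len(nrow(puncta))) {
    d <- disk_mask(dim(img), c(puncta$row[i], puncta$col[i]), puncta$radius_px[i])
    img[d] <- value_fun(puncta$fold[i])
  }
  img
}

apply_noise <- function(m, p, seed) {
  if (!p$shot_noise && p$read_noise_sd == 0) return(m)
  with_seed(seed, {
    v <- pmax(as.numeric(m), 0)   # blur can ring slightly below zero
    if (p$shot_noise) v <- rpois(length(v), lambda = v)
    if (p$read_noise_sd > 0) v <- v + rnorm(length(v), 0, p$read_noise_sd)
    v <- pmax(v, 0)
    dim(v) <- dim(m)
    v
  })
}

#' Simulate one multi-channel cell image with known ground truth
#'
#' Renders up to five channels — `receptor`, `organelle`, `rna`, `tf`,
#' `nucleus` — on a common grid. Pre-noise intensities are exact by
#' construction: the receptor channel is `baseline_intensity` in free
#' cytosol, `baseline * enrichment_rho` on the organelle network, and
#' `baseline * fold` inside each punctum. Blur (if any) is applied before
#' noise, matching physical image formation. The returned truth carries
#' every mask and punctum used, so parameter recovery can be tested
#' directly.
#'
#' @param params a [sim_params()] object.
#' @param channels which channels to render (rendering fewer channels is
#'   cheaper). RNA puncta are placed only when the `rna` channel is
#'   rendered; all other truth fields are independent of the selection.
#' @return a list with elements `image` (a [microscopy_image()]) and
#'   `truth` (class `sim_truth`: `cell_mask`, `nucleus_mask`,
#'   `organelle_mask_true`, `puncta_true` tibble with columns
#'   `channel, row, col, radius_px, diameter_um, fold, shared`,
#'   plus `enrichment_rho`, `nuclear_fraction_tf`, `seed`).
#' @examples
#' sim <- simulate_cell(sim_params(image_shape = c(96, 96), cell_radius_um = 3.5,
#'                                 nucleus_radius_um = 1.3, seed = 7))
#' sim$image
#' @export
simulate_cell <- function(params,
                          channels = c("receptor", "organelle", "rna",
                                       "tf", "nucleus")) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  shape <- p$image_shape
  ctr <- (shape + 1) / 2
  r_cell <- um_to_px(p$cell_radius_um, p$pixel_size_nm)
  r_nuc <- um_to_px(p$nucleus_radius_um, p$pixel_size_nm)
  cell <- ellipse_mask(shape, ctr, 0.85 * r_cell, r_cell)
  nucleus <- disk_mask(shape, ctr, r_nuc)
  nucleus <- nucleus & cell
  cytosol <- cell & !nucleus
  if (!any(cytosol)) abort("geometry yields an empty cytosol")

  organelle <- if (p$organelle_filaments > 0) {
    with_seed(derive_seed(p$seed, "filaments"),
              draw_filaments(p, cytosol, cell))
  } else matrix(FALSE, shape[1], shape[2])
  if (p$organelle_filaments > 0 && !any(organelle)) {
    abort("organelle network is empty; increase filament count or width")
  }

  rec_puncta <- with_seed(derive_seed(p$seed, "puncta"),
                          place_puncta(p$puncta_spec, cytosol, organelle, p))
  # RNA puncta: a fraction share receptor punctum centres, the rest are
  # placed independently (kept clear of receptor puncta).
  rna_puncta <- rec_puncta[0, ]
  shared_flag <- logical(0)
  if (nrow(rec_puncta) > 0 && "rna" %in% channels) {
    n_shared <- round(p$rna_coloc_fraction * nrow(rec_puncta))
    shared <- rec_puncta[seq_len(n_shared), , drop = FALSE]
    n_free <- nrow(rec_puncta) - n_shared
    free <- if (n_free > 0) {
      free_specs <- lapply(seq_len(n_free), function(i) {
        j <- n_shared + i
        c(rec_puncta$diameter_um[j], rec_puncta$fold[j], 1)
      })
      with_seed(derive_seed(p$seed, "rna-puncta"),
                place_puncta(free_specs, cytosol, organelle, p,
                             avoid = rec_puncta))
    } else rec_puncta[0, ]
    rna_puncta <- bind_rows(shared, free)
    shared_flag <- c(rep(TRUE, nrow(shared)), rep(FALSE, nrow(free)))
  }

  base <- p$baseline_intensity
  render <- list()
  if ("receptor" %in% channels) {
    m <- matrix(0, shape[1], shape[2])
    m[cytosol] <- base
    m[organelle] <- base * p$enrichment_rho
    m <- paint_puncta(m, rec_puncta, function(fold) base * fold)
    render$receptor <- m
  }
  if ("organelle" %in% channels) {
    m <- matrix(0, shape[1], shape[2])
    m[cytosol] <- 0.1 * base
    m[organelle] <- 5 * base
    render$organelle <- m
  }
  if ("rna" %in% channels) {
    rna_base <- 0.2 * base
    m <- matrix(0, shape[1], shape[2])
    m[cytosol] <- rna_base
    m <- paint_puncta(m, rna_puncta, function(fold) rna_base * fold)
    render$rna <- m
  }
  if ("tf" %in% channels) {
    m <- matrix(0, shape[1], shape[2])
    m[cytosol] <- base
    m[nucleus] <- base * p$nuclear_fraction_tf
    render$tf <- m
  }
  if ("nucleus" %in% channels) {
    m <- matrix(0, shape[1], shape[2])
    m[cell] <- 0.1 * base
    m[nucleus] <- 2 * base
    render$nucleus <- m
  }

  if (p$psf_sigma_um > 0) {
    sigma_px <- um_to_px(p$psf_sigma_um, p$pixel_size_nm)
    render <- lapply(render, function(m) {
      out <- EBImage::imageData(EBImage::gblur(m, sigma = sigma_px))
      dim(out) <- dim(m)
      out
    })
  }
  for (nm in names(render)) {
    render[[nm]] <- apply_noise(render[[nm]], p,
                                derive_seed(p$seed, "noise", nm))
  }

  puncta_true <- bind_rows(
    if (nrow(rec_puncta)) mutate(rec_puncta, channel = "receptor", shared = NA),
    if (nrow(rna_puncta)) mutate(rna_puncta, channel = "rna",
                                 shared = shared_flag)
  )
  if (is.null(puncta_true) || nrow(puncta_true) == 0) {
    puncta_true <- tibble(row = numeric(), col = numeric(),
                          radius_px = numeric(), diameter_um = numeric(),
                          fold = numeric(), spec_id = integer(),
                          channel = character(), shared = logical())
  }

  truth <- structure(
    list(cell_mask = cell, nucleus_mask = nucleus,
         organelle_mask_true = organelle, puncta_true = puncta_true,
         enrichment_rho = p$enrichment_rho,
         nuclear_fraction_tf = p$nuclear_fraction_tf,
         pixel_size_nm = p$pixel_size_nm, seed = p$seed, params = p),
    class = "sim_truth")
  list(image = microscopy_image(render, p$pixel_size_nm), truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> cell %d px, organelle %d px, %d puncta, rho = %g, tf eta = %g\n",
    sum(x$cell_mask), sum(x$organelle_mask_true), nrow(x$puncta_true),
    x$enrichment_rho, x$nuclear_fraction_tf))
  invisible(x)
}

#' Ground truth for a synthetic qPCR plate
#'
#' Describes the true per-well template copy numbers and the log-linear
#' standard-curve regime used to turn copies into Ct values:
#' `Ct = intercept + slope * log10(copies) + N(0, ct_noise_sd)`.
#' Wells with zero copies are emitted as non-detects.
#'
#' @param wells data frame with columns `sample_id`, `condition`, `gene`,
#'   `replicate`, `copies` (copies >= 0).
#' @param curve_slope Ct change per log10(copies); must be negative
#'   (default -3.3219 corresponds to a perfect doubling per cycle).
#' @param curve_intercept Ct at 1 copy.
#' @param ct_noise_sd Gaussian noise on Ct, in cycles.
#' @param seed integer seed.
#' @return an object of class `qpcr_truth`.
#' @export
qpcr_truth <- function(wells, curve_slope = -3.3219, curve_intercept = 43.2877,
                       ct_noise_sd = 0.2, seed = 1L) {
  wells <- as_tibble(wells)
  need <- c("sample_id", "condition", "gene", "replicate", "copies")
  if (!all(need %in% names(wells))) {
    abort(paste("wells must have columns:", paste(need, collapse = ", ")))
  }
  if (any(wells$copies < 0)) abort("copies must be >= 0")
  if (curve_slope >= 0) abort("curve_slope must be negative")
  if (ct_noise_sd < 0) abort("ct_noise_sd must be >= 0")
  structure(list(wells = wells, curve_slope = as.numeric(curve_slope),
                 curve_intercept = as.numeric(curve_intercept),
                 ct_noise_sd = as.numeric(ct_noise_sd),
                 seed = as.integer(seed)),
            class = "qpcr_truth")
}

#' Simulate Ct values for a qPCR plate from known copy numbers
#'
#' @param truth a [qpcr_truth()] object.
#' @return a tibble (`sample_id`, `condition`, `gene`, `replicate`, `ct`,
#'   `detected`); wells with zero copies are non-detects (`detected =
#'   FALSE`, `ct = NA`).
#' @examples
#' tr <- qpcr_truth(tibble::tibble(sample_id = "s1", condition = "Mock",
#'                                 gene = "IFNB", replicate = 1, copies = 1e4),
#'                  ct_noise_sd = 0)
#' simulate_qpcr_plate(tr)
#' @export
simulate_qpcr_plate <- function(truth) {
  stopifnot(inherits(truth, "qpcr_truth"))
  w <- truth$wells
  ct <- rep(NA_real_, nrow(w))
  pos <- w$copies > 0
  ct[pos] <- truth$curve_intercept + truth$curve_slope * log10(w$copies[pos])
  if (truth$ct_noise_sd > 0) {
    noise <- with_seed(derive_seed(truth$seed, "ct-noise"),
                       rnorm(nrow(w), 0, truth$ct_noise_sd))
    ct[pos] <- ct[pos] + noise[pos]
  }
  mutate(w, ct = ct, detected = pos, copies = NULL)
}
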