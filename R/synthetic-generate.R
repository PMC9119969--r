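#' @noRd
disc_mask <- function(height, width, ci, cj, r) {
  i0 <- max(1L, floor(ci - r)); i1 <- min(height, ceiling(ci + r))
  j0 <- max(1L, floor(cj - r)); j1 <- min(width, ceiling(cj + r))
  out <- matrix(FALSE, height, width)
  if (i0 > i1 || j0 > j1) return(out)
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - ci)^2, (jj - cj)^2, `+`)
  out[ii, jj] <- d2 <= r^2
  out
}

#' Render textured cells on smooth background (0-255 scale)
#' @noRd
render_texture <- function(mask, texture_contrast, background_level, noise_sd) {
  h <- nrow(mask); w <- ncol(mask)
  px <- matrix(background_level, h, w)
  n_in <- sum(mask)
  if (n_in > 0) {
    # bimodal speckle: half the cell pixels at background + contrast, half at
    # background, randomly interleaved -- guarantees high local entropy after
    # Gaussian smoothing while the background stays near-constant
    px[mask] <- background_level +
      texture_contrast * sample(c(0, 1), n_in, replace = TRUE)
  }
  if (noise_sd > 0) px <- px + matrix(rnorm(h * w, 0, noise_sd), h, w)
  clip255(px)
}

#' @noRd
new_ground_truth <- function(assay, seed, ...) {
  structure(c(list(assay = assay, seed = seed), list(...)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> assay %s, seed %d\n", x$assay, x$seed))
  cat("  fields:", paste(setdiff(names(x), c("assay", "seed")), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a ground-truth sidecar as JSON
#'
#' Matrices are stored with their dimensions so the round trip is lossless.
#'
#' @param gt a `ground_truth` object.
#' @param path JSON file path.
#' @return `path` invisibly / the restored `ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  ser <- lapply(unclass(gt), function(v) {
    if (is.matrix(v)) list(.matrix = TRUE, dim = dim(v), data = as.vector(v))
    else v
  })
  # rows format: an array of objects, which read_json(simplifyVector = TRUE)
  # restores as a data.frame (the columns format reads back as a bare list)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(ser, function(v) {
    if (is.list(v) && isTRUE(v$.matrix)) matrix(v$data, v$dim[1], v$dim[2])
    else v
  })
  class(out) <- "ground_truth"
  out
}

#' Generate a synthetic phase-contrast field with known confluence
#'
#' Places random textured discs until the union mask covers
#' `confluence_target` percent of the frame to within +/- 1 percentage point
#' (the last disc is shrunk as needed). The emitted ground truth carries the
#' exact cell mask and its area fraction.
#'
#' @param spec a [phase_field_spec()].
#' @return list with elements `frame` (an [image_frame()]) and `truth`
#'   (a `ground_truth` with `mask` and `confluence_pct`).
#' @export
generate_phase_field <- function(spec) {
  stopifnot(inherits(spec, "phase_field_spec"))
  withr::with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    total <- h * w
    target <- round(spec$confluence_target / 100 * total)
    tol <- 0.01 * total
    mask <- matrix(FALSE, h, w)
    if (spec$confluence_target >= 100) {
      mask[] <- TRUE
    } else if (target > 0) {
      # cells grow in colonies: each new disc usually attaches to an existing
      # one, so the cell region stays compact and the background stays open,
      # as in a real culture, instead of a sieve of slivers
      covered <- 0L
      centres <- matrix(numeric(0), 0, 3)  # ci, cj, r
      max_iter <- 2000L + 60L * ceiling(target / max(1, pi * spec$cell_radius_range[1]^2))
      iter <- 0L
      while (covered < target - tol) {
        iter <- iter + 1L
        if (iter > max_iter)
          stop_input("packing error: confluence target ", spec$confluence_target,
                     " % unreachable with cell radii [",
                     spec$cell_radius_range[1], ", ", spec$cell_radius_range[2], "]")
        r <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
        if (nrow(centres) == 0L || runif(1) < 0.02) {
          ci <- runif(1, 1, h); cj <- runif(1, 1, w)
        } else {
          parent <- centres[sample.int(nrow(centres), 1L), ]
          ang <- runif(1, 0, 2 * pi)
          dist <- runif(1, 0.35, 0.75) * (parent[3] + r)
          ci <- parent[1] + dist * sin(ang); cj <- parent[2] + dist * cos(ang)
          if (ci < 1 || ci > h || cj < 1 || cj > w) next
        }
        # shrink the disc if it would overshoot the +1 point tolerance
        repeat {
          d <- disc_mask(h, w, ci, cj, r)
          new <- d & !mask
          if (covered + sum(new) <= target + tol) {
            mask <- mask | d
            covered <- covered + sum(new)
            centres <- rbind(centres, c(ci, cj, r))
            break
          }
          r <- r * 0.7
          if (r < 1) break
        }
      }
    }
    px <- render_texture(mask, spec$texture_contrast, spec$background_level, spec$noise_sd)
    frame <- image_frame(px, channel = "phase", field_id = paste0("phase_s", spec$seed))
    truth <- new_ground_truth("phase_field", spec$seed,
                              mask = mask, confluence_pct = 100 * mean(mask))
    list(frame = frame, truth = truth)
  })
}

#' Generate a synthetic two-channel fluorescence field
#'
#' Non-overlapping nuclei (rejection sampling honouring `min_separation`) are
#' textured in the 405 channel; `round(positive_fraction * n_nuclei)`
#' (half away from zero) randomly chosen nuclei carry supra-threshold 488
#' means, the rest sub-threshold ones. Per-nucleus centres, radii, assigned
#' 488 means and positivity labels go into the ground truth.
#'
#' @param spec a [fluor_field_spec()].
#' @return list with `frame405`, `frame488` ([image_frame()]s) and `truth`
#'   (a `ground_truth` with a per-nucleus `nuclei` data.frame).
#' @export
generate_fluor_field <- function(spec) {
  stopifnot(inherits(spec, "fluor_field_spec"))
  withr::with_seed(spec$seed, {
    h <- spec$height; w <- spec$width; n <- spec$n_nuclei
    rmin <- spec$nucleus_radius_range[1]; rmax <- spec$nucleus_radius_range[2]
    margin <- rmax + 2
    centres <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    attempts <- 0L; max_attempts <- 400L * max(1L, n)
    while (nrow(centres) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop_input("packing error: cannot place ", n, " nuclei at min_separation ",
                   spec$min_separation, " in a ", h, " x ", w, " frame")
      ci <- runif(1, margin, h - margin); cj <- runif(1, margin, w - margin)
      if (nrow(centres) == 0 ||
          all((centres[, 1] - ci)^2 + (centres[, 2] - cj)^2 >= spec$min_separation^2)) {
        centres <- rbind(centres, c(ci, cj))
        radii <- c(radii, runif(1, rmin, rmax))
      }
    }
    n_pos <- as.integer(round_half_away(spec$positive_fraction * n))
    positive <- rep(FALSE, n)
    if (n_pos > 0) positive[sample.int(n, n_pos)] <- TRUE
    # 488 means drawn around the class centres but kept on the right side of
    # the classification cutoff (10) so labels stay exact ground truth
    mean488 <- ifelse(positive,
                      pmax(12, rnorm(n, spec$positive_488_mean, 2)),
                      pmin(8, pmax(0, rnorm(n, spec$negative_488_mean, 1))))
    px405 <- matrix(2, h, w)
    px488 <- matrix(0.5, h, w)
    for (k in seq_len(n)) {
      d <- disc_mask(h, w, centres[k, 1], centres[k, 2], radii[k])
      nd <- sum(d)
      # textured nuclear stain (high local entropy); near-uniform marker level
      px405[d] <- clip255(runif(nd, spec$nucleus_405_mean - 50,
                                spec$nucleus_405_mean + 50))
      px488[d] <- mean488[k]
    }
    if (spec$noise_sd > 0) {
      px405 <- px405 + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
      px488 <- px488 + matrix(rnorm(h * w, 0, spec$noise_sd / 2), h, w)
    }
    fid <- paste0("fluor_s", spec$seed)
    nuclei <- data.frame(nucleus = seq_len(n),
                         centre_row = centres[, 1], centre_col = centres[, 2],
                         radius = radii, mean_488_true = mean488,
                         positive = positive)
    list(frame405 = image_frame(clip255(px405), channel = "405", field_id = fid),
         frame488 = image_frame(clip255(px488), channel = "488", field_id = fid),
         truth = new_ground_truth("fluor_field", spec$seed,
                                  nuclei = nuclei, n_positive = n_pos,
                                  positive_pct = if (n > 0) 100 * n_pos / n else NA_real_))
  })
}

#' Generate a synthetic scratch-wound image series
#'
#' Each frame is a fully textured cell sheet with a central cell-free stripe;
#' the stripe narrows symmetrically so that its area at timepoint `t` equals
#' `A_0 * (1 - recovery_targets[t] / 100)` up to column rounding (well within
#' +/- 1 % of `A_0`). Ground truth stores every wound area in pixels.
#'
#' @param spec a [wound_series_spec()].
#' @return list with `frames` (list of [image_frame()]s, one per timepoint)
#'   and `truth` (`ground_truth` with `areas` data.frame).
#' @export
generate_wound_series <- function(spec) {
  stopifnot(inherits(spec, "wound_series_spec"))
  withr::with_seed(spec$seed, {
    vertical <- spec$wound_orientation == "vertical"
    h <- spec$height; w <- spec$width
    span <- if (vertical) w else h
    depth <- if (vertical) h else w
    w0 <- round(spec$initial_wound_fraction * span)
    if (w0 < 2) stop_input("initial wound too narrow")
    frames <- vector("list", length(spec$timepoints))
    area_px <- integer(length(spec$timepoints))
    centre <- (span + 1) / 2
    for (t in seq_along(spec$timepoints)) {
      a_target <- w0 * depth * (1 - spec$recovery_targets[t] / 100)
      wt <- round(a_target / depth)
      mask <- matrix(TRUE, h, w)  # cells everywhere...
      if (wt > 0) {
        lo <- floor(centre - wt / 2) + 1L
        cols <- seq(lo, length.out = wt)
        if (vertical) mask[, cols] <- FALSE else mask[cols, ] <- FALSE
      }
      px <- render_texture(mask, spec$texture_contrast, spec$background_level,
                           spec$noise_sd)
      frames[[t]] <- image_frame(px, channel = "phase",
                                 timepoint = spec$timepoints[t],
                                 field_id = paste0("wound_s", spec$seed))
      area_px[t] <- sum(!mask)
    }
    truth <- new_ground_truth("wound_series", spec$seed,
                              areas = data.frame(timepoint = spec$timepoints,
                                                 wound_area_px = area_px,
                                                 recovery_target = spec$recovery_targets),
                              baseline_area_px = area_px[1])
    list(frames = frames, truth = truth)
  })
}

#' Solubilisation curve container
#'
#' Concentration versus absorbance-difference data for CMC estimation
#' (dye absorbance difference at 376 vs 400 nm) or shedding quantitation
#' (377 vs 396 nm).
#'
#' @param concentration wt%, strictly positive.
#' @param delta_absorbance absorbance-difference values, same length.
#' @param wavelength_pair nm tuple, for provenance.
#' @param temperature degrees C, for provenance.
#' @return an object of class `solubilisation_curve` (a data.frame).
#' @export
solubilisation_curve <- function(concentration, delta_absorbance,
                                 wavelength_pair = c(376, 400),
                                 temperature = 37) {
  if (length(concentration) != length(delta_absorbance))
    stop_input("concentration and delta_absorbance lengths differ")
  if (any(concentration <= 0)) stop_input("concentrations must be > 0")
  o <- order(concentration)
  structure(data.frame(concentration = concentration[o],
                       delta_absorbance = delta_absorbance[o]),
            wavelength_pair = wavelength_pair, temperature = temperature,
            class = c("solubilisation_curve", "data.frame"))
}

#' Generate a synthetic dye-solubilisation curve
#'
#' Evaluates the continuous two-segment piecewise-linear model of the spec at
#' its concentrations and adds Gaussian noise.
#'
#' @param spec a [solubilisation_spec()].
#' @return a [solubilisation_curve()] with attribute `truth` (a
#'   `ground_truth` holding the breakpoint and slopes).
#' @export
generate_solubilisation <- function(spec) {
  stopifnot(inherits(spec, "solubilisation_spec"))
  withr::with_seed(spec$seed, {
    cc <- spec$concentrations
    y <- ifelse(cc <= spec$breakpoint,
                spec$intercept + spec$unimeric_slope * cc,
                spec$intercept + spec$unimeric_slope * spec$breakpoint +
                  spec$micellar_slope * (cc - spec$breakpoint))
    if (spec$noise_sd > 0) y <- y + rnorm(length(cc), 0, spec$noise_sd)
    curve <- solubilisation_curve(cc, y)
    attr(curve, "truth") <- new_ground_truth("solubilisation", spec$seed,
                                             breakpoint = spec$breakpoint,
                                             unimeric_slope = spec$unimeric_slope,
                                             micellar_slope = spec$micellar_slope,
                                             intercept = spec$intercept)
    curve
  })
}

#' Ct table container
#'
#' Long-format qPCR cycle thresholds with the reference (housekeeping) gene
#' and control condition recorded as attributes.
#'
#' @param data data.frame with columns `gene`, `condition`, `replicate`, `ct`.
#' @param reference_gene housekeeping gene identifier present in `gene`.
#' @param control_condition control condition identifier present in
#'   `condition`.
#' @return an object of class `ct_table` (a data.frame).
#' @export
ct_table <- function(data, reference_gene, control_condition) {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(data)))
    stop_input("ct table needs columns: ", paste(need, collapse = ", "))
  if (!reference_gene %in% data$gene)
    stop_input("reference gene '", reference_gene, "' absent from table")
  if (!control_condition %in% data$condition)
    stop_input("control condition '", control_condition, "' absent from table")
  if (any(!is.finite(data$ct))) stop_input("non-finite Ct values")
  structure(as.data.frame(data), reference_gene = reference_gene,
            control_condition = control_condition,
            class = c("ct_table", "data.frame"))
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' The reference gene sits at `base_ct` in every condition; each target
#' gene's control Ct is `base_ct + 5` and its Ct under any other condition is
#' the control Ct minus the true log2 fold change, so the noiseless
#' comparative-CT computation recovers the spec's fold changes exactly.
#' Replicates are perturbed by `ct_noise_sd`.
#'
#' @param spec a [ct_table_spec()].
#' @return a [ct_table()] with attribute `truth` (log2 fold-change matrix).
#' @export
generate_ct_table <- function(spec) {
  stopifnot(inherits(spec, "ct_table_spec"))
  withr::with_seed(spec$seed, {
    grid <- expand.grid(gene = c(spec$reference_gene, spec$genes),
                        condition = spec$conditions,
                        replicate = seq_len(spec$replicates),
                        stringsAsFactors = FALSE)
    ct0 <- mapply(function(g, cond) {
      if (g == spec$reference_gene) spec$base_ct
      else spec$base_ct + 5 - spec$true_log2_fold_changes[g, cond]
    }, grid$gene, grid$condition)
    grid$ct <- ct0 + if (spec$ct_noise_sd > 0)
      rnorm(nrow(grid), 0, spec$ct_noise_sd) else 0
    tab <- ct_table(grid, spec$reference_gene, spec$conditions[1])
    attr(tab, "truth") <- new_ground_truth("ct_table", spec$seed,
                                           true_log2_fold_changes = spec$true_log2_fold_changes)
    tab
  })
}
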