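#' Read and validate a pipeline manifest
#'
#' A manifest is a CSV with columns `assay`, `condition`, `replicate`,
#' `field`, `channel`, `timepoint`, `path` (paths relative to the manifest's
#' directory or absolute). Validation is fail-fast with row-level
#' diagnostics: missing files and duplicate (assay, field, channel,
#' timepoint) keys are reported with their row numbers.
#'
#' @param path manifest CSV path.
#' @return a `manifest` data.frame with resolved absolute paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_input("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay", "condition", "replicate", "field", "channel", "timepoint", "path")
  if (!all(need %in% names(m)))
    stop_input("manifest needs columns: ", paste(need, collapse = ", "))
  if (nrow(m) == 0) stop_input("manifest is empty")
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path, file.path(base, m$path))
  missing <- which(!file.exists(abs) & nzchar(m$path))
  if (length(missing))
    stop_input("manifest references missing files (rows ",
               paste(missing, collapse = ", "), "): ",
               paste(head(m$path[missing], 5), collapse = ", "))
  key <- paste(m$assay, m$field, m$channel, m$timepoint)
  dup <- which(duplicated(key))
  if (length(dup))
    stop_input("duplicate (assay, field, channel, timepoint) rows: ",
               paste(dup, collapse = ", "))
  m$path <- abs
  class(m) <- c("manifest", "data.frame")
  m
}

#' Simulate a complete on-disk demo dataset
#'
#' Writes seeded synthetic inputs for the selected assays into `dir`:
#' single-channel TIFFs named `{assay}_{field}_{channel}_t{###}.tif`, CSV
#' curve/table inputs, JSON ground-truth sidecars, and a `manifest.csv`
#' ready for [run_pipeline()].
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed; per-file seeds are derived from it.
#' @param assays subset of `c("confluence", "ki67", "wound", "cmc", "ldh",
#'   "ddct")`.
#' @param n_replicates image replicates per assay (kept small by default:
#'   this is a demonstration dataset).
#' @param config generator sizing knobs: a named list overriding fields of
#'   the default generator specs.
#' @return the manifest path, invisibly.
#' @export
simulate_dataset <- function(dir, seed = 1,
                             assays = c("confluence", "ki67", "wound", "cmc",
                                        "ldh", "ddct"),
                             n_replicates = 2, config = list()) {
  assays <- match.arg(assays, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  add_row <- function(assay, condition, replicate, field, channel, timepoint, path) {
    rows[[length(rows) + 1L]] <<- data.frame(
      assay = assay, condition = condition, replicate = replicate,
      field = field, channel = channel, timepoint = timepoint,
      path = basename(path))
  }
  if ("confluence" %in% assays) {
    # logistic-like confluence trajectory sampled at 4 timepoints
    targets <- c(20, 40, 62, 80)
    tps <- c(0, 24, 48, 72)
    for (r in seq_len(n_replicates)) {
      for (t in seq_along(tps)) {
        s <- seed * 1000L + r * 10L + t
        g <- generate_phase_field(phase_field_spec(
          height = 192, width = 192, confluence_target = targets[t], seed = s))
        fid <- sprintf("conf_r%d", r)
        p <- file.path(dir, sprintf("confluence_%s_phase_t%03d.tif", fid, tps[t]))
        write_image_frame(g$frame, p)
        write_ground_truth(g$truth, sub("\\.tif$", "_truth.json", p))
        add_row("confluence", "media", r, fid, "phase", tps[t], p)
      }
    }
  }
  if ("ki67" %in% assays) {
    for (r in seq_len(n_replicates)) {
      s <- seed * 1000L + 500L + r
      g <- generate_fluor_field(fluor_field_spec(
        height = 384, width = 384, n_nuclei = 40, positive_fraction = 0.35,
        seed = s))
      fid <- sprintf("ki67_r%d", r)
      p405 <- file.path(dir, sprintf("ki67_%s_405_t000.tif", fid))
      p488 <- file.path(dir, sprintf("ki67_%s_488_t000.tif", fid))
      write_image_frame(g$frame405, p405)
      write_image_frame(g$frame488, p488)
      write_ground_truth(g$truth, sub("\\.tif$", "_truth.json", p405))
      add_row("ki67", "media", r, fid, "405", 0, p405)
      add_row("ki67", "media", r, fid, "488", 0, p488)
    }
  }
  if ("wound" %in% assays) {
    for (r in seq_len(n_replicates)) {
      s <- seed * 1000L + 700L + r
      spec <- wound_series_spec(height = 256, width = 512, seed = s)
      g <- generate_wound_series(spec)
      fid <- sprintf("wound_w%d", r)
      for (t in seq_along(spec$timepoints)) {
        p <- file.path(dir, sprintf("wound_%s_phase_t%03d.tif", fid, spec$timepoints[t]))
        write_image_frame(g$frames[[t]], p)
        add_row("wound", "media", r, fid, "phase", spec$timepoints[t], p)
      }
      write_ground_truth(g$truth, file.path(dir, sprintf("wound_%s_truth.json", fid)))
    }
  }
  if ("cmc" %in% assays) {
    # noise at typical plate-reader repeatability (~0.01 AU); the two-line
    # intersection is noise-sensitive on log-spaced designs (see estimate_cmc)
    curve <- generate_solubilisation(solubilisation_spec(
      noise_sd = 0.01, seed = seed * 1000L + 900L))
    p <- file.path(dir, "cmc_curve.csv")
    write.csv(as.data.frame(curve), p, row.names = FALSE)
    write_ground_truth(attr(curve, "truth"), file.path(dir, "cmc_curve_truth.json"))
    add_row("cmc", "polymer", 1, "curve", "", NA, p)
  }
  if ("ldh" %in% assays) {
    withr::with_seed(seed * 1000L + 950L, {
      ldh <- data.frame(
        well = sprintf("w%d", 1:9),
        role = rep(c("medium_blank", "lysis_control", "sample"), each = 3),
        a490 = c(rnorm(3, 0.11, 0.004), rnorm(3, 1.32, 0.02), rnorm(3, 0.16, 0.01)),
        a690 = rnorm(9, 0.05, 0.002))
    })
    p <- file.path(dir, "ldh_plate.csv")
    write.csv(ldh, p, row.names = FALSE)
    add_row("ldh", "media", 1, "plate", "", NA, p)
  }
  if ("ddct" %in% assays) {
    tab <- generate_ct_table(ct_table_spec(ct_noise_sd = 0.15,
                                           seed = seed * 1000L + 990L))
    p <- file.path(dir, "qpcr_ct.csv")
    write.csv(as.data.frame(tab), p, row.names = FALSE)
    write_ground_truth(attr(tab, "truth"), file.path(dir, "qpcr_ct_truth.json"))
    add_row("ddct", "qpcr", 1, "plate", "", NA, p)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' @noRd
write_csv_out <- function(df, out_dir, name) {
  p <- file.path(out_dir, name)
  write.csv(df, p, row.names = FALSE)
  p
}

#' Run the analysis pipeline over a manifest
#'
#' Dispatches every assay present in the manifest to its quantification
#' pipeline and writes per-sample CSVs plus condition summaries to
#' `out_dir`, together with a machine-readable run log (`run_log.json`)
#' recording the package version, the resolved imaging configuration and the
#' seed. Outputs are a pure function of (manifest, config, seed): a rerun is
#' byte-identical.
#'
#' @param manifest_path path to a manifest CSV (see [read_manifest()]).
#' @param out_dir output directory (created if needed).
#' @param config a [filter_config()].
#' @param reference_gene,control_condition comparative-CT settings for
#'   `ddct` rows.
#' @param seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(manifest_path, out_dir, config = filter_config(),
                         reference_gene = "Gapdh",
                         control_condition = NULL, seed = 0) {
  m <- read_manifest(manifest_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  if (any(m$assay == "confluence")) {
    mc <- m[m$assay == "confluence", ]
    recs <- do.call(rbind, lapply(seq_len(nrow(mc)), function(i) {
      fr <- read_image_frame(mc$path[i], channel = "phase",
                             timepoint = mc$timepoint[i], field_id = mc$field[i])
      cbind(condition = mc$condition[i], replicate = mc$replicate[i],
            confluence_from_phase(fr, config))
    }))
    attr(recs, "mask") <- NULL
    outputs$confluence <- write_csv_out(recs, out_dir, "confluence_per_field.csv")
    outputs$growth <- write_csv_out(as.data.frame(growth_curve(recs)),
                                    out_dir, "growth_curve.csv")
  }
  if (any(m$assay == "ki67")) {
    mk <- m[m$assay == "ki67", ]
    fields <- unique(mk$field)
    quant <- do.call(rbind, lapply(fields, function(f) {
      p405 <- mk$path[mk$field == f & mk$channel == "405"]
      p488 <- mk$path[mk$field == f & mk$channel == "488"]
      if (length(p405) != 1 || length(p488) != 1)
        stop_input("ki67 field ", f, " needs exactly one 405 and one 488 frame")
      fr405 <- read_image_frame(p405, channel = "405", field_id = f)
      fr488 <- read_image_frame(p488, channel = "488", field_id = f)
      regions <- segment_nuclei(fr405, fr488, config)
      q <- classify_ki67(regions, field_id = f)
      q$nuclear_mfi_488 <- nuclear_mfi(regions)
      cbind(condition = mk$condition[mk$field == f][1],
            replicate = mk$replicate[mk$field == f][1], q)
    }))
    outputs$ki67 <- write_csv_out(quant, out_dir, "ki67_per_field.csv")
  }
  if (any(m$assay == "wound")) {
    mw <- m[m$assay == "wound", ]
    traj <- do.call(rbind, lapply(unique(mw$field), function(wl) {
      rows <- mw[mw$field == wl, ]
      rows <- rows[order(rows$timepoint), ]
      areas <- vapply(seq_len(nrow(rows)), function(i) {
        fr <- read_image_frame(rows$path[i], channel = "phase",
                               timepoint = rows$timepoint[i], field_id = wl)
        sum(wound_mask(fr, config))
      }, numeric(1))
      cbind(condition = rows$condition[1],
            wound_recovery(areas, rows$timepoint, well_id = wl))
    }))
    outputs$wound <- write_csv_out(traj, out_dir, "wound_trajectories.csv")
    tps <- setdiff(sort(unique(traj$timepoint)), 0)
    outputs$wound_summary <- write_csv_out(
      as.data.frame(recovery_summary(traj, timepoints = tps)),
      out_dir, "wound_summary.csv")
  }
  if (any(m$assay == "cmc")) {
    for (p in m$path[m$assay == "cmc"]) {
      curve <- read.csv(p)
      fit <- estimate_cmc(curve)
      rep_path <- file.path(out_dir, paste0(sub("\\.csv$", "", basename(p)),
                                            "_cmc.json"))
      jsonlite::write_json(list(cmc_wt_pct = fit$cmc,
                                split_index = fit$split_index,
                                sse_total = fit$sse_total,
                                left_line = as.list(fit$left_line),
                                right_line = as.list(fit$right_line),
                                diagnostics = fit$diagnostics),
                           rep_path, digits = NA, auto_unbox = TRUE)
      outputs$cmc <- rep_path
    }
  }
  if (any(m$assay == "ldh")) {
    for (p in m$path[m$assay == "ldh"]) {
      rel <- ldh_release(read.csv(p))
      outputs$ldh <- write_csv_out(as.data.frame(rel), out_dir,
                                   paste0(sub("\\.csv$", "", basename(p)),
                                          "_release.csv"))
    }
  }
  if (any(m$assay == "ddct")) {
    for (p in m$path[m$assay == "ddct"]) {
      raw <- read.csv(p)
      ctrl <- if (is.null(control_condition)) raw$condition[1] else control_condition
      fc <- ddct_fold_change(ct_table(raw, reference_gene, ctrl))
      outputs$ddct <- write_csv_out(as.data.frame(fc), out_dir,
                                    paste0(sub("\\.csv$", "", basename(p)),
                                           "_foldchange.csv"))
    }
  }
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(list(
    package = "rpequant",
    version = as.character(utils::packageVersion("rpequant")),
    seed = seed, manifest = basename(manifest_path),
    n_manifest_rows = nrow(m),
    config = unclass(config),
    outputs = lapply(outputs, basename)),
    log_path, digits = NA, auto_unbox = TRUE)
  outputs$run_log <- log_path
  invisible(outputs)
}
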