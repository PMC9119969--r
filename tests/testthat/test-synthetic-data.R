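test_that("phase field generator hits its confluence target and is seeded", {
  spec <- phase_field_spec(height = 160, width = 160, confluence_target = 40,
                           seed = 4)
  g1 <- generate_phase_field(spec)
  g2 <- generate_phase_field(spec)
  expect_identical(g1$frame$pixels, g2$frame$pixels)  # bit-exact determinism
  expect_identical(g1$truth$mask, g2$truth$mask)
  expect_lt(abs(g1$truth$confluence_pct - 40), 1)     # +/- 1 point contract
  expect_equal(g1$truth$confluence_pct, 100 * mean(g1$truth$mask))
  # a different seed gives a different field
  g3 <- generate_phase_field(phase_field_spec(height = 160, width = 160,
                                              confluence_target = 40, seed = 5))
  expect_false(identical(g1$frame$pixels, g3$frame$pixels))
})

test_that("phase field extremes work: 0 and 100 percent confluence", {
  g0 <- generate_phase_field(phase_field_spec(height = 96, width = 96,
                                              confluence_target = 0))
  expect_equal(sum(g0$truth$mask), 0)
  g100 <- generate_phase_field(phase_field_spec(height = 96, width = 96,
                                                confluence_target = 100))
  expect_equal(mean(g100$truth$mask), 1)
})

test_that("phase field pixels stay in [0, 255]", {
  g <- generate_phase_field(phase_field_spec(height = 96, width = 96,
                                             confluence_target = 60, noise_sd = 10))
  expect_gte(min(g$frame$pixels), 0)
  expect_lte(max(g$frame$pixels), 255)
})

test_that("phase field spec validates", {
  expect_error(phase_field_spec(confluence_target = 120), "\\[0, 100\\]")
  expect_error(phase_field_spec(height = 10), ">= 64")
  expect_error(phase_field_spec(cell_radius_range = c(9, 4)), "min <= max")
  expect_error(phase_field_spec(noise_sd = -1), ">= 0")
})

test_that("fluor field generator respects count, fraction and separation", {
  spec <- fluor_field_spec(height = 300, width = 300, n_nuclei = 20,
                           positive_fraction = 0.35, seed = 8)
  g <- generate_fluor_field(spec)
  nu <- g$truth$nuclei
  expect_equal(nrow(nu), 20L)
  expect_equal(sum(nu$positive), as.integer(round(0.35 * 20)))
  expect_equal(g$truth$n_positive, sum(nu$positive))
  # pairwise separation contract
  d2 <- as.matrix(dist(nu[, c("centre_row", "centre_col")]))^2
  diag(d2) <- Inf
  expect_gte(min(d2), spec$min_separation^2)
  # positives strictly above the 10-cutoff, negatives at or below
  expect_true(all(nu$mean_488_true[nu$positive] > 10))
  expect_true(all(nu$mean_488_true[!nu$positive] <= 10))
  # determinism
  g2 <- generate_fluor_field(spec)
  expect_identical(g$frame405$pixels, g2$frame405$pixels)
  expect_identical(g$frame488$pixels, g2$frame488$pixels)
})

test_that("fluor field spec guards the classification margin", {
  expect_error(fluor_field_spec(positive_488_mean = 9), "positive_488_mean")
  expect_error(fluor_field_spec(negative_488_mean = 11), "positive_488_mean")
  expect_error(fluor_field_spec(positive_fraction = 1.2), "\\[0, 1\\]")
})

test_that("impossible nucleus packing errors out rather than looping", {
  expect_error(
    generate_fluor_field(fluor_field_spec(height = 100, width = 100,
                                          n_nuclei = 50)),
    "packing")
})

test_that("wound series areas follow the prescribed recovery trajectory", {
  spec <- wound_series_spec(height = 200, width = 400,
                            recovery_targets = c(0, 30, 55, 75), seed = 2)
  g <- generate_wound_series(spec)
  ar <- g$truth$areas
  a0 <- g$truth$baseline_area_px
  realised <- 100 * (a0 - ar$wound_area_px) / a0
  expect_equal(ar$recovery_target, c(0, 30, 55, 75))
  expect_lt(max(abs(realised - ar$recovery_target)), 1)  # within 1 % of A0
  expect_equal(length(g$frames), 4L)
  expect_equal(vapply(g$frames, function(f) f$timepoint, numeric(1)),
               c(0, 12, 24, 36))
})

test_that("wound series spec validates monotone recovery and timepoints", {
  expect_error(wound_series_spec(timepoints = c(0, 12), recovery_targets = c(0)),
               "equal length")
  expect_error(wound_series_spec(timepoints = c(1, 12, 24, 36)), "start at 0")
  expect_error(wound_series_spec(recovery_targets = c(0, 50, 40, 75)),
               "nondecreasing")
  expect_error(wound_series_spec(initial_wound_fraction = 0), "\\(0, 1\\)")
})

test_that("solubilisation generator is exact when noiseless", {
  spec <- solubilisation_spec(breakpoint = 0.03, unimeric_slope = 0.5,
                              micellar_slope = 10, intercept = 0.05,
                              noise_sd = 0)
  cur <- generate_solubilisation(spec)
  below <- cur$concentration <= 0.03
  expect_equal(cur$delta_absorbance[below],
               0.05 + 0.5 * cur$concentration[below])
  expect_equal(cur$delta_absorbance[!below],
               0.05 + 0.5 * 0.03 + 10 * (cur$concentration[!below] - 0.03))
  expect_equal(attr(cur, "truth")$breakpoint, 0.03)
})

test_that("solubilisation spec validates the breakpoint position", {
  expect_error(solubilisation_spec(breakpoint = 2), "inside")
  expect_error(solubilisation_spec(unimeric_slope = 5, micellar_slope = 1),
               "micellar_slope")
  expect_error(solubilisation_spec(concentrations = c(-1, 1)), "> 0")
})

test_that("ct table generator encodes fold changes exactly when noiseless", {
  spec <- ct_table_spec(ct_noise_sd = 0)
  tab <- generate_ct_table(spec)
  expect_s3_class(tab, "ct_table")
  # reference gene constant across conditions
  ref <- tab[tab$gene == "Gapdh", ]
  expect_equal(unique(ref$ct), 18)
  # target Ct = control Ct - lfc
  nqo1 <- tab[tab$gene == "Nqo1", ]
  expect_equal(unique(nqo1$ct[nqo1$condition == "media"]), 23)
  expect_equal(unique(nqo1$ct[nqo1$condition == "polyCEP"]), 22)  # lfc +1
})

test_that("ct table spec validates the control column and reference gene", {
  expect_error(ct_table_spec(true_log2_fold_changes =
                               matrix(c(1, 0, 0, 1, 2, -1), 3, 2)),
               "control")
  expect_error(ct_table_spec(genes = c("Gapdh", "Nqo1", "X"),
                             true_log2_fold_changes = matrix(0, 3, 2)),
               "reference_gene")
})

test_that("ground truth sidecars round-trip through JSON losslessly", {
  g <- generate_phase_field(phase_field_spec(height = 64, width = 64,
                                             confluence_target = 30, seed = 3))
  p <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(g$truth, p)
  back <- read_ground_truth(p)
  expect_equal(matrix(as.logical(back$mask), 64, 64),
               matrix(as.logical(g$truth$mask), 64, 64))
  expect_equal(back$confluence_pct, g$truth$confluence_pct)
  expect_equal(back$assay, "phase_field")
  # data.frame fields must come back as data.frames (rows format)
  f <- generate_fluor_field(fluor_field_spec(height = 96, width = 96,
                                             n_nuclei = 4, seed = 2))
  p2 <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(f$truth, p2)
  back2 <- read_ground_truth(p2)
  expect_s3_class(back2$nuclei, "data.frame")
  expect_equal(nrow(back2$nuclei), 4L)
  expect_equal(back2$nuclei$mean488, f$truth$nuclei$mean488)
})

test_that("image frames round-trip through float TIFF", {
  g <- generate_phase_field(phase_field_spec(height = 64, width = 64,
                                             confluence_target = 50, seed = 6))
  p <- withr::local_tempfile(fileext = ".tif")
  write_image_frame(g$frame, p)
  back <- read_image_frame(p, channel = "phase")
  expect_equal(back$pixels, g$frame$pixels, tolerance = 1e-6)
})
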