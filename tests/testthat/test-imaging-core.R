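test_that("gaussian_denoise preserves constants and mass (DC gain 1)", {
  m <- matrix(7.5, 20, 30)
  expect_equal(gaussian_denoise(m, 2), m)
  set.seed(42)
  r <- matrix(runif(400, 0, 255), 20, 20)
  sm <- gaussian_denoise(r, 1.5)
  # smoothing shrinks variance but a reflective-padded unit-sum kernel cannot
  # change the range bounds
  expect_lt(var(as.vector(sm)), var(as.vector(r)))
  expect_gte(min(sm), min(r))
  expect_lte(max(sm), max(r))
})

test_that("gaussian_denoise is symmetric: flipping commutes with filtering", {
  set.seed(7)
  m <- matrix(runif(600, 0, 255), 20, 30)
  flip <- function(x) x[nrow(x):1, ncol(x):1]
  expect_equal(gaussian_denoise(flip(m), 2), flip(gaussian_denoise(m, 2)))
})

test_that("gaussian_denoise validates input", {
  expect_error(gaussian_denoise(matrix(1, 10, 10), sigma = 0), "sigma")
  expect_error(gaussian_denoise(matrix(c(NA, 1:99), 10, 10), 1), "finite")
})

test_that("dog_bandpass removes constants and requires sigma_low < sigma_high", {
  m <- matrix(100, 30, 30)
  expect_equal(dog_bandpass(m, 2, 8), matrix(0, 30, 30))
  expect_error(dog_bandpass(m, 8, 2), "sigma_low")
})

test_that("local_entropy matches the brute-force oracle on small images", {
  set.seed(11)
  imgs <- list(
    matrix(runif(15 * 15, 0, 255), 15, 15),
    matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32),
    matrix(rep(c(0, 255), length.out = 13 * 17), 13, 17),
    matrix(seq(0, 255, length.out = 11 * 11), 11, 11)
  )
  for (img in imgs) {
    for (w in c(3, 5, 9)) {
      expect_equal(local_entropy(img, w), entropy_oracle(img, w),
                   tolerance = 1e-12)
    }
  }
})

test_that("local_entropy of a constant image is zero everywhere", {
  expect_equal(local_entropy(matrix(42, 12, 12), 9), matrix(0, 12, 12))
})

test_that("local_entropy of a two-value checkerboard is the two-class bound", {
  m <- matrix(0, 18, 18)
  m[(row(m) + col(m)) %% 2 == 0] <- 255
  ent <- local_entropy(m, 9)
  # every 9 x 9 window holds 40 of one value and 41 of the other (reflection
  # preserves the parity pattern), so entropy is H(40/81) everywhere
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(ent, matrix(h(40 / 81), 18, 18), tolerance = 1e-12)
  expect_lte(max(ent), 1)
})

test_that("local_entropy of an isolated impulse is highest at the impulse", {
  m <- matrix(0, 21, 21)
  m[11, 11] <- 200
  ent <- local_entropy(m, 9)
  # windows containing the impulse: 1 pixel of 200, 80 of 0
  expect_equal(ent[11, 11], -(1 / 81) * log2(1 / 81) - (80 / 81) * log2(80 / 81),
               tolerance = 1e-12)
  expect_equal(ent[1, 1], 0)
})

test_that("local_entropy is invariant to monotone bin-preserving relabelling", {
  set.seed(3)
  m <- matrix(sample(c(10, 80, 160), 20 * 20, replace = TRUE), 20, 20)
  relab <- m
  relab[m == 10] <- 0; relab[m == 80] <- 100; relab[m == 160] <- 255
  expect_equal(local_entropy(m, 5), local_entropy(relab, 5))
})

test_that("local_entropy validates the window", {
  m <- matrix(0, 10, 10)
  expect_error(local_entropy(m, 4), "odd")
  expect_error(local_entropy(m, 1), "odd|>= 3")
  expect_error(local_entropy(m, 11), "fit")
})

test_that("entropy is bounded by log2 of window area and of 256", {
  set.seed(5)
  m <- matrix(runif(900, 0, 255), 30, 30)
  expect_lte(max(local_entropy(m, 3)), log2(9))
  expect_lte(max(local_entropy(m, 9)), log2(81))
  expect_gte(min(local_entropy(m, 9)), 0)
})

test_that("threshold_entropy separates a textured block from background", {
  set.seed(9)
  m <- matrix(30, 60, 60)
  m[20:45, 20:45] <- runif(26 * 26, 0, 255)  # many-valued texture
  ent <- local_entropy(m, 9)
  mask <- threshold_entropy(ent, filter_config())
  expect_true(all(mask[25:40, 25:40]))   # block interior detected
  expect_false(any(mask[1:10, 1:10]))    # far background clear
})

test_that("threshold_entropy warns and returns empty mask on a flat map", {
  expect_warning(mask <- threshold_entropy(matrix(0, 10, 10)), "degenerate")
  expect_false(any(mask))
})

test_that("fixed entropy threshold is honoured exactly", {
  ent <- matrix(c(1, 2, 3, 4), 2, 2)
  mask <- threshold_entropy(ent, filter_config(entropy_threshold = 2))
  expect_equal(matrix(as.logical(mask), 2, 2),
               matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))  # strict >
})

test_that("morphological_cleanup removes speckle and fills holes", {
  set.seed(2)
  m <- matrix(FALSE, 50, 50)
  m[10:40, 10:40] <- TRUE
  m[20:22, 20:22] <- FALSE          # interior hole -> filled
  speck <- m; speck[3, 3] <- TRUE   # isolated pixel -> opened away
  out <- morphological_cleanup(speck, filter_config())
  expect_false(out[3, 3])
  expect_true(all(out[20:22, 20:22]))
})

test_that("morphological opening+closing is idempotent on its own output", {
  set.seed(13)
  m <- matrix(runif(2500) > 0.5, 50, 50)
  cfg <- filter_config(fill_holes = FALSE, min_object_area = 0)
  once <- morphological_cleanup(m, cfg)
  twice <- morphological_cleanup(matrix(as.logical(once), 50, 50), cfg)
  expect_equal(matrix(as.logical(twice), 50, 50), matrix(as.logical(once), 50, 50))
})

test_that("boundary_erode shrinks the mask it is given", {
  m <- matrix(FALSE, 40, 40)
  m[10:30, 10:30] <- TRUE
  cfg <- filter_config(r_open = 0, r_close = 0, fill_holes = FALSE,
                       min_object_area = 0)
  er <- morphological_cleanup(m, cfg, boundary_erode = 3)
  expect_lt(sum(er), sum(m))
  expect_true(all(which(er) %in% which(m)))
})

test_that("label_regions labelling matches the flood-fill oracle", {
  set.seed(21)
  for (k in 1:5) {
    m <- matrix(runif(20 * 20) > 0.6, 20, 20)
    tab <- label_regions(m)
    orc <- label_oracle(m)
    expect_equal(nrow(tab), attr(orc, "n"))
    expect_equal(sum(tab$area), sum(m))
    # identical partition: label images agree up to renumbering
    lab <- rpequant:::label_components_cpp(m)
    agree <- table(lab[m], orc[m])
    expect_true(all(rowSums(agree > 0) == 1) && all(colSums(agree > 0) == 1))
  }
})

test_that("labelling is 8-connected: diagonal pixels join one component", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE
  expect_equal(nrow(label_regions(m)), 1L)
  # and 4-separated pixels with a gap stay distinct
  m2 <- matrix(FALSE, 5, 5)
  m2[1, 1] <- m2[1, 3] <- TRUE
  expect_equal(nrow(label_regions(m2)), 2L)
})

test_that("label_regions measures area, centroid and channel means", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE         # 3x3 square, centroid (3, 3)
  m[8:9, 8:9] <- TRUE         # 2x2 square, centroid (8.5, 8.5)
  ch <- matrix(0, 10, 10); ch[2:4, 2:4] <- 10; ch[8:9, 8:9] <- 50
  tab <- label_regions(m, list(sig = ch))
  tab <- tab[order(tab$area, decreasing = TRUE), ]
  expect_equal(tab$area, c(9L, 4L))
  expect_equal(tab$centroid_row, c(3, 8.5))
  expect_equal(tab$centroid_col, c(3, 8.5))
  expect_equal(tab$mean_sig, c(10, 50))
})

test_that("label_regions on an empty mask returns an empty table", {
  tab <- label_regions(matrix(FALSE, 5, 5), list(x = matrix(0, 5, 5)))
  expect_equal(nrow(tab), 0L)
  expect_true(all(c("label", "area", "centroid_row", "centroid_col", "mean_x")
                  %in% names(tab)))
})

test_that("label_regions rejects incongruent intensity frames", {
  expect_error(label_regions(matrix(TRUE, 5, 5), list(x = matrix(0, 4, 4))),
               "shape")
})
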