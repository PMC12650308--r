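test_that("spectrum smoothing averages with shrunken edge windows", {
  expect_equal(smooth_spectrum(rep(4, 7)), rep(4, 7))
  expect_equal(smooth_spectrum(c(0, 3, 0)), c(1.5, 1, 1.5))
  expect_equal(smooth_spectrum(c(0, 3, 0))[2], 1)
  expect_equal(smooth_spectrum(1:5, window = 1), 1:5)
  expect_equal(smooth_spectrum(c(1, 2, 3, 4), window = 3), c(1.5, 2, 3, 3.5))
  expect_error(smooth_spectrum(1:5, window = 2))
})

test_that("peak binning recovers well-separated planted peaks exactly", {
  g <- simulate_pixel_grid(15, 10, n_peaks = 50, mz_spacing = 1, seed = 3)
  bins <- bin_peaks(g, tolerance = 0.18, min_freq = 0.0384)
  expect_equal(nrow(bins$bins), 50)
  expect_true(all(bins$bins$detection_frequency >= 0.0384))
  expect_equal(nrow(bins$intensities), 150)
})

test_that("peaks within the tolerance merge into one bin", {
  spectra <- tidyr::expand_grid(x = 0:4, y = 0:4) |>
    dplyr::mutate(peaks = list(tibble::tibble(
      mz = c(100.00, 100.10, 200.00),
      intensity = c(50, 40, 30)
    ))) |>
    tidyr::unnest(peaks)
  bins <- bin_peaks(spectra, tolerance = 0.18, min_freq = 0)
  expect_equal(nrow(bins$bins), 2)
  # maximum-intensity interval processing: merged bin keeps the 50 peak
  merged <- which.min(abs(bins$bins$mz - 100))
  expect_equal(unname(bins$intensities[1, merged]), 50)
})

test_that("rare peaks below the detection-frequency floor are dropped", {
  g <- simulate_pixel_grid(25, 40,
    n_peaks = 20, mz_spacing = 1,
    n_rare = 2, rare_detect_rate = 0.01, seed = 4
  )
  all_bins <- bin_peaks(g, tolerance = 0.18, min_freq = 0)
  kept <- bin_peaks(g, tolerance = 0.18, min_freq = 0.0384)
  expect_equal(nrow(all_bins$bins), 22)
  expect_equal(nrow(kept$bins), 20)
  # raising the floor never increases the bin count
  freqs <- c(0, 0.005, 0.0384, 0.5, 1)
  counts <- vapply(
    freqs,
    function(f) nrow(bin_peaks(g, tolerance = 0.18, min_freq = f)$bins),
    numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("binning the bin centres is idempotent", {
  g <- simulate_pixel_grid(8, 8, n_peaks = 25, mz_spacing = 1, seed = 5)
  bins <- bin_peaks(g, tolerance = 0.18, min_freq = 0)
  centres <- tibble::tibble(
    x = 0, y = 0, mz = bins$bins$mz, intensity = 1
  )
  again <- bin_peaks(centres, tolerance = 0.18, min_freq = 0)
  expect_equal(again$bins$mz, bins$bins$mz, tolerance = 1e-9)
})

test_that("RMS normalization gives every pixel unit RMS", {
  mat <- rbind(c(3, 4), c(1, 1))
  out <- rms_normalize(mat)
  expect_equal(sqrt(rowMeans(out^2)), c(1, 1), tolerance = 1e-12)
  expect_equal(out[1, ], c(3, 4) / sqrt(12.5))
  # already unit RMS: unchanged
  expect_equal(rms_normalize(out), out, tolerance = 1e-12)
  # random grid postcondition
  g <- simulate_pixel_grid(10, 10, n_peaks = 15, mz_spacing = 1, seed = 6)
  bins <- rms_normalize(bin_peaks(g, min_freq = 0))
  expect_true(all(abs(sqrt(rowMeans(bins$intensities^2)) - 1) < 1e-12))
  bad <- rbind(c(1, 2), c(0, 0))
  expect_error(rms_normalize(bad), "All-zero pixel")
})

test_that("pixel clustering recovers planted tissue classes", {
  # three planted classes with distinct spectral profiles on a 12x6 grid
  set.seed(7)
  profiles <- list(c(100, 5, 5), c(5, 100, 5), c(5, 5, 100))
  cells <- tidyr::expand_grid(x = 0:11, y = 0:5) |>
    dplyr::mutate(class = 1 + (x >= 4) + (x >= 8))
  peaks <- purrr::pmap_dfr(cells, function(x, y, class) {
    tibble::tibble(
      x = x, y = y, mz = c(100, 200, 300),
      intensity = profiles[[class]] * runif(3, 0.95, 1.05)
    )
  })
  bins <- bin_peaks(peaks, tolerance = 0.18, min_freq = 0)
  seg <- cluster_pixels(rms_normalize(bins), k = 3)
  joined <- dplyr::left_join(seg$labels, cells, by = c("x", "y"))
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(joined$cluster, joined$class), 1.0)
  # contiguous 1-based ids, deterministic across runs
  expect_setequal(unique(seg$labels$cluster), 1:3)
  seg2 <- cluster_pixels(rms_normalize(bins), k = 3)
  expect_identical(seg$labels, seg2$labels)
  # duplicated pixels co-cluster
  expect_error(cluster_pixels(bins, k = 10000), "exceeds")
})

test_that("ROI differential analysis flags planted effects and is antisymmetric", {
  g <- simulate_pixel_grid(30, 30,
    n_peaks = 120, mz_spacing = 1, n_up = 7, n_down = 9,
    effect_log2fc = 2, noise_cv = 0.02, seed = 8
  )
  bins <- bin_peaks(g, min_freq = 0)
  d <- roi_differential(bins, "lesion", "contra", fc_threshold = 1)
  expect_equal(sum(d$pass & d$direction == "up"), 7)
  expect_equal(sum(d$pass & d$direction == "down"), 9)
  # swapping the ROIs negates every log2FC exactly
  d_rev <- roi_differential(bins, "contra", "lesion", fc_threshold = 1)
  expect_equal(d_rev$log2fc, -d$log2fc, tolerance = 1e-12)
  # identical ROIs give no passes
  same <- roi_differential(bins, "lesion", "lesion", fc_threshold = 1) |>
    try(silent = TRUE)
  expect_s3_class(same, "try-error") # identical masks are not disjoint
  expect_error(
    roi_differential(bins, rep(FALSE, 900), "contra"),
    "non-empty"
  )
  # simple arithmetic case with zero pseudocount
  tbl <- bins
  tbl$intensities <- matrix(c(rep(4, 450), rep(1, 450)), 900, 1)
  tbl$bins <- tbl$bins[1, ]
  roi_a <- c(rep(TRUE, 450), rep(FALSE, 450))
  one <- roi_differential(tbl, roi_a, !roi_a, pseudocount = 0)
  expect_equal(one$log2fc, 2)
  expect_true(one$pass)
})

test_that("pixel grids round-trip through long CSVs", {
  g <- simulate_pixel_grid(6, 5, n_peaks = 10, mz_spacing = 1, seed = 9)
  tmp <- withr::local_tempdir()
  write_pixel_grid(g, file.path(tmp, "g"))
  back <- read_pixel_grid(file.path(tmp, "g"))
  expect_equal(back$width, 6)
  expect_equal(nrow(back$peaks), nrow(g$peaks))
  bins1 <- bin_peaks(g, min_freq = 0)
  bins2 <- bin_peaks(back, min_freq = 0)
  expect_equal(bins1$bins$mz, bins2$bins$mz, tolerance = 1e-9)
})
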