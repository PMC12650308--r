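#' Smooth a spectrum with a centred moving average
#'
#' Three-point (by default) moving-average denoising along the m/z axis, the
#' "medium denoising" convention of imaging workflows. Edges use shrunken
#' windows so length is preserved.
#'
#' @param intensity Numeric vector of peak intensities ordered by m/z.
#' @param window Odd window width >= 1.
#' @return Smoothed vector of the same length.
#' @examples
#' smooth_spectrum(c(0, 3, 0))
#' @export
smooth_spectrum <- function(intensity, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1 || length(intensity) == 1) return(intensity)
  half <- (window - 1) / 2
  n <- length(intensity)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(intensity[lo:hi])
  }, numeric(1))
}

#' Bin pixel peaks into consensus m/z features
#'
#' Pools the peaks of all pixels and groups them into +/- `tolerance` Da
#' intervals around consensus centres found by greedy intensity-ordered
#' grouping: the strongest unclaimed peak founds a bin, claiming every peak
#' within the tolerance. Within a bin each pixel contributes its
#' maximum-intensity peak (interval processing mode "maximum"). Bins detected
#' in fewer than `min_freq` of all pixels are dropped.
#'
#' @param grid A `pixel_grid`, or a long tibble with columns `x`, `y`, `mz`,
#'   `intensity`.
#' @param tolerance Half-width of the bin interval in Da.
#' @param min_freq Minimum detection frequency (fraction of pixels in which a
#'   bin must contain a peak) for retention.
#' @param smooth_window Moving-average window applied per spectrum before
#'   binning (1 = off).
#' @return Object of class `peak_bin_table`: list with `intensities`
#'   (pixels x bins matrix, zero where undetected), `bins` (tibble `mz`,
#'   `detection_frequency`), `pixels` (coordinate tibble, with ROI masks when
#'   the input was a `pixel_grid`).
#' @export
bin_peaks <- function(grid, tolerance = 0.180, min_freq = 0.0384,
                      smooth_window = 1) {
  stopifnot(tolerance > 0, min_freq >= 0, min_freq <= 1)
  if (inherits(grid, "pixel_grid")) {
    peaks <- grid$peaks
    pixels <- grid$pixels
  } else {
    peaks <- tibble::as_tibble(grid)
    pixels <- dplyr::distinct(peaks[, c("x", "y")])
  }
  if (nrow(peaks) == 0) abort("No peaks to bin.")
  if (smooth_window > 1) {
    peaks <- peaks |>
      dplyr::group_by(.data$x, .data$y) |>
      dplyr::arrange(.data$mz, .by_group = TRUE) |>
      dplyr::mutate(intensity = smooth_spectrum(.data$intensity, smooth_window)) |>
      dplyr::ungroup()
  }

  ## greedy intensity-ordered consensus centres
  ord <- order(peaks$intensity, decreasing = TRUE)
  mz_sorted <- peaks$mz[ord]
  centers <- numeric(0)
  for (m in mz_sorted) {
    if (length(centers) == 0 || min(abs(centers - m)) > tolerance) {
      centers <- c(centers, m)
    }
  }
  centers <- sort(centers)
  if (length(centers) == 1 && length(unique(peaks$mz)) > 1) {
    warn("Tolerance merges all peaks into a single bin.")
  }

  ## assign every peak to the nearest centre within tolerance
  bin_of <- findInterval(peaks$mz, c(-Inf, centers[-1] - diff(centers) / 2))
  keep <- abs(peaks$mz - centers[bin_of]) <= tolerance
  peaks <- peaks[keep, , drop = FALSE]
  bin_of <- bin_of[keep]

  pixels <- dplyr::arrange(pixels, .data$y, .data$x)
  pix_key <- paste(peaks$x, peaks$y)
  pix_of <- match(pix_key, paste(pixels$x, pixels$y))

  n_pix <- nrow(pixels)
  n_bin <- length(centers)
  mat <- matrix(0, n_pix, n_bin)
  ## per pixel per bin keep the maximum-intensity peak
  o <- order(peaks$intensity) # later writes win, so ascending order
  mat[cbind(pix_of[o], bin_of[o])] <- peaks$intensity[o]
  detected <- matrix(FALSE, n_pix, n_bin)
  detected[cbind(pix_of, bin_of)] <- TRUE
  freq <- colMeans(detected)

  retain <- freq >= min_freq
  structure(
    list(
      intensities = mat[, retain, drop = FALSE],
      bins = tibble::tibble(
        mz = centers[retain],
        detection_frequency = freq[retain]
      ),
      pixels = pixels,
      tolerance = tolerance, min_freq = min_freq
    ),
    class = "peak_bin_table"
  )
}

#' @export
print.peak_bin_table <- function(x, ...) {
  cat(sprintf(
    "<peak_bin_table> %d pixels x %d bins (+/- %.3f Da, min detection %.2f%%)\n",
    nrow(x$intensities), nrow(x$bins), x$tolerance, 100 * x$min_freq
  ))
  invisible(x)
}

#' Root-mean-square normalization of pixel spectra
#'
#' Divides each pixel row of a binned intensity matrix by the root mean
#' square of its intensities, so every pixel has unit RMS afterwards.
#'
#' @param table A `peak_bin_table` (or bare pixels x bins matrix).
#' @return Same type as the input with normalized intensities.
#' @export
rms_normalize <- function(table) {
  mat <- if (inherits(table, "peak_bin_table")) table$intensities else table
  rms <- sqrt(rowMeans(mat^2))
  bad <- which(rms == 0)
  if (length(bad) > 0) {
    coords <- if (inherits(table, "peak_bin_table")) {
      sprintf("(%d, %d)", table$pixels$x[bad[1]], table$pixels$y[bad[1]])
    } else {
      sprintf("row %d", bad[1])
    }
    abort(sprintf("All-zero pixel %s cannot be RMS-normalized.", coords))
  }
  out <- mat / rms
  if (inherits(table, "peak_bin_table")) {
    table$intensities <- out
    table
  } else {
    out
  }
}

#' Segment pixels by hierarchical clustering of their spectra
#'
#' Agglomerative clustering of pixel intensity profiles under cosine
#' dissimilarity with Ward's linkage (the Lance-Williams Ward update applied
#' to the cosine dissimilarities), cut at `k` clusters.
#'
#' @param table A `peak_bin_table`.
#' @param k Number of clusters (2 <= k <= number of pixels).
#' @return Object of class `segmentation_result`: list with `labels` (tibble
#'   `x`, `y`, `cluster`), `k`, and the `hclust` tree.
#' @export
cluster_pixels <- function(table, k) {
  stopifnot(inherits(table, "peak_bin_table"))
  n_pix <- nrow(table$intensities)
  if (k > n_pix) abort("k exceeds the number of pixels.")
  stopifnot(k >= 2)
  d <- cosine_dissimilarity(table$intensities)
  tree <- hclust(stats::as.dist(d), method = "ward.D")
  cl <- cutree(tree, k = k)
  structure(
    list(
      labels = dplyr::mutate(table$pixels[, c("x", "y")], cluster = as.integer(cl)),
      k = as.integer(k),
      linkage = "ward", metric = "cosine",
      tree = tree
    ),
    class = "segmentation_result"
  )
}

cosine_dissimilarity <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  norms[norms == 0] <- 1
  sim <- tcrossprod(mat / norms)
  sim[sim > 1] <- 1
  1 - sim
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d pixels in %d clusters (cosine/Ward)\n",
    nrow(x$labels), x$k
  ))
  print(table(x$labels$cluster))
  invisible(x)
}

#' ROI differential analysis of binned features
#'
#' Compares each bin's mean intensity between two regions of interest and
#' flags bins whose absolute log2 fold change strictly exceeds the
#' threshold. A pseudocount guards against zero means.
#'
#' @param table A `peak_bin_table`.
#' @param roi_a,roi_b Logical vectors over the pixels of `table` (e.g. the
#'   `lesion` / `contra` masks carried over from [simulate_pixel_grid()]), or
#'   names of logical columns in `table$pixels`. Must be non-empty and
#'   disjoint.
#' @param fc_threshold Absolute log2 fold-change pass threshold.
#' @param pseudocount Added to both means before the ratio; default 1% of
#'   the global median positive intensity.
#' @return Tibble with one row per bin: `mz`, `mean_a`, `mean_b`, `log2fc`,
#'   `direction` (`"up"` / `"down"`), `pass`.
#' @export
roi_differential <- function(table, roi_a, roi_b, fc_threshold = 1,
                             pseudocount = NULL) {
  stopifnot(inherits(table, "peak_bin_table"))
  resolve <- function(roi) {
    if (is.character(roi) && length(roi) == 1) {
      if (!roi %in% names(table$pixels)) {
        abort(sprintf("No ROI mask column named '%s' in the pixel table.", roi))
      }
      roi <- table$pixels[[roi]]
    }
    stopifnot(is.logical(roi), length(roi) == nrow(table$intensities))
    roi
  }
  roi_a <- resolve(roi_a)
  roi_b <- resolve(roi_b)
  if (!any(roi_a) || !any(roi_b)) abort("ROI masks must be non-empty.")
  if (any(roi_a & roi_b)) abort("ROI masks must be disjoint.")
  if (is.null(pseudocount)) {
    pos <- table$intensities[table$intensities > 0]
    pseudocount <- if (length(pos)) 0.01 * median(pos) else 0
  }
  mean_a <- colMeans(table$intensities[roi_a, , drop = FALSE])
  mean_b <- colMeans(table$intensities[roi_b, , drop = FALSE])
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  tibble::tibble(
    mz = table$bins$mz,
    mean_a = mean_a, mean_b = mean_b,
    log2fc = log2fc,
    direction = ifelse(log2fc >= 0, "up", "down"),
    pass = abs(log2fc) > fc_threshold
  )
}
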