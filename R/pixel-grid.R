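#' Simulate a MALDI-imaging pixel grid
#'
#' Generates a rectangular grid of per-pixel mass spectra with a shared panel
#' of peaks, a lesion region of interest (ROI) and its mirrored contralateral
#' ROI, and a configurable number of peaks shifted up or down inside the
#' lesion. Peak m/z positions jitter slightly from pixel to pixel (as real
#' spectra do) but stay well inside the binning tolerance.
#'
#' @param width,height Grid dimensions in pixels.
#' @param n_peaks Number of consensus peaks present in every pixel.
#' @param mz_min First consensus peak position (Da).
#' @param mz_spacing Spacing between consensus peaks (Da); must exceed twice
#'   the intended binning tolerance so neighbouring peaks cannot merge.
#' @param mz_jitter_sd Per-pixel m/z jitter standard deviation (Da).
#' @param lesion Optional lesion specification,
#'   `list(cx =, cy =, radius =)` in pixel coordinates; default is a disc in
#'   the left hemifield. The contralateral ROI is its mirror across the
#'   vertical midline.
#' @param n_up,n_down Number of peaks planted up-/down-regulated inside the
#'   lesion ROI.
#' @param effect_log2fc Absolute planted log2 fold change (>= 1).
#' @param noise_cv CV of multiplicative intensity noise.
#' @param n_rare Number of additional rare peaks detected only in a
#'   `rare_detect_rate` fraction of pixels (for detection-frequency tests).
#' @param rare_detect_rate Detection rate of the rare peaks.
#' @param seed Integer seed.
#'
#' @return Object of class `pixel_grid`: list with `peaks` (long tibble
#'   `x`, `y`, `mz`, `intensity`), `pixels` (tibble of coordinates with
#'   logical `lesion` / `contra` masks), `truth` (per-peak tibble with
#'   consensus `mz` and planted `log2fc`), and the grid dimensions.
#' @examples
#' grid <- simulate_pixel_grid(12, 10, n_peaks = 30, n_up = 2, n_down = 3, seed = 1)
#' grid
#' @export
simulate_pixel_grid <- function(width = 40, height = 40,
                                n_peaks = 285,
                                mz_min = 100, mz_spacing = 3,
                                mz_jitter_sd = 0.02,
                                lesion = NULL,
                                n_up = 0, n_down = 0,
                                effect_log2fc = 2,
                                noise_cv = 0.02,
                                n_rare = 0, rare_detect_rate = 0.01,
                                seed = 1L) {
  stopifnot(
    width >= 2, height >= 1, n_peaks >= 1,
    n_up + n_down <= n_peaks, effect_log2fc >= 0, noise_cv >= 0
  )
  set.seed(seed)
  if (is.null(lesion)) {
    cx <- floor(width / 4)
    cy <- floor(height / 2)
    ## default radius: as large as fits inside the hemifield without
    ## touching the mirrored contralateral disc or the grid border
    radius <- min(
      floor(min(width, height) / 5),
      cx, cy, height - 1 - cy,
      floor((width - 1 - 2 * cx - 1) / 2)
    )
    lesion <- list(cx = cx, cy = cy, radius = max(1, radius))
  }
  if (lesion$cx - lesion$radius < 0 || lesion$cx + lesion$radius >= width ||
    lesion$cy - lesion$radius < 0 || lesion$cy + lesion$radius >= height) {
    abort("Lesion mask extends outside the grid.")
  }

  pixels <- tidyr::expand_grid(y = 0:(height - 1), x = 0:(width - 1)) |>
    dplyr::select("x", "y")
  in_disc <- function(x, y, cx, cy, r) (x - cx)^2 + (y - cy)^2 <= r^2
  pixels$lesion <- in_disc(pixels$x, pixels$y, lesion$cx, lesion$cy, lesion$radius)
  ## contralateral ROI: mirror across the vertical midline
  pixels$contra <- in_disc(
    pixels$x, pixels$y,
    width - 1 - lesion$cx, lesion$cy, lesion$radius
  )
  if (any(pixels$lesion & pixels$contra)) {
    abort("Lesion and contralateral masks overlap; move the lesion off-centre.")
  }
  n_pix <- nrow(pixels)

  mz_centers <- mz_min + mz_spacing * (seq_len(n_peaks) - 1)
  base_int <- rlnorm(n_peaks, meanlog = log(1000), sdlog = 0.5)
  effect <- rep(0, n_peaks)
  if (n_up + n_down > 0) {
    shifted <- sample(n_peaks, n_up + n_down)
    effect[shifted[seq_len(n_up)]] <- effect_log2fc
    if (n_down > 0) effect[shifted[n_up + seq_len(n_down)]] <- -effect_log2fc
  }

  ## dense layout: every consensus peak observed in every pixel
  peak_idx <- rep(seq_len(n_peaks), times = n_pix)
  pix_idx <- rep(seq_len(n_pix), each = n_peaks)
  intensity <- base_int[peak_idx] * 2^(effect[peak_idx] * pixels$lesion[pix_idx])
  if (noise_cv > 0) {
    sdl <- sqrt(log(1 + noise_cv^2))
    intensity <- intensity * rlnorm(length(intensity), -sdl^2 / 2, sdl)
  }
  mz <- mz_centers[peak_idx]
  if (mz_jitter_sd > 0) mz <- mz + rnorm(length(mz), 0, mz_jitter_sd)

  peaks <- tibble::tibble(
    x = pixels$x[pix_idx], y = pixels$y[pix_idx],
    mz = mz, intensity = intensity
  )
  truth <- tibble::tibble(mz = mz_centers, log2fc = effect, rare = FALSE)

  if (n_rare > 0) {
    rare_mz <- max(mz_centers) + mz_spacing * seq_len(n_rare)
    n_det <- max(1L, round(rare_detect_rate * n_pix))
    rare_rows <- purrr::map_dfr(seq_len(n_rare), function(j) {
      det <- sample(n_pix, n_det)
      tibble::tibble(
        x = pixels$x[det], y = pixels$y[det],
        mz = rare_mz[j], intensity = rlnorm(n_det, log(500), 0.3)
      )
    })
    peaks <- dplyr::bind_rows(peaks, rare_rows)
    truth <- dplyr::bind_rows(
      truth,
      tibble::tibble(mz = rare_mz, log2fc = 0, rare = TRUE)
    )
  }
  peaks <- dplyr::arrange(peaks, .data$y, .data$x, .data$mz)

  structure(
    list(
      peaks = peaks, pixels = pixels, truth = truth,
      width = as.integer(width), height = as.integer(height),
      pixel_size_um = 200
    ),
    class = "pixel_grid",
    parameters = list(
      n_peaks = n_peaks, n_up = n_up, n_down = n_down,
      effect_log2fc = effect_log2fc, noise_cv = noise_cv, seed = seed
    )
  )
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf(
    "<pixel_grid> %d x %d pixels, %d peak records, %d consensus peaks\n",
    x$width, x$height, nrow(x$peaks), nrow(x$truth)
  ))
  cat(sprintf(
    "  lesion pixels: %d, contralateral pixels: %d\n",
    sum(x$pixels$lesion), sum(x$pixels$contra)
  ))
  invisible(x)
}

#' Write / read a pixel grid as long CSVs
#'
#' Writes the peak list as a long CSV (`x`, `y`, `mz`, `intensity`) and the
#' ROI masks as a second CSV sharing `path` as prefix.
#'
#' @param grid A `pixel_grid`.
#' @param path File prefix.
#' @return `path`, invisibly.
#' @export
write_pixel_grid <- function(grid, path) {
  stopifnot(inherits(grid, "pixel_grid"))
  readr::write_csv(grid$peaks, paste0(path, "_peaks.csv"))
  readr::write_csv(grid$pixels, paste0(path, "_masks.csv"))
  jsonlite::write_json(
    c(attr(grid, "parameters"), list(width = grid$width, height = grid$height)),
    paste0(path, "_provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_pixel_grid
#' @export
read_pixel_grid <- function(path) {
  peaks <- readr::read_csv(paste0(path, "_peaks.csv"), show_col_types = FALSE)
  pixels <- readr::read_csv(paste0(path, "_masks.csv"), show_col_types = FALSE)
  structure(
    list(
      peaks = peaks, pixels = pixels, truth = NULL,
      width = max(pixels$x) + 1L, height = max(pixels$y) + 1L,
      pixel_size_um = 200
    ),
    class = "pixel_grid"
  )
}
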