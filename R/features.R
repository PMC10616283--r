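#' Discrete Fourier transform of a pixel sequence
#'
#' Computes `DFT_m = sum_{n=1..N} p_n * [cos(2*pi*m*n/N) - i*sin(2*pi*m*n/N)]`
#' for `m = 1..N` (note the 1-based phase convention: the last bin, not the
#' first, carries the DC term). Implemented through the FFT with a one-step
#' phase shift.
#'
#' @param signal non-empty finite numeric vector.
#' @return list with `spectrum` (complex, length N, indices m = 1..N) and
#'   `magnitude` (its modulus).
#' @export
dft_features <- function(signal) {
  n <- length(signal)
  if (n == 0) stop("empty signal")
  if (any(!is.finite(signal))) stop("signal must be finite")
  x <- stats::fft(signal)                    # X_k, k = 0..N-1
  m <- seq_len(n)
  spectrum <- x[(m %% n) + 1L] * exp(-2i * pi * m / n)
  list(spectrum = spectrum, magnitude = Mod(spectrum))
}

#' Orthonormal DCT-II of a signal
#'
#' `y_k = s_k * sum_{n=0..N-1} x_n cos(pi*(2n+1)*k/(2N))` with
#' `s_0 = sqrt(1/N)`, `s_k = sqrt(2/N)`, so the transform is orthonormal
#' (Parseval holds exactly). Computed through a single FFT of the
#' even-odd reordered signal.
#'
#' @param signal non-empty finite numeric vector.
#' @return numeric coefficient vector in natural order (DC first).
#' @export
dct_features <- function(signal) {
  n <- length(signal)
  if (n == 0) stop("empty signal")
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (n == 1) return(signal)
  idx <- c(seq(1, n, by = 2), rev(seq(2, n, by = 2)))
  v <- stats::fft(signal[idx])
  k <- 0:(n - 1)
  raw <- Re(v * exp(-1i * pi * k / (2 * n)))
  scale <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
  raw * scale
}

#' Real Gabor kernel
#'
#' `g(x, y) = exp(-(x'^2 + aspect^2 * y'^2) / (2 sigma^2)) *
#'  cos(2 pi x' / lambda)` with `(x', y')` the coordinates rotated by
#' `theta`. The kernel value at the origin is 1.
#'
#' @param lambda wavelength of the cosine carrier, px (> 0).
#' @param sigma Gaussian envelope standard deviation, px (> 0).
#' @param aspect spatial aspect ratio (> 0); values < 1 elongate the
#'   envelope orthogonally to the carrier.
#' @param theta orientation in radians.
#' @return numeric matrix (odd dimensions), the kernel.
#' @export
gabor_kernel <- function(lambda = 8, sigma = 4, aspect = 0.5, theta = 0) {
  if (lambda <= 0 || sigma <= 0) stop("lambda and sigma must be positive")
  if (aspect <= 0) stop("aspect must be positive")
  half <- ceiling(3 * sigma / min(1, aspect))
  g <- seq(-half, half)
  x <- matrix(rep(g, each = length(g)), length(g))   # column offset
  y <- matrix(g, length(g), length(g))               # row offset
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  exp(-(xr^2 + aspect^2 * yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda)
}

#' Gabor filter response of an image
#'
#' Convolves the image with [gabor_kernel()] (replicate border handling).
#'
#' @param image a [fundus_image] or numeric matrix.
#' @inheritParams gabor_kernel
#' @return numeric response matrix of the image's dimensions.
#' @export
gabor_response <- function(image, lambda = 8, sigma = 4, aspect = 0.5,
                           theta = 0) {
  px <- as_pixels(image)
  k <- gabor_kernel(lambda, sigma, aspect, theta)
  as.matrix(EBImage::filter2(px, k, boundary = "replicate"))
}

#' Haar pair wavelet: approximation and detail coefficients
#'
#' Over non-overlapping sample pairs: approximation `(p_n + p_{n+1}) / 2`
#' and detail `(p_n - p_{n+1}) / 2`. Odd-length signals are extended by
#' duplicating the last sample. The transform is exactly invertible:
#' `p_n = a + d`, `p_{n+1} = a - d`.
#'
#' @param signal non-empty finite numeric vector.
#' @return list with `approx` and `detail`, each of length `ceiling(N/2)`.
#' @export
haar_pair_wavelet <- function(signal) {
  n <- length(signal)
  if (n == 0) stop("empty signal")
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (n %% 2 == 1) signal <- c(signal, signal[n])
  odd <- signal[seq(1, length(signal), by = 2)]
  even <- signal[seq(2, length(signal), by = 2)]
  list(approx = (odd + even) / 2, detail = (odd - even) / 2)
}

#' Shannon entropy of a histogram of values
#'
#' Base-2 entropy of the occupancy of `bins` equal-width bins spanning the
#' observed min-max range. Bounded by `log2(bins)`; a constant input (zero
#' range) has entropy 0.
#'
#' @param values non-empty finite numeric vector.
#' @param bins number of histogram bins (>= 2).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(values, bins = 32) {
  if (length(values) == 0) stop("empty input")
  stopifnot(bins >= 2)
  rng <- range(values)
  if (diff(rng) <= .Machine$double.eps) return(0)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  cnt <- tabulate(.bincode(values, breaks, include.lowest = TRUE), nbins = bins)
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log2(p))
}

#' DRFV extraction configuration
#'
#' @param gabor_orientations carrier orientations in radians.
#' @param gabor_lambda,gabor_sigma,gabor_aspect Gabor kernel parameters.
#' @param entropy_bins histogram bins for the entropy statistic.
#' @return a list of class `drfv_config`.
#' @export
drfv_config <- function(gabor_orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                        gabor_lambda = 8, gabor_sigma = 4, gabor_aspect = 0.5,
                        entropy_bins = 32) {
  structure(list(gabor_orientations = gabor_orientations,
                 gabor_lambda = gabor_lambda, gabor_sigma = gabor_sigma,
                 gabor_aspect = gabor_aspect, entropy_bins = entropy_bins),
            class = "drfv_config")
}

drfv_channels <- c("image", "od", "macula", "vessels", "exudates",
                   "hemorrhages")
drfv_families <- c("pix", "dft", "dct", "gabor", "haar")
drfv_stats <- c("mean", "sd", "energy", "entropy")

# Four summary statistics of a coefficient vector; population sd so that a
# single coefficient gives 0, not NA. Energy is the mean square, so blocks
# are comparable across channels of different pixel counts.
stat_block <- function(x, bins) {
  if (length(x) == 0) return(c(0, 0, 0, 0))
  mu <- mean(x)
  c(mu, sqrt(mean((x - mu)^2)), mean(x^2), shannon_entropy(x, bins))
}

#' Descriptor names of the DRFV, in extraction order
#'
#' @param config a [drfv_config].
#' @return character vector `channel.family.statistic`, length
#'   `6 * 5 * 4 = 120` under the default configuration.
#' @export
drfv_descriptors <- function(config = drfv_config()) {
  as.vector(vapply(drfv_channels, function(ch)
    vapply(drfv_families, function(fam)
      paste(ch, fam, drfv_stats, sep = "."), character(4)),
    character(20)))
}

#' Build the Diabetic Retinopathy Feature Vector for one image
#'
#' Six channels are summarized: the whole image plus the five masked
#' structures. Each channel's pixels are serialized row-major (masked
#' channels keep only foreground pixels) and passed through five descriptor
#' families -- raw intensities, DFT magnitudes, DCT coefficients, Gabor
#' response magnitudes (pooled over the configured orientations) and
#' Haar-pair wavelet coefficients (approximation and detail pooled) -- each
#' summarized by mean, population standard deviation, energy (mean square)
#' and Shannon entropy. A channel with an empty mask contributes zeros.
#'
#' @param image a [fundus_image].
#' @param masks a [mask_set] aligned to the image (for example from
#'   [segment_all()]).
#' @param config a [drfv_config].
#' @return an object of class `drfv`: list with numeric `values` and
#'   character `descriptors`, both of length 120 by default.
#' @export
build_drfv <- function(image, masks, config = drfv_config()) {
  px <- as_pixels(image)
  stopifnot(inherits(masks, "mask_set"))
  if (!all(dim(masks$od) == dim(px))) stop("masks misaligned with image")

  gb <- lapply(config$gabor_orientations, function(th)
    gabor_response(px, config$gabor_lambda, config$gabor_sigma,
                   config$gabor_aspect, th))
  tpx <- t(px)                              # row-major serialization
  tgb <- lapply(gb, t)
  bins <- config$entropy_bins

  channel_block <- function(sel) {
    if (!any(sel)) return(numeric(20))
    p <- tpx[sel]
    gvals <- abs(unlist(lapply(tgb, function(r) r[sel]), use.names = FALSE))
    hw <- haar_pair_wavelet(p)
    c(stat_block(p, bins),
      stat_block(dft_features(p)$magnitude, bins),
      stat_block(dct_features(p), bins),
      stat_block(gvals, bins),
      stat_block(c(hw$approx, hw$detail), bins))
  }

  full <- matrix(TRUE, ncol(px), nrow(px))  # transposed-space selector
  vals <- c(channel_block(full),
            unlist(lapply(masks, function(m) channel_block(t(m) == 1L)),
                   use.names = FALSE))
  structure(list(values = as.numeric(vals),
                 descriptors = drfv_descriptors(config)),
            class = "drfv")
}

#' @export
print.drfv <- function(x, ...) {
  cat(sprintf("<drfv> %d descriptors (%d channels x %d families x %d stats)\n",
              length(x$values), length(drfv_channels),
              length(drfv_families), length(drfv_stats)))
  invisible(x)
}

#' Featurize a list of images into a feature matrix
#'
#' Segments each image with the preset rules (unless ground-truth masks are
#' supplied alongside) and extracts its DRFV. Rows are images; columns are
#' the DRFV descriptors plus `id` and `grade`.
#'
#' @param dataset list of [fundus_image]s, or of `list(image=, masks=)`
#'   pairs as produced by [generate_fundus_dataset()].
#' @param config a [drfv_config].
#' @param masks `"segmented"` (default) runs [segment_all()] per image;
#'   `"provided"` uses the masks bundled with the dataset items.
#' @return data frame: `id`, `grade`, then one column per descriptor.
#' @export
featurize_images <- function(dataset, config = drfv_config(),
                             masks = c("segmented", "provided")) {
  masks <- match.arg(masks)
  rows <- lapply(dataset, function(item) {
    img <- if (inherits(item, "fundus_image")) item else item$image
    ms <- if (masks == "provided") item$masks else segment_all(img)
    fv <- build_drfv(img, ms, config)
    stats::setNames(as.data.frame(as.list(fv$values)), fv$descriptors)
  })
  out <- do.call(rbind, rows)
  ids <- vapply(dataset, function(item)
    (if (inherits(item, "fundus_image")) item else item$image)$id, "")
  grades <- vapply(dataset, function(item) {
    g <- (if (inherits(item, "fundus_image")) item else item$image)$grade
    if (is.null(g)) NA_integer_ else g
  }, 0L)
  cbind(data.frame(id = ids, grade = grades), out)
}

#' Feature-matrix CSV round trip
#'
#' @param x feature data frame (`id`, `grade`, descriptors).
#' @param path CSV path.
#' @return `path` / the data frame.
#' @export
write_feature_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

# Names of feature columns (everything except id/grade bookkeeping).
feature_columns <- function(df) setdiff(names(df), c("id", "grade"))
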