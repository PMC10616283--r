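#' Normalize image intensities to the full [0, 1] range
#'
#' Per-image min-max normalization: `(I - min) / (max - min)`. A constant
#' image (zero range) maps to all zeros.
#'
#' @param image a [fundus_image] or numeric matrix.
#' @return numeric matrix in \[0, 1\].
#' @export
normalize_minmax <- function(image) {
  px <- as_pixels(image)
  rng <- range(px)
  if (diff(rng) <= .Machine$double.eps) {
    return(matrix(0, nrow(px), ncol(px)))
  }
  (px - rng[1]) / diff(rng)
}

#' Threshold an image into a binary mask
#'
#' Pixels are compared directly against `level` on the \[0, 1\] scale:
#' bright polarity marks pixels `>= level`, dark polarity marks pixels
#' `<= level`. Use [segment_structure()] for the fraction-of-range
#' ("adaptive") semantics that renormalizes each image first.
#'
#' @param image a [fundus_image] or numeric matrix in \[0, 1\].
#' @param level threshold in \[0, 1\].
#' @param polarity `"bright"` or `"dark"`: which side is foreground.
#' @return integer 0/1 matrix of the image's dimensions.
#' @export
threshold_binarize <- function(image, level, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  px <- as_pixels(image)
  if (length(px) == 0) stop("empty image")
  stopifnot(level >= 0, level <= 1)
  m <- if (polarity == "bright") px >= level else px <= level
  m + 0L
}

# Flat disc structuring element of radius r (diameter 2r + 1).
disc_brush <- function(radius) {
  stopifnot(radius >= 1)
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Run an EBImage morphological op with reflect padding wide enough (2r) that
# the composed erode/dilate pair sees the mirrored extension, keeping
# opening/closing exact (and idempotent) up to the border.
morph_padded <- function(mask, radius, op) {
  stopifnot(is.matrix(mask), radius >= 1)
  pad <- 2L * as.integer(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  if (pad >= nr || pad >= nc)
    stop("mask too small for structuring radius ", radius)
  padded <- pad_reflect(mask, pad)
  out <- op(padded, disc_brush(radius))
  out <- out[(pad + 1):(pad + nr), (pad + 1):(pad + nc), drop = FALSE]
  (out > 0.5) + 0L
}

#' Morphological opening with a disc structuring element
#'
#' Erosion followed by dilation with a flat disc of the given radius;
#' removes foreground blobs that cannot contain the disc. Borders are
#' handled by reflect padding, so a full-foreground mask is unchanged.
#'
#' @param mask binary matrix.
#' @param radius structuring disc radius in pixels (>= 1).
#' @return integer 0/1 matrix.
#' @export
morph_open <- function(mask, radius) {
  morph_padded(mask, radius, EBImage::opening)
}

#' Morphological closing with a disc structuring element
#'
#' Dilation followed by erosion; fills gaps and bridges structures closer
#' than the disc diameter. Reflect-padded borders.
#'
#' @inheritParams morph_open
#' @return integer 0/1 matrix.
#' @export
morph_close <- function(mask, radius) {
  morph_padded(mask, radius, EBImage::closing)
}

#' Thresholding rule for one retinal structure
#'
#' @param level fraction of the normalized intensity range in \[0, 1\].
#' @param polarity `"bright"` or `"dark"`.
#' @param open_radius,close_radius optional disc radii for morphological
#'   opening/closing applied after thresholding (opening first).
#' @return an object of class `threshold_rule`.
#' @export
threshold_rule <- function(level, polarity = c("bright", "dark"),
                           open_radius = NULL, close_radius = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(level >= 0, level <= 1)
  for (r in c(open_radius, close_radius)) {
    stopifnot(r >= 1, r == as.integer(r))
  }
  structure(list(level = level, polarity = polarity,
                 open_radius = open_radius, close_radius = close_radius),
            class = "threshold_rule")
}

#' Preset segmentation rules for the five retinal structures
#'
#' Threshold levels and structuring radii: optic disc 0.4, macula 0.6,
#' vessels 0.5 followed by closing with a radius-5 disc, exudates 0.3
#' followed by opening with a radius-10 disc, hemorrhages 0.7 (dark
#' polarity) followed by opening with a radius-3 disc. Polarities mark the
#' structures as they appear in fundus images: all bright except
#' hemorrhages.
#'
#' @return named list of [threshold_rule]s
#'   (`od`, `macula`, `vessels`, `exudates`, `hemorrhages`).
#' @export
segmentation_presets <- function() {
  list(
    od          = threshold_rule(0.4, "bright"),
    macula      = threshold_rule(0.6, "bright"),
    vessels     = threshold_rule(0.5, "bright", close_radius = 5),
    exudates    = threshold_rule(0.3, "bright", open_radius = 10),
    hemorrhages = threshold_rule(0.7, "dark",  open_radius = 3)
  )
}

# Windowed variant: the same fraction-of-range rule computed inside a
# k x k neighbourhood (local min/max via grayscale erosion/dilation).
local_range_threshold <- function(px, level, polarity, window) {
  stopifnot(window >= 3, window %% 2 == 1)
  br <- EBImage::makeBrush(window, shape = "box")
  pad <- (window - 1L) / 2L
  padded <- pad_reflect(px, pad)
  lo <- EBImage::erode(padded, br)
  hi <- EBImage::dilate(padded, br)
  keep <- function(m) m[(pad + 1):(pad + nrow(px)),
                        (pad + 1):(pad + ncol(px)), drop = FALSE]
  lo <- keep(lo); hi <- keep(hi)
  thr <- lo + level * pmax(hi - lo, .Machine$double.eps)
  m <- if (polarity == "bright") px >= thr else px <= thr
  m + 0L
}

#' Segment one retinal structure
#'
#' Applies the rule's threshold to the per-image normalized intensities
#' (fraction of the min-max range), then morphological opening and/or
#' closing as configured. `method = "windowed"` instead computes the same
#' fraction rule inside a sliding window (local min/max), the textbook
#' locally adaptive variant.
#'
#' @param image a [fundus_image] or numeric matrix.
#' @param rule a [threshold_rule], or the name of a preset from
#'   [segmentation_presets()].
#' @param method `"global"` (per-image normalized range, the default) or
#'   `"windowed"` (local range within `window`).
#' @param window odd window size for the windowed method.
#' @return integer 0/1 mask.
#' @export
segment_structure <- function(image, rule, method = c("global", "windowed"),
                              window = 31) {
  method <- match.arg(method)
  if (is.character(rule)) {
    presets <- segmentation_presets()
    if (!rule %in% names(presets))
      stop("unknown structure preset: ", rule)
    rule <- presets[[rule]]
  }
  stopifnot(inherits(rule, "threshold_rule"))
  px <- as_pixels(image)
  mask <- if (method == "global") {
    threshold_binarize(normalize_minmax(px), rule$level, rule$polarity)
  } else {
    local_range_threshold(px, rule$level, rule$polarity, window)
  }
  if (!is.null(rule$open_radius)) mask <- morph_open(mask, rule$open_radius)
  if (!is.null(rule$close_radius)) mask <- morph_close(mask, rule$close_radius)
  mask
}

#' Segment all five retinal structures
#'
#' Runs the five preset rules ([segmentation_presets()]) on one image and
#' returns the aligned [mask_set].
#'
#' @inheritParams segment_structure
#' @param presets optional named list of rules overriding the defaults;
#'   must contain `od`, `macula`, `vessels`, `exudates`, `hemorrhages`.
#' @return a [mask_set].
#' @export
segment_all <- function(image, presets = segmentation_presets(),
                        method = c("global", "windowed"), window = 31) {
  method <- match.arg(method)
  masks <- lapply(c("od", "macula", "vessels", "exudates", "hemorrhages"),
                  function(nm) segment_structure(image, presets[[nm]],
                                                 method = method,
                                                 window = window))
  mask_set(od = masks[[1]], macula = masks[[2]], vessels = masks[[3]],
           exudates = masks[[4]], hemorrhages = masks[[5]])
}
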