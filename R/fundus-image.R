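#' Fundus image container
#'
#' A 2-D grayscale intensity grid with values in \[0, 1\], an optional severity
#' grade (0 healthy ... 4 proliferative) and an identifier. RGB inputs are
#' converted to luminance on read.
#'
#' @param pixels numeric matrix with finite values in \[0, 1\]; rows index the
#'   vertical image axis.
#' @param grade optional integer 0--4.
#' @param id identifier string.
#' @return an object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, grade = NULL, id = "image") {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (length(pixels) == 0) stop("empty image")
  if (any(!is.finite(pixels))) stop("image contains non-finite pixels")
  if (any(pixels < 0 | pixels > 1)) stop("pixel intensities must lie in [0, 1]")
  if (!is.null(grade)) {
    stopifnot(length(grade) == 1, grade %in% 0:4)
    grade <- as.integer(grade)
  }
  structure(list(pixels = pixels, grade = grade, id = as.character(id)),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image '%s'> %d x %d px, grade %s, range [%.3f, %.3f]\n",
              x$id, nrow(x$pixels), ncol(x$pixels),
              if (is.null(x$grade)) "NA" else x$grade,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.fundus_image <- function(x) dim(x$pixels)

# Accept a fundus_image or a bare matrix.
as_pixels <- function(image) {
  if (inherits(image, "fundus_image")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected a fundus_image or a numeric matrix")
}

#' Aligned per-structure binary masks
#'
#' Holds one binary mask per segmented retinal structure: optic disc, macula,
#' blood vessels, exudates and hemorrhages, all with the source image's
#' dimensions.
#'
#' @param od,macula,vessels,exudates,hemorrhages binary (0/1) matrices of a
#'   common dimension.
#' @return an object of class `mask_set`; a named list of integer matrices.
#' @export
mask_set <- function(od, macula, vessels, exudates, hemorrhages) {
  masks <- list(od = od, macula = macula, vessels = vessels,
                exudates = exudates, hemorrhages = hemorrhages)
  d <- dim(od)
  masks <- lapply(masks, function(m) {
    stopifnot(is.matrix(m), all(dim(m) == d), all(m %in% c(0, 1)))
    storage.mode(m) <- "integer"
    m
  })
  structure(masks, class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %d x %d px; pixels: %s\n",
              nrow(x$od), ncol(x$od),
              paste(sprintf("%s=%d", names(x), vapply(x, sum, 0L)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a fundus image from PNG or JPEG
#'
#' RGB(A) images are converted to grayscale by the Rec.601 luminance
#' `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param path file path ending in `.png`, `.jpg` or `.jpeg`.
#' @param grade optional grade to attach.
#' @return a [fundus_image].
#' @export
read_fundus <- function(path, grade = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: ", ext)
  )
  px <- if (length(dim(arr)) == 3) {
    0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  } else {
    arr
  }
  fundus_image(clamp(px), grade = grade,
               id = tools::file_path_sans_ext(basename(path)))
}

#' Write a fundus image (or a binary mask) as PNG
#'
#' @param image a [fundus_image] or a numeric/binary matrix in \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fundus_png <- function(image, path) {
  px <- as_pixels(image)
  png::writePNG(clamp(px), target = path)
  invisible(path)
}
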