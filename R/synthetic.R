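#' Scene specification for the synthetic fundus generator
#'
#' Describes one fundus-like scene: a circular field of view on a dark
#' surround, a bright optic disc, a smaller bright macular region with a
#' brighter core, thin bright vessels radiating from the disc, small
#' very-bright exudate blobs and small dark hemorrhage blobs, plus additive
#' Gaussian pixel noise. Default render levels are chosen so that
#' fraction-of-range thresholding at the preset levels recovers the optic
#' disc and macula (see the methods vignette): on the normalized scale the
#' optic disc sits inside the \[0.4, 0.6) band and the macula above 0.6,
#' while the dark surround pins the minimum and the macular core pins the
#' maximum of the per-image intensity range across all grades.
#'
#' @param image_size integer vector (rows, cols); default 256 x 256.
#' @param background_level retinal background intensity in \[0, 1\].
#' @param od_center,od_radius optic disc center (row, col) and radius, px.
#' @param macula_center,macula_radius macular region center and radius, px.
#' @param vessel_count,vessel_width number of vessel strokes and their width.
#' @param exudate_count,exudate_radius_range exudate blob count and radius
#'   range (px).
#' @param hemorrhage_count,hemorrhage_radius_range hemorrhage blob count and
#'   radius range (px).
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param grade severity grade 0--4.
#' @param levels named list of render intensities
#'   (`vessel`, `od`, `macula`, `macula_core`, `exudate`, `hemorrhage`,
#'   `surround`).
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(256L, 256L),
                       background_level = 0.25,
                       od_center = c(88, 128), od_radius = 24,
                       macula_center = c(178, 128), macula_radius = 12,
                       vessel_count = 6, vessel_width = 2,
                       exudate_count = 0, exudate_radius_range = c(2, 2),
                       hemorrhage_count = 0, hemorrhage_radius_range = c(2, 2),
                       noise_sigma = 0.015,
                       grade = 0L,
                       levels = list(vessel = 0.32, od = 0.48,
                                     macula = 0.70, macula_core = 0.95,
                                     exudate = 0.90, hemorrhage = 0.10,
                                     surround = 0.0)) {
  spec <- list(image_size = as.integer(image_size),
               background_level = background_level,
               od_center = od_center, od_radius = od_radius,
               macula_center = macula_center, macula_radius = macula_radius,
               vessel_count = as.integer(vessel_count),
               vessel_width = vessel_width,
               exudate_count = as.integer(exudate_count),
               exudate_radius_range = exudate_radius_range,
               hemorrhage_count = as.integer(hemorrhage_count),
               hemorrhage_radius_range = hemorrhage_radius_range,
               noise_sigma = noise_sigma,
               grade = as.integer(grade),
               levels = levels)
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(spec) {
  sz <- spec$image_size
  stopifnot(length(sz) == 2, all(sz >= 32))
  stopifnot(spec$grade %in% 0:4)
  stopifnot(spec$od_radius > 0, spec$macula_radius > 0, spec$vessel_width > 0)
  stopifnot(spec$background_level >= 0, spec$background_level <= 1,
            spec$noise_sigma >= 0)
  stopifnot(spec$exudate_count >= 0, spec$hemorrhage_count >= 0)
  inside <- function(ct) all(ct >= 1) && ct[1] <= sz[1] && ct[2] <= sz[2]
  if (!inside(spec$od_center) || !inside(spec$macula_center))
    stop("structure centers must lie inside the image")
  sep <- sqrt(sum((spec$od_center - spec$macula_center)^2))
  if (sep < spec$od_radius + spec$macula_radius)
    stop("optic disc and macula overlap: centers closer than the sum of radii")
  if (any(spec$exudate_radius_range <= 0) ||
      any(spec$hemorrhage_radius_range <= 0))
    stop("lesion radii must be positive")
  invisible(spec)
}

#' Default grade profile for the synthetic generator
#'
#' Maps a severity grade to a [scene_spec]. Lesion load grows with grade:
#' grade 0 has no lesions, grade 1 carries a few small dark blobs
#' (microaneurysm-like), higher grades add hemorrhages and exudates so that
#' the total lesion pixel count is non-decreasing in grade.
#'
#' @param grade integer 0--4.
#' @param ... overrides forwarded to [scene_spec()].
#' @return a [scene_spec] for that grade.
#' @export
default_grade_profile <- function(grade, ...) {
  stopifnot(grade %in% 0:4)
  ex <- c(0L, 0L, 2L, 5L, 9L)[grade + 1]
  hem <- c(0L, 2L, 4L, 7L, 10L)[grade + 1]
  scene_spec(exudate_count = ex, hemorrhage_count = hem, grade = grade, ...)
}

# Stamp a disc of given radius at each (row, col) point onto logical canvas.
stamp_points <- function(canvas, pts, radius) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  r <- max(1, radius)
  off <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
  for (p in seq_len(nrow(pts))) {
    rr <- pts[p, 1] + off$dr
    cc <- pts[p, 2] + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    canvas[cbind(rr[ok], cc[ok])] <- TRUE
  }
  canvas
}

# Quadratic Bezier points between p0 and p2 with control point p1.
bezier_points <- function(p0, p1, p2, n = 220) {
  t <- seq(0, 1, length.out = n)
  rr <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  cc <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  cbind(round(rr), round(cc))
}

# Sample lesion centers inside the field of view, away from the optic disc
# and macula, by rejection sampling.
sample_lesion_centers <- function(n, radius_max, spec, fov_center, fov_radius) {
  out <- matrix(0, 0, 2)
  tries <- 0
  while (nrow(out) < n && tries < 2000) {
    tries <- tries + 1
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * (fov_radius - radius_max - 3)
    ct <- fov_center + rad * c(cos(ang), sin(ang))
    d_od <- sqrt(sum((ct - spec$od_center)^2))
    d_mac <- sqrt(sum((ct - spec$macula_center)^2))
    if (d_od > spec$od_radius + radius_max + 2 &&
        d_mac > spec$macula_radius + radius_max + 2) {
      out <- rbind(out, round(ct))
    }
  }
  out
}

#' Generate one synthetic fundus image with ground-truth masks
#'
#' Deterministic for a fixed `(spec, seed)` pair. The returned masks record
#' the exact rendered pixels of each structure before noise is added; where
#' structures overlap during painting, a pixel belongs to the structure that
#' owns its final pre-noise intensity (vessels lose to the disc, macula and
#' lesions; hemorrhages lose to exudates).
#'
#' @param spec a [scene_spec].
#' @param seed integer RNG seed.
#' @param id identifier for the resulting image.
#' @return a list with elements `image` ([fundus_image]) and `masks`
#'   ([mask_set]).
#' @export
generate_fundus_image <- function(spec, seed = 1L, id = NULL) {
  validate_scene_spec(spec)
  if (is.null(id)) id <- sprintf("synthetic-g%d-s%d", spec$grade, seed)
  withr::with_seed(seed, {
    nr <- spec$image_size[1]; nc <- spec$image_size[2]
    lv <- spec$levels
    fov_center <- c((nr + 1) / 2, (nc + 1) / 2)
    fov_radius <- min(nr, nc) / 2 - 4
    fov <- disc_mask(fov_center, fov_radius, nr, nc)

    img <- matrix(lv$surround, nr, nc)
    img[fov] <- spec$background_level

    # vessels: curved strokes radiating from the optic disc
    vess <- matrix(FALSE, nr, nc)
    for (v in seq_len(spec$vessel_count)) {
      ang <- stats::runif(1, 0, 2 * pi)
      p0 <- spec$od_center
      p2 <- fov_center + (fov_radius - 3) *
        c(cos(ang + stats::runif(1, -0.4, 0.4)),
          sin(ang + stats::runif(1, -0.4, 0.4)))
      mid <- (p0 + p2) / 2
      dirv <- p2 - p0
      perp <- c(-dirv[2], dirv[1]) / max(1e-9, sqrt(sum(dirv^2)))
      p1 <- mid + perp * stats::runif(1, -30, 30)
      pts <- bezier_points(p0, p1, p2)
      vess <- stamp_points(vess, pts, spec$vessel_width / 2)
    }
    vess <- vess & fov
    img[vess] <- lv$vessel

    # macula (body + bright core) and optic disc
    mac <- disc_mask(spec$macula_center, spec$macula_radius, nr, nc) & fov
    core <- disc_mask(spec$macula_center,
                      max(2, round(spec$macula_radius / 4)), nr, nc) & fov
    od <- disc_mask(spec$od_center, spec$od_radius, nr, nc) & fov
    img[mac] <- lv$macula
    img[core] <- lv$macula_core
    img[od] <- lv$od

    # lesions, outside the disc and macula
    draw_lesions <- function(count, rng) {
      canvas <- matrix(FALSE, nr, nc)
      if (count > 0) {
        rmax <- max(rng)
        centers <- sample_lesion_centers(count, rmax, spec,
                                         fov_center, fov_radius)
        for (i in seq_len(nrow(centers))) {
          r <- stats::runif(1, min(rng), max(rng))
          canvas <- canvas | disc_mask(centers[i, ], r, nr, nc)
        }
      }
      canvas & fov & !od & !mac
    }
    hem <- draw_lesions(spec$hemorrhage_count, spec$hemorrhage_radius_range)
    ex <- draw_lesions(spec$exudate_count, spec$exudate_radius_range)
    img[hem] <- lv$hemorrhage
    img[ex] <- lv$exudate
    hem <- hem & !ex          # exudates painted last win overlaps
    vess <- vess & !od & !mac & !hem & !ex

    masks <- mask_set(od = od + 0L, macula = mac + 0L, vessels = vess + 0L,
                      exudates = ex + 0L, hemorrhages = hem + 0L)

    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
    }
    img <- clamp(img)
    list(image = fundus_image(img, grade = spec$grade, id = id),
         masks = masks)
  })
}

#' Generate a labelled synthetic dataset, n images per grade
#'
#' @param n_per_grade images per grade (>= 1).
#' @param profile function mapping a grade 0--4 to a [scene_spec];
#'   defaults to [default_grade_profile].
#' @param seed integer seed; each image gets a seed derived from it, so the
#'   whole dataset is reproducible.
#' @return list of `5 * n_per_grade` elements, each a list with `image` and
#'   `masks` as in [generate_fundus_image()].
#' @export
generate_fundus_dataset <- function(n_per_grade,
                                    profile = default_grade_profile,
                                    seed = 1L) {
  stopifnot(n_per_grade >= 1)
  out <- vector("list", 5L * n_per_grade)
  k <- 0L
  for (g in 0:4) {
    spec <- profile(g)
    for (i in seq_len(n_per_grade)) {
      k <- k + 1L
      out[[k]] <- generate_fundus_image(
        spec, seed = derive_seed(seed, 1000L * g + i),
        id = sprintf("g%d-i%03d", g, i))
    }
  }
  out
}

#' Augment a fundus image by rotation, zoom and shear
#'
#' Applies an affine transform about the image center (rotation, then
#' isotropic zoom, then horizontal shear) with bilinear resampling. The
#' output keeps the input dimensions; pixels mapped from outside the source
#' are filled with the image's median intensity. The grade label is
#' preserved. Any parameter left `NULL` is drawn uniformly from its default
#' range (rotation \[-20, 20\] degrees, zoom \[0.9, 1.1\], shear
#' \[-10, 10\] degrees) using `seed`.
#'
#' @param image a [fundus_image].
#' @param rotation_deg rotation angle in degrees.
#' @param zoom scale factor > 0 (2 doubles object size).
#' @param shear_deg horizontal shear angle in degrees.
#' @param seed seed used only when parameters are drawn.
#' @return an augmented [fundus_image].
#' @export
augment_image <- function(image, rotation_deg = NULL, zoom = NULL,
                          shear_deg = NULL, seed = 1L) {
  px <- as_pixels(image)
  draw <- is.null(rotation_deg) || is.null(zoom) || is.null(shear_deg)
  if (draw) {
    pars <- withr::with_seed(seed, list(
      rot = stats::runif(1, -20, 20),
      zm = stats::runif(1, 0.9, 1.1),
      sh = stats::runif(1, -10, 10)))
    if (is.null(rotation_deg)) rotation_deg <- pars$rot
    if (is.null(zoom)) zoom <- pars$zm
    if (is.null(shear_deg)) shear_deg <- pars$sh
  }
  if (!all(is.finite(c(rotation_deg, zoom, shear_deg))))
    stop("augmentation parameters must be finite")
  if (zoom <= 0) stop("zoom must be positive")

  th <- rotation_deg * pi / 180
  ph <- shear_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  zm <- diag(c(zoom, zoom))
  sh <- matrix(c(1, 0, tan(ph), 1), 2, 2)
  fwd <- rot %*% zm %*% sh        # (x, y) column vectors, x = col, y = row
  inv <- solve(fwd)

  nr <- nrow(px); nc <- ncol(px)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  gx <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cx
  gy <- matrix(seq_len(nr), nr, nc) - cy
  sx <- inv[1, 1] * gx + inv[1, 2] * gy + cx
  sy <- inv[2, 1] * gx + inv[2, 2] * gy + cy

  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  fill <- stats::median(px)
  at <- function(yy, xx) {
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    v <- matrix(fill, nr, nc)
    v[ok] <- px[cbind(yy[ok], xx[ok])]
    v
  }
  out <- (1 - fx) * (1 - fy) * at(y0, x0) +
    fx * (1 - fy) * at(y0, x0 + 1) +
    (1 - fx) * fy * at(y0 + 1, x0) +
    fx * fy * at(y0 + 1, x0 + 1)
  grade <- if (inherits(image, "fundus_image")) image$grade else NULL
  id <- if (inherits(image, "fundus_image")) paste0(image$id, "-aug") else "aug"
  fundus_image(clamp(out), grade = grade, id = id)
}

#' Write a synthetic dataset to disk
#'
#' Writes each image and its five structure masks as PNG plus a manifest CSV
#' (identifier, grade, seed and scene parameters).
#'
#' @param dataset output of [generate_fundus_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_fundus_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset, function(item) {
    img <- item$image
    write_fundus_png(img, file.path(dir, paste0(img$id, ".png")))
    for (nm in names(item$masks)) {
      write_fundus_png(item$masks[[nm]],
                       file.path(dir, sprintf("%s_mask_%s.png", img$id, nm)))
    }
    data.frame(id = img$id, grade = img$grade,
               rows = nrow(img$pixels), cols = ncol(img$pixels))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
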