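# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's fast paths (stats::fft etc.) so that agreement is a
# real cross-check.

# Direct O(N^2) evaluation of the 1-based DFT:
# S_m = sum_n p_n * [cos(2 pi m n / N) - i sin(2 pi m n / N)], m = 1..N
oracle_dft <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(m) {
    ang <- 2 * pi * m * seq_len(n) / n
    sum(p * complex(real = cos(ang), imaginary = -sin(ang)))
  }, complex(1))
}

# Direct O(N^2) orthonormal DCT-II.
oracle_dct <- function(p) {
  n <- length(p)
  vapply(seq_len(n) - 1, function(k) {
    s <- if (k == 0) sqrt(1 / n) else sqrt(2 / n)
    s * sum(p * cos(pi * (2 * seq_len(n) - 1) * k / (2 * n)))
  }, 0)
}

# Per-pixel disc rasterization: counts pixels within `radius` of `center`
# on an nr x nc grid, by explicit looping.
oracle_disc_count <- function(center, radius, nr, nc) {
  cnt <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) cnt <- cnt + 1L
    }
  }
  cnt
}

# Direct formula for the population-sd (variance) fitness of one feature set.
oracle_variance_fitness <- function(x, idx) {
  vals <- vapply(idx, function(j) {
    v <- x[, j]
    sqrt(sum((v - mean(v))^2) / length(v))
  }, 0)
  mean(vals)
}

# Direct nested-radical inter-class fitness.
oracle_interclass_fitness <- function(x, y, idx) {
  classes <- sort(unique(y))
  vals <- vapply(idx, function(j) {
    inner <- vapply(classes, function(cl) {
      v <- x[y == cl, j]
      sqrt(sum((v - mean(v))^2) / (length(v) - 1))
    }, 0)
    sqrt(sum((inner - mean(inner))^2) / (length(inner) - 1))
  }, 0)
  mean(vals)
}

# Enumeration oracle for the accuracy-weighted vote: explicitly accumulate
# each model's weight onto its voted class and scan classes in order.
oracle_weighted_vote <- function(votes, weights, classes) {
  apply(votes, 1, function(row) {
    score <- setNames(numeric(length(classes)), classes)
    for (j in seq_along(row)) {
      score[as.character(row[j])] <- score[as.character(row[j])] + weights[j]
    }
    best <- names(score)[score == max(score)][1]  # lowest class on ties
    type.convert(best, as.is = TRUE)
  })
}

# Small fundus scene used by unit tests (cheap to render and featurize).
small_scene <- function(grade = 0, ...) {
  ex <- c(0L, 0L, 2L, 4L, 6L)[grade + 1]
  hem <- c(0L, 2L, 3L, 5L, 7L)[grade + 1]
  scene_spec(image_size = c(96L, 96L),
             od_center = c(34, 48), od_radius = 10,
             macula_center = c(68, 48), macula_radius = 5,
             vessel_count = 3,
             exudate_count = ex, hemorrhage_count = hem,
             grade = grade, ...)
}

small_profile <- function(grade, ...) small_scene(grade, ...)

# Random blobby binary mask for morphology property tests.
random_blob_mask <- function(n = 48, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n * n), n, n)
    sm <- as.matrix(EBImage::filter2(m, matrix(1 / 25, 5, 5),
                                     boundary = "replicate"))
    (sm > stats::quantile(sm, 0.7)) + 0L
  })
}
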