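#' Configuration for the moth flame feature-selection wrapper
#'
#' @param NM population size (>= 2 moths).
#' @param NI iterations per phase (>= 1).
#' @param LM moth learning rate in (0, 1]: each moth holds
#'   `round(LM * n_features)` features.
#' @param seed integer seed; the whole selection is deterministic in it.
#' @return a list of class `mmfo_config`.
#' @export
mmfo_config <- function(NM = 20L, NI = 25L, LM = 0.8, seed = 1L) {
  stopifnot(NM >= 2, NI >= 1, LM > 0, LM <= 1)
  structure(list(NM = as.integer(NM), NI = as.integer(NI), LM = LM,
                 seed = as.integer(seed)),
            class = "mmfo_config")
}

# Subset size rule shared by initialization and replacement.
moth_subset_size <- function(n_features, LM) {
  k <- round(LM * n_features)
  if (k < 1) {
    warning("LM * n_features rounds below 1; clamping subset size to 1")
    k <- 1
  }
  as.integer(min(k, n_features))
}

#' Initialize a moth population
#'
#' Each of the `NM` moths holds `round(LM * n_features)` distinct feature
#' indices (1-based), drawn uniformly without replacement. Deterministic for
#' a fixed seed.
#'
#' @param n_features size of the feature universe (>= 1).
#' @param config an [mmfo_config].
#' @return a list of class `moth_population` with elements `moths` (list of
#'   sorted integer vectors), `fitness` (numeric, `NA` until evaluated),
#'   `k` (subset size) and `iteration`.
#' @export
init_population <- function(n_features, config = mmfo_config()) {
  stopifnot(n_features >= 1)
  k <- moth_subset_size(n_features, config$LM)
  moths <- withr::with_seed(config$seed, lapply(seq_len(config$NM), function(i)
    sort(sample.int(n_features, k))))
  structure(list(moths = moths, fitness = rep(NA_real_, config$NM),
                 k = k, n_features = as.integer(n_features), iteration = 0L),
            class = "moth_population")
}

# Coerce a feature matrix argument (data frame with id/grade bookkeeping, or
# plain numeric matrix) to the numeric sample-by-feature matrix.
fm_matrix <- function(matrix) {
  if (is.data.frame(matrix)) {
    as.matrix(matrix[feature_columns(matrix)])
  } else {
    as.matrix(matrix)
  }
}

fm_labels <- function(matrix, labels = NULL) {
  if (!is.null(labels)) return(labels)
  if (is.data.frame(matrix) && "grade" %in% names(matrix)) return(matrix$grade)
  stop("class labels required: supply `labels` or a 'grade' column")
}

# Per-feature population standard deviation sqrt(sum((x - mean)^2) / N).
per_feature_variance_fitness <- function(x) {
  mu <- colMeans(x)
  sqrt(colMeans(sweep(x, 2, mu)^2))
}

# Per-feature inter-class dispersion: the sample standard deviation (m - 1
# denominator) across classes of the per-class sample standard deviations
# (n_c - 1 denominator).
per_feature_interclass_fitness <- function(x, y) {
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need >= 2 classes")
  per_class_sd <- vapply(classes, function(cl) {
    rows <- y == cl
    if (sum(rows) < 2)
      stop("class ", cl, " has fewer than 2 samples")
    apply(x[rows, , drop = FALSE], 2, stats::sd)
  }, numeric(ncol(x)))
  per_class_sd <- matrix(per_class_sd, nrow = ncol(x))  # features x classes
  apply(per_class_sd, 1, stats::sd)
}

#' Variance fitness of one moth
#'
#' For each feature the moth holds, the population standard deviation of
#' that feature's values across samples (`sqrt(mean((x - mean)^2))`); the
#' moth's fitness is the mean of these per-feature values, so subsets of
#' different sizes stay comparable.
#'
#' @param moth integer vector of feature indices (or a list with element
#'   `feature_indices`).
#' @param matrix feature matrix: data frame with descriptor columns (plus
#'   optional `id`/`grade`) or numeric matrix, samples in rows.
#' @return non-negative fitness value.
#' @export
variance_fitness <- function(moth, matrix) {
  x <- fm_matrix(matrix)
  if (nrow(x) < 2) stop("need >= 2 samples")
  idx <- if (is.list(moth)) moth$feature_indices else moth
  if (any(idx < 1 | idx > ncol(x))) stop("moth references out-of-range index")
  mean(per_feature_variance_fitness(x[, idx, drop = FALSE]))
}

#' Inter-class fitness of one moth
#'
#' Per feature: the sample standard deviation of each class's values (n - 1
#' denominator), then the sample standard deviation of those per-class
#' spreads across classes (m - 1 denominator). The moth's fitness is the
#' mean over its features. Note this scores *dispersion of spreads*, not
#' separation of class means: two classes with identical variances but
#' different means score 0.
#'
#' @inheritParams variance_fitness
#' @param labels class label per row; defaults to the data frame's `grade`
#'   column.
#' @return non-negative fitness value.
#' @export
inter_class_fitness <- function(moth, matrix, labels = NULL) {
  x <- fm_matrix(matrix)
  y <- fm_labels(matrix, labels)
  idx <- if (is.list(moth)) moth$feature_indices else moth
  if (any(idx < 1 | idx > ncol(x))) stop("moth references out-of-range index")
  mean(per_feature_interclass_fitness(x[, idx, drop = FALSE], y))
}

#' Fitness threshold of a population
#'
#' `mean(fitnesses) * LM`.
#'
#' @param fitnesses non-empty numeric vector of moth fitness values.
#' @param LM learning rate.
#' @return the threshold.
#' @export
fitness_threshold <- function(fitnesses, LM) {
  stopifnot(length(fitnesses) > 0)
  mean(fitnesses) * LM
}

#' One population update step
#'
#' Computes the threshold from the population's evaluated fitness values;
#' moths below it are handed a fresh uniformly drawn feature subset (same
#' size rule as initialization), moths at or above it pass unchanged. Uses
#' the current RNG state; wrap in `withr::with_seed()` for standalone
#' determinism.
#'
#' @param pop an evaluated `moth_population` (no `NA` fitness).
#' @param LM learning rate used for the threshold.
#' @return the updated population (iteration counter advanced, fitness of
#'   replaced moths reset to `NA`).
#' @export
update_population <- function(pop, LM) {
  stopifnot(inherits(pop, "moth_population"), !anyNA(pop$fitness))
  f_th <- fitness_threshold(pop$fitness, LM)
  for (i in seq_along(pop$moths)) {
    if (pop$fitness[i] < f_th) {
      pop$moths[[i]] <- sort(sample.int(pop$n_features, pop$k))
      pop$fitness[i] <- NA_real_
    }
  }
  pop$iteration <- pop$iteration + 1L
  pop
}

#' Run one selection phase
#'
#' `NI` iterations of evaluate / threshold / replace, then the deduplicated
#' union of the subsets of all moths whose final fitness reaches the final
#' threshold. Never empty: if no moth survives, the best moth's subset is
#' returned.
#'
#' @param matrix feature matrix (data frame or numeric matrix).
#' @param fitness_fn either `"variance"`, `"interclass"`, or a function
#'   `(moth_indices, matrix, labels)` returning one fitness value.
#' @param config an [mmfo_config].
#' @param labels class labels (needed for `"interclass"`).
#' @return sorted unique integer vector of selected feature indices.
#' @export
run_phase <- function(matrix, fitness_fn = "variance",
                      config = mmfo_config(), labels = NULL) {
  x <- fm_matrix(matrix)
  per_feature <- NULL
  if (identical(fitness_fn, "variance")) {
    per_feature <- per_feature_variance_fitness(x)
  } else if (identical(fitness_fn, "interclass")) {
    per_feature <- per_feature_interclass_fitness(x, fm_labels(matrix, labels))
  } else {
    stopifnot(is.function(fitness_fn))
  }
  evaluate <- function(idx) {
    if (!is.null(per_feature)) mean(per_feature[idx])
    else fitness_fn(idx, matrix, labels)
  }
  withr::with_seed(config$seed, {
    pop <- local({
      # population drawn inside the same RNG stream as the updates
      k <- moth_subset_size(ncol(x), config$LM)
      moths <- lapply(seq_len(config$NM), function(i)
        sort(sample.int(ncol(x), k)))
      structure(list(moths = moths, fitness = rep(NA_real_, config$NM),
                     k = k, n_features = ncol(x), iteration = 0L),
                class = "moth_population")
    })
    initial_mean <- NA_real_
    for (it in seq_len(config$NI)) {
      pop$fitness <- vapply(pop$moths, evaluate, 0)
      if (it == 1L) initial_mean <- mean(pop$fitness)
      if (it < config$NI) pop <- update_population(pop, config$LM)
    }
    f_th <- fitness_threshold(pop$fitness, config$LM)
    survivors <- which(pop$fitness >= f_th)
    if (!length(survivors)) survivors <- which.max(pop$fitness)
    out <- sort(unique(unlist(pop$moths[survivors])))
    attr(out, "initial_mean_fitness") <- initial_mean
    attr(out, "surviving_fitness") <- pop$fitness[survivors]
    attr(out, "final_threshold") <- f_th
    out
  })
}

#' Two-phase moth flame feature selection
#'
#' Phase 1 maximizes the variance fitness over the full feature universe and
#' returns the initial survivor set; phase 2 re-runs the population over that
#' set only, under the inter-class fitness, and returns the final set (always
#' nested inside the phase-1 set).
#'
#' @param matrix feature data frame with a `grade` column (or numeric matrix
#'   plus `labels`), samples in rows; every class needs >= 2 samples.
#' @param config an [mmfo_config]; phase 2 uses `seed + 1`.
#' @param labels optional class labels overriding the `grade` column.
#' @param standardize z-score each feature (sample sd) before fitness
#'   evaluation, so feature scale does not dominate. Disable when the
#'   matrix is already standardized.
#' @return list of class `selected_features`: `indices`, `descriptors`,
#'   `phase1_indices`, `phase1_size`, `final_size`, `config`.
#' @export
select_features <- function(matrix, config = mmfo_config(), labels = NULL,
                            standardize = TRUE) {
  x <- fm_matrix(matrix)
  y <- fm_labels(matrix, labels)
  descriptors <- if (is.data.frame(matrix)) feature_columns(matrix)
                 else colnames(x)
  if (standardize) x <- standardize_features(x)$x
  cfg1 <- config
  phase1 <- run_phase(x, "variance", cfg1)
  cfg2 <- config
  cfg2$seed <- derive_seed(config$seed, 1L)
  phase2_local <- run_phase(x[, phase1, drop = FALSE], "interclass", cfg2,
                            labels = y)
  final <- phase1[phase2_local]
  structure(list(indices = final,
                 descriptors = if (!is.null(descriptors))
                   descriptors[final] else NULL,
                 phase1_indices = phase1,
                 phase1_size = length(phase1),
                 final_size = length(final),
                 config = config),
            class = "selected_features")
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf(
    "<selected_features> phase 1: %d features, final: %d features\n",
    x$phase1_size, x$final_size))
  invisible(x)
}

#' Serialize a selected feature set to JSON
#'
#' @param selected a `selected_features` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selected_json <- function(selected, path) {
  jsonlite::write_json(
    list(indices = selected$indices,
         descriptors = selected$descriptors,
         phase1_size = selected$phase1_size,
         final_size = selected$final_size,
         config = unclass(selected$config)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Z-score standardization helper shared with the pipeline; zero-spread
# features are left centered with unit divisor.
standardize_features <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale < .Machine$double.eps] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}
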