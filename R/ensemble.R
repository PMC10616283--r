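#' Ensemble configuration
#'
#' Hyperparameters of the six base learners and of the accuracy-weighted
#' vote. Defaults: kNN with k = 5; RBF-kernel SVM with cost 1; multinomial
#' logistic regression; single-hidden-layer perceptron with 64 units and at
#' most 500 epochs; random forest with 100 trees; Gaussian naive Bayes.
#'
#' @param knn_k neighbours for kNN.
#' @param svm_cost SVM cost parameter.
#' @param mlp_size,mlp_maxit hidden units and max epochs of the MLP.
#' @param rf_trees trees in the random forest.
#' @param val_fraction fraction of the training split held out (stratified)
#'   to measure each model's accuracy weight.
#' @param strict_eq29 if `TRUE`, the vote uses only the five classifiers of
#'   the printed combination formula (random forest trained but given zero
#'   weight).
#' @param classes the label universe (default grades 0--4).
#' @param seed integer seed controlling the validation split and all
#'   stochastic fits.
#' @return a list of class `ensemble_config`.
#' @export
ensemble_config <- function(knn_k = 5L, svm_cost = 1, mlp_size = 64L,
                            mlp_maxit = 500L, rf_trees = 100L,
                            val_fraction = 0.25, strict_eq29 = FALSE,
                            classes = 0:4, seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1)
  structure(list(knn_k = as.integer(knn_k), svm_cost = svm_cost,
                 mlp_size = as.integer(mlp_size),
                 mlp_maxit = as.integer(mlp_maxit),
                 rf_trees = as.integer(rf_trees),
                 val_fraction = val_fraction,
                 strict_eq29 = isTRUE(strict_eq29),
                 classes = classes, seed = as.integer(seed)),
            class = "ensemble_config")
}

model_names <- c("NB", "kNN", "SVM", "LR", "MLP", "RF")

# Fit one named base model; returns list(fit, predict(newx) -> factor).
fit_base_model <- function(name, x, y, config) {
  lv <- levels(y)
  switch(name,
    NB = {
      fit <- e1071::naiveBayes(x, y)
      list(fit = fit, predict = function(newx)
        predict(fit, newx, eps = 1e-9, threshold = 1e-6))
    },
    kNN = {
      list(fit = list(x = x, y = y), predict = function(newx)
        withr::with_seed(config$seed, class::knn(x, newx, y,
                                                 k = config$knn_k)))
    },
    SVM = {
      # no internal rescaling: features reach the ensemble standardized
      fit <- e1071::svm(x, y, kernel = "radial", cost = config$svm_cost,
                        scale = FALSE)
      list(fit = fit, predict = function(newx) predict(fit, newx))
    },
    LR = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      fit <- withr::with_seed(config$seed,
        nnet::multinom(.y ~ ., data = df, trace = FALSE,
                       MaxNWts = 100000, maxit = 200))
      list(fit = fit, predict = function(newx)
        factor(as.character(predict(fit,
          data.frame(newx, check.names = FALSE))), levels = lv))
    },
    MLP = {
      fit <- withr::with_seed(config$seed,
        nnet::nnet(x, nnet::class.ind(y), size = config$mlp_size,
                   softmax = TRUE, maxit = config$mlp_maxit,
                   MaxNWts = 100000, trace = FALSE))
      list(fit = fit, predict = function(newx) {
        p <- predict(fit, newx)
        factor(lv[max.col(p, ties.method = "first")], levels = lv)
      })
    },
    RF = {
      fit <- withr::with_seed(config$seed,
        randomForest::randomForest(x, y, ntree = config$rf_trees))
      list(fit = fit, predict = function(newx) predict(fit, newx))
    },
    stop("unknown base model: ", name)
  )
}

# Stratified index split: for each class, `fraction` of its rows (at least
# one, never all) go to the second part.
stratified_holdout <- function(y, fraction, seed) {
  withr::with_seed(seed, {
    val <- integer(0)
    for (cl in unique(y)) {
      rows <- which(y == cl)
      n_val <- max(1L, min(length(rows) - 1L, round(fraction * length(rows))))
      val <- c(val, sample(rows, n_val))
    }
    sort(val)
  })
}

#' Train the accuracy-weighted six-classifier ensemble
#'
#' Fits naive Bayes, kNN, RBF SVM, multinomial logistic regression, an MLP
#' and a random forest on the selected feature columns of the training
#' split, and weighs each model by its accuracy on an internal stratified
#' validation holdout (default 25% of the training rows). Deterministic for
#' a fixed config seed.
#'
#' @param train training feature data frame (`grade` column + descriptors)
#'   or numeric matrix with `labels`.
#' @param selected a `selected_features` object, or an integer vector of
#'   feature column indices; `NULL` uses all features.
#' @param config an [ensemble_config].
#' @param labels optional labels overriding the `grade` column.
#' @return an object of class `weighted_ensemble` with fitted `models`,
#'   named `weights` in \[0, 1\], `classes` and the `selected` indices.
#' @export
train_ensemble <- function(train, selected = NULL,
                           config = ensemble_config(), labels = NULL) {
  x <- fm_matrix(train)
  y_raw <- fm_labels(train, labels)
  idx <- if (is.null(selected)) seq_len(ncol(x))
         else if (inherits(selected, "selected_features")) selected$indices
         else as.integer(selected)
  if (any(idx < 1 | idx > ncol(x))) stop("selected indices out of range")
  x <- x[, idx, drop = FALSE]
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (length(unique(y_raw)) < 2) stop("training split needs >= 2 classes")
  if (!all(y_raw %in% config$classes))
    stop("labels outside the configured class universe")
  y <- factor(y_raw, levels = sort(config$classes))
  if (any(table(y)[unique(as.character(y_raw))] < 2))
    stop("every present class needs >= 2 training samples")

  val <- stratified_holdout(as.character(y), config$val_fraction,
                            derive_seed(config$seed, 7L))
  fit_rows <- setdiff(seq_len(nrow(x)), val)
  models <- lapply(model_names, function(nm)
    fit_base_model(nm, x[fit_rows, , drop = FALSE], droplevels(y[fit_rows]),
                   config))
  names(models) <- model_names
  weights <- vapply(models, function(m) {
    pred <- as.character(m$predict(x[val, , drop = FALSE]))
    mean(pred == as.character(y[val]))
  }, 0)
  structure(list(models = models, weights = weights,
                 classes = sort(config$classes), selected = idx,
                 config = config),
            class = "weighted_ensemble")
}

#' @export
print.weighted_ensemble <- function(x, ...) {
  cat("<weighted_ensemble>\n  weights:",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights),
            collapse = " "), "\n")
  invisible(x)
}

#' Accuracy-weighted vote combination
#'
#' Each model's predicted class becomes a one-hot vector over the class
#' universe, scaled by the model's weight; the vectors are summed and the
#' output class is the argmax, ties broken toward the lowest class.
#'
#' @param votes integer/character matrix or data frame, samples x models,
#'   of predicted class labels.
#' @param weights one non-negative weight per model (column).
#' @param classes the ordered class universe.
#' @return vector of combined class labels, one per sample row.
#' @export
weighted_vote <- function(votes, weights, classes = 0:4) {
  votes <- as.matrix(votes)
  stopifnot(ncol(votes) == length(weights), all(weights >= 0),
            all(is.finite(weights)), any(weights > 0))
  scores <- matrix(0, nrow(votes), length(classes))
  for (j in seq_along(weights)) {
    hit <- match(votes[, j], classes)
    if (anyNA(hit)) stop("vote outside the class universe")
    scores[cbind(seq_len(nrow(votes)), hit)] <-
      scores[cbind(seq_len(nrow(votes)), hit)] + weights[j]
  }
  classes[max.col(scores, ties.method = "first")]
}

#' Predict classes with a weighted ensemble
#'
#' @param ens a fitted `weighted_ensemble`.
#' @param newdata feature data frame or matrix with the full feature
#'   universe the ensemble was trained against (the selected columns are
#'   extracted), or exactly the selected columns.
#' @return integer vector of predicted grades.
#' @export
ensemble_predict <- function(ens, newdata) {
  x <- fm_matrix(newdata)
  if (ncol(x) != length(ens$selected)) {
    if (ncol(x) < max(ens$selected))
      stop("feature count mismatch with the fitted ensemble")
    x <- x[, ens$selected, drop = FALSE]
  }
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  votes <- vapply(ens$models, function(m) as.character(m$predict(x)),
                  character(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  w <- ens$weights
  if (ens$config$strict_eq29) w["RF"] <- 0
  if (all(w == 0)) w <- w + 1  # degenerate: fall back to plain majority
  weighted_vote(votes, w, ens$classes)
}

#' @export
predict.weighted_ensemble <- function(object, newdata, ...) {
  ensemble_predict(object, newdata)
}
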