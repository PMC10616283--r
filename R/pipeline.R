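#' Full pipeline configuration
#'
#' @param source input source: `list(type = "synthetic", n_per_grade = 50)`,
#'   `list(type = "images", dir = "...")` (directory of PNG/JPEG files with
#'   a `manifest.csv` holding `id` and `grade` columns), or
#'   `list(type = "csv", path = "...")` (precomputed feature matrix with a
#'   `grade` column).
#' @param split training fraction in (0, 1); the split is stratified by
#'   grade (default 0.8).
#' @param seed master seed; every stage derives its own seed from it.
#' @param augment_per_image augmented copies added per *training* image
#'   (rotation/zoom/shear drawn from the default ranges); 0 disables.
#' @param drfv a [drfv_config].
#' @param mmfo an [mmfo_config] (its seed is overridden by the derived
#'   stage seed).
#' @param ensemble an [ensemble_config] (seed likewise derived).
#' @param out_dir optional artifact directory (features CSV, selected
#'   features JSON, model weights JSON, confusion CSV, report JSON, log).
#' @return a list of class `run_config`.
#' @export
run_config <- function(source = list(type = "synthetic", n_per_grade = 50L),
                       split = 0.8, seed = 42L, augment_per_image = 0L,
                       drfv = drfv_config(), mmfo = mmfo_config(),
                       ensemble = ensemble_config(), out_dir = NULL) {
  stopifnot(split > 0, split < 1, augment_per_image >= 0)
  structure(list(source = source, split = split, seed = as.integer(seed),
                 augment_per_image = as.integer(augment_per_image),
                 drfv = drfv, mmfo = mmfo, ensemble = ensemble,
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Flat keys override [run_config()] defaults; nested blocks `mmfo`,
#' `ensemble` and `source` override the corresponding sub-configurations.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  take <- function(defaults, overrides) {
    for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
    defaults
  }
  if (!is.null(y$source)) cfg$source <- take(cfg$source, y$source)
  if (!is.null(y$split)) cfg$split <- y$split
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  if (!is.null(y$augment_per_image))
    cfg$augment_per_image <- as.integer(y$augment_per_image)
  if (!is.null(y$mmfo)) cfg$mmfo <- do.call(mmfo_config, take(
    unclass(cfg$mmfo), y$mmfo))
  if (!is.null(y$ensemble)) cfg$ensemble <- do.call(ensemble_config, take(
    unclass(cfg$ensemble)[setdiff(names(unclass(cfg$ensemble)), "classes")],
    y$ensemble))
  if (!is.null(y$out_dir)) cfg$out_dir <- y$out_dir
  cfg
}

#' Stratified train/test split
#'
#' `round(fraction * n_c)` training rows per class (at least one row on
#' each side of the split for every class), drawn with the given seed.
#'
#' @param labels class label per sample.
#' @param fraction training fraction.
#' @param seed integer seed.
#' @return list with integer row indices `train` and `test`.
#' @export
stratified_split <- function(labels, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  withr::with_seed(seed, {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      rows <- which(labels == cl)
      n_tr <- max(1L, min(length(rows) - 1L,
                          round(fraction * length(rows))))
      train <- c(train, sample(rows, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

pipeline_stage <- function(log, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  log(sprintf("%-12s %8.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the end-to-end severity-grading pipeline
#'
#' Images (generated, read from disk, or a precomputed feature CSV) are
#' split 80:20 stratified by grade; training images are optionally
#' augmented; every image is segmented with the preset rules and its DRFV
#' extracted; features are z-scored with statistics fitted on the training
#' rows only; the moth flame wrapper selects features on the training rows
#' only; the six-model ensemble is trained and the held-out test split is
#' evaluated. Re-running with the same configuration reproduces the report
#' byte for byte.
#'
#' @param config a [run_config].
#' @return list of class `dr_run`: `report` ([evaluate_predictions()]
#'   output), `selected`, `ensemble`, `split`, `features` (full matrix),
#'   `config`, and `artifacts` (paths, when `out_dir` is set).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  log <- function(line) log_lines <<- c(log_lines, line)
  src <- config$source

  if (identical(src$type, "csv")) {
    features <- pipeline_stage(log, "load", {
      df <- read_feature_csv(src$path)
      if (!"grade" %in% names(df)) stop("feature CSV lacks a 'grade' column")
      df
    })
    images <- NULL
  } else {
    images <- pipeline_stage(log, "load", {
      if (identical(src$type, "synthetic")) {
        generate_fundus_dataset(src$n_per_grade,
                                seed = derive_seed(config$seed, 0L))
      } else if (identical(src$type, "images")) {
        manifest <- utils::read.csv(file.path(src$dir, "manifest.csv"))
        if (!all(c("id", "grade") %in% names(manifest)))
          stop("manifest.csv needs 'id' and 'grade' columns")
        lapply(seq_len(nrow(manifest)), function(i) {
          path <- file.path(src$dir, paste0(manifest$id[i], ".png"))
          if (!file.exists(path))
            path <- file.path(src$dir, paste0(manifest$id[i], ".jpg"))
          read_fundus(path, grade = manifest$grade[i])
        })
      } else {
        stop("unknown source type: ", src$type)
      }
    })
    features <- NULL
  }

  grades <- if (is.null(images)) features$grade else
    vapply(images, function(it)
      (if (inherits(it, "fundus_image")) it else it$image)$grade, 0L)
  if (anyNA(grades)) stop("[stage load] missing grade labels")

  split <- stratified_split(grades, config$split,
                            derive_seed(config$seed, 1L))

  if (!is.null(images)) {
    if (config$augment_per_image > 0) {
      images <- pipeline_stage(log, "augment", {
        extra <- list()
        for (i in split$train) {
          img <- if (inherits(images[[i]], "fundus_image")) images[[i]]
                 else images[[i]]$image
          for (a in seq_len(config$augment_per_image)) {
            extra <- c(extra, list(augment_image(
              img, seed = derive_seed(config$seed, 100000L + 100L * i + a))))
          }
        }
        c(images, extra)
      })
      # augmented copies join the training split
      n_extra <- length(images) - length(grades)
      split$train <- c(split$train, length(grades) + seq_len(n_extra))
      grades <- c(grades, vapply(images[length(grades) + seq_len(n_extra)],
                                 function(x) x$grade, 0L))
    }
    features <- pipeline_stage(log, "featurize",
      featurize_images(images, config$drfv, masks = "segmented"))
  }

  x <- fm_matrix(features)
  y <- features$grade
  scaler <- pipeline_stage(log, "standardize",
    standardize_features(x[split$train, , drop = FALSE]))
  x_train <- scaler$x
  x_test <- standardize_features(x[split$test, , drop = FALSE],
                                 scaler$center, scaler$scale)$x

  mm_cfg <- config$mmfo
  mm_cfg$seed <- derive_seed(config$seed, 2L)
  selected <- pipeline_stage(log, "select", {
    df <- data.frame(grade = y[split$train], x_train, check.names = FALSE)
    sel <- select_features(df, mm_cfg, standardize = FALSE)
    sel$descriptors <- feature_columns(features)[sel$indices]
    sel
  })

  ens_cfg <- config$ensemble
  ens_cfg$seed <- derive_seed(config$seed, 3L)
  ensemble <- pipeline_stage(log, "train", {
    df <- data.frame(grade = y[split$train], x_train, check.names = FALSE)
    train_ensemble(df, selected, ens_cfg)
  })

  report <- pipeline_stage(log, "evaluate", {
    pred <- ensemble_predict(ensemble, x_test)
    evaluate_predictions(pred, y[split$test], classes = ens_cfg$classes)
  })

  artifacts <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_feature_csv(features, p("features.csv"))
    write_selected_json(selected, p("selected.json"))
    jsonlite::write_json(as.list(ensemble$weights), p("weights.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_eval_report(report, p("report.json"), p("confusion.csv"))
    writeLines(log_lines, p("run.log"))
    artifacts <- vapply(c("features.csv", "selected.json", "weights.json",
                          "report.json", "confusion.csv", "run.log"), p, "")
  }

  structure(list(report = report, selected = selected, ensemble = ensemble,
                 split = split, features = features, config = config,
                 log = log_lines, artifacts = artifacts),
            class = "dr_run")
}

#' @export
print.dr_run <- function(x, ...) {
  cat("<dr_run>\n")
  print(x$report)
  print(x$selected)
  invisible(x)
}
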