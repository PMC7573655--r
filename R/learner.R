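# Learn the mapping from image quality metrics to the per-ROI corrections
# ComBat prescribes, so single images from scanners never seen by ComBat can
# be harmonized: correction_ROI = f(IQMs, age, sex, vROI). One forest
# regressor per ROI; leave-one-scanner-out hyperparameter search;
# out-of-training-range warnings at predict time.
#
# Two regressor layouts are provided (see the methods vignette):
#  * "pca" (default): one component basis over all features (IQMs, age, sex,
#    all relative volumes) and a single forest per ROI on the components.
#  * "detrended": the age/sex component of the correction is estimated by
#    within-scanner fixed-effects regression (identified from within-scanner
#    variation only), and a forest on the IQM principal components plus the
#    ROI's relative volume fits the scanner-driven remainder.

rf_train <- function(X, y, num_trees = 100L, mtry = NULL, min_leaf = 1L,
                     max_depth = 0L, bootstrap = TRUE) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (is.null(mtry)) mtry <- ncol(X)  # sklearn regression default: all features
  forest <- .rf_fit(X, as.numeric(y), as.integer(num_trees), as.integer(mtry),
                    as.integer(min_leaf), as.integer(max_depth), bootstrap)
  structure(list(forest = forest, p = ncol(X),
                 hyper = list(num_trees = num_trees, mtry = mtry,
                              min_leaf = min_leaf, max_depth = max_depth)),
            class = "rh_forest")
}

#' @export
predict.rh_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata); storage.mode(newdata) <- "double"
  stopifnot(ncol(newdata) == object$p)
  .rf_predict(object$forest, newdata)
}

#' Assemble the learner's feature matrix
#'
#' Columns are, in order: the IQMs, age, sex (encoded 0/1 by factor level) and
#' the raw relative volume of each requested target ROI. The column order is
#' frozen into any model trained on the result.
#'
#' @param table a `cohort_table` with relative volumes and IQM columns.
#' @param rois target ROI name(s); default all ROIs with relative volumes.
#' @param iqms IQM column names; default all declared IQMs.
#' @return numeric matrix, one row per subject.
#' @export
assemble_features <- function(table, rois = NULL, iqms = NULL) {
  iqms <- iqms %||% iqm_names(table)
  rel <- relvol_matrix(table)
  rois <- rois %||% colnames(rel)
  missing <- setdiff(c(iqms, rois), c(names(table), colnames(rel)))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  iq <- as.matrix(as.data.frame(table)[, iqms, drop = FALSE])
  if (nrow(iq) > 1L) {   # single-subject prediction tables are trivially constant
    const <- iqms[apply(iq, 2, function(v) length(unique(v)) == 1L)]
    if (length(const))
      warning("constant IQM column(s) retained: ", paste(const, collapse = ", "))
  }
  out <- cbind(iq, age = table$age, sex = as.numeric(table$sex) - 1,
               rel[, rois, drop = FALSE])
  colnames(out) <- c(iqms, "age", "sex", paste0("vROI.", rois))
  rownames(out) <- table$subject_id
  out
}

#' Fit a principal-component basis retaining a variance fraction
#'
#' Columns are standardized (zero-variance columns get unit scale with a
#' warning), then the smallest number of principal components whose cumulative
#' explained variance reaches `threshold` is retained.
#'
#' @param features numeric matrix, subjects x features.
#' @param threshold fraction of variance to conserve, in (0, 1]; default 0.99.
#' @return a `component_basis` with centering/scaling, the loading matrix and
#'   the retained count `k`.
#' @export
fit_component_basis <- function(features, threshold = 0.99) {
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must lie in (0, 1]")
  features <- as.matrix(features)
  ctr <- colMeans(features)
  scl <- apply(features, 2, sd)
  zero <- !is.finite(scl) | scl == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s); given unit scale")
    scl[zero] <- 1
  }
  std <- sweep(sweep(features, 2, ctr), 2, scl, "/")
  pc <- prcomp(std, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= threshold - 1e-12)[1]
  structure(list(center = ctr, scale = scl,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 k = k, explained = cum, threshold = threshold),
            class = "component_basis")
}

#' @rdname fit_component_basis
#' @param basis a fitted `component_basis`.
#' @param features matrix with the same columns as at fit time.
#' @export
project_basis <- function(basis, features) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == length(basis$center))
  std <- sweep(sweep(features, 2, basis$center), 2, basis$scale, "/")
  std %*% basis$rotation
}

default_hyper <- function() list(num_trees = 100L, max_depth = 0L, min_leaf = 5L)

# Fit the per-ROI estimators on one training set; shared by harmony_train and
# the LOSO folds so search and final fit use identical machinery.
core_fit <- function(table, y_all, rois, iqms, method, threshold, hyper) {
  rel <- relvol_matrix(table)[, rois, drop = FALSE]
  age <- table$age
  sex <- as.numeric(table$sex) - 1
  coefs <- matrix(0, 2, length(rois), dimnames = list(c("age", "sex"), rois))
  if (method == "detrended") {
    iq <- as.matrix(as.data.frame(table)[, iqms, drop = FALSE])
    basis <- fit_component_basis(iq, threshold)
    P <- project_basis(basis, iq)
    D <- if (length(unique(table$scanner)) > 1L)
      stats::model.matrix(~ age + sex + factor(table$scanner))
    else stats::model.matrix(~ age + sex)
    fe <- qr.coef(qr(D), y_all[, rois, drop = FALSE])
    fe[is.na(fe)] <- 0   # e.g. single-sex training data
    coefs["age", ] <- fe["age", ]
    coefs["sex", ] <- fe["sex", ]
  } else {
    F <- assemble_features(table, rois = rois, iqms = iqms)
    basis <- fit_component_basis(F, threshold)
    P <- project_basis(basis, F)
  }
  regressors <- list()
  for (g in rois) {
    y <- y_all[, g] - coefs["age", g] * age - coefs["sex", g] * sex
    if (var(y_all[, g]) == 0) {
      warning("zero-variance corrections for ROI ", g,
              "; using a constant predictor")
      regressors[[g]] <- structure(list(value = mean(y_all[, g])),
                                   class = "rh_constant")
      next
    }
    h <- if (is.data.frame(hyper)) as.list(hyper[g, ]) else hyper
    X <- if (method == "detrended") cbind(P, v = rel[, g]) else P
    regressors[[g]] <- rf_train(X, y, num_trees = h$num_trees,
                                min_leaf = h$min_leaf, max_depth = h$max_depth)
  }
  list(method = method, basis = basis, coefs = coefs, rois = rois,
       iqms = iqms, regressors = regressors)
}

core_predict <- function(core, table) {
  rel <- relvol_matrix(table)[, core$rois, drop = FALSE]
  age <- table$age
  sex <- as.numeric(table$sex) - 1
  if (core$method == "detrended") {
    iq <- as.matrix(as.data.frame(table)[, core$iqms, drop = FALSE])
    P <- project_basis(core$basis, iq)
  } else {
    F <- assemble_features(table, rois = core$rois, iqms = core$iqms)
    P <- project_basis(core$basis, F)
  }
  pred <- matrix(0, nrow(rel), length(core$rois),
                 dimnames = list(table$subject_id, core$rois))
  for (g in core$rois) {
    reg <- core$regressors[[g]]
    if (inherits(reg, "rh_constant")) {
      pred[, g] <- reg$value
      next
    }
    X <- if (core$method == "detrended") cbind(P, v = rel[, g]) else P
    pred[, g] <- predict(reg, X) +
      core$coefs["age", g] * age + core$coefs["sex", g] * sex
  }
  pred
}

#' Leave-one-scanner-out fold assignment
#'
#' Builds cross-validation folds at scanner granularity. For the split only,
#' scanners holding fewer than `merge_below` subjects are pooled into one
#' pseudo-scanner, and the largest scanner is randomly under-sampled to the
#' size of the second-largest so it cannot dominate every training fold.
#'
#' @param scanners character vector, one scanner label per subject.
#' @param merge_below pool scanners smaller than this into one fold
#'   (default 30).
#' @param cap_to_second_largest under-sample the largest scanner (default on).
#' @return list with `fold` (fold label per subject) and `use` (logical;
#'   `FALSE` for rows dropped by the under-sampling).
#' @export
loso_folds <- function(scanners, merge_below = 30L, cap_to_second_largest = TRUE) {
  scanners <- as.character(scanners)
  sizes <- sort(table(scanners), decreasing = TRUE)
  fold <- scanners
  small <- names(sizes)[sizes < merge_below]
  if (length(small) > 1L) fold[scanners %in% small] <- ".merged"
  use <- rep(TRUE, length(scanners))
  if (cap_to_second_largest && length(sizes) >= 2L && sizes[1] > sizes[2]) {
    big <- names(sizes)[1]
    idx <- which(scanners == big)
    keep <- sample(idx, as.integer(sizes[2]))
    use[setdiff(idx, keep)] <- FALSE
  }
  list(fold = fold, use = use)
}

#' Default forest hyperparameter grid
#'
#' Rows are ordered by the tie-break rule: fewest trees first, then shallowest
#' (finite depth before unlimited, encoded 0), then largest leaf.
#' @export
default_grid <- function() {
  g <- expand.grid(num_trees = c(100L, 500L), max_depth = c(10L, 0L),
                   min_leaf = c(5L, 1L))
  g <- g[order(g$num_trees, ifelse(g$max_depth == 0L, Inf, g$max_depth),
               -g$min_leaf), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Leave-one-scanner-out hyperparameter search
#'
#' For every fold (one scanner or pseudo-scanner left out; see
#' [loso_folds()]), fits the per-ROI estimators on the remaining subjects for
#' each grid point and scores the mean absolute error of the predicted
#' corrections on the left-out subjects. The grid point with the smallest
#' mean fold MAE is chosen per ROI; ties go to the earlier grid row (fewest
#' trees, then shallowest). The final model should then be refit on all data
#' with no scanners merged.
#'
#' @param table a `cohort_table` (relative volumes + IQMs).
#' @param corrections aligned `correction_table` (the regression target).
#' @param grid data.frame with columns num_trees, max_depth (0 = unlimited),
#'   min_leaf; default [default_grid()].
#' @param rois target ROIs (default all).
#' @param merge_below,cap_to_second_largest see [loso_folds()].
#' @param variance_threshold passed to [fit_component_basis()].
#' @param method `"detrended"` or `"pca"` (see [harmony_train()]).
#' @param target `"cumulative"` or a step name.
#' @param seed optional integer seed.
#' @return list with `choices` (one grid row per ROI) and `cv_report`
#'   (long data.frame of fold x grid x ROI MAE).
#' @export
loso_search <- function(table, corrections, grid = default_grid(), rois = NULL,
                        merge_below = 30L, cap_to_second_largest = TRUE,
                        variance_threshold = 0.99, method = "pca",
                        target = "cumulative", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  if (length(unique(table$scanner)) < 3L)
    stop("leave-one-scanner-out needs at least 3 scanners")
  y_all <- correction_target(corrections, target)
  rois <- rois %||% colnames(relvol_matrix(table))
  iqms <- iqm_names(table)
  fl <- loso_folds(table$scanner, merge_below, cap_to_second_largest)
  folds <- unique(fl$fold)
  mae <- array(NA_real_, c(length(folds), nrow(grid), length(rois)),
               dimnames = list(folds, NULL, rois))
  for (f in seq_along(folds)) {
    test <- fl$fold == folds[f]
    train <- !test & fl$use
    for (gi in seq_len(nrow(grid))) {
      core <- core_fit(table[train, ], y_all[train, , drop = FALSE], rois,
                       iqms, method, variance_threshold,
                       as.list(grid[gi, ]))
      pred <- core_predict(core, table[test, ])
      mae[f, gi, ] <- colMeans(abs(pred - y_all[test, rois, drop = FALSE]))
    }
  }
  mean_mae <- apply(mae, c(2, 3), mean)
  best <- apply(mean_mae, 2, which.min)   # first minimum = tie-break order
  choices <- grid[best, , drop = FALSE]
  rownames(choices) <- rois
  cv_report <- do.call(rbind, lapply(seq_along(folds), function(f)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(gi)
      data.frame(fold = folds[f], grid_row = gi, roi = rois,
                 mae = mae[f, gi, ], stringsAsFactors = FALSE,
                 row.names = NULL)))))
  list(choices = choices, cv_report = cv_report)
}

correction_target <- function(corrections, target) {
  y <- if (identical(target, "cumulative")) corrections$cumulative
       else corrections$steps[[target]]
  if (is.null(y)) stop("no such correction target: ", target)
  y
}

#' Train the unseen-scanner harmonizer
#'
#' Learns `correction_ROI = f(IQMs, age, sex, vROI)` from ComBat output, one
#' random-forest regressor per ROI, so that the corrections ComBat would
#' prescribe can be predicted for subjects whose scanner was never seen.
#' Scanners intended for validation must be excluded from both the ComBat fit
#' and this training set.
#'
#' With `method = "pca"` (default) one component basis over all features
#' feeds one forest per ROI directly. With `method = "detrended"` the age and
#' sex component of the correction is first estimated by within-scanner
#' fixed-effects regression and the forest fits the remainder from the IQM
#' principal components plus the ROI's relative volume — an alternative
#' layout for settings where covariate effects must extrapolate far outside
#' each scanner's demographic window (see the methods vignette).
#'
#' @param table a `cohort_table` of training subjects (raw relative volumes).
#' @param corrections aligned `correction_table` from [stepwise_harmonize()].
#' @param rois target ROIs (default all with relative volumes).
#' @param variance_threshold PCA variance fraction to conserve (default 0.99).
#' @param method `"detrended"` (default) or `"pca"`.
#' @param hyper either a single list of forest hyperparameters
#'   (`num_trees`, `max_depth`, `min_leaf`) used for every ROI, or the
#'   `choices` data.frame from [loso_search()] (one row per ROI).
#' @param grid if non-NULL, run [loso_search()] with this grid first and use
#'   its per-ROI choices.
#' @param target `"cumulative"` (default) or a step name.
#' @param merge_below,cap_to_second_largest forwarded to the search.
#' @param seed integer seed; fixes the forests bit-for-bit.
#' @return a `harmony_model`.
#' @export
harmony_train <- function(table, corrections, rois = NULL,
                          variance_threshold = 0.99,
                          method = c("pca", "detrended"),
                          hyper = NULL, grid = NULL,
                          target = "cumulative", merge_below = 30L,
                          cap_to_second_largest = TRUE, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(identical(table$subject_id, corrections$subject_id))
  rois <- rois %||% colnames(relvol_matrix(table))
  iqms <- iqm_names(table)
  y_all <- correction_target(corrections, target)
  cv_report <- NULL
  if (!is.null(grid)) {
    search <- loso_search(table, corrections, grid = grid, rois = rois,
                          merge_below = merge_below,
                          cap_to_second_largest = cap_to_second_largest,
                          variance_threshold = variance_threshold,
                          method = method, target = target)
    hyper <- search$choices
    cv_report <- search$cv_report
  }
  if (is.null(hyper)) hyper <- default_hyper()

  F <- assemble_features(table, rois = rois, iqms = iqms)
  training_ranges <- t(apply(F, 2, range))
  colnames(training_ranges) <- c("min", "max")
  core <- core_fit(table, y_all, rois, iqms, method, variance_threshold, hyper)
  structure(list(feature_names = colnames(F), rois = rois, iqms = iqms,
                 method = method, core = core, basis = core$basis,
                 n_components = core$basis$k,
                 variance_threshold = variance_threshold,
                 regressors = core$regressors, hyper = hyper,
                 training_ranges = training_ranges, cv_report = cv_report,
                 target = target),
            class = "harmony_model")
}

#' @export
predict.rh_constant <- function(object, newdata, ...) {
  rep(object$value, nrow(as.matrix(newdata)))
}

#' @export
print.harmony_model <- function(x, ...) {
  cat(sprintf(paste0("<harmony_model> %d ROIs, %d features, method '%s', ",
                     "%d components (>= %.0f%% variance), target '%s'\n"),
              length(x$rois), length(x$feature_names), x$method,
              x$n_components, 100 * x$variance_threshold, x$target))
  invisible(x)
}

#' Flag subjects outside the training envelope
#'
#' Lists every (subject, feature) pair whose value falls outside the
#' per-feature training range stored in the model. Predictions for such
#' subjects are extrapolations and cannot be guaranteed effective.
#'
#' @param model a `harmony_model`.
#' @param table a `cohort_table`.
#' @return data.frame with subject_id, feature, value, train_min, train_max
#'   (zero rows when every subject is inside the envelope).
#' @export
range_check <- function(model, table) {
  F <- model_features(model, table)
  r <- model$training_ranges
  flags <- list()
  for (j in colnames(F)) {
    out <- F[, j] < r[j, "min"] | F[, j] > r[j, "max"]
    if (any(out))
      flags[[j]] <- data.frame(subject_id = rownames(F)[out], feature = j,
                               value = F[out, j], train_min = r[j, "min"],
                               train_max = r[j, "max"],
                               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(flags))
    return(data.frame(subject_id = character(), feature = character(),
                      value = numeric(), train_min = numeric(),
                      train_max = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(flags, list(make.row.names = FALSE)))
}

model_features <- function(model, table) {
  F <- assemble_features(table, rois = model$rois, iqms = model$iqms)
  if (!identical(colnames(F), model$feature_names))
    stop("assembled features do not match the model's feature list")
  F
}

#' Predict ComBat-style corrections for new subjects
#'
#' Needs only the subject's own IQMs, age, sex and raw relative volumes -
#' never a batch sample - so a single image from an unknown scanner is a
#' valid input. Out-of-range subjects are flagged (and a warning raised) but
#' still predicted.
#'
#' @param model a `harmony_model`.
#' @param table a `cohort_table`.
#' @return a `correction_table` (single step `"predicted"`); the range report
#'   is attached as attribute `"range_flags"`.
#' @export
predict_corrections <- function(model, table) {
  invisible(model_features(model, table))  # feature presence check
  pred <- core_predict(model$core, table)
  flags <- range_check(model, table)
  if (nrow(flags))
    warning(length(unique(flags$subject_id)),
            " subject(s) outside the training range on ",
            length(unique(flags$feature)), " feature(s); see range_flags")
  out <- new_correction_table(table$subject_id, table$scanner,
                              steps = list(predicted = pred),
                              cumulative = pred)
  attr(out, "range_flags") <- flags
  out
}

#' Harmonize a table with a trained model
#'
#' Adds the predicted per-ROI corrections to the raw relative volumes; the
#' input table is never mutated.
#'
#' @param model a `harmony_model`.
#' @param table a `cohort_table` with relative volumes.
#' @return list with `table` (harmonized), `corrections` and `range_flags`.
#' @export
harmony_apply <- function(model, table) {
  corr <- predict_corrections(model, table)
  rel <- relvol_matrix(table)
  rel[, model$rois] <- rel[, model$rois] + corr$cumulative
  list(table = set_relvol_matrix(table, rel), corrections = corr,
       range_flags = attr(corr, "range_flags"))
}
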