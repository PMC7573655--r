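# Empirical-Bayes location/scale batch harmonization (ComBat) with preserved
# covariates, plus the stepwise multi-covariate scheme (sex -> age -> scanner)
# and the per-step / cumulative correction bookkeeping.
#
# Model per feature g and batch b:  y = alpha + X beta + gamma_b + delta_b eps.
# Fitting standardizes each feature with a batch-size-weighted grand mean and
# pooled variance, estimates per-batch location (gamma) and scale (delta)
# effects, shrinks them toward parametric priors (normal for gamma,
# inverse-gamma for delta^2) by iterated conditional empirical-Bayes updates,
# and adjusts:  y* = sqrt(var_pooled / delta*) (z - gamma*) + alpha + X beta.
#
# Convention note: per-batch variances and the pooled variance both use the
# maximum-likelihood denominator (n), so a single-batch fit gives exactly
# gamma* = 0, delta* = 1 and an identity transform.

as_cov_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) {
    covariates <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == n)
  storage.mode(covariates) <- "double"
  covariates
}

#' Fit an empirical-Bayes ComBat harmonization model
#'
#' @param data numeric matrix, subjects in rows, features (e.g. relative ROI
#'   volumes) in columns.
#' @param batch factor of batch labels (scanner, or the covariate being
#'   removed in a stepwise scheme); every level needs at least 2 subjects
#'   (5 or more recommended).
#' @param covariates optional design whose variance is preserved: a numeric
#'   matrix or a data.frame (factors are dummy-encoded); its effects are
#'   estimated jointly with the batch means and added back after adjustment.
#' @param eb use empirical-Bayes shrinkage of the batch effects (default);
#'   `FALSE` uses the raw per-batch estimates.
#' @param tol,max_iter convergence control for the iterated conditional
#'   updates of (gamma*, delta*).
#' @return a `combat_model` with the standardization parameters, per-batch
#'   effects, hyperpriors and convergence record.
#' @export
combat_fit <- function(data, batch, covariates = NULL, eb = TRUE,
                       tol = 1e-6, max_iter = 1000L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(colnames(data)))
    colnames(data) <- paste0("feature", seq_len(ncol(data)))
  batch <- droplevels(as.factor(batch))
  stopifnot(length(batch) == nrow(data))
  n <- nrow(data); p <- ncol(data)
  n_b <- table(batch)
  if (any(n_b < 2L))
    stop("every batch needs at least 2 subjects; offending batch(es): ",
         paste(names(n_b)[n_b < 2L], collapse = ", "))
  B <- nlevels(batch)

  batch_design <- vapply(levels(batch), function(l) as.numeric(batch == l),
                         numeric(n))
  Z <- as_cov_matrix(covariates, n)
  if (!is.null(Z)) {
    # drop covariate columns aliased with the batch design (or each other),
    # e.g. an age category observed in a single scanner
    keep <- logical(ncol(Z))
    for (j in seq_len(ncol(Z))) {
      Xj <- cbind(batch_design, Z[, which(keep), drop = FALSE], Z[, j])
      keep[j] <- qr(Xj)$rank == ncol(Xj)
    }
    if (!all(keep)) {
      warning("dropping preserved-covariate column(s) confounded with batch: ",
              paste(colnames(Z)[!keep], collapse = ", "))
      Z <- Z[, keep, drop = FALSE]
      if (ncol(Z) == 0L) Z <- NULL
    }
  }
  X <- cbind(batch_design, Z)
  if (qr(X)$rank < ncol(X))
    stop("design is rank-deficient after aliasing checks")

  B_hat <- solve(crossprod(X), crossprod(X, data))     # (B + q) x p
  w <- as.numeric(n_b) / n
  alpha <- drop(w %*% B_hat[seq_len(B), , drop = FALSE])   # weighted grand mean
  beta <- if (is.null(Z)) NULL else B_hat[-seq_len(B), , drop = FALSE]

  resid <- data - X %*% B_hat
  var_pooled <- colSums(resid^2) / n
  if (any(var_pooled <= 0))
    stop("zero pooled variance for feature(s): ",
         paste(colnames(data)[var_pooled <= 0], collapse = ", "))

  stand_mean <- matrix(alpha, n, p, byrow = TRUE)
  if (!is.null(Z)) stand_mean <- stand_mean + Z %*% beta
  s_data <- sweep(data - stand_mean, 2, sqrt(var_pooled), "/")

  gamma_hat <- matrix(0, B, p, dimnames = list(levels(batch), colnames(data)))
  delta_hat <- gamma_hat
  for (b in seq_len(B)) {
    idx <- which(as.integer(batch) == b)
    sb <- s_data[idx, , drop = FALSE]
    gamma_hat[b, ] <- colMeans(sb)
    delta_hat[b, ] <- colSums(sweep(sb, 2, gamma_hat[b, ])^2) / length(idx)
  }

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  hyper <- NULL
  iterations <- setNames(integer(B), levels(batch))
  do_eb <- isTRUE(eb) && p >= 2L
  if (isTRUE(eb) && p < 2L)
    warning("empirical-Bayes shrinkage needs >= 2 features; using raw batch estimates")
  if (do_eb) {
    gamma_bar <- rowMeans(gamma_hat)
    t2 <- apply(gamma_hat, 1, var)
    m_d <- rowMeans(delta_hat)
    s2_d <- apply(delta_hat, 1, var)
    a_prior <- (2 * s2_d + m_d^2) / s2_d
    b_prior <- (m_d * s2_d + m_d^3) / s2_d
    for (b in seq_len(B)) {
      if (!is.finite(t2[b]) || t2[b] <= 0 || !is.finite(s2_d[b]) || s2_d[b] <= 0) {
        warning("degenerate hyperprior for batch ", levels(batch)[b],
                "; shrinkage skipped for this batch")
        next
      }
      nb <- as.numeric(n_b[b])
      idx <- which(as.integer(batch) == b)
      sb <- s_data[idx, , drop = FALSE]
      g_old <- gamma_hat[b, ]; d_old <- delta_hat[b, ]
      it <- 0L
      repeat {
        it <- it + 1L
        g_new <- (nb * t2[b] * gamma_hat[b, ] + d_old * gamma_bar[b]) /
          (nb * t2[b] + d_old)
        sum2 <- colSums(sweep(sb, 2, g_new)^2)
        d_new <- (0.5 * sum2 + b_prior[b]) / (nb / 2 + a_prior[b] - 1)
        change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                      abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
        g_old <- g_new; d_old <- d_new
        if (change < tol || it >= max_iter) break
      }
      gamma_star[b, ] <- g_old
      delta_star[b, ] <- d_old
      iterations[b] <- it
    }
    hyper <- list(gamma_bar = gamma_bar, t2 = t2,
                  a_prior = a_prior, b_prior = b_prior)
  }
  if (any(delta_star <= 0))
    stop("non-positive multiplicative batch effect estimated")

  structure(list(features = colnames(data),
                 batch_levels = levels(batch),
                 batch_n = as.integer(n_b),
                 alpha = alpha, beta = beta,
                 cov_names = if (is.null(Z)) NULL else colnames(Z),
                 var_pooled = var_pooled,
                 gamma_hat = gamma_hat, delta_hat = delta_hat,
                 gamma_star = gamma_star, delta_star = delta_star,
                 hyperpriors = hyper, eb = do_eb,
                 convergence = list(iterations = iterations, tol = tol)),
            class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d features, %d batches (%s)%s\n",
              length(x$features), length(x$batch_levels),
              paste(head(x$batch_levels, 4), collapse = ", "),
              if (x$eb) ", EB shrinkage" else ", no shrinkage"))
  invisible(x)
}

#' Apply a fitted ComBat model
#'
#' Adjusts each row with its batch's location/scale effects:
#' `y* = sqrt(var_pooled / delta*) (z - gamma*) + alpha + X beta`. Rows whose
#' batch label was not seen at fit time cannot be adjusted this way - that is
#' what the quality-metric learner ([harmony_train()]) exists for.
#'
#' @param model a `combat_model`.
#' @param data numeric matrix, subjects x features (same features as at fit).
#' @param batch batch labels of the incoming rows.
#' @param covariates preserved-covariate design for the incoming rows, same
#'   encoding as at fit time (required iff the model was fitted with one).
#' @return list with `harmonized` (matrix) and `corrections`
#'   (`harmonized - data`).
#' @export
combat_transform <- function(model, data, batch, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  data <- as.matrix(data)
  if (is.null(colnames(data)))
    colnames(data) <- model$features
  if (!setequal(colnames(data), model$features))
    stop("feature columns do not match the fitted model")
  data <- data[, model$features, drop = FALSE]
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batch_levels)
  if (length(unseen))
    stop("unseen batch label(s): ", paste(unseen, collapse = ", "),
         ". ComBat needs a representative sample per batch; use the trained ",
         "quality-metric harmonizer (harmony_apply) for unseen scanners.")
  n <- nrow(data); p <- ncol(data)
  Z <- as_cov_matrix(covariates, n)
  if (is.null(Z) != is.null(model$beta))
    stop("covariates must be supplied exactly as at fit time")
  if (!is.null(Z) && !identical(colnames(Z), model$cov_names))
    stop("covariate encoding does not match the fitted model (expected columns: ",
         paste(model$cov_names, collapse = ", "), ")")

  stand_mean <- matrix(model$alpha, n, p, byrow = TRUE)
  if (!is.null(Z)) stand_mean <- stand_mean + Z %*% model$beta
  z <- sweep(data - stand_mean, 2, sqrt(model$var_pooled), "/")
  bi <- match(batch, model$batch_levels)
  adj <- (z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  harmonized <- sweep(adj, 2, sqrt(model$var_pooled), "*") + stand_mean
  dimnames(harmonized) <- dimnames(data)
  list(harmonized = harmonized, corrections = harmonized - data)
}

#' Round age to an integer category
#'
#' Rounds half away from zero (25.5 -> 26), so each category is the rounded
#' integer age in years.
#'
#' @param age numeric vector of ages (years).
#' @return integer vector.
#' @export
age_to_category <- function(age) {
  stopifnot(all(is.finite(age)))
  as.integer(sign(age) * floor(abs(age) + 0.5))
}

#' Merge under-populated integer categories
#'
#' Repeatedly reassigns every member of the least-populated category holding
#' fewer than `min_n` subjects to the nearest remaining category (distance on
#' the category value; ties go to the lower category) until all categories
#' hold at least `min_n` or one category remains.
#'
#' @param cat integer category labels (e.g. rounded ages).
#' @param min_n minimum category size.
#' @return integer vector of merged labels.
#' @export
merge_small_categories <- function(cat, min_n) {
  cat <- as.integer(cat)
  repeat {
    tab <- table(cat)
    vals <- as.integer(names(tab))
    small <- which(tab < min_n)
    if (!length(small) || length(tab) == 1L) break
    i <- small[order(tab[small], vals[small])][1L]
    others <- vals[-i]
    d <- abs(others - vals[i])
    target <- others[order(d, others)][1L]
    cat[cat == vals[i]] <- target
  }
  cat
}

new_correction_table <- function(subject_id, scanner, steps, cumulative) {
  structure(list(subject_id = subject_id, scanner = scanner,
                 steps = steps, cumulative = cumulative),
            class = "correction_table")
}

#' @export
print.correction_table <- function(x, ...) {
  cat(sprintf("<correction_table> %d subjects x %d ROIs; steps: %s\n",
              nrow(x$cumulative), ncol(x$cumulative),
              paste(names(x$steps), collapse = ", ")))
  invisible(x)
}

#' Stepwise multi-covariate ComBat harmonization
#'
#' Applies one ComBat instance per step, each fitted on the previous step's
#' output, to remove in turn the variance associated with each listed
#' covariate. The default order removes sex effects, then age effects (age
#' treated as a categorical batch at integer-year resolution, small categories
#' merged), then the scanner bias. Alternatively a covariate can be preserved
#' (its variance retained) at a given step instead of removed.
#'
#' @param table a `cohort_table` with relative volumes computed.
#' @param steps ordered character vector from `"sex"`, `"age"`, `"scanner"`;
#'   each becomes the batch of one ComBat instance.
#' @param preserve named list: for each step, roles whose variance to preserve
#'   during that step (entered as regression covariates). By default the sex
#'   and age steps preserve scanner variance, so their effects are estimated
#'   from within-scanner contrasts and cannot absorb scanner bias when
#'   demographics and scanner are confounded across sites; pass `list()` to
#'   remove each covariate unconditionally instead.
#' @param eb,tol,max_iter passed to [combat_fit()].
#' @param age_min_batch minimum subjects per integer-age category before
#'   merging with the nearest category (default 5).
#' @return list with `table` (harmonized relative volumes), `corrections`
#'   (a `correction_table` with per-step and cumulative corrections, in
#'   relative-volume units, `harmonized - raw`), and `models` (one
#'   `combat_model` per step).
#' @export
stepwise_harmonize <- function(table, steps = c("sex", "age", "scanner"),
                               preserve = list(sex = "scanner",
                                               age = "scanner"),
                               eb = TRUE, tol = 1e-6,
                               max_iter = 1000L, age_min_batch = 5L) {
  stopifnot(all(steps %in% c("sex", "age", "scanner")))
  m <- relvol_matrix(table)
  raw <- m
  step_corr <- list()
  models <- list()
  for (s in steps) {
    batch <- step_batch(table, s, age_min_batch)
    cov_roles <- preserve[[s]]
    Z <- if (length(cov_roles)) role_design(table, cov_roles) else NULL
    fit <- combat_fit(m, batch, covariates = Z, eb = eb, tol = tol,
                      max_iter = max_iter)
    tr <- combat_transform(fit, m, batch, covariates = Z)
    step_corr[[s]] <- tr$harmonized - m
    models[[s]] <- fit
    m <- tr$harmonized
  }
  cumulative <- m - raw
  corr <- new_correction_table(table$subject_id, table$scanner,
                               step_corr, cumulative)
  models <- structure(models, class = "stepwise_models")
  list(table = set_relvol_matrix(table, m), corrections = corr,
       models = models)
}

step_batch <- function(table, step, age_min_batch) {
  switch(step,
         sex = droplevels(table$sex),
         age = factor(merge_small_categories(age_to_category(table$age),
                                             age_min_batch)),
         scanner = factor(table$scanner),
         stop("unknown step: ", step))
}

role_design <- function(table, roles) {
  cols <- lapply(roles, function(r) {
    switch(r,
           sex = {
             m <- matrix(as.numeric(table$sex) - 1)
             colnames(m) <- "sex"
             m
           },
           age = {
             m <- matrix(table$age)
             colnames(m) <- "age"
             m
           },
           scanner = {
             # scanner dummies (reference level dropped): removing a covariate
             # while preserving scanner variance identifies the covariate
             # effects from within-scanner contrasts
             s <- factor(table$scanner)
             m <- stats::model.matrix(~s)[, -1, drop = FALSE]
             colnames(m) <- paste0("scanner.", levels(s)[-1])
             m
           },
           {
             if (!r %in% names(table)) stop("unknown covariate role: ", r)
             m <- matrix(table[[r]])
             colnames(m) <- r
             m
           })
  })
  do.call(cbind, cols)
}
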