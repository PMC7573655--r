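# Independent oracles and fixture builders used across the suite.

# Exhaustive-permutation two-sample K-S p-value (independent of stats::ks.test):
# enumerates every assignment of the pooled sample into groups of the original
# sizes and counts how often the permuted D reaches the observed D.
ecdf_dist <- function(a, b) {
  vals <- sort(unique(c(a, b)))
  Fa <- vapply(vals, function(v) mean(a <= v), 0)
  Fb <- vapply(vals, function(v) mean(b <= v), 0)
  max(abs(Fa - Fb))
}

perm_ks_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  D0 <- ecdf_dist(x, y)
  idx <- utils::combn(length(pool), nx)
  Ds <- apply(idx, 2, function(i) ecdf_dist(pool[i], pool[-i]))
  mean(Ds >= D0 - 1e-12)
}

# Closed-form no-EB ComBat for a single feature, no covariates: standardize
# with the batch-size-weighted grand mean and ML pooled variance, align each
# batch's mean and (ML) variance.
combat_oracle_1f <- function(x, batch) {
  b <- droplevels(as.factor(batch))
  n <- length(x)
  nb <- table(b)
  means <- tapply(x, b, mean)
  alpha <- sum(as.numeric(nb) / n * means)
  vp <- sum((x - means[b])^2) / n
  z <- (x - alpha) / sqrt(vp)
  gb <- tapply(z, b, mean)
  db <- tapply(z, b, function(v) mean((v - mean(v))^2))
  as.numeric(alpha + sqrt(vp) * (z - gb[b]) / sqrt(db[b]))
}

# Hand-built cohort with explicit values (one row per subject).
make_cohort <- function(n_per = c(A = 6, B = 6), n_rois = 3, seed = 1,
                        age = NULL, sex = NULL) {
  set.seed(seed)
  n <- sum(n_per)
  scanner <- rep(names(n_per), n_per)
  df <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                   scanner = scanner,
                   age = age %||% runif(n, 20, 65),
                   sex = factor(sex %||% sample(c("F", "M"), n, TRUE),
                                levels = c("F", "M")),
                   tiv = rep(1.5e6, n), stringsAsFactors = FALSE)
  rois <- sprintf("roi%02d", seq_len(n_rois))
  for (g in rois) df[[g]] <- rnorm(n, 3000, 150)
  cohort_table(df, rois = rois)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small simulated cohort for integration-flavoured unit tests.
small_sim <- function(seed = 1, n_scanners = 4, n_per = 25, n_rois = 6,
                      n_iqms = 5, ...) {
  simulate_cohort(sim_config(n_scanners = n_scanners,
                             subjects_per_scanner = n_per,
                             n_rois = n_rois, n_iqms = n_iqms, ...),
                  seed = seed)
}
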