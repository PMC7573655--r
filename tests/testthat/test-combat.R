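test_that("single batch fit is the identity", {
  set.seed(1)
  X <- matrix(rnorm(200, 10, 2), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  z <- data.frame(z = rnorm(50))
  fit <- combat_fit(X, rep("A", 50), covariates = z)
  expect_lt(max(abs(fit$gamma_star)), 1e-8)
  expect_lt(max(abs(fit$delta_star - 1)), 1e-8)
  out <- combat_transform(fit, X, rep("A", 50), covariates = z)
  expect_equal(out$harmonized, X, tolerance = 1e-8)
  expect_lt(max(abs(out$corrections)), 1e-8 * max(abs(X)))
})

test_that("location/scale recovery matches the closed-form oracle (eb off)", {
  set.seed(7)
  x <- c(rnorm(500, 0, 1), rnorm(500, 3, 2))
  batch <- rep(c("A", "B"), each = 500)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "f"))
  fit <- combat_fit(X, batch, eb = FALSE)
  out <- combat_transform(fit, X, batch)

  # the injected shift/scale is recovered up to Monte-Carlo error
  vp <- fit$var_pooled
  expect_equal(unname((fit$gamma_hat["B", ] - fit$gamma_hat["A", ]) * sqrt(vp)),
               3, tolerance = 0.2)
  expect_equal(unname(sqrt(fit$delta_hat["B", ] / fit$delta_hat["A", ])),
               2, tolerance = 0.1)

  # harmonized batch means agree within 2 standard errors
  h <- out$harmonized[, 1]
  se <- sqrt(var(h[1:500]) / 500 + var(h[501:1000]) / 500)
  expect_lt(abs(mean(h[1:500]) - mean(h[501:1000])), 2 * se)

  # exact equality with the explicit one-feature standardization closed form
  expect_equal(unname(h), combat_oracle_1f(x, batch), tolerance = 1e-10)
})

test_that("EB shrinks batch effects toward the prior mean", {
  set.seed(8)
  B <- 6; p <- 60; n <- 30
  gamma <- matrix(rnorm(B * p, 0, 0.6), B, p)
  X <- do.call(rbind, lapply(seq_len(B), function(b)
    matrix(rnorm(n * p), n, p) + matrix(gamma[b, ], n, p, byrow = TRUE)))
  batch <- rep(paste0("b", seq_len(B)), each = n)
  fit_eb <- combat_fit(X, batch, eb = TRUE)
  frac_between <- mean(vapply(seq_len(B), function(b) {
    lo <- pmin(fit_eb$hyperpriors$gamma_bar[b], fit_eb$gamma_hat[b, ])
    hi <- pmax(fit_eb$hyperpriors$gamma_bar[b], fit_eb$gamma_hat[b, ])
    mean(fit_eb$gamma_star[b, ] >= lo - 1e-12 & fit_eb$gamma_star[b, ] <= hi + 1e-12)
  }, 0))
  expect_gte(frac_between, 0.95)
})

test_that("transform refuses unseen batches and handles the null model", {
  sim <- small_sim(seed = 3)
  tab <- compute_relative_volumes(sim$cohort)
  m <- relvol_matrix(tab)
  fit <- combat_fit(m, tab$scanner)
  expect_error(combat_transform(fit, m[1:2, ], c("NEW", "NEW")),
               "unseen batch")
  # gamma* = 0, delta* = 1 model is the identity
  fit0 <- fit
  fit0$gamma_star[] <- 0
  fit0$delta_star[] <- 1
  out <- combat_transform(fit0, m, tab$scanner)
  expect_equal(out$harmonized, m, tolerance = 1e-12)

  expect_error(combat_fit(m[1:5, ], c("A", "A", "B", "B", "C")), "C")
})

test_that("re-harmonizing harmonized data is a no-op (eb off)", {
  sim <- small_sim(seed = 9)
  tab <- compute_relative_volumes(sim$cohort)
  m <- relvol_matrix(tab)
  fit <- combat_fit(m, tab$scanner, eb = FALSE)
  h <- combat_transform(fit, m, tab$scanner)$harmonized
  fit2 <- combat_fit(h, tab$scanner, eb = FALSE)
  expect_lt(max(abs(fit2$gamma_star)), 1e-6)
  expect_lt(max(abs(fit2$delta_star - 1)), 1e-6)
  h2 <- combat_transform(fit2, h, tab$scanner)$harmonized
  expect_lt(max(abs(h2 - h) / apply(m, 2, sd)), 1e-6)
})

test_that("batch effect parameters are recovered across many batches", {
  set.seed(13)
  B <- 20; p <- 50; n <- 100
  gamma_true <- matrix(rnorm(B * p, 0, 0.5), B, p)
  delta_true <- matrix(exp(rnorm(B * p, 0, 0.25)), B, p)
  X <- do.call(rbind, lapply(seq_len(B), function(b)
    sweep(matrix(rnorm(n * p), n, p), 2, delta_true[b, ], "*") +
      matrix(gamma_true[b, ], n, p, byrow = TRUE)))
  batch <- rep(sprintf("b%02d", seq_len(B)), each = n)
  fit <- combat_fit(X, batch)
  expect_gte(cor(as.numeric(fit$gamma_star), as.numeric(gamma_true)), 0.95)
  expect_gte(cor(as.numeric(sqrt(fit$delta_star)), as.numeric(delta_true)), 0.9)
})

test_that("age categories round half away from zero and merge small cells", {
  expect_equal(age_to_category(c(25.4, 25.6, 25.5)), c(25L, 26L, 26L))
  merged <- merge_small_categories(c(60, 60, 61, 61, 62, 62, 63, 64, 64),
                                   min_n = 2)
  expect_equal(merged[7], 62L)  # lone 63 ties 62/64 -> lower
  expect_equal(sort(unique(merged)), c(60L, 61L, 62L, 64L))
})

test_that("stepwise harmonization composes single ComBat instances", {
  sim <- small_sim(seed = 14, n_scanners = 4, n_per = 30)
  tab <- compute_relative_volumes(sim$cohort)
  m <- relvol_matrix(tab)

  one <- stepwise_harmonize(tab, steps = "scanner")
  direct <- combat_transform(combat_fit(m, tab$scanner), m, tab$scanner)
  expect_equal(relvol_matrix(one$table), direct$harmonized, tolerance = 1e-12)

  full <- stepwise_harmonize(tab)
  expect_equal(full$corrections$cumulative,
               Reduce(`+`, full$corrections$steps), tolerance = 1e-10)
  expect_equal(relvol_matrix(full$table) - m, full$corrections$cumulative,
               tolerance = 1e-12)
})

test_that("stepwise harmonization attenuates sex, age and scanner effects", {
  # overlapping age windows: the property isolates effect removal from the
  # separate question of robustness to scanner-by-demographics confounding
  sim <- simulate_cohort(sim_config(n_scanners = 6, subjects_per_scanner = 80,
                                    n_rois = 8, n_iqms = 4,
                                    age_window_halfwidth = 26,
                                    age_slope_frac_mean = -0.003,
                                    sex_offset_frac_sd = 0.03), seed = 15)
  tab <- sim$cohort
  res <- stepwise_harmonize(tab, eb = FALSE)
  m0 <- relvol_matrix(tab); m1 <- relvol_matrix(res$table)
  sex <- as.numeric(tab$sex) - 1
  agecat <- age_to_category(tab$age)
  ratio <- vapply(colnames(m0), function(g) {
    b0 <- coef(lm(m0[, g] ~ sex + agecat + factor(tab$scanner)))[-1]
    b1 <- coef(lm(m1[, g] ~ sex + agecat + factor(tab$scanner)))[-1]
    max(abs(b1)) / max(abs(b0))
  }, 0)
  expect_lt(median(ratio), 0.1)
})

test_that("preserved covariates keep their variance", {
  set.seed(16)
  n <- 2000
  age <- runif(n, 18, 70)
  scanner <- sample(c("A", "B", "C", "D"), n, TRUE)
  slope <- 5
  y <- 1000 + slope * age + c(A = 0, B = 200, C = -150, D = 60)[scanner] +
    rnorm(n, 0, 60)
  X <- matrix(y, ncol = 1, dimnames = list(NULL, "f"))
  fit <- combat_fit(X, scanner, covariates = data.frame(age = age), eb = FALSE)
  out <- combat_transform(fit, X, scanner, covariates = data.frame(age = age))
  slope_hat <- coef(lm(out$harmonized[, 1] ~ age))[["age"]]
  expect_equal(slope_hat, slope, tolerance = 0.1 * slope)
  # and the scanner effect is gone
  expect_lt(max(abs(coef(lm(out$harmonized[, 1] ~ age + factor(scanner)))[-(1:2)])), 15)
})
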