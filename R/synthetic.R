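# Multi-scanner cohort simulator with ground truth. Stands in for a large
# multi-site morphometry mega-dataset: per-scanner additive and multiplicative
# effects on relative volumes driven by a one-dimensional latent scanner
# quality, age and sex effects, scanner-correlated IQMs, and demographic
# imbalance across scanners.

#' Simulation configuration
#'
#' Defaults describe a desk-scale but structurally realistic multi-scanner
#' cohort: 10 scanners of 80 adults (18-70 y), 20 ROIs on the relative-volume
#' scale of real brain structures (5e-4 to 3e-2), natural between-subject
#' variability of ~8% of the mean, mild age atrophy and sex offsets, scanner
#' location effects up to ~1.5 within-scanner SD and scale effects up to
#' ~20%, both smooth monotone functions of a latent scanner quality
#' `q in [-1, 1]`, and IQMs that are linear in `q` with small subject-level
#' noise (quality metrics are strongly scanner-associated).
#'
#' @param n_scanners number of scanners.
#' @param subjects_per_scanner scalar or per-scanner vector (>= 2 each).
#' @param n_rois,n_iqms feature-space sizes.
#' @param age_range cohort age window (years).
#' @param age_window_halfwidth each scanner recruits from a random sub-window
#'   of this half-width (years), creating age imbalance.
#' @param sex_imbalance per-scanner probability of the second sex level;
#'   `NULL` draws each from Uniform(0.2, 0.8).
#' @param roi_means,roi_sds relative-volume means/SDs; `NULL` for defaults
#'   (log-spaced means, SD = 8% of mean).
#' @param age_slope_frac_mean,age_slope_frac_sd per-ROI age slope as a
#'   fraction of the ROI mean per year, drawn Normal(mean, sd).
#' @param sex_offset_frac_sd per-ROI sex offset (fraction of mean),
#'   drawn Normal(0, sd).
#' @param gamma_amp amplitude of the additive scanner effect in units of the
#'   ROI SD (0 disables location effects).
#' @param delta_log_range per-ROI log-scale amplitude range of the
#'   multiplicative effect `delta = exp(d q)`; `c(0, 0)` disables it.
#' @param iqm_noise_sd subject-level IQM noise SD (IQMs are O(1)).
#' @param measurement_noise_frac observation noise SD as a fraction of the
#'   ROI SD.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_scanners = 10L, subjects_per_scanner = 80L,
                       n_rois = 20L, n_iqms = 10L, age_range = c(18, 70),
                       age_window_halfwidth = 15,
                       sex_imbalance = NULL, roi_means = NULL, roi_sds = NULL,
                       age_slope_frac_mean = -0.002, age_slope_frac_sd = 0.001,
                       sex_offset_frac_sd = 0.015,
                       gamma_amp = 1.0, delta_log_range = c(0.05, 0.2),
                       iqm_noise_sd = 0.05, measurement_noise_frac = 0.1) {
  n_per <- rep_len(as.integer(subjects_per_scanner), n_scanners)
  if (any(n_per < 2L)) stop("subjects_per_scanner must be >= 2")
  if (is.null(roi_means))
    roi_means <- exp(seq(log(5e-4), log(3e-2), length.out = n_rois))
  if (is.null(roi_sds)) roi_sds <- 0.08 * roi_means
  stopifnot(length(roi_means) == n_rois, length(roi_sds) == n_rois,
            all(roi_sds > 0), diff(age_range) > 0)
  structure(list(n_scanners = as.integer(n_scanners), n_per = n_per,
                 n_rois = as.integer(n_rois), n_iqms = as.integer(n_iqms),
                 age_range = age_range,
                 age_window_halfwidth = age_window_halfwidth,
                 sex_imbalance = sex_imbalance,
                 roi_means = roi_means, roi_sds = roi_sds,
                 age_slope_frac_mean = age_slope_frac_mean,
                 age_slope_frac_sd = age_slope_frac_sd,
                 sex_offset_frac_sd = sex_offset_frac_sd,
                 gamma_amp = gamma_amp, delta_log_range = delta_log_range,
                 iqm_noise_sd = iqm_noise_sd,
                 measurement_noise_frac = measurement_noise_frac),
            class = "sim_config")
}

#' Simulate a multi-scanner cohort with ground truth
#'
#' Per subject, the true relative volume of ROI g is
#' `mean_g + slope_g (age - mid) + offset_g sex + Normal(0, sd_g^2)`; the
#' observed value is `delta_sg * true + gamma_sg + noise`, with scanner
#' effects `gamma_sg = gamma_amp * sd_g * w_g * q_s` and
#' `delta_sg = exp(d_g q_s)` driven by the scanner's latent quality
#' `q_s ~ Uniform(-1, 1)`. IQM j is `a_j + b_j q_s + noise`, so quality
#' metrics carry the scanner signature. Ages are drawn uniformly from a
#' per-scanner sub-window and sex from a per-scanner imbalanced Bernoulli.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list with `cohort` (a `cohort_table` with raw volumes, relative
#'   volumes, IQMs and a `qc_prob_image` column) and `truth` (latent `q`,
#'   per-scanner-by-ROI `gamma`/`delta`, true relative volumes, per-ROI age
#'   slopes and sex offsets).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cf <- config
  S <- cf$n_scanners; G <- cf$n_rois; J <- cf$n_iqms
  scanners <- sprintf("SCAN%02d", seq_len(S))
  rois <- sprintf("roi%02d", seq_len(G))
  iqms <- sprintf("iqm%02d", seq_len(J))
  n <- sum(cf$n_per)
  scanner <- rep(scanners, cf$n_per)

  q <- setNames(runif(S, -1, 1), scanners)
  w <- runif(G, 0.5, 1.5) * sample(c(-1, 1), G, replace = TRUE)
  gamma <- outer(q, cf$gamma_amp * cf$roi_sds * w)            # S x G
  d <- runif(G, cf$delta_log_range[1], cf$delta_log_range[2])
  delta <- exp(outer(q, d))                                   # S x G
  dimnames(gamma) <- dimnames(delta) <- list(scanners, rois)

  slopes <- cf$roi_means * rnorm(G, cf$age_slope_frac_mean, cf$age_slope_frac_sd)
  offsets <- cf$roi_means * rnorm(G, 0, cf$sex_offset_frac_sd)

  hw <- cf$age_window_halfwidth
  centers <- runif(S, cf$age_range[1] + hw, cf$age_range[2] - hw)
  age <- numeric(n)
  for (s in seq_len(S)) {
    idx <- which(scanner == scanners[s])
    age[idx] <- runif(length(idx), max(cf$age_range[1], centers[s] - hw),
                      min(cf$age_range[2], centers[s] + hw))
  }
  p_sex <- cf$sex_imbalance %||% runif(S, 0.2, 0.8)
  p_sex <- rep_len(p_sex, S)
  sex01 <- rbinom(n, 1, p_sex[match(scanner, scanners)])

  mid <- mean(cf$age_range)
  true_rel <- matrix(cf$roi_means, n, G, byrow = TRUE) +
    outer(age - mid, slopes) + outer(sex01, offsets) +
    sweep(matrix(rnorm(n * G), n, G), 2, cf$roi_sds, "*")
  si <- match(scanner, scanners)
  noise <- sweep(matrix(rnorm(n * G), n, G), 2,
                 cf$measurement_noise_frac * cf$roi_sds, "*")
  obs_rel <- delta[si, , drop = FALSE] * true_rel +
    gamma[si, , drop = FALSE] + noise
  colnames(obs_rel) <- colnames(true_rel) <- rois

  a <- runif(J, -1, 1)
  b <- runif(J, 0.5, 1.5) * sample(c(-1, 1), J, replace = TRUE)
  iqm <- matrix(a, n, J, byrow = TRUE) + outer(q[si], b) +
    matrix(rnorm(n * J, 0, cf$iqm_noise_sd), n, J)
  colnames(iqm) <- iqms

  tiv <- pmax(rnorm(n, 1.5e6, 1.2e5), 1e6)
  df <- data.frame(subject_id = sprintf("sub%05d", seq_len(n)),
                   scanner = scanner, age = age,
                   sex = factor(c("F", "M")[sex01 + 1], levels = c("F", "M")),
                   tiv = tiv,
                   qc_prob_image = stats::rbeta(n, 1, 15),
                   stringsAsFactors = FALSE)
  vol <- obs_rel * tiv
  for (g in rois) df[[g]] <- vol[, g]
  for (j in iqms) df[[j]] <- iqm[, j]
  cohort <- cohort_table(df, rois = rois, iqms = iqms)
  cohort <- set_relvol_matrix(cohort, obs_rel)
  rownames(true_rel) <- df$subject_id
  list(cohort = cohort,
       truth = list(q = q, gamma = gamma, delta = delta,
                    true_rel = true_rel, age_slopes = setNames(slopes, rois),
                    sex_offsets = setNames(offsets, rois),
                    roi_means = setNames(cf$roi_means, rois),
                    roi_sds = setNames(cf$roi_sds, rois),
                    sex_prob = setNames(p_sex, scanners),
                    age_centers = setNames(centers, scanners)))
}

#' Scanner-level train/validation split
#'
#' Holds out whole scanners: held-out subjects must never enter the ComBat
#' fit or the learner training. With `stratified = TRUE` (default) the
#' held-out scanners are chosen among those whose latent quality lies
#' strictly inside the quality range of the remaining training scanners, so
#' validation probes interpolation rather than extrapolation.
#'
#' @param sim result of [simulate_cohort()] (needs `truth$q` when
#'   `stratified`).
#' @param n_holdout number of scanners to hold out (< number of scanners).
#' @param seed integer seed for the scanner draw.
#' @param stratified keep held-out quality inside the training envelope.
#' @return list with `train` and `holdout` cohort tables and
#'   `holdout_scanners`.
#' @export
make_validation_split <- function(sim, n_holdout, seed = 1L, stratified = TRUE) {
  cohort <- sim$cohort
  scanners <- unique(cohort$scanner)
  if (n_holdout >= length(scanners))
    stop("n_holdout must be smaller than the number of scanners")
  set.seed(seed)
  candidates <- scanners
  if (stratified) {
    q <- sim$truth$q[scanners]
    candidates <- setdiff(scanners,
                          c(names(q)[which.min(q)], names(q)[which.max(q)]))
    if (length(candidates) < n_holdout)
      stop("too few interior scanners for a stratified holdout")
  }
  holdout <- sample(candidates, n_holdout)
  list(train = cohort[!cohort$scanner %in% holdout, ],
       holdout = cohort[cohort$scanner %in% holdout, ],
       holdout_scanners = holdout)
}
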