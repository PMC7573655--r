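# Exclusion pipeline for multi-scanner morphometry cohorts: age window,
# quality-probability cutoffs, relative-volume computation, iterative
# per-scanner outlier removal, and the minimum-scanner-size filter.

qc_report <- function(n_input, excluded = NULL, outlier_iterations = integer()) {
  excluded <- excluded %||% data.frame(subject_id = character(),
                                       reason = character(),
                                       stringsAsFactors = FALSE)
  reasons <- c("age", "quality", "missing", "outlier", "small_scanner")
  counts <- setNames(integer(length(reasons)), reasons)
  tab <- table(factor(excluded$reason, levels = reasons))
  counts[names(tab)] <- as.integer(tab)
  structure(list(n_input = n_input,
                 n_retained = n_input - nrow(excluded),
                 n_excluded_age = counts[["age"]],
                 n_excluded_quality = counts[["quality"]],
                 n_excluded_missing = counts[["missing"]],
                 n_excluded_outlier = counts[["outlier"]],
                 n_excluded_small_scanner = counts[["small_scanner"]],
                 outlier_iterations = outlier_iterations,
                 excluded_ids = excluded),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  input %d -> retained %d\n", x$n_input, x$n_retained))
  for (f in c("n_excluded_age", "n_excluded_quality", "n_excluded_missing",
              "n_excluded_outlier", "n_excluded_small_scanner"))
    if (x[[f]] > 0) cat(sprintf("  %s: %d\n", f, x[[f]]))
  if (length(x$outlier_iterations))
    cat("  outlier iterations per scanner:",
        paste(sprintf("%s=%d", names(x$outlier_iterations), x$outlier_iterations),
              collapse = ", "), "\n")
  invisible(x)
}

merge_reports <- function(reports, n_input) {
  excluded <- do.call(rbind, lapply(reports, function(r) r$excluded_ids))
  iters <- unlist(lapply(reports, function(r) r$outlier_iterations))
  qc_report(n_input, excluded, iters)
}

#' Retain subjects inside an age window
#'
#' Subjects strictly younger than `min_age` or strictly older than `max_age`
#' are excluded; both boundaries are inclusive.
#'
#' @param table a `cohort_table`.
#' @param min_age,max_age window in years (defaults 18 and 70).
#' @return list with elements `table` (filtered) and `report` (a `qc_report`).
#' @export
filter_age_range <- function(table, min_age = 18, max_age = 70) {
  if (min_age > max_age) stop("min_age must not exceed max_age")
  keep <- table$age >= min_age & table$age <= max_age
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("no subjects remain inside the age window")
  rep <- qc_report(nrow(table),
                   data.frame(subject_id = table$subject_id[!keep],
                              reason = rep("age", sum(!keep)),
                              stringsAsFactors = FALSE))
  list(table = table[keep, ], report = rep)
}

#' Exclude images flagged as probably unusable
#'
#' Drops any subject whose available quality probabilities (`qc_prob_image`,
#' the image-level unusable probability, and/or `qc_prob_seg`, the
#' segmentation-level one) are strictly greater than `threshold`.
#'
#' @param table a `cohort_table`.
#' @param threshold probability cutoff (default 0.5, strict `>`).
#' @return list with `table` and `report`.
#' @export
filter_quality <- function(table, threshold = 0.5) {
  cols <- intersect(c("qc_prob_image", "qc_prob_seg"), names(table))
  if (!length(cols)) {
    warning("no quality-probability column present; quality filter is a no-op")
    return(list(table = table, report = qc_report(nrow(table))))
  }
  for (col in cols) {
    v <- table[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(col, " contains values outside [0, 1]")
  }
  bad <- Reduce(`|`, lapply(cols, function(col) {
    v <- table[[col]]
    !is.na(v) & v > threshold
  }))
  rep <- qc_report(nrow(table),
                   data.frame(subject_id = table$subject_id[bad],
                              reason = rep("quality", sum(bad)),
                              stringsAsFactors = FALSE))
  list(table = table[!bad, ], report = rep)
}

#' Exclude subjects with missing ROI or IQM values
#'
#' Imputation is deliberately not offered; rows with any missing ROI volume or
#' IQM are excluded with a logged count.
#'
#' @param table a `cohort_table`.
#' @return list with `table` and `report`.
#' @export
filter_missing <- function(table) {
  cols <- c(roi_names(table), iqm_names(table), relvol_names(table))
  if (!length(cols)) return(list(table = table, report = qc_report(nrow(table))))
  ok <- complete.cases(as.data.frame(table)[, cols, drop = FALSE])
  rep <- qc_report(nrow(table),
                   data.frame(subject_id = table$subject_id[!ok],
                              reason = rep("missing", sum(!ok)),
                              stringsAsFactors = FALSE))
  list(table = table[ok, ], report = rep)
}

#' Compute relative volumes
#'
#' Relative volume of an ROI is its raw volume divided by the subject's total
#' intracranial volume (TIV); dimensionless.
#'
#' @param table a `cohort_table` with raw ROI volumes and `tiv > 0`.
#' @return the table with one relative-volume column added per ROI.
#' @export
compute_relative_volumes <- function(table) {
  bad <- is.na(table$tiv) | table$tiv <= 0
  if (any(bad))
    stop("tiv must be > 0 to compute relative volumes; offending subject(s): ",
         paste(head(table$subject_id[bad], 5), collapse = ", "))
  if (!length(roi_names(table))) stop("table has no ROI volume columns")
  m <- roi_matrix(table) / table$tiv
  set_relvol_matrix(table, m)
}

#' Iterative per-scanner outlier removal
#'
#' Within each scanner group, repeatedly: compute the per-ROI mean and sample
#' standard deviation of the relative volumes over the currently retained
#' subjects; flag every subject lying more than `z_cut` standard deviations
#' from the mean on at least `min_rois` ROIs; remove all flagged subjects at
#' once; recompute; stop at the fixed point. Scanners are processed in
#' isolation so between-scanner offsets can never create outliers.
#'
#' @param table a `cohort_table` with relative volumes computed.
#' @param z_cut flag threshold as a multiple of sigma (default 2.5, strict `>`).
#' @param min_rois minimum number of flagged ROIs for exclusion (default 10).
#'   Alternatively `roi_fraction` gives it as a fraction of the feature space.
#' @param roi_fraction optional fraction in (0, 1]; overrides `min_rois` with
#'   `ceiling(roi_fraction * n_rois)`.
#' @return list with `table` and `report` (iteration counts per scanner).
#' @export
iterative_outlier_filter <- function(table, z_cut = 2.5, min_rois = 10,
                                     roi_fraction = NULL) {
  m <- relvol_matrix(table)
  if (!is.null(roi_fraction)) {
    stopifnot(roi_fraction > 0, roi_fraction <= 1)
    min_rois <- ceiling(roi_fraction * ncol(m))
  }
  scanners <- unique(table$scanner)
  removed <- character(0)
  iters <- setNames(integer(length(scanners)), scanners)
  for (s in scanners) {
    idx <- which(table$scanner == s)
    if (length(idx) < 2L) {
      warning("scanner ", s, " has fewer than 2 subjects; outlier rule skipped")
      next
    }
    current <- idx
    it <- 0L
    repeat {
      it <- it + 1L
      sub <- m[current, , drop = FALSE]
      mu <- colMeans(sub)
      sig <- apply(sub, 2, sd)
      n_flagged <- rowSums(sweep(abs(sweep(sub, 2, mu)), 2, z_cut * sig) > 0)
      flag <- n_flagged >= min_rois
      if (!any(flag)) break
      removed <- c(removed, table$subject_id[current[flag]])
      current <- current[!flag]
      if (length(current) < 2L) break
    }
    iters[s] <- it
  }
  keep <- !(table$subject_id %in% removed)
  rep <- qc_report(nrow(table),
                   data.frame(subject_id = removed,
                              reason = rep("outlier", length(removed)),
                              stringsAsFactors = FALSE),
                   outlier_iterations = iters)
  list(table = table[keep, ], report = rep)
}

#' Drop scanners without statistical representation
#'
#' Removes all subjects of any scanner with fewer than `min_n` retained
#' subjects (the empirical-Bayes harmonization needs a minimal sample per
#' batch; 5 is the established floor).
#'
#' @param table a `cohort_table`.
#' @param min_n minimum scanner size (default 5).
#' @return list with `table` and `report`.
#' @export
filter_min_scanner_size <- function(table, min_n = 5) {
  sizes <- table(table$scanner)
  small <- names(sizes)[sizes < min_n]
  bad <- table$scanner %in% small
  rep <- qc_report(nrow(table),
                   data.frame(subject_id = table$subject_id[bad],
                              reason = rep("small_scanner", sum(bad)),
                              stringsAsFactors = FALSE))
  list(table = table[!bad, ], report = rep)
}

#' Full exclusion pipeline
#'
#' Applies, in order: age window, quality-probability cutoff, missing-data
#' exclusion, relative-volume computation, iterative per-scanner outlier
#' removal, and the minimum-scanner-size filter. The merged report's counts
#' partition the input.
#'
#' @param table a `cohort_table` with raw ROI volumes.
#' @param min_age,max_age,qc_threshold,z_cut,min_rois,roi_fraction,min_scanner_n
#'   passed to the individual filters.
#' @return list with `table` (filtered, relative volumes computed) and `report`.
#' @export
qc_pipeline <- function(table, min_age = 18, max_age = 70, qc_threshold = 0.5,
                        z_cut = 2.5, min_rois = 10, roi_fraction = NULL,
                        min_scanner_n = 5) {
  n0 <- nrow(table)
  s1 <- filter_age_range(table, min_age, max_age)
  s2 <- filter_quality(s1$table, qc_threshold)
  s3 <- filter_missing(s2$table)
  t3 <- compute_relative_volumes(s3$table)
  s4 <- iterative_outlier_filter(t3, z_cut, min_rois, roi_fraction)
  s5 <- filter_min_scanner_size(s4$table, min_scanner_n)
  list(table = s5$table,
       report = merge_reports(list(s1$report, s2$report, s3$report,
                                   s4$report, s5$report), n0))
}
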