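# Harmonization efficacy assessment: pairwise two-sample Kolmogorov-Smirnov
# matrices over scanners x ROIs, correction-strength summaries (correction
# ratio, CV, QCV) and the per-covariate correction decomposition.

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided D is the maximum gap between the two empirical CDFs. The default
#' p-value comes from the asymptotic Kolmogorov distribution at effective size
#' `n = nx ny / (nx + ny)`; `method = "exact"` computes the exact
#' permutation-null p (tie-aware), recommended when `nx + ny < 30`. No
#' multiplicity correction is ever applied: when screening many scanner pairs
#' and regions for residual bias, type II errors (missed differences) are the
#' costly ones, so per-test p-values are reported as-is.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param method `"asymptotic"` (default) or `"exact"`.
#' @return list with elements `D` and `p`.
#' @export
ks_two_sample <- function(x, y, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = (method == "exact")))
  list(D = unname(kt$statistic), p = min(1, max(0, unname(kt$p.value))))
}

#' Pairwise K-S matrix over scanners and ROIs
#'
#' Runs the two-sample K-S test on the relative volume of every ROI for every
#' unordered pair of scanners, and reduces each pair to its minimum p over
#' ROIs (the worst-harmonized region for that pair).
#'
#' @param table a `cohort_table` with relative volumes.
#' @param condition free label stored with the result (e.g. `"before"`,
#'   `"after"`).
#' @param min_n only pairs where both scanners have at least this many
#'   subjects are tested (default 2).
#' @param method passed to [ks_two_sample()].
#' @return a `ks_matrix`: list with `pairs` (long data.frame scanner_a,
#'   scanner_b, roi, D, p), `min_p` (one row per pair) and `condition`.
#' @export
ks_pair_matrix <- function(table, condition = "before", min_n = 2L,
                           method = "asymptotic") {
  m <- relvol_matrix(table)
  scanners <- sort(unique(table$scanner))
  if (length(scanners) < 2L) stop("need at least 2 scanners")
  sizes <- table(table$scanner)
  scanners <- scanners[sizes[scanners] >= min_n]
  combos <- utils::combn(scanners, 2L)
  rows <- vector("list", ncol(combos))
  for (k in seq_len(ncol(combos))) {
    a <- combos[1L, k]; b <- combos[2L, k]
    ia <- table$scanner == a; ib <- table$scanner == b
    res <- lapply(colnames(m), function(g)
      ks_two_sample(m[ia, g], m[ib, g], method = method))
    rows[[k]] <- data.frame(scanner_a = a, scanner_b = b, roi = colnames(m),
                            D = vapply(res, `[[`, 0, "D"),
                            p = vapply(res, `[[`, 0, "p"),
                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  min_p <- do.call(rbind, lapply(rows, function(r)
    data.frame(scanner_a = r$scanner_a[1], scanner_b = r$scanner_b[1],
               min_p = min(r$p), stringsAsFactors = FALSE)))
  structure(list(pairs = pairs, min_p = min_p, condition = condition),
            class = "ks_matrix")
}

#' @export
print.ks_matrix <- function(x, ...) {
  cat(sprintf("<ks_matrix> condition '%s': %d pairs x %d ROIs; min p = %.3g\n",
              x$condition, nrow(x$min_p),
              length(unique(x$pairs$roi)), min(x$min_p$min_p)))
  invisible(x)
}

#' Aggregate relative volumes by tissue class
#'
#' Sums each subject's relative volumes within user-supplied tissue groups
#' (typically grey matter and white matter) and over all mapped ROIs
#' (`whole`). ROIs absent from the map count toward `whole` only and are
#' reported with a warning.
#'
#' @param table a `cohort_table` with relative volumes.
#' @param roi_groups named character vector mapping ROI name to `"GM"` or
#'   `"WM"`; unmapped ROIs fall in neither class.
#' @return data.frame with subject_id, scanner and one column per non-empty
#'   group plus `whole`.
#' @export
aggregate_tissue <- function(table, roi_groups) {
  m <- relvol_matrix(table)
  rois <- colnames(m)
  unmapped <- setdiff(rois, names(roi_groups))
  if (length(unmapped))
    warning(length(unmapped), " ROI(s) not in the tissue map; counted in 'whole' only")
  out <- data.frame(subject_id = table$subject_id, scanner = table$scanner,
                    stringsAsFactors = FALSE)
  for (cls in c("GM", "WM")) {
    members <- intersect(rois, names(roi_groups)[roi_groups == cls])
    if (length(members))
      out[[cls]] <- rowSums(m[, members, drop = FALSE])
  }
  if (is.null(out$GM) && is.null(out$WM) && !any(roi_groups %in% c("GM", "WM")))
    warning("tissue map assigns no ROI to GM or WM")
  if (!length(rois)) stop("no ROIs present")
  out$whole <- rowSums(m)
  out
}

quartiles <- function(v) quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)

#' Per-ROI correction strength and dispersion
#'
#' For each ROI: the correction ratio (median relative volume divided by the
#' median absolute correction), its reciprocal expressed as a percentage of
#' the volume, the coefficient of variation `CV = 100 sd / mean` and the
#' quartile-based variant `QCV = 100 (Q3 - Q1) / Q2` (quartiles by linear
#' interpolation), the latter two computed on the raw relative volumes.
#'
#' @param raw a `cohort_table` with the unharmonized relative volumes.
#' @param corrections a `correction_table` aligned with `raw` (same subjects).
#' @param which which correction to summarize: `"cumulative"` or a step name.
#' @return data.frame, one row per ROI.
#' @export
correction_strength <- function(raw, corrections, which = "cumulative") {
  m <- relvol_matrix(raw)
  cm <- if (identical(which, "cumulative")) corrections$cumulative
        else corrections$steps[[which]]
  if (is.null(cm)) stop("no such correction step: ", which)
  stopifnot(identical(rownames(m), corrections$subject_id))
  cm <- cm[, colnames(m), drop = FALSE]
  res <- lapply(colnames(m), function(g) {
    v <- m[, g]; cc <- abs(cm[, g])
    med_v <- median(v); med_c <- median(cc)
    q <- quartiles(v)
    data.frame(roi = g, median_volume = med_v, median_abs_correction = med_c,
               correction_ratio = if (med_c > 0) med_v / med_c else Inf,
               correction_percent = if (med_v != 0) 100 * med_c / med_v else NA_real_,
               cv = 100 * sd(v) / mean(v),
               qcv = if (q[2] != 0) 100 * (q[3] - q[1]) / q[2] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (any(is.na(out$correction_percent) | is.na(out$qcv)))
    warning("ROI(s) with zero median volume: percent/QCV undefined")
  out
}

#' Per-scanner covariate contributions to the total correction
#'
#' For each scanner and each harmonization step (sex, age, scanner), the raw
#' contribution is the median over the scanner's subjects of the absolute
#' step correction, summed over ROIs. Each scanner's contributions are then
#' normalized by their total so the shares sum to one.
#'
#' @param corrections a `correction_table` holding all step corrections.
#' @param median_over take the median over `"subjects"` per ROI then sum over
#'   ROIs (default), or over `"rois"` per subject then sum over subjects.
#' @return data.frame with one row per scanner: raw contribution and share
#'   per step.
#' @export
covariate_contributions <- function(corrections, median_over = c("subjects", "rois")) {
  median_over <- match.arg(median_over)
  steps <- names(corrections$steps)
  if (!length(steps)) stop("correction table holds no step corrections")
  scanners <- sort(unique(corrections$scanner))
  raw <- sapply(steps, function(s) {
    cm <- abs(corrections$steps[[s]])
    vapply(scanners, function(sc) {
      sub <- cm[corrections$scanner == sc, , drop = FALSE]
      if (median_over == "subjects") sum(apply(sub, 2, median))
      else sum(apply(sub, 1, median))
    }, 0)
  })
  raw <- matrix(raw, nrow = length(scanners),
                dimnames = list(scanners, steps))
  tot <- rowSums(raw)
  shares <- raw / tot
  if (any(tot == 0)) {
    warning("scanner(s) with zero total correction: shares undefined")
    shares[tot == 0, ] <- NA_real_
  }
  out <- data.frame(scanner = scanners, stringsAsFactors = FALSE)
  for (s in steps) out[[paste0("raw_", s)]] <- raw[, s]
  for (s in steps) out[[paste0("share_", s)]] <- shares[, s]
  out
}
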