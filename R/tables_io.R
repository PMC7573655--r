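#' @useDynLib roiharmony, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats prcomp predict quantile median sd var ks.test runif rnorm rbinom setNames complete.cases
#' @importFrom utils head modifyList
NULL

REL_PREFIX <- ".rel."
BUNDLE_VERSION <- "1.0"

#' Construct a cohort table
#'
#' A `cohort_table` is a `data.frame` with one row per subject carrying the
#' canonical columns `subject_id`, `scanner`, `age`, `sex` (two-level factor)
#' and `tiv` (total intracranial volume, mm^3), plus raw ROI volume columns,
#' optional relative-volume columns (ROI volume / TIV, dimensionless), optional
#' image-quality-metric (IQM) columns and optional quality-probability columns
#' `qc_prob_image` / `qc_prob_seg`. The ROI and IQM column sets are recorded as
#' attributes so that downstream operations are column-name addressed.
#'
#' @param df data.frame holding the canonical columns plus ROI/IQM columns.
#' @param rois character vector of ROI volume column names (may be empty if
#'   only relative volumes are present).
#' @param iqms character vector of IQM column names.
#' @param validate check invariants (unique ids, tiv > 0, relative volumes
#'   consistent with raw volumes / tiv).
#' @return object of class `cohort_table`.
#' @export
cohort_table <- function(df, rois = character(), iqms = character(),
                         validate = TRUE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  needed <- c("subject_id", "scanner", "age", "sex", "tiv")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("cohort table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$scanner <- as.character(df$scanner)
  if (!is.factor(df$sex)) df$sex <- factor(df$sex)
  bad <- setdiff(c(rois, iqms), names(df))
  if (length(bad))
    stop("declared ROI/IQM column(s) absent from table: ",
         paste(bad, collapse = ", "))
  attr(df, "rois") <- as.character(rois)
  attr(df, "iqms") <- as.character(iqms)
  class(df) <- c("cohort_table", "data.frame")
  if (validate) validate_cohort(df)
  df
}

validate_cohort <- function(x) {
  if (nrow(x) == 0L) stop("cohort table is empty")
  if (anyDuplicated(x$subject_id))
    stop("subject_id values are not unique")
  if (any(is.na(x$scanner) | !nzchar(x$scanner)))
    stop("every row must have a non-empty scanner label")
  if (nlevels(x$sex) > 2L)
    stop("sex must have at most two levels; found: ",
         paste(levels(x$sex), collapse = ", "))
  if (any(!is.na(x$tiv) & x$tiv <= 0))
    stop("tiv must be > 0; offending subject(s): ",
         paste(head(x$subject_id[!is.na(x$tiv) & x$tiv <= 0], 5), collapse = ", "))
  rois <- roi_names(x)
  rel <- relvol_names(x)
  both <- intersect(rois, sub(REL_PREFIX, "", rel, fixed = TRUE))
  for (g in both) {
    v <- x[[g]] / x$tiv
    r <- x[[paste0(REL_PREFIX, g)]]
    ok <- is.na(v) | is.na(r) | abs(v - r) <= 1e-12 * pmax(abs(v), abs(r), 1e-300)
    if (!all(ok))
      stop("relative volumes inconsistent with roi_volumes / tiv for ROI ", g)
  }
  invisible(x)
}

#' @export
`[.cohort_table` <- function(x, i, ...) {
  at <- attributes(x)
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), names(x))) {
    attr(out, "rois") <- at$rois
    attr(out, "iqms") <- at$iqms
    class(out) <- c("cohort_table", "data.frame")
  }
  out
}

#' ROI, relative-volume and IQM column accessors
#' @param x a `cohort_table`.
#' @return character vector of column names (`roi_names`, `iqm_names`), or a
#'   numeric matrix with subjects as rows (`roi_matrix`, `relvol_matrix`).
#' @export
roi_names <- function(x) attr(x, "rois") %||% character()

#' @rdname roi_names
#' @export
iqm_names <- function(x) attr(x, "iqms") %||% character()

relvol_names <- function(x) grep(REL_PREFIX, names(x), fixed = TRUE, value = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname roi_names
#' @export
roi_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, roi_names(x), drop = FALSE])
  rownames(m) <- x$subject_id
  m
}

#' @rdname roi_names
#' @export
relvol_matrix <- function(x) {
  cols <- relvol_names(x)
  if (!length(cols)) stop("relative volumes not present; run compute_relative_volumes() first")
  m <- as.matrix(as.data.frame(x)[, cols, drop = FALSE])
  colnames(m) <- sub(REL_PREFIX, "", cols, fixed = TRUE)
  rownames(m) <- x$subject_id
  m
}

set_relvol_matrix <- function(x, m) {
  stopifnot(nrow(m) == nrow(x))
  for (g in colnames(m)) x[[paste0(REL_PREFIX, g)]] <- as.numeric(m[, g])
  x
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects, %d scanners, %d ROIs, %d IQMs%s\n",
              nrow(x), length(unique(x$scanner)), length(roi_names(x)),
              length(iqm_names(x)),
              if (length(relvol_names(x))) ", relative volumes present" else ""))
  invisible(x)
}

#' Column-mapping schema for reading cohort tables
#'
#' Maps the caller's column names onto the canonical roles. ROI and IQM column
#' lists are user-supplied; when `rois` is `NULL`, every column not mapped to a
#' role and not listed as an IQM is treated as an ROI volume column.
#'
#' @param subject,scanner,age,sex,tiv column names carrying each role.
#' @param qc_prob_image,qc_prob_seg optional quality-probability column names.
#' @param rois,iqms character vectors of ROI / IQM column names.
#' @param sex_levels two labels; the first is encoded 0, the second 1. Any
#'   other observed level is an error, never a third category.
#' @export
cohort_schema <- function(subject = "subject_id", scanner = "scanner",
                          age = "age", sex = "sex", tiv = "tiv",
                          qc_prob_image = NULL, qc_prob_seg = NULL,
                          rois = NULL, iqms = character(),
                          sex_levels = c("F", "M")) {
  stopifnot(length(sex_levels) == 2L)
  list(subject = subject, scanner = scanner, age = age, sex = sex, tiv = tiv,
       qc_prob_image = qc_prob_image, qc_prob_seg = qc_prob_seg,
       rois = rois, iqms = iqms, sex_levels = as.character(sex_levels))
}

#' Read a cohort table from CSV/TSV
#'
#' Reads a delimited file with a header row, applies the schema's column
#' mapping, coerces the canonical columns, and drops (with a reported count)
#' rows whose mandatory fields fail to parse.
#'
#' @param path file path.
#' @param schema a [cohort_schema()].
#' @param delim field delimiter; `NULL` sniffs between tab and comma.
#' @return a `cohort_table`; the number of dropped rows is available as
#'   `attr(, "n_dropped")`.
#' @export
read_cohort_table <- function(path, schema = cohort_schema(), delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (nrow(raw) == 0L) stop("table at ", path, " has no rows")
  roles <- c(subject = schema$subject, scanner = schema$scanner,
             age = schema$age, sex = schema$sex, tiv = schema$tiv)
  missing <- roles[!roles %in% names(raw)]
  if (length(missing))
    stop("schema error: mandatory column(s) not found in file: ",
         paste(sprintf("%s (role %s)", missing, names(missing)), collapse = ", "))

  df <- data.frame(subject_id = as.character(raw[[schema$subject]]),
                   scanner = as.character(raw[[schema$scanner]]),
                   age = suppressWarnings(as.numeric(raw[[schema$age]])),
                   tiv = suppressWarnings(as.numeric(raw[[schema$tiv]])),
                   stringsAsFactors = FALSE)
  sex_raw <- as.character(raw[[schema$sex]])
  unknown <- setdiff(unique(sex_raw[!is.na(sex_raw)]), schema$sex_levels)
  if (length(unknown))
    stop("unknown sex level(s): ", paste(unknown, collapse = ", "),
         " (expected ", paste(schema$sex_levels, collapse = "/"), ")")
  df$sex <- factor(sex_raw, levels = schema$sex_levels)

  for (qc in c("qc_prob_image", "qc_prob_seg")) {
    col <- schema[[qc]]
    if (!is.null(col)) {
      if (!col %in% names(raw)) stop("schema error: column not found: ", col)
      df[[qc]] <- suppressWarnings(as.numeric(raw[[col]]))
    }
  }

  taken <- c(unname(roles), schema$qc_prob_image, schema$qc_prob_seg, schema$iqms)
  rel_cols <- grep(REL_PREFIX, names(raw), fixed = TRUE, value = TRUE)
  rois <- schema$rois %||% setdiff(names(raw), c(taken, rel_cols))
  for (g in c(rois, schema$iqms, rel_cols))
    df[[g]] <- suppressWarnings(as.numeric(raw[[g]]))

  ok <- !is.na(df$subject_id) & nzchar(df$subject_id) &
    !is.na(df$scanner) & nzchar(df$scanner) &
    !is.na(df$age) & !is.na(df$sex) & !is.na(df$tiv)
  n_dropped <- sum(!ok)
  if (n_dropped) {
    message(n_dropped, " row(s) dropped: unparseable mandatory field(s)")
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid rows remain after coercion")
  out <- cohort_table(df, rois = rois, iqms = schema$iqms)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a cohort table to CSV/TSV
#'
#' Inverse of [read_cohort_table()]: values round-trip to within float text
#' precision (15 significant digits).
#'
#' @param table a `cohort_table`.
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_cohort_table <- function(table, path, delim = "\t") {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a FreeSurfer aseg.stats-style file
#'
#' Reads the comment header for the `EstimatedTotalIntraCranialVol` measure and
#' the whitespace-delimited body for per-structure volumes. Structure names are
#' preserved verbatim.
#'
#' @param path path to an `aseg.stats`-dialect file.
#' @return list with `roi_volumes` (named numeric, mm^3) and `tiv` (mm^3).
#' @export
parse_freesurfer_aseg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  tiv_line <- grep("^#\\s*Measure\\s+EstimatedTotalIntraCranialVol", lines, value = TRUE)
  if (!length(tiv_line))
    stop("no '# Measure EstimatedTotalIntraCranialVol' line in ", path)
  fields <- strsplit(tiv_line[1], ",")[[1]]
  tiv <- suppressWarnings(as.numeric(trimws(fields[length(fields) - 1L])))
  if (is.na(tiv)) stop("could not parse TIV value from measure line")

  vol_col <- 4L; name_col <- 5L
  hdr <- grep("^#\\s*ColHeaders", lines, value = TRUE)
  if (length(hdr)) {
    cols <- strsplit(trimws(sub("^#\\s*ColHeaders\\s*", "", hdr[1])), "\\s+")[[1]]
    vol_col <- match("Volume_mm3", cols)
    name_col <- match("StructName", cols)
    if (is.na(vol_col) || is.na(name_col))
      stop("ColHeaders line lacks Volume_mm3/StructName")
  }
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  vols <- numeric(0)
  for (i in body_idx) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < max(vol_col, name_col))
      stop("malformed body row at line ", i, " of ", path)
    v <- suppressWarnings(as.numeric(f[vol_col]))
    if (is.na(v)) stop("malformed body row at line ", i, " of ", path,
                       " (non-numeric volume)")
    nm <- f[name_col]
    if (nm %in% names(vols)) stop("duplicate StructName: ", nm)
    vols[nm] <- v
  }
  list(roi_volumes = vols, tiv = tiv)
}

#' Persist and reload fitted models
#'
#' A bundle is a directory holding a human-readable `manifest.json` (kind,
#' format version, creation time, feature names, training ranges and the
#' configuration snapshot used at fit time) plus a binary payload with the
#' estimator state. Reloading reproduces predictions bit-identically; a
#' manifest with an unknown format version refuses to load.
#'
#' @param model a fitted `combat_model`, `harmony_model`, or stepwise
#'   harmonization model list.
#' @param path bundle directory (created if absent).
#' @export
save_bundle <- function(model, path) {
  kind <- if (inherits(model, "combat_model")) "combat"
  else if (inherits(model, "harmony_model")) "harmony"
  else if (inherits(model, "stepwise_models")) "combat_stepwise"
  else stop("not a saveable model: ", paste(class(model), collapse = "/"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(kind = kind, version = BUNDLE_VERSION,
                   created = format(Sys.time(), tz = "UTC"),
                   package = as.character(utils::packageVersion("roiharmony")),
                   feature_names = bundle_features(model),
                   training_ranges = bundle_ranges(model),
                   config_snapshot = attr(model, "config") %||% list())
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(model, file.path(path, "payload.rds"))
  invisible(path)
}

bundle_features <- function(model) {
  if (inherits(model, "harmony_model")) model$feature_names
  else if (inherits(model, "combat_model")) model$features
  else unique(unlist(lapply(model, function(m) m$features)))
}

bundle_ranges <- function(model) {
  if (inherits(model, "harmony_model") && !is.null(model$training_ranges)) {
    r <- model$training_ranges
    setNames(lapply(seq_len(nrow(r)), function(i) unname(r[i, ])), rownames(r))
  } else list()
}

#' @rdname save_bundle
#' @return `load_bundle` returns the model with the parsed manifest attached as
#'   attribute `"manifest"`.
#' @export
load_bundle <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("not a model bundle (no manifest.json): ", path)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(manifest$version, BUNDLE_VERSION))
    stop("bundle format version ", manifest$version,
         " is not supported by this build (expected ", BUNDLE_VERSION, ")")
  payload <- file.path(path, "payload.rds")
  if (!file.exists(payload)) stop("bundle payload missing: ", payload)
  model <- tryCatch(readRDS(payload),
                    error = function(e) stop("corrupted bundle payload: ",
                                             conditionMessage(e)))
  attr(model, "manifest") <- manifest
  model
}
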