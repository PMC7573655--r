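test_that("read_cohort_table parses a delimited file and reports drops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tscanner\tage\tsex\ttiv\tLeft-Hippocampus",
               "s1\tA\t30\tF\t1500000\t3000",
               "s2\tA\t40\tM\t1400000\t3100",
               "s3\tB\t50\tF\t1600000\t2900"), path)
  tab <- read_cohort_table(path, cohort_schema(subject = "subject"))
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(roi_names(tab), "Left-Hippocampus")
  expect_equal(attr(tab, "n_dropped"), 0L)

  # unparseable age row is dropped with a reported count
  writeLines(c("subject\tscanner\tage\tsex\ttiv\tLeft-Hippocampus",
               "s1\tA\t30\tF\t1500000\t3000",
               "s2\tA\tabc\tM\t1400000\t3100",
               "s3\tB\t50\tF\t1600000\t2900"), path)
  expect_message(tab2 <- read_cohort_table(path, cohort_schema(subject = "subject")),
                 "1 row")
  expect_equal(nrow(tab2), 2L)
  expect_equal(attr(tab2, "n_dropped"), 1L)

  # missing mandatory column named in the error
  writeLines(c("subject\tage\tsex\ttiv\tLeft-Hippocampus",
               "s1\t30\tF\t1500000\t3000"), path)
  expect_error(read_cohort_table(path, cohort_schema(subject = "subject")),
               "scanner")
})

test_that("sex levels are a closed two-level set", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,scanner,age,sex,tiv,roi01",
               "s1,A,30,F,1500000,3000",
               "s2,A,40,X,1400000,3100"), path)
  expect_error(read_cohort_table(path), "unknown sex level")
})

test_that("write/read round-trips values", {
  sim <- small_sim(seed = 4)
  tab <- compute_relative_volumes(sim$cohort)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(tab, path)
  back <- read_cohort_table(path, cohort_schema(
    qc_prob_image = "qc_prob_image",
    rois = roi_names(tab), iqms = iqm_names(tab)))
  expect_equal(back$subject_id, tab$subject_id)
  expect_equal(back$age, tab$age, tolerance = 1e-12)
  expect_equal(relvol_matrix(back), relvol_matrix(tab), tolerance = 1e-12)
  expect_equal(as.matrix(as.data.frame(back)[, iqm_names(tab)]),
               as.matrix(as.data.frame(tab)[, iqm_names(tab)]),
               tolerance = 1e-12)
})

test_that("cohort_table enforces its invariants", {
  df <- data.frame(subject_id = c("a", "a"), scanner = "S", age = 30,
                   sex = "F", tiv = 1.5e6, roi01 = 3000)
  expect_error(cohort_table(df, rois = "roi01"), "unique")
  df2 <- data.frame(subject_id = c("a", "b"), scanner = c("S", ""), age = 30,
                    sex = "F", tiv = 1.5e6, roi01 = 3000)
  expect_error(cohort_table(df2, rois = "roi01"), "scanner")
  df3 <- data.frame(subject_id = "a", scanner = "S", age = 30, sex = "F",
                    tiv = -1, roi01 = 3000)
  expect_error(cohort_table(df3, rois = "roi01"), "tiv")
})

test_that("parse_freesurfer_aseg reads the stats dialect", {
  path <- withr::local_tempfile(fileext = ".stats")
  writeLines(c(
    "# Title Segmentation Statistics",
    "# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, 1500000.0, mm^3",
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean",
    "  1   4   1234   3000.5  Left-Lateral-Ventricle  25.0",
    "  2  10   5678   7100.2  Left-Thalamus           80.1"), path)
  res <- parse_freesurfer_aseg(path)
  expect_equal(res$tiv, 1.5e6)
  expect_equal(res$roi_volumes,
               c("Left-Lateral-Ventricle" = 3000.5, "Left-Thalamus" = 7100.2))

  writeLines(c("# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
               " 1 4 1 3000 A"), path)
  expect_error(parse_freesurfer_aseg(path), "EstimatedTotalIntraCranialVol")

  writeLines(c(
    "# Measure EstimatedTotalIntraCranialVol, eTIV, x, 1500000.0, mm^3",
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
    " 1 4 1 3000 A", " 2 5 1 3100 A"), path)
  expect_error(parse_freesurfer_aseg(path), "duplicate StructName")

  writeLines(c(
    "# Measure EstimatedTotalIntraCranialVol, eTIV, x, 1500000.0, mm^3",
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
    " 1 4 1 bad A"), path)
  expect_error(parse_freesurfer_aseg(path), "line 3")
})

test_that("model bundles round-trip bit-identically and check versions", {
  sim <- small_sim(seed = 5)
  tab <- compute_relative_volumes(sim$cohort)
  m <- relvol_matrix(tab)
  fit <- combat_fit(m, tab$scanner)
  dir <- withr::local_tempdir()
  save_bundle(fit, file.path(dir, "b"))
  fit2 <- load_bundle(file.path(dir, "b"))
  out1 <- combat_transform(fit, m, tab$scanner)
  out2 <- combat_transform(fit2, m, tab$scanner)
  expect_identical(out1$harmonized, out2$harmonized)

  # harmony model: >= 100 random inputs predict bit-identically after reload
  sh <- stepwise_harmonize(tab, steps = "scanner")
  hm <- harmony_train(tab, sh$corrections, seed = 1)
  save_bundle(hm, file.path(dir, "h"))
  hm2 <- load_bundle(file.path(dir, "h"))
  p1 <- predict_corrections(hm, tab)
  p2 <- predict_corrections(hm2, tab)
  expect_identical(p1$cumulative, p2$cumulative)
  expect_gte(nrow(p1$cumulative), 100L)

  expect_error(load_bundle(file.path(dir, "nope")), "manifest")
  mf <- jsonlite::read_json(file.path(dir, "b", "manifest.json"))
  mf$version <- "999.0"
  jsonlite::write_json(mf, file.path(dir, "b", "manifest.json"), auto_unbox = TRUE)
  expect_error(load_bundle(file.path(dir, "b")), "version")
})
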