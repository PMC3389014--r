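ext <- function(f) system.file("extdata", f, package = "morphclass")

write_tmp_stats <- function(lines) {
  path <- withr::local_tempfile(fileext = ".stats",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("aseg dialect parsing extracts labels and volumes verbatim", {
  p <- write_tmp_stats(c(
    "# subjectname subA",
    "# Measure EstimatedTotalIntraCranialVol, eTIV, estimate, 1500000.0, mm^3",
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
    " 1 10 7500 7500.0 Left-Thalamus",
    " 2 49 7600 7600.0 Right-Thalamus",
    " 3 30 30 30.0 vessel"
  ))
  rec <- parse_stats_file(p, dialect = "aseg")
  expect_s3_class(rec, "region_volume_record")
  expect_identical(rec$subject_id, "subA")
  expect_identical(rec$volumes,
                   c("Left-Thalamus" = 7500, "Right-Thalamus" = 7600,
                     vessel = 30))
  # summary '# Measure' lines (ICV etc.) are comments, never regions
  expect_false("eTIV" %in% names(rec$volumes))
})

test_that("the 'vessel' label (FreeSurfer's name for basal putamen) is kept as-is", {
  rec <- parse_stats_file(ext("sub01.aseg.stats"), dialect = "aseg")
  expect_true("vessel" %in% names(rec$volumes))
  expect_equal(rec$volumes[["vessel"]], 28.5)
})

test_that("parse errors are specific: bad volume cites the line, bad file the column", {
  p <- write_tmp_stats(c(
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
    " 1 10 7500 7500.0 Left-Thalamus",
    " 2 49 7600 abc Right-Thalamus"
  ))
  expect_error(parse_stats_file(p, dialect = "aseg"), "line 3.*abc")

  p2 <- write_tmp_stats(c(
    "# ColHeaders Index SegId NVoxels StructName",
    " 1 10 7500 Left-Thalamus"
  ))
  expect_error(parse_stats_file(p2, dialect = "aseg"), "Volume_mm3")

  p3 <- write_tmp_stats(c(
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
    " 1 10 7500 7500.0 Left-Thalamus",
    " 2 49 7600 7600.0 Left-Thalamus"
  ))
  expect_error(parse_stats_file(p3, dialect = "aseg"), "duplicate")
})

test_that("aparc regions get hemisphere prefixes from the file header", {
  lh <- parse_stats_file(ext("sub01.lh.aparc.stats"), dialect = "aparc")
  rh <- parse_stats_file(ext("sub01.rh.aparc.stats"), dialect = "aparc")
  expect_true(all(startsWith(names(lh$volumes), "lh_")))
  expect_true(all(startsWith(names(rh$volumes), "rh_")))
  expect_equal(lh$volumes[["lh_precentral"]], 12933.8)
  expect_equal(rh$volumes[["rh_precentral"]], 12703.1)
})

test_that("assembling merges aseg + both aparc hemispheres per subject", {
  demo <- read.csv(ext("demographics.csv"))
  recs <- unlist(lapply(c("sub01", "sub02"), function(s) {
    list(parse_stats_file(ext(paste0(s, ".aseg.stats")), "aseg"),
         parse_stats_file(ext(paste0(s, ".lh.aparc.stats")), "aparc"),
         parse_stats_file(ext(paste0(s, ".rh.aparc.stats")), "aparc"))
  }), recursive = FALSE)
  tab <- assemble_feature_table(recs, demo)
  expect_equal(dim(tab), c(2L, 13L))  # 5 aseg + 2x4 aparc
  # lexicographic region order, identical for all subjects
  expect_identical(tab$region_names, sort(tab$region_names, method = "radix"))
  expect_equal(tab$X["sub01", "vessel"], 28.5)
  expect_equal(tab$X["sub02", "rh_entorhinal"], 1745.5)
  # hand-computed sum of the sub01 aseg fixture rows
  aseg_cols <- c("Left-Thalamus-Proper", "Right-Thalamus-Proper", "vessel",
                 "Left-Putamen", "Right-Putamen")
  expect_equal(sum(tab$X["sub01", aseg_cols]),
               7523.0 + 7610.5 + 28.5 + 5110.2 + 5242.8)
})

test_that("assembly validates coverage and uses the all-subject intersection", {
  ra <- structure(list(subject_id = "A", source_file = "a",
                       volumes = c(r1 = 1, r2 = 2, r3 = 3)),
                  class = "region_volume_record")
  rb <- structure(list(subject_id = "B", source_file = "b",
                       volumes = c(r2 = 5, r3 = 6, r4 = 7)),
                  class = "region_volume_record")
  demo <- data.frame(subject_id = c("A", "B"), group = c("g1", "g2"),
                     age = c(40, 50), sex = c(0, 1))
  tab <- assemble_feature_table(list(ra, rb), demo)
  expect_identical(tab$region_names, c("r2", "r3"))

  expect_error(assemble_feature_table(list(ra, rb), demo,
                                      region_list = c("r2", "r4")),
               "A.*r4")
  # records without demographics are excluded with a warning
  rc <- structure(list(subject_id = "C", source_file = "c",
                       volumes = c(r2 = 1, r3 = 2)),
                  class = "region_volume_record")
  expect_warning(t2 <- assemble_feature_table(list(ra, rb, rc), demo), "C")
  expect_equal(nrow(t2$X), 2L)
})

test_that("feature-table CSV round-trips bit-identically", {
  tab <- generate_cohort(synthetic_config(n_pos = 4, n_neg = 4, n_regions = 6,
                                          planted_regions = 1, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path, positive_class = "meditator")
  expect_identical(back$X, tab$X)
  expect_identical(back$age, tab$age)
  expect_identical(back$group, tab$group)
})

test_that("assembling the same records twice gives identical column order", {
  demo <- read.csv(ext("demographics.csv"))
  recs <- unlist(lapply(c("sub01", "sub02"), function(s) {
    list(parse_stats_file(ext(paste0(s, ".aseg.stats")), "aseg"),
         parse_stats_file(ext(paste0(s, ".lh.aparc.stats")), "aparc"))
  }), recursive = FALSE)
  t1 <- assemble_feature_table(recs, demo)
  t2 <- assemble_feature_table(recs, demo)
  expect_identical(t1$region_names, t2$region_names)
  expect_identical(t1$X, t2$X)
})
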