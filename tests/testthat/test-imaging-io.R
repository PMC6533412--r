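# Data model validation and NIfTI/manifest round trips.

test_that("volume and mask constructors enforce their invariants", {
  expect_error(volume_image(array(1, c(2, 2)), c(1, 1, 1), "suv"), "3-D")
  expect_error(volume_image(array(c(1, NA), c(2, 1, 1)), c(1, 1, 1), "suv"),
               "non-finite")
  expect_error(volume_image(array(1, c(2, 2, 2)), c(1, -1, 1), "suv"),
               "positive")
  expect_error(seg_mask(array(0, c(2, 2, 2)), c(1, 1, 1)), "degenerate")
  expect_warning(m <- seg_mask(array(255, c(2, 2, 2)), c(1, 1, 1)),
                 "coerced")
  expect_true(all(m$data == 1))
})

test_that("case_record rejects grid mismatches between image and mask", {
  img <- volume_image(array(1, c(20, 20, 10)), c(1, 1, 1), "suv")
  bad_shape <- seg_mask(array(1, c(20, 20, 11)), c(1, 1, 1))
  good <- seg_mask(array(1, c(20, 20, 10)), c(1, 1, 1))
  bad_spacing <- seg_mask(array(1, c(20, 20, 10)), c(1, 1, 2))
  expect_error(case_record("a", list(suv = img), bad_shape), "grid mismatch")
  expect_error(case_record("a", list(suv = img), bad_spacing),
               "grid mismatch")
  cr <- case_record("a", list(suv = img), good, metastatic = TRUE)
  expect_s3_class(cr, "case_record")
  expect_true(cr$metastatic)
})

test_that("cohort rejects duplicate ids and labels are recoverable", {
  img <- volume_image(array(1, c(4, 4, 3)), c(1, 1, 1), "suv")
  msk <- seg_mask(array(1, c(4, 4, 3)), c(1, 1, 1))
  a <- case_record("a", list(suv = img), msk, TRUE)
  b <- case_record("b", list(suv = img), msk, FALSE)
  expect_error(cohort(list(a, a)), "duplicate")
  expect_identical(cohort_labels(cohort(list(a, b))), c(TRUE, FALSE))
})

test_that("write_cohort / read_manifest round-trips a synthetic cohort", {
  coh <- small_cohort(n = 2L, seed = 7L)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  expect_identical(basename(manifest), "manifest.csv")
  # 5 modalities + mask per case, plus the manifest
  expect_length(list.files(dir), length(coh) * 6L + 1L)
  back <- read_manifest(manifest)
  expect_identical(length(back), length(coh))
  for (i in seq_along(coh$cases)) {
    expect_identical(back$cases[[i]]$case_id, coh$cases[[i]]$case_id)
    expect_identical(back$cases[[i]]$metastatic, coh$cases[[i]]$metastatic)
    expect_identical(names(back$cases[[i]]$images),
                     names(coh$cases[[i]]$images))
    expect_equal(back$cases[[i]]$mask$data, coh$cases[[i]]$mask$data)
    expect_equal(back$cases[[i]]$mask$spacing, coh$cases[[i]]$mask$spacing)
    for (m in names(coh$cases[[i]]$images))
      expect_equal(back$cases[[i]]$images[[m]]$data,
                   coh$cases[[i]]$images[[m]]$data, tolerance = 1e-6)
  }
})

test_that("read_case flags missing files, bad grids and empty masks", {
  dir <- withr::local_tempdir()
  img <- array(rnorm(20 * 20 * 10), c(20, 20, 10))
  msk <- array(0, c(20, 20, 10)); msk[8:12, 8:12, 4:6] <- 1
  write_vol <- function(a, f) {
    x <- RNifti::asNifti(a); RNifti::pixdim(x) <- c(1, 1, 1)
    RNifti::writeNifti(x, file.path(dir, f))
  }
  write_vol(img, "suv.nii.gz"); write_vol(msk, "mask.nii.gz")
  write_vol(array(0, c(20, 20, 11)), "mask_bad.nii.gz")
  write_vol(array(0, c(20, 20, 10)), "mask_empty.nii.gz")
  cr <- read_case(list(suv = file.path(dir, "suv.nii.gz")),
                  file.path(dir, "mask.nii.gz"), case_id = "c1")
  expect_identical(names(cr$images), "suv")
  expect_equal(cr$images$suv$data, img, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(read_case(list(suv = file.path(dir, "suv.nii.gz")),
                         file.path(dir, "mask_bad.nii.gz")), "grid|degenerate")
  expect_error(read_case(list(suv = file.path(dir, "suv.nii.gz")),
                         file.path(dir, "mask_empty.nii.gz")), "degenerate")
  expect_error(read_case(list(suv = file.path(dir, "nope.nii.gz")),
                         file.path(dir, "mask.nii.gz")), "not found")
})

test_that("manifest validation catches duplicates, bad labels and blanks", {
  coh <- small_cohort(n = 1L, seed = 3L)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  df <- read.csv(manifest, colClasses = "character")
  # duplicate id
  dup <- rbind(df, df)
  f1 <- file.path(dir, "dup.csv"); write.csv(dup, f1, row.names = FALSE)
  expect_error(read_manifest(f1), "duplicate")
  # unparsable label
  bad <- df; bad$metastatic <- "maybe"
  f2 <- file.path(dir, "bad.csv"); write.csv(bad, f2, row.names = FALSE)
  expect_error(read_manifest(f2), "label")
  # blank path cell -> missing modality
  blank <- df; blank$adc <- ""
  f3 <- file.path(dir, "blank.csv"); write.csv(blank, f3, row.names = FALSE)
  coh3 <- read_manifest(f3)
  expect_false("adc" %in% names(coh3$cases[[1]]$images))
  expect_true("suv" %in% names(coh3$cases[[1]]$images))
})
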