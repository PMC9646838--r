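test_that("spec validation names the offending field", {
  expect_error(cohort_spec(1, 1, lesion_fraction = 0), "lesion_fraction")
  expect_error(cohort_spec(1, 1, lesion_fraction = 1.2), "lesion_fraction")
  expect_error(cohort_spec(1, 1, patches_per_slide = c(0, 4)), "patches_per_slide")
  expect_error(cohort_spec(1, 1, censoring_rate = 1), "censoring_rate")
  expect_error(cohort_spec(1, 1, n_classes = 1), "n_classes")
})

test_that("negative-only cohorts carry no lesion patches", {
  spec <- cohort_spec(0, 3, patches_per_slide = 4, patch_size = 8, seed = 2)
  slides <- generate_cohort(spec)
  expect_length(slides, 3)
  expect_true(all(vapply(slides, function(s) length(s$patches), 0L) == 4))
  expect_false(any(unlist(lapply(slides, `[[`, "patch_truth"))))
  expect_true(all(vapply(slides, `[[`, 0L, "label") == 0L))
})

test_that("lesion count is round(fraction * n) with a floor of one", {
  spec <- cohort_spec(1, 0, patches_per_slide = 10, lesion_fraction = 0.1,
                      patch_size = 8, seed = 3)
  s <- generate_cohort(spec)[[1]]
  expect_identical(sum(s$patch_truth), 1L)
  # a fraction that rounds to zero still yields one lesion patch
  spec2 <- cohort_spec(1, 0, patches_per_slide = 10, lesion_fraction = 0.01,
                       patch_size = 8, seed = 3)
  expect_identical(sum(generate_cohort(spec2)[[1]]$patch_truth), 1L)
})

test_that("identical spec and seed reproduce byte-identical cohorts", {
  spec <- cohort_spec(2, 2, patches_per_slide = c(3, 6), patch_size = 16,
                      seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  sa <- generate_survival(a, spec)
  sb <- generate_survival(b, spec)
  expect_identical(sa, sb)
})

test_that("patch grids are unique and sizes uniform within a slide", {
  spec <- cohort_spec(3, 3, patches_per_slide = c(5, 17), patch_size = 16,
                      seed = 7)
  for (s in generate_cohort(spec)) {
    rc <- vapply(s$patches, function(p) paste(p$grid_row, p$grid_col), "")
    expect_false(any(duplicated(rc)))
    dims <- vapply(s$patches, function(p) paste(dim(p$img), collapse = "x"), "")
    expect_length(unique(dims), 1)
    rng <- range(unlist(lapply(s$patches, `[[`, "img")))
    expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  }
})

test_that("survival generation needs lesion flags and honours censoring", {
  spec <- cohort_spec(2, 2, patches_per_slide = 4, patch_size = 8, seed = 5)
  slides <- generate_cohort(spec)
  bad <- slides
  bad[[1]]$patch_truth <- NULL
  expect_error(generate_survival(bad, spec), "patch_truth")

  spec0 <- cohort_spec(5, 5, patches_per_slide = 4, patch_size = 8,
                       censoring_rate = 0, seed = 5)
  s0 <- generate_survival(generate_cohort(spec0), spec0)
  expect_true(all(vapply(s0, `[[`, 0L, "event") == 1L))
})

test_that("null hazard decouples time from burden; positive hazard orders terciles", {
  # 500 slides, tiny patches: burden spread comes from a lesion-fraction range
  spec <- cohort_spec(250, 250, patches_per_slide = c(4, 8), patch_size = 8,
                      lesion_fraction = c(0.1, 0.9), hazard_coef = 0,
                      censoring_rate = 0, seed = 23)
  slides <- generate_survival(generate_cohort(spec), spec)
  burden <- vapply(slides, function(s) mean(s$patch_truth), 0)
  tt <- vapply(slides, `[[`, 0, "time")
  expect_lt(abs(stats::cor(burden, tt, method = "spearman")), 0.1)

  spec2 <- cohort_spec(250, 250, patches_per_slide = c(4, 8), patch_size = 8,
                       lesion_fraction = c(0.1, 0.9), hazard_coef = 2,
                       censoring_rate = 0, seed = 23)
  slides2 <- generate_survival(generate_cohort(spec2), spec2)
  burden2 <- vapply(slides2, function(s) mean(s$patch_truth), 0)
  tt2 <- vapply(slides2, `[[`, 0, "time")
  hi <- tt2[burden2 >= stats::quantile(burden2, 2 / 3)]
  zero <- tt2[burden2 == 0]
  expect_lt(mean(hi), mean(zero))
})

test_that("achieved censoring fraction tracks the requested rate", {
  spec <- cohort_spec(250, 250, patches_per_slide = c(4, 8), patch_size = 8,
                      lesion_fraction = c(0.1, 0.9), censoring_rate = 0.3,
                      seed = 31)
  slides <- generate_survival(generate_cohort(spec), spec)
  cens <- 1 - mean(vapply(slides, `[[`, 0L, "event"))
  expect_lt(abs(cens - 0.3), 0.05)
})

test_that("cohorts round-trip through the on-disk PNG + manifest layout", {
  spec <- cohort_spec(1, 1, patches_per_slide = 4, patch_size = 16, seed = 13)
  slides <- generate_survival(generate_cohort(spec), spec)
  dir <- withr::local_tempdir()
  write_cohort(slides, dir)
  back <- read_cohort(dir)
  expect_length(back, 2)
  expect_identical(back[[1]]$slide_id, slides[[1]]$slide_id)
  expect_equal(back[[1]]$time, slides[[1]]$time, tolerance = 1e-6)
  # PNG quantises to 8 bits
  expect_equal(back[[1]]$patches[[1]]$img, slides[[1]]$patches[[1]]$img,
               tolerance = 1 / 254)
  expect_identical(back[[1]]$patches[[2]]$grid_row,
                   slides[[1]]$patches[[2]]$grid_row)
})
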