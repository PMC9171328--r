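test_that("label grouping conserves voxels and hits all eight tissues", {
  ph <- make_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 2L,
                                  lesion_count = 1L))
  tis <- group_labels(ph$labels, ph$scheme, "tissue")
  expect_equal(sort(unique(as.vector(tis$labels[tis$labels != 0L]))), 1:8)
  # conservation per class: cWM = left + right structures minus nothing
  expect_equal(sum(tis$labels == 3L),
               sum(ph$labels$labels %in% c(21L, 22L)))
  expect_equal(sum(tis$labels != 0L), sum(ph$labels$labels != 0L))

  # idempotence at the same scale (tissue ids relabeled through an identity scheme)
  idsch <- label_scheme(data.frame(
    label_id = 1:8, name = densefuse:::TISSUE_CLASSES,
    hemisphere = "none", tissue_class = densefuse:::TISSUE_CLASSES,
    lobe_class = NA))
  expect_identical(group_labels(tis, idsch, "tissue")$labels, tis$labels)

  # structures without the requested class raise unless zeroing is requested
  expect_error(group_labels(ph$labels, ph$scheme, "lobe"), "without")
  lz <- group_labels(ph$labels, ph$scheme, "lobe", na_action = "zero")
  expect_equal(sum(lz$labels != 0L),
               sum(ph$labels$labels %in% c(11L, 12L, 13L, 14L)))
})

test_that("volumes scale with the voxel size and the native determinant", {
  lab <- array(0L, c(12, 12, 12)); lab[1:10, 1:10, 1:10] <- 3L
  lv <- label_volume(lab)
  v <- structure_volumes(lv)
  expect_equal(v$volume_mm3_template, 1000)
  expect_equal(structure_volumes(lv, native_affine_det = 2)$volume_mm3_native,
               2000)
  # anisotropic voxels enter through the affine determinant
  lv2 <- label_volume(lab, affine = diag(c(2, 1, 1, 1)))
  expect_equal(structure_volumes(lv2)$volume_mm3_template, 2000)

  # structure volumes partition the labeled region
  ph <- make_phantom(phantom_spec(shape = c(32L, 32L, 32L)))
  sv <- structure_volumes(ph$labels)
  expect_equal(sum(sv$n_voxels), sum(ph$labels$labels != 0L))
})

test_that("asymmetry ratios are normalized, signed, and antisymmetric", {
  sc <- toy_scheme()
  vols <- data.frame(label_id = c(11L, 12L, 21L, 22L),
                     n_voxels = c(5, 5, 1, 3),
                     volume_mm3_template = c(5, 5, 1, 3),
                     volume_mm3_native = c(5, 5, 1, 3))
  a <- asymmetry_ratios(vols, sc)
  expect_equal(a$asymmetry_pct[a$left_id == 11L], 0)
  expect_equal(a$asymmetry_pct[a$left_id == 21L], 100)

  swapped <- vols; swapped$volume_mm3_template <- c(5, 5, 3, 1)
  b <- asymmetry_ratios(swapped, sc)
  expect_equal(b$asymmetry_pct[b$left_id == 21L], -100)

  # both-zero pair is undefined
  vols$volume_mm3_template <- c(0, 0, 1, 3)
  expect_true(is.na(asymmetry_ratios(vols, sc)$asymmetry_pct[1]))
})

test_that("thickness summaries are masked means over positive voxels", {
  lab <- array(0L, c(8, 8, 8)); lab[1:4, , ] <- 11L; lab[5:8, , ] <- 12L
  lv <- label_volume(lab)
  th <- array(2.5, c(8, 8, 8))
  s <- thickness_summary(th, lv)
  expect_equal(s$thickness_mean_mm, c(2.5, 2.5))
  expect_equal(s$thickness_sd_mm, c(0, 0))

  # region with no positive thickness is omitted
  th[lab == 12L] <- 0
  s <- thickness_summary(th, lv)
  expect_equal(s$label_id, 11L)

  set.seed(9)
  th <- array(runif(512), c(8, 8, 8))
  s <- thickness_summary(th, lv, 11L)
  ref <- th[lab == 11L & th > 0]
  expect_equal(s$thickness_mean_mm, mean(ref))
  expect_equal(s$thickness_sd_mm, sd(ref))
})

test_that("reports assemble all scales and write deterministically", {
  ph <- make_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 3L))
  rep1 <- volume_report(ph$labels, ph$scheme)
  expect_setequal(unique(rep1$scale), c("ICC", "tissue", "lobe", "structure"))
  # tissue rows partition the ICC volume
  expect_equal(sum(rep1$volume_mm3_template[rep1$scale == "tissue"]),
               rep1$volume_mm3_template[rep1$scale == "ICC"])
  # mirror-symmetric noiseless phantom: near-zero asymmetries
  asym <- rep1$asymmetry_pct[rep1$scale == "structure"]
  expect_lt(max(abs(asym), na.rm = TRUE), 5)

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_report(rep1, f1)
  write_report(volume_report(ph$labels, ph$scheme), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  back <- read_report(f1)
  expect_equal(nrow(back), nrow(rep1))
  expect_equal(back$volume_mm3_template, rep1$volume_mm3_template)

  # thickness columns appear only when a map is supplied
  expect_false("thickness_mean_mm" %in% names(rep1))
  th <- array(2, dim(ph$labels$labels))
  rep2 <- volume_report(ph$labels, ph$scheme, thickness_map = th)
  expect_true("thickness_mean_mm" %in% names(rep2))
  i <- which(rep2$scale == "structure" & rep2$region == "left frontal cortex")
  expect_equal(rep2$thickness_mean_mm[i], 2)
})
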