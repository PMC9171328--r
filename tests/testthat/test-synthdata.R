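test_that("phantoms are deterministic, mirror-symmetric, and fully labeled", {
  sp <- phantom_spec(shape = c(32L, 32L, 32L), seed = 17L)
  p1 <- make_phantom(sp)
  p2 <- make_phantom(sp)
  expect_identical(p1$image$voxels, p2$image$voxels)
  expect_identical(p1$labels$labels, p2$labels$labels)

  # noiseless: per-tissue intensities are exactly the specified means
  sp0 <- phantom_spec(shape = c(32L, 32L, 32L), noise_sigma = 0)
  p0 <- make_phantom(sp0)
  for (tis in c("cGM", "cWM", "CSF")) {
    ids <- p0$scheme$entries$label_id[p0$scheme$entries$tissue_class == tis]
    sel <- array(p0$labels$labels %in% ids, dim(p0$labels$labels))
    expect_equal(unique(p0$image$voxels[sel]), unname(sp0$means[[tis]]))
  }

  # mirror symmetry: flipping the noiseless phantom reproduces it
  fl <- flip_lr(p0$image, p0$labels, p0$scheme)
  expect_identical(fl$image$voxels, p0$image$voxels)
  expect_identical(fl$labels$labels, p0$labels$labels)

  # labels partition the intracranial ellipsoid: nonzero exactly inside it
  d <- dim(p0$labels$labels)
  ctr <- (d - 1) / 2
  ax <- 0.42 * d
  idx <- which(array(TRUE, d), arr.ind = TRUE) - 1
  rho <- sqrt(((idx[, 1] - ctr[1]) / ax[1])^2 + ((idx[, 2] - ctr[2]) / ax[2])^2 +
                ((idx[, 3] - ctr[3]) / ax[3])^2)
  expect_identical(as.vector(p0$labels$labels != 0L), rho <= 1)
})

test_that("library members are warped copies with bounded volume change", {
  sp0 <- phantom_spec(shape = c(32L, 32L, 32L), noise_sigma = 0,
                      deformation_amplitude = 0, intensity_jitter = 0)
  lb0 <- make_library(sp0, n_members = 2L, seed = 1L)
  expect_identical(lb0$library$images[[1]]$voxels, lb0$base$image$voxels)
  expect_identical(lb0$library$images[[2]]$voxels, lb0$base$image$voxels)
  expect_identical(lb0$library$labels[[1]]$labels, lb0$base$labels$labels)

  # at the generator's default conditions (48^3, amplitude 2) no structure
  # gains or loses more than 20% of its volume in any member
  fx <- acc_fixture()
  base_v <- structure_volumes(fx$lb$base$labels)
  for (m in seq_len(fx$lb$library$N)) {
    mv <- structure_volumes(fx$lb$library$labels[[m]])
    shared <- intersect(base_v$label_id, mv$label_id)
    rel <- abs(mv$n_voxels[match(shared, mv$label_id)] -
                 base_v$n_voxels[match(shared, base_v$label_id)]) /
      base_v$n_voxels[match(shared, base_v$label_id)]
    expect_lt(max(rel), 0.20)
  }
  # different seeds give different members
  lb <- tiny_library()
  expect_false(identical(lb$library$images[[1]]$voxels,
                         lb$library$images[[2]]$voxels))
})

test_that("lesion insertion stays inside white matter", {
  sp <- phantom_spec(shape = c(32L, 32L, 32L), seed = 6L, lesion_count = 2L)
  base <- make_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 6L))
  les <- make_phantom(sp)
  changed <- which(les$labels$labels != base$labels$labels)
  expect_gt(length(changed), 0)
  expect_true(all(les$labels$labels[changed] %in% c(71L, 72L)))
  expect_true(all(base$labels$labels[changed] %in% c(21L, 22L)))
  expect_equal(length(changed), sum(les$labels$labels %in% c(71L, 72L)))
  # lesion intensities sit near the cGM mean, far from the WM mean
  expect_lt(abs(mean(les$image$voxels[changed]) - sp$means[["cGM"]]), 10)

  sp$lesion_count <- 0L
  id <- insert_lesions(base$image, base$labels, sp)
  expect_identical(id$labels$labels, base$labels$labels)
})

test_that("systematic corruption moves cGM into cWM deterministically", {
  ph <- make_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 8L))
  expect_identical(
    corrupt_segmentation(ph$labels, ph$scheme, "dilate_cGM_into_cWM", 0,
                         seed = 1L)$labels,
    ph$labels$labels)

  cgm <- c(11L, 13L, 12L, 14L)
  cwm <- c(21L, 22L)
  count <- function(l, ids) sum(l$labels %in% ids)
  co <- corrupt_segmentation(ph$labels, ph$scheme, "dilate_cGM_into_cWM", 0.5,
                             seed = 2L)
  gain <- count(co, cgm) - count(ph$labels, cgm)
  loss <- count(ph$labels, cwm) - count(co, cwm)
  expect_gt(gain, 0)
  expect_equal(gain, loss)

  d_small <- mean(dice(corrupt_segmentation(ph$labels, ph$scheme,
                                            "dilate_cGM_into_cWM", 0.25,
                                            seed = 2L),
                       ph$labels)$dice, na.rm = TRUE)
  d_big <- mean(dice(corrupt_segmentation(ph$labels, ph$scheme,
                                          "dilate_cGM_into_cWM", 0.9,
                                          seed = 2L),
                     ph$labels)$dice, na.rm = TRUE)
  expect_lt(d_big, d_small)
  expect_lt(d_small, 1)

  sh <- corrupt_segmentation(ph$labels, ph$scheme, "shift", 2, seed = 1L)
  expect_lt(mean(dice(sh, ph$labels)$dice, na.rm = TRUE), 1)
})
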