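test_that("distance map measures voxels to the structure contour", {
  d <- c(16L, 16L, 16L)
  lab <- array(0L, d)
  lab[7:9, 7:9, 7:9] <- 4L  # isolated 3^3 cube
  lv <- label_volume(lab)
  dm <- distance_map(lv, 4L)
  # every cube voxel except the center is contour
  expect_equal(dm[7, 7, 7], 0)
  expect_equal(dm[8, 8, 8], 1)
  expect_error(distance_map(lv, 99L), "absent")

  # random blob vs exhaustive all-pairs distances
  set.seed(11)
  lab <- array(0L, d)
  lab[sample(prod(d), 40)] <- 2L
  lv <- label_volume(lab)
  dm <- distance_map(lv, 2L)
  inside <- array(lab == 2L, d)
  nb_out <- array(FALSE, d)
  # 6-neighbor outside test, brute force
  contour <- which(inside, arr.ind = TRUE)
  is_contour <- apply(contour, 1, function(v) {
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      w <- v; w[ax] <- w[ax] + s
      if (any(w < 1) || any(w > d)) return(TRUE)
      if (!inside[w[1], w[2], w[3]]) return(TRUE)
    }
    FALSE
  })
  cpts <- contour[is_contour, , drop = FALSE]
  for (i in sample(prod(d), 25)) {
    v <- arrayInd(i, d)
    ref <- sqrt(min(colSums((t(cpts) - as.vector(v))^2)))
    expect_equal(dm[i], ref)
  }
})

test_that("feature vectors have the fixed 112-entry layout", {
  ph <- make_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 2L))
  X <- pec_features(ph$image, ph$labels, 21L, c(16L, 16L, 16L))
  expect_equal(ncol(X), 112L)
  expect_equal(nrow(X), 1L)

  # constant image and constant (binary) segmentation: first 108 constant
  cimg <- image_volume(array(3, c(16, 16, 16)))
  clab <- label_volume(array(5L, c(16, 16, 16)))
  dm <- array(0, c(16, 16, 16))
  X <- pec_features(cimg, clab, 5L, rbind(c(8L, 8L, 8L), c(4L, 9L, 12L)),
                    dmap = dm)
  expect_equal(unname(apply(X[, 1:108], 2, function(col) length(unique(col)))),
               rep(1L, 108))

  # the voxel sitting at the world origin reports coordinates (0, 0, 0)
  aff <- diag(4); aff[1:3, 4] <- c(-7, -7, -7)
  cimg <- image_volume(array(0, c(16, 16, 16)), aff)
  clab <- label_volume(array(1L, c(16, 16, 16)), aff)
  X <- pec_features(cimg, clab, 1L, c(8L, 8L, 8L), dmap = dm)
  expect_equal(unname(X[1, 110:112]), c(0, 0, 0))
})

pec_fixture <- function() {
  if (is.null(fixture_env$pec)) {
    lb <- make_library(phantom_spec(shape = c(32L, 32L, 32L), seed = 13L),
                       n_members = 3L, seed = 21L)
    fixture_env$pec <- lb
  }
  fixture_env$pec
}

test_that("training is seeded, sized, and a near-no-op on error-free data", {
  lb <- pec_fixture()
  tr <- lapply(1:2, function(m) list(t1 = lb$library$images[[m]],
                                     auto = lb$library$labels[[m]],
                                     manual = lb$library$labels[[m]]))
  m1 <- pec_train(tr, 21L, n_samples = 400L, ensemble_size = 3L,
                  epochs = 4L, seed = 3L)
  m2 <- pec_train(tr, 21L, n_samples = 400L, ensemble_size = 3L,
                  epochs = 4L, seed = 3L)
  expect_equal(m1$networks[[1]]$W, m2$networks[[1]]$W)
  expect_equal(length(m1$networks), 3L)

  mfull <- pec_train(tr, 21L, n_samples = 400L, ensemble_size = 10L,
                     epochs = 2L, seed = 3L)
  expect_equal(length(mfull$networks), 10L)

  # error-free training data: applying the model changes almost nothing
  t1 <- lb$library$images[[3]]
  auto <- lb$library$labels[[3]]
  fixed <- pec_apply(m1, t1, auto)
  changed <- mean(fixed$labels != auto$labels)
  expect_lte(changed, 0.01)
})

test_that("the corrector removes an injected systematic dilation", {
  lb <- pec_fixture()
  corrupt <- function(m, s)
    corrupt_segmentation(lb$library$labels[[m]], lb$scheme,
                         "dilate_cGM_into_cWM", 0.5, seed = s)
  tr <- lapply(1:2, function(m) list(t1 = lb$library$images[[m]],
                                     auto = corrupt(m, m),
                                     manual = lb$library$labels[[m]]))
  mod <- pec_train(tr, 21L, n_samples = 1500L, ensemble_size = 5L,
                   epochs = 15L, seed = 4L)
  auto <- corrupt(3, 33)
  manual <- lb$library$labels[[3]]
  fixed <- pec_apply(mod, lb$library$images[[3]], auto)
  before <- dice(auto, manual, 21L)$dice
  after <- dice(fixed, manual, 21L)$dice
  expect_gt(after, before)

  # locality: voxels beyond the contour band are untouched
  dm <- distance_map(auto, 21L)
  far <- dm > mod$band + 1e-9
  expect_identical(fixed$labels[far], auto$labels[far])
})

test_that("corrector models serialize to portable text and back", {
  lb <- pec_fixture()
  tr <- list(list(t1 = lb$library$images[[1]], auto = lb$library$labels[[1]],
                  manual = lb$library$labels[[1]]))
  mod <- pec_train(tr, 21L, n_samples = 200L, ensemble_size = 2L,
                   epochs = 2L, seed = 9L)
  f <- withr::local_tempfile(fileext = ".txt")
  write_pec_model(mod, f)
  back <- read_pec_model(f)
  expect_equal(back$networks, mod$networks)
  expect_equal(back$center, mod$center)
  out1 <- pec_apply(mod, lb$library$images[[1]], lb$library$labels[[1]])
  out2 <- pec_apply(back, lb$library$images[[1]], lb$library$labels[[1]])
  expect_identical(out1$labels, out2$labels)
})
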