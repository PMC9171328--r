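test_that("patch distance is the element-mean of squared differences", {
  p <- array(1, c(3, 3, 3))
  expect_equal(patch_distance(p, p), 0)
  expect_equal(patch_distance(p, array(0, c(3, 3, 3))), 1)

  set.seed(1)
  a <- array(rnorm(8), c(2, 2, 2))
  b <- array(rnorm(8), c(2, 2, 2))
  brute <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    brute <- brute + (a[i, j, k] - b[i, j, k])^2
  expect_equal(patch_distance(a, b), brute / 8)
  expect_error(patch_distance(a, array(0, c(3, 3, 3))), "differ")
})

test_that("patch weights peak at the minimum distance", {
  expect_equal(patch_weights(c(0, 2, 5))[1], 1)
  w <- patch_weights(c(0.5, 1.0), h_epsilon = 1e-9)
  expect_equal(w, c(exp(-1), exp(-2)), tolerance = 1e-6)
  set.seed(2)
  d <- sort(runif(20))
  expect_true(all(diff(patch_weights(d)) <= 0))
  expect_error(patch_weights(numeric(0)), "empty")
})

test_that("exhaustive fusion matches an independent triple-loop oracle", {
  set.seed(3)
  d <- c(8L, 8L, 8L)
  mk <- function() image_volume(array(rnorm(prod(d), 100, 10), d))
  mkl <- function() label_volume(array(sample(c(0L, 3L, 7L), prod(d), TRUE), d))
  lib <- atlas_library(list(mk(), mk()), list(mkl(), mkl()))
  sub <- mk()
  mask <- array(FALSE, d); mask[3:6, 3:6, 3:6] <- TRUE
  pars <- fusion_params(patch_sizes = c(3, 3), search_radius = 1)
  p <- fuse_labels_exhaustive(sub, lib, mask, 3L, pars)
  o <- slow_fuse(sub, lib, mask, 3L, 1L)
  expect_equal(p$labels, o$labels)
  expect_lt(max(abs(p$maps - o$maps)), 1e-12)
  # per-voxel normalization
  expect_lt(max(abs(apply(p$maps, 1:3, sum)[mask] - 1)), 1e-6)
})

test_that("identical images with conflicting labels split the vote", {
  d <- c(6L, 6L, 6L)
  img <- image_volume(array(50, d))
  l1 <- label_volume(array(1L, d))
  l2 <- label_volume(array(2L, d))
  lib <- atlas_library(list(img, img), list(l1, l2))
  mask <- array(FALSE, d); mask[3, 3, 3] <- TRUE
  p <- fuse_labels_exhaustive(img, lib, mask, 3L,
                              fusion_params(patch_sizes = c(3, 3), search_radius = 1))
  expect_equal(p$maps[3, 3, 3, ], c(0.5, 0.5))
})

test_that("a subject present in its own library is reproduced", {
  lb <- tiny_library()
  sub <- lb$base$image
  distractor <- lb$library
  lib <- atlas_library(c(list(sub), distractor$images[1]),
                       c(list(lb$base$labels), distractor$labels[1]))
  mask <- lb$base$labels$labels != 0L
  p <- fuse_labels_exhaustive(sub, lib, mask, 3L, fusion_params(search_radius = 2))
  am <- argmax_labels(p)
  agree <- mean(am$labels[mask] == lb$base$labels$labels[mask])
  expect_gte(agree, 0.999)
})

test_that("the ANNF is deterministic, monotone, and exact on tiny pools", {
  lb <- tiny_library()
  sub <- lb$library$images[[1]]
  lib <- atlas_library(lb$library$images[2:3], lb$library$labels[2:3])
  mask <- array(FALSE, c(32, 32, 32)); mask[10:22, 10:22, 10:22] <- TRUE

  pars <- fusion_params(patch_sizes = c(3, 3), search_radius = 2,
                        annf_k = 4, annf_iterations = 2, seed = 99)
  f1 <- build_annf(sub, lib, mask, 3L, pars)
  f2 <- build_annf(sub, lib, mask, 3L, pars)
  expect_identical(f1$subject, f2$subject)
  expect_identical(f1$position, f2$position)
  expect_identical(f1$distance, f2$distance)

  # mean best distance non-increasing in the iteration count
  means <- sapply(1:4, function(it) {
    p <- fusion_params(patch_sizes = c(3, 3), search_radius = 2,
                       annf_k = 4, annf_iterations = it, seed = 7)
    mean(build_annf(sub, lib, mask, 3L, p)$distance[, 1])
  })
  expect_true(all(diff(means) <= 1e-12))

  # pool <= k: the field must equal the exhaustive best-k
  pars0 <- fusion_params(patch_sizes = c(1, 1), search_radius = 0,
                         annf_k = 2, annf_iterations = 1)
  f0 <- build_annf(sub, lib, mask, 1L, pars0)
  # with radius 0 the only candidate position is the voxel itself, per member
  i <- 5L
  v <- f0$vox[i]
  expect_setequal(f0$position[i, ], c(v, v))
  expect_setequal(f0$subject[i, ], c(0L, 1L))
})

test_that("ANNF fusion with the full candidate pool matches the oracle", {
  set.seed(8)
  d <- c(8L, 8L, 8L)
  mk <- function() image_volume(array(rnorm(prod(d), 100, 10), d))
  mkl <- function() label_volume(array(sample(c(0L, 2L, 9L), prod(d), TRUE), d))
  lib <- atlas_library(list(mk(), mk()), list(mkl(), mkl()))
  sub <- mk()
  mask <- array(FALSE, d); mask[3:6, 3:6, 3:6] <- TRUE
  # k = full pool (2 members x 27 window positions) -> exhaustive equivalence
  pars <- fusion_params(patch_sizes = c(3, 3), search_radius = 1,
                        annf_k = 54, annf_iterations = 1)
  f <- build_annf(sub, lib, mask, 3L, pars)
  pa <- fuse_labels_annf(sub, lib, f, 3L, pars, voting = "central")
  o <- slow_fuse(sub, lib, mask, 3L, 1L)
  expect_lt(max(abs(pa$maps - o$maps)), 1e-12)
})

test_that("unanimous candidate labels give probability one", {
  d <- c(6L, 6L, 6L)
  set.seed(4)
  img <- image_volume(array(rnorm(prod(d)), d))
  lib <- atlas_library(list(img), list(label_volume(array(5L, d))))
  mask <- array(TRUE, d)
  pars <- fusion_params(patch_sizes = c(3, 3), search_radius = 1,
                        annf_k = 4, annf_iterations = 1)
  f <- build_annf(img, lib, mask, 3L, pars)
  p <- fuse_labels_annf(img, lib, f, 3L, pars)
  expect_equal(max(abs(p$maps[, , , 1] - 1)), 0)
})

test_that("multiscale mixing is a convex combination with exact endpoints", {
  lb <- tiny_library()
  sub <- lb$library$images[[1]]
  lib <- atlas_library(lb$library$images[2:3], lb$library$labels[2:3])
  mask <- array(FALSE, c(32, 32, 32)); mask[14:18, 14:18, 14:18] <- TRUE
  pars <- fusion_params(annf_k = 4, annf_iterations = 2)
  f1 <- build_annf(sub, lib, mask, 3L, pars)
  p1 <- fuse_labels_annf(sub, lib, f1, 3L, pars)
  f2 <- build_annf(sub, lib, mask, 5L, pars)
  p2 <- fuse_labels_annf(sub, lib, f2, 5L, pars)

  expect_identical(fuse_multiscale(p1, p2, 1)$maps, p1$maps)
  expect_identical(fuse_multiscale(p1, p2, 0)$maps, p2$maps)
  pm <- fuse_multiscale(p1, p2, 0.5)
  i <- which(mask)[1]
  expect_equal(pm$maps[i], 0.5 * p1$maps[i] + 0.5 * p2$maps[i])
  expect_lt(max(abs(apply(pm$maps, 1:3, sum)[mask] - 1)), 1e-6)
})

test_that("argmax extraction takes the highest probability, lowest id on ties", {
  d <- c(4L, 4L, 4L)
  mask <- array(TRUE, d)
  maps <- array(0, c(d, 3))
  maps[, , , 2] <- 1
  p <- structure(list(labels = c(40L, 44L, 45L), maps = maps, mask = mask),
                 class = "probability_maps")
  expect_true(all(argmax_labels(p)$labels == 44L))

  # exact tie between 44 and 45 -> 44
  maps[, , , 2] <- 0.5; maps[, , , 3] <- 0.5
  p$maps <- maps
  expect_true(all(argmax_labels(p)$labels == 44L))

  # random maps agree with a per-voxel scan
  set.seed(6)
  maps <- array(runif(prod(d) * 3), c(d, 3))
  p$maps <- maps
  am <- argmax_labels(p)
  for (i in sample(prod(d), 10)) {
    v <- arrayInd(i, d)
    expect_equal(am$labels[i],
                 p$labels[which.max(maps[v[1], v[2], v[3], ])])
  }
})

test_that("ICC extraction recovers the intracranial mask", {
  lb <- tiny_library()
  sub <- lb$library$images[[1]]
  truth <- lb$library$labels[[1]]$labels != 0L
  bin <- function(l) label_volume(array(as.integer(l$labels != 0L),
                                        dim(l$labels)), l$affine)
  icc_lib <- atlas_library(lb$library$images[2:3],
                           lapply(lb$library$labels[2:3], bin))
  m <- extract_icc(sub, icc_lib, fusion_params(annf_k = 4, annf_iterations = 2))
  dsc <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gte(dsc, 0.95)

  expect_error(extract_icc(sub, atlas_library(lb$library$images[2:3],
                                              lb$library$labels[2:3])),
               "binary")
})
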