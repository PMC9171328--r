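# Independent brute-force oracle for non-local label fusion: plain R triple
# loop over masked voxels, window positions, and members, using only
# patch_distance / patch_weights semantics re-derived here. Deliberately slow
# and simple; never calls the compiled path it validates.

clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# patch with edge replication, as a vector
extract_patch <- function(arr, ctr, half) {
  d <- dim(arr)
  xs <- clamp((ctr[1] - half):(ctr[1] + half), 1, d[1])
  ys <- clamp((ctr[2] - half):(ctr[2] + half), 1, d[2])
  zs <- clamp((ctr[3] - half):(ctr[3] + half), 1, d[3])
  as.vector(arr[xs, ys, zs])
}

slow_fuse <- function(subject, library, mask, patch_size, radius,
                      h_eps = 1e-6) {
  d <- dim(subject$voxels)
  half <- patch_size %/% 2
  labels <- sort(unique(unlist(lapply(library$labels,
                                      function(l) unique(as.vector(l$labels))))))
  maps <- array(0, c(d, length(labels)))
  vox <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    v <- vox[r, ]
    pv <- extract_patch(subject$voxels, v, half)
    dists <- c()
    labs <- c()
    for (s in seq_len(library$N)) {
      xs <- clamp((v[1] - radius):(v[1] + radius), 1, d[1])
      ys <- clamp((v[2] - radius):(v[2] + radius), 1, d[2])
      zs <- clamp((v[3] - radius):(v[3] + radius), 1, d[3])
      for (zz in unique(zs)) for (yy in unique(ys)) for (xx in unique(xs)) {
        pj <- extract_patch(library$images[[s]]$voxels, c(xx, yy, zz), half)
        dists <- c(dists, mean((pv - pj)^2))
        labs <- c(labs, library$labels[[s]]$labels[xx, yy, zz])
      }
    }
    w <- exp(-dists / (min(dists) + h_eps))
    for (li in seq_along(labels))
      maps[v[1], v[2], v[3], li] <- sum(w[labs == labels[li]]) / sum(w)
  }
  list(labels = labels, maps = maps)
}

# small shared fixtures, built once per test run
fixture_env <- new.env(parent = emptyenv())

tiny_library <- function() {
  if (is.null(fixture_env$tiny)) {
    fixture_env$tiny <- make_library(
      phantom_spec(shape = c(32L, 32L, 32L), seed = 5L), n_members = 3L,
      seed = 2L)
  }
  fixture_env$tiny
}

# study-scale fixture: 48^3 phantom library of 10 members at the generator
# defaults, with a leave-one-out pipeline run; shared by several files
acc_fixture <- function() {
  if (is.null(fixture_env$acc)) {
    sp <- phantom_spec(shape = c(48L, 48L, 48L), seed = 3L)
    lb <- make_library(sp, n_members = 10L, seed = 7L)
    subject <- lb$library$images[[1]]
    truth <- lb$library$labels[[1]]
    library <- atlas_library(lb$library$images[-1], lb$library$labels[-1])
    res <- run_pipeline(subject, library, lb$scheme,
                        fusion_params(seed = 42L))
    fixture_env$acc <- list(sp = sp, lb = lb, subject = subject,
                            truth = truth, library = library, res = res)
  }
  fixture_env$acc
}

toy_scheme <- function() {
  label_scheme(
    data.frame(label_id = c(11L, 12L, 21L, 22L),
               name = c("left cGM", "right cGM", "left cWM", "right cWM"),
               hemisphere = c("left", "right", "left", "right"),
               tissue_class = c("cGM", "cGM", "cWM", "cWM"),
               lobe_class = NA),
    data.frame(left_id = c(11L, 21L), right_id = c(12L, 22L)))
}
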