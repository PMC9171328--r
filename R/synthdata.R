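#' Specification of a labeled brain phantom
#'
#' Describes the geometry, intensities, noise, lesion load, and
#' inter-subject deformation model of the synthetic labeled brains used as
#' the validation test bed. The geometry is a nested-ellipsoid caricature of
#' a head in template space: an intracranial ellipsoid holding a CSF shell,
#' a cortical GM ribbon around a cerebral WM core, subcortical GM blobs per
#' hemisphere, a cerebellum (GM shell / WM core), and a brainstem cylinder,
#' split left/right at the grid midplane into hemisphere-specific structures
#' with flip pairs.
#'
#' @param shape grid dimensions (voxels), default `c(48, 48, 48)`.
#' @param means named tissue intensity means (arbitrary units) for
#'   CSF, cGM, cWM, sGM, ceGM, ceWM, BS, WML. The default WML mean sits near
#'   the cGM mean, the failure mode lesion-robust fusion must handle.
#' @param noise_sigma Gaussian noise SD; default 2.5, i.e. 5% of the
#'   cGM-cWM contrast of the default means.
#' @param n_subcortical_blobs subcortical GM blobs per hemisphere (1 or 2).
#' @param lesion_count WM lesions per hemisphere pair to insert (0 = none).
#' @param lesion_radius inclusive integer radius range of lesion spheres.
#' @param deformation_amplitude per-axis SD (voxels) of the smooth random
#'   displacement fields applied to library members.
#' @param deformation_smoothness Gaussian smoothing SD (mm = voxels at the
#'   1 mm template resolution) of the displacement fields.
#' @param intensity_jitter multiplicative per-member intensity scale is
#'   drawn from `U(1 - j, 1 + j)`.
#' @param seed random seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L),
                         means = c(CSF = 10, cGM = 70, cWM = 120, sGM = 85,
                                   ceGM = 65, ceWM = 115, BS = 100, WML = 72),
                         noise_sigma = 2.5,
                         n_subcortical_blobs = 2L,
                         lesion_count = 0L,
                         lesion_radius = c(1L, 2L),
                         deformation_amplitude = 2,
                         deformation_smoothness = 8,
                         intensity_jitter = 0.05,
                         seed = 1L) {
  if (anyDuplicated(means)) stop("tissue intensity means must be distinct")
  miss <- setdiff(TISSUE_CLASSES, names(means))
  if (length(miss)) stop("means missing tissues: ", paste(miss, collapse = ", "))
  if (deformation_amplitude < 0) stop("deformation amplitude must be >= 0")
  if (any(shape < 32L)) stop("grid too small for the phantom geometry")
  if (!n_subcortical_blobs %in% 1:2) stop("n_subcortical_blobs must be 1 or 2")
  structure(list(shape = as.integer(shape), means = means,
                 noise_sigma = noise_sigma,
                 n_subcortical_blobs = as.integer(n_subcortical_blobs),
                 lesion_count = as.integer(lesion_count),
                 lesion_radius = as.integer(lesion_radius),
                 deformation_amplitude = deformation_amplitude,
                 deformation_smoothness = deformation_smoothness,
                 intensity_jitter = intensity_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# structure ids of the phantom labeling protocol
PHANTOM_IDS <- list(
  csf = 1L, cgm_front = c(L = 11L, R = 12L), cgm_post = c(L = 13L, R = 14L),
  cwm = c(L = 21L, R = 22L), sgm_a = c(L = 31L, R = 32L),
  sgm_b = c(L = 33L, R = 34L), cegm = c(L = 41L, R = 42L),
  cewm = c(L = 45L, R = 46L), bs = 60L, wml = c(L = 71L, R = 72L))

phantom_scheme <- function(n_blobs = 2L) {
  row <- function(id, name, hemi, tis, lobe = NA)
    data.frame(label_id = id, name = name, hemisphere = hemi,
               tissue_class = tis, lobe_class = lobe)
  e <- rbind(
    row(1L, "external CSF", "none", "CSF"),
    row(11L, "left frontal cortex", "left", "cGM", "frontal"),
    row(12L, "right frontal cortex", "right", "cGM", "frontal"),
    row(13L, "left posterior cortex", "left", "cGM", "posterior"),
    row(14L, "right posterior cortex", "right", "cGM", "posterior"),
    row(21L, "left cerebral WM", "left", "cWM"),
    row(22L, "right cerebral WM", "right", "cWM"),
    row(31L, "left thalamus-like blob", "left", "sGM"),
    row(32L, "right thalamus-like blob", "right", "sGM"))
  if (n_blobs >= 2L)
    e <- rbind(e,
               row(33L, "left putamen-like blob", "left", "sGM"),
               row(34L, "right putamen-like blob", "right", "sGM"))
  e <- rbind(e,
             row(41L, "left cerebellar GM", "left", "ceGM"),
             row(42L, "right cerebellar GM", "right", "ceGM"),
             row(45L, "left cerebellar WM", "left", "ceWM"),
             row(46L, "right cerebellar WM", "right", "ceWM"),
             row(60L, "brainstem", "none", "BS"),
             row(71L, "left WM lesions", "left", "WML"),
             row(72L, "right WM lesions", "right", "WML"))
  lefts <- e$label_id[e$hemisphere == "left"]
  pairs <- data.frame(left_id = lefts, right_id = lefts + 1L)
  label_scheme(e, pairs)
}

#' Generate a labeled brain phantom
#'
#' Builds the nested geometry of [phantom_spec()] on the requested grid,
#' assigns hemisphere-specific structure ids (mirror-symmetric about the
#' grid midplane), fills intensities with the tissue means plus Gaussian
#' noise, and optionally inserts WM lesions. Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` ([image_volume()]), `labels`
#'   ([label_volume()]), and `scheme` ([label_scheme()]).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  d <- spec$shape
  # world origin at the grid center so coordinate features are centered
  aff <- diag(4); aff[1:3, 4] <- -(d - 1) / 2
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2; cz <- (d[3] - 1) / 2
  x <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), d)
  y <- array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]), d)
  z <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d)

  rho <- function(ctr, ax) sqrt(((x - ctr[1]) / ax[1])^2 +
                                ((y - ctr[2]) / ax[2])^2 +
                                ((z - ctr[3]) / ax[3])^2)
  lab <- array(0L, d)
  # intracranial cavity: filled with CSF first
  icc <- rho(c(cx, cy, cz), 0.42 * d) <= 1
  lab[icc] <- PHANTOM_IDS$csf
  # cerebrum: cGM ribbon over cWM core, shifted superior
  rc <- rho(c(cx, cy, cz + 0.06 * d[3]), c(0.34, 0.36, 0.30) * d)
  left <- x < cx
  post <- y < cy
  sel <- icc & rc <= 1
  lab[sel & left & !post] <- PHANTOM_IDS$cgm_front["L"]
  lab[sel & !left & !post] <- PHANTOM_IDS$cgm_front["R"]
  lab[sel & left & post] <- PHANTOM_IDS$cgm_post["L"]
  lab[sel & !left & post] <- PHANTOM_IDS$cgm_post["R"]
  core <- icc & rc <= 0.78
  lab[core & left] <- PHANTOM_IDS$cwm["L"]
  lab[core & !left] <- PHANTOM_IDS$cwm["R"]
  # subcortical GM blobs inside the WM core
  blob <- function(ctr, r) rho(ctr, c(r, r, r)) <= 1
  r1 <- 0.085 * min(d)
  b <- blob(c(cx - 0.12 * d[1], cy + 0.02 * d[2], cz + 0.08 * d[3]), r1)
  lab[b & core & left] <- PHANTOM_IDS$sgm_a["L"]
  b <- blob(c(cx + 0.12 * d[1], cy + 0.02 * d[2], cz + 0.08 * d[3]), r1)
  lab[b & core & !left] <- PHANTOM_IDS$sgm_a["R"]
  if (spec$n_subcortical_blobs >= 2L) {
    b <- blob(c(cx - 0.17 * d[1], cy + 0.12 * d[2], cz + 0.10 * d[3]), r1)
    lab[b & core & left] <- PHANTOM_IDS$sgm_b["L"]
    b <- blob(c(cx + 0.17 * d[1], cy + 0.12 * d[2], cz + 0.10 * d[3]), r1)
    lab[b & core & !left] <- PHANTOM_IDS$sgm_b["R"]
  }
  # cerebellum: posterior-inferior ellipsoid, GM shell / WM core
  rcb <- rho(c(cx, cy - 0.24 * d[2], cz - 0.26 * d[3]), c(0.20, 0.15, 0.13) * d)
  sel <- icc & rcb <= 1
  lab[sel & left] <- PHANTOM_IDS$cegm["L"]
  lab[sel & !left] <- PHANTOM_IDS$cegm["R"]
  sel <- icc & rcb <= 0.7
  lab[sel & left] <- PHANTOM_IDS$cewm["L"]
  lab[sel & !left] <- PHANTOM_IDS$cewm["R"]
  # brainstem: midline cylinder, inferior
  bs <- icc & ((x - cx)^2 + (y - cy + 0.06 * d[2])^2 <= (0.07 * min(d))^2) &
    z >= cz - 0.40 * d[3] & z <= cz - 0.05 * d[3]
  lab[bs] <- PHANTOM_IDS$bs

  scheme <- phantom_scheme(spec$n_subcortical_blobs)
  set.seed(spec$seed)
  img <- tissue_intensities(lab, scheme, spec$means, spec$noise_sigma)
  out <- list(image = image_volume(img, aff),
              labels = label_volume(array(lab, d), aff),
              scheme = scheme)
  if (spec$lesion_count > 0L)
    out[c("image", "labels")] <- insert_lesions(out$image, out$labels, spec)
  out
}

# intensities from a label map: tissue mean per structure + Gaussian noise
tissue_intensities <- function(lab, scheme, means, sigma) {
  img <- array(0, dim(lab))
  for (i in seq_len(nrow(scheme$entries))) {
    id <- scheme$entries$label_id[i]
    sel <- lab == id
    if (any(sel)) img[sel] <- means[[scheme$entries$tissue_class[i]]]
  }
  if (sigma > 0) img <- img + array(rnorm(length(img), 0, sigma), dim(lab))
  img
}

#' Insert white-matter lesions into a phantom
#'
#' Places `lesion_count` spheres per hemisphere entirely inside cerebral WM,
#' relabels them with the hemisphere's WML id, and sets their intensity near
#' the cGM mean — so an intensity-only classifier would mislabel them as
#' gray matter, the failure mode a lesion-bearing library protects against.
#'
#' @param image,labels phantom volumes from [make_phantom()].
#' @param spec the [phantom_spec()] (fields `lesion_count`, `lesion_radius`,
#'   `means`, `noise_sigma`, `seed`).
#' @return A list with modified `image` and `labels`.
#' @export
insert_lesions <- function(image, labels, spec) {
  if (spec$lesion_count == 0L) return(list(image = image, labels = labels))
  lab <- labels$labels
  img <- image$voxels
  d <- dim(lab)
  set.seed(spec$seed + 7L)
  for (side in c("L", "R")) {
    wm_id <- PHANTOM_IDS$cwm[side]
    wml_id <- PHANTOM_IDS$wml[side]
    placed <- 0L
    tries <- 0L
    while (placed < spec$lesion_count && tries < 200L) {
      tries <- tries + 1L
      rs <- spec$lesion_radius[1]:spec$lesion_radius[2]
      r <- rs[sample.int(length(rs), 1L)]
      wm <- which(lab == wm_id, arr.ind = TRUE)
      if (nrow(wm) == 0L) stop("no cerebral WM to place lesions in")
      ctr <- wm[sample(nrow(wm), 1L), ]
      xr <- max(1L, ctr[1] - r):min(d[1], ctr[1] + r)
      yr <- max(1L, ctr[2] - r):min(d[2], ctr[2] + r)
      zr <- max(1L, ctr[3] - r):min(d[3], ctr[3] + r)
      sub <- expand.grid(x = xr, y = yr, z = zr)
      sub <- sub[(sub$x - ctr[1])^2 + (sub$y - ctr[2])^2 + (sub$z - ctr[3])^2 <= r^2, ]
      ind <- cbind(sub$x, sub$y, sub$z)
      if (!all(lab[ind] == wm_id)) next  # sphere must sit fully inside WM
      lab[ind] <- wml_id
      img[ind] <- spec$means[["WML"]] +
        rnorm(nrow(ind), 0, spec$noise_sigma)
      placed <- placed + 1L
    }
    if (placed < spec$lesion_count)
      stop("no room for the requested lesions in ", side, " WM")
  }
  list(image = image_volume(img, image$affine),
       labels = label_volume(lab, labels$affine))
}

# Smooth random displacement fields for one library member, built as the
# curl of a Gaussian-filtered random vector potential. The curl makes the
# field divergence-free (volume-preserving to first order): inter-subject
# residuals after affine registration deform shapes without inflating or
# deflating structures wholesale. Components are rescaled jointly so each
# axis has the requested displacement SD (voxels).
smooth_displacement3 <- function(d, amplitude, smoothness) {
  zero <- array(0, d)
  if (amplitude == 0) return(list(zero, zero, zero))
  A <- lapply(1:3, function(i) .cpp_gauss3d(array(rnorm(prod(d)), d), smoothness))
  dd <- function(f, ax) {  # central difference along one axis
    n <- d[ax]
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    if (ax == 1) (f[idx_p, , ] - f[idx_m, , ]) / 2
    else if (ax == 2) (f[, idx_p, ] - f[, idx_m, ]) / 2
    else (f[, , idx_p] - f[, , idx_m]) / 2
  }
  u <- list(dd(A[[3]], 2) - dd(A[[2]], 3),
            dd(A[[1]], 3) - dd(A[[3]], 1),
            dd(A[[2]], 1) - dd(A[[1]], 2))
  s <- mean(vapply(u, sd, numeric(1)))
  lapply(u, function(f) f / s * amplitude)
}

#' Generate a deformed atlas library from one phantom
#'
#' Emulates inter-subject anatomical variability after affine registration:
#' each member is the base phantom warped by a smooth random displacement
#' field (labels nearest-neighbor, intensities trilinear), with a per-member
#' global intensity scale jitter and fresh Gaussian noise. Ground-truth
#' labels are retained for every member.
#'
#' @param spec a [phantom_spec()] describing the base anatomy.
#' @param n_members library size.
#' @param seed seed governing all member-level randomness.
#' @return A list with `library` (an [atlas_library()]), `scheme`, and
#'   `base` (the undeformed phantom).
#' @export
make_library <- function(spec = phantom_spec(), n_members = 10L, seed = spec$seed) {
  if (n_members < 1L) stop("n_members must be >= 1")
  base <- make_phantom(spec)
  must_have <- setdiff(sort(unique(as.vector(base$labels$labels))), 0L)
  # noiseless base intensities: noise is re-drawn per member
  clean_spec <- spec; clean_spec$noise_sigma <- 0
  clean <- make_phantom(clean_spec)
  imgs <- vector("list", n_members)
  labs <- vector("list", n_members)
  d <- spec$shape
  for (m in seq_len(n_members)) {
    set.seed((seed + 1000L * m) %% .Machine$integer.max)
    disp <- smooth_displacement3(d, spec$deformation_amplitude,
                                 spec$deformation_smoothness)
    dx <- disp[[1]]; dy <- disp[[2]]; dz <- disp[[3]]
    wlab <- .cpp_warp_nearest(clean$labels$labels, dx, dy, dz)
    if (!all(must_have %in% wlab))
      stop("deformation amplitude too large: structures vanished in member ", m)
    wimg <- .cpp_warp_trilinear(clean$image$voxels, dx, dy, dz)
    scale <- runif(1, 1 - spec$intensity_jitter, 1 + spec$intensity_jitter)
    wimg <- wimg * scale + array(rnorm(prod(d), 0, spec$noise_sigma), d)
    imgs[[m]] <- image_volume(wimg, base$image$affine)
    labs[[m]] <- label_volume(wlab, base$labels$affine)
  }
  list(library = atlas_library(imgs, labs), scheme = base$scheme, base = base)
}

#' Inject a systematic segmentation error
#'
#' Produces the kind of reproducible, non-random labeling bias a corrective
#' learner is meant to remove. Mode `"dilate_cGM_into_cWM"` relabels a fixed
#' fraction (`magnitude` in `[0, 1]`) of cerebral-WM voxels that touch
#' cortical GM (6-connectivity) with the adjacent cGM id — cortical GM
#' overestimation at the cGM/cWM interface. Mode `"shift"` translates all
#' labels by `magnitude` voxels along the first axis.
#'
#' @param labels a [label_volume()].
#' @param scheme the [label_scheme()] identifying cGM/cWM structures.
#' @param mode `"dilate_cGM_into_cWM"` or `"shift"`.
#' @param magnitude interface fraction (dilation) or voxel shift (shift).
#' @param seed seed for the interface-voxel selection.
#' @return A corrupted [label_volume()].
#' @export
corrupt_segmentation <- function(labels, scheme,
                                 mode = c("dilate_cGM_into_cWM", "shift"),
                                 magnitude = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  lab <- labels$labels
  if (mode == "shift") {
    k <- as.integer(magnitude)
    if (k == 0L) return(labels)
    d <- dim(lab)
    out <- array(0L, d)
    if (k > 0) out[(k + 1):d[1], , ] <- lab[1:(d[1] - k), , ]
    else out[1:(d[1] + k), , ] <- lab[(1 - k):d[1], , ]
    return(label_volume(out, labels$affine))
  }
  if (magnitude == 0) return(labels)
  cgm_ids <- scheme$entries$label_id[scheme$entries$tissue_class == "cGM"]
  cwm_ids <- scheme$entries$label_id[scheme$entries$tissue_class == "cWM"]
  is_cgm <- array(lab %in% cgm_ids, dim(lab))
  is_cwm <- array(lab %in% cwm_ids, dim(lab))
  touch <- is_cwm & neighbors_any(is_cgm)
  if (!any(touch)) stop("no cGM/cWM interface to corrupt")
  idx <- which(touch)
  set.seed(seed)
  take <- idx[runif(length(idx)) < magnitude]
  if (length(take)) {
    # adjacent cGM id: nearest cGM voxel decides (ties -> lowest id)
    new_id <- nearest_id_of_set(lab, take, cgm_ids)
    lab[take] <- new_id
  }
  label_volume(lab, labels$affine)
}

# does any 6-connected neighbor satisfy the mask?
neighbors_any <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  sh <- function(m, ax, by) {
    r <- array(FALSE, d)
    if (ax == 1) { if (by > 0) r[-d[1], , ] <- m[-1, , ] else r[-1, , ] <- m[-d[1], , ] }
    if (ax == 2) { if (by > 0) r[, -d[2], ] <- m[, -1, ] else r[, -1, ] <- m[, -d[2], ] }
    if (ax == 3) { if (by > 0) r[, , -d[3]] <- m[, , -1] else r[, , -1] <- m[, , -d[3]] }
    r
  }
  for (ax in 1:3) for (by in c(-1, 1)) out <- out | sh(mask, ax, by)
  out
}

# for each linear voxel index, the id (from `ids`, present in lab) of the
# nearest voxel carrying one of those ids; ties broken by lowest id
nearest_id_of_set <- function(lab, idx, ids) {
  ids <- sort(as.integer(ids))
  ids <- ids[vapply(ids, function(i) any(lab == i), logical(1))]
  if (!length(ids)) stop("none of the target ids are present")
  dmat <- vapply(ids, function(i) .cpp_edt_sq(array(lab == i, dim(lab)))[idx],
                 numeric(length(idx)))
  dmat <- matrix(dmat, nrow = length(idx))
  ids[max.col(-dmat, ties.method = "first")]
}
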