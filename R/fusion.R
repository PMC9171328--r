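#' Atlas library of co-registered (intensity, label) pairs
#'
#' @param images list of [image_volume()] members, all on one grid.
#' @param labels list of matching [label_volume()] members.
#' @return An object of class `atlas_library` with elements `images`,
#'   `labels`, and `N`.
#' @export
atlas_library <- function(images, labels) {
  if (length(images) < 1L) stop("library must have at least one member")
  if (length(images) != length(labels))
    stop("images and labels differ in length")
  d0 <- vol_dim(images[[1]])
  for (i in seq_along(images)) {
    if (!inherits(images[[i]], "image_volume")) stop("member ", i, ": not an image_volume")
    if (!inherits(labels[[i]], "label_volume")) stop("member ", i, ": not a label_volume")
    if (!identical(vol_dim(images[[i]]), d0) || !identical(vol_dim(labels[[i]]), d0))
      stop("member ", i, " is not on the shared grid")
  }
  structure(list(images = images, labels = labels, N = length(images)),
            class = "atlas_library")
}

#' @export
print.atlas_library <- function(x, ...) {
  cat(sprintf("<atlas_library> %d members on a %s grid\n", x$N,
              paste(vol_dim(x$images[[1]]), collapse = "x")))
  invisible(x)
}

#' Append left-right mirrored members to a library
#'
#' @param library an [atlas_library()].
#' @param scheme [label_scheme()] with flip pairs.
#' @return An [atlas_library()] with `2N` members.
#' @export
mirror_library <- function(library, scheme) {
  imgs <- library$images
  labs <- library$labels
  for (i in seq_len(library$N)) {
    f <- flip_lr(library$images[[i]], library$labels[[i]], scheme)
    imgs[[library$N + i]] <- f$image
    labs[[library$N + i]] <- f$labels
  }
  atlas_library(imgs, labs)
}

#' Parameters of the patch-based label fusion engine
#'
#' @param patch_sizes two odd patch edge lengths (voxels); probability maps
#'   are computed at both scales and mixed by `alpha`.
#' @param search_radius half-width of the cubic search volume around each
#'   voxel (voxels).
#' @param alpha mixing coefficient of the two scales' probability maps,
#'   in `[0, 1]` (1 = small scale only).
#' @param annf_iterations propagation/random-search rounds of the
#'   approximate nearest neighbor field.
#' @param annf_k matches kept per voxel per scale.
#' @param seed random seed for the ANNF initialization and search.
#' @param h_epsilon small positive constant added to the minimum patch
#'   distance when estimating the weight bandwidth `h^2`.
#' @return An object of class `fusion_params`.
#' @export
fusion_params <- function(patch_sizes = c(3L, 5L), search_radius = 4L,
                          alpha = 0.5, annf_iterations = 4L, annf_k = 8L,
                          seed = 1L, h_epsilon = 1e-6) {
  patch_sizes <- as.integer(patch_sizes)
  if (any(patch_sizes < 1L) || any(patch_sizes %% 2L == 0L))
    stop("patch sizes must be odd and >= 1")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (search_radius < max(patch_sizes) %/% 2L)
    stop("search_radius must be at least the patch half-width")
  if (annf_iterations < 1L || annf_k < 1L)
    stop("annf_iterations and annf_k must be positive")
  if (h_epsilon <= 0) stop("h_epsilon must be positive")
  structure(list(patch_sizes = patch_sizes,
                 search_radius = as.integer(search_radius), alpha = alpha,
                 annf_iterations = as.integer(annf_iterations),
                 annf_k = as.integer(annf_k), seed = as.integer(seed),
                 h_epsilon = h_epsilon),
            class = "fusion_params")
}

#' Normalized squared L2 distance between two intensity patches
#'
#' The mean over patch elements of squared intensity differences — the
#' similarity metric driving all patch comparisons.
#'
#' @param patch_a,patch_b numeric arrays of identical shape.
#' @return Non-negative scalar.
#' @export
patch_distance <- function(patch_a, patch_b) {
  if (!identical(dim(patch_a) %||% length(patch_a),
                 dim(patch_b) %||% length(patch_b)))
    stop("patch shapes differ")
  mean((patch_a - patch_b)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Patch similarity weights from distances
#'
#' Weights `w = exp(-D / h^2)` with the bandwidth estimated per target voxel
#' from the minimum patch distance in its search volume:
#' `h^2 = min(D) + h_epsilon`. The best match therefore always gets the
#' largest weight (exactly 1 when its distance is 0).
#'
#' @param distances non-empty vector of non-negative patch distances.
#' @param h_epsilon small positive stabilizer.
#' @return Weights in `(0, 1]`, same length as `distances`.
#' @export
patch_weights <- function(distances, h_epsilon = 1e-6) {
  if (length(distances) == 0L) stop("empty distance list")
  if (any(distances < 0)) stop("distances must be non-negative")
  exp(-distances / (min(distances) + h_epsilon))
}

label_set <- function(library) {
  sort(unique(unlist(lapply(library$labels, function(l) unique(as.vector(l$labels))))))
}

new_probability_maps <- function(maps4d, labels, mask) {
  structure(list(labels = as.integer(labels), maps = maps4d, mask = mask),
            class = "probability_maps")
}

#' @export
print.probability_maps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<probability_maps> %d labels on a %dx%dx%d grid, %d masked voxels\n",
              length(x$labels), d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

as_mask <- function(mask, d) {
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d)) stop("mask is not on the volume grid")
  storage.mode(mask) <- "logical"
  mask
}

#' Exhaustive non-local label fusion at one patch scale
#'
#' For each masked voxel, every position in the cubic search volume of every
#' library member votes for its label with weight `exp(-D/h^2)`, where `D` is
#' the normalized squared patch distance and `h^2` is estimated per voxel
#' from the minimum distance in the search volume. Votes are normalized to
#' per-voxel label probabilities. This is the brute-force reference the
#' ANNF-accelerated path is validated against; it is quadratic in window
#' volume and only practical on small grids.
#'
#' @param subject an [image_volume()].
#' @param library an [atlas_library()] on the same grid.
#' @param mask logical array of voxels to process (`NULL` = whole grid).
#' @param patch_size odd patch edge length.
#' @param params a [fusion_params()].
#' @return A `probability_maps` object (label 0 = background class included).
#' @export
fuse_labels_exhaustive <- function(subject, library, mask = NULL,
                                   patch_size = 3L, params = fusion_params()) {
  d <- vol_dim(subject)
  check_same_grid(subject, library$images[[1]])
  mask <- as_mask(mask, d)
  if (!any(mask)) stop("mask is empty")
  labels <- label_set(library)
  maps <- .cpp_fuse_exhaustive(subject$voxels,
                               lapply(library$images, `[[`, "voxels"),
                               lapply(library$labels, `[[`, "labels"),
                               mask, as.integer(patch_size),
                               params$search_radius, params$h_epsilon,
                               as.integer(labels))
  new_probability_maps(maps, labels, mask)
}

#' Build an approximate nearest neighbor field
#'
#' PatchMatch-style correspondence search: per masked voxel, `annf_k`
#' candidate matches across the library are randomly initialized inside the
#' search volume, then improved over `annf_iterations` rounds of propagation
#' from already-scanned raster neighbors and random search with a
#' geometrically decaying radius. Candidates are kept sorted by patch
#' distance; best distances never increase across iterations, and the field
#' is a pure function of the seed. When a voxel's candidate pool (window
#' positions times members) does not exceed `annf_k`, the field is the exact
#' exhaustive best-k.
#'
#' @inheritParams fuse_labels_exhaustive
#' @return An object of class `annf_field` (candidate member, position,
#'   distance per masked voxel).
#' @export
build_annf <- function(subject, library, mask = NULL, patch_size = 3L,
                       params = fusion_params()) {
  d <- vol_dim(subject)
  check_same_grid(subject, library$images[[1]])
  mask <- as_mask(mask, d)
  if (!any(mask)) stop("mask is empty")
  pool <- library$N * (2 * params$search_radius + 1)^3
  if (params$annf_k > pool)
    stop("annf_k (", params$annf_k, ") exceeds the candidate pool (", pool, ")")
  # decouple the RNG stream per patch scale
  seed <- (params$seed * 2654435761 + patch_size * 40503) %% 2^31
  f <- .cpp_build_annf(subject$voxels, lapply(library$images, `[[`, "voxels"),
                       mask, as.integer(patch_size), params$search_radius,
                       params$annf_k, params$annf_iterations, seed)
  structure(c(f, list(mask = mask, dims = d, patch_size = as.integer(patch_size))),
            class = "annf_field")
}

#' @export
print.annf_field <- function(x, ...) {
  cat(sprintf("<annf_field> %d voxels x %d candidates (patch %d), mean best distance %.4g\n",
              length(x$vox), ncol(x$subject), x$patch_size,
              mean(x$distance[, 1])))
  invisible(x)
}

#' Label fusion over an approximate nearest neighbor field
#'
#' Each candidate match votes with weight `exp(-D/h^2)` (`h^2` per target
#' voxel from its best candidate). In `"patchwise"` mode (the default, the
#' OPAL-lineage late aggregation) a matched patch votes labels for every
#' masked voxel it covers; in `"central"` mode only the central voxel
#' receives the candidate's central label, which reproduces the exhaustive
#' rule restricted to the candidate set.
#'
#' @param subject an [image_volume()] (used for grid checking only).
#' @param library the [atlas_library()] the field was built against.
#' @param field an `annf_field` from [build_annf()].
#' @param patch_size odd patch edge length (must match the field's).
#' @param params a [fusion_params()].
#' @param voting `"patchwise"` or `"central"`.
#' @return A `probability_maps` object.
#' @export
fuse_labels_annf <- function(subject, library, field, patch_size = field$patch_size,
                             params = fusion_params(),
                             voting = c("patchwise", "central")) {
  voting <- match.arg(voting)
  d <- vol_dim(subject)
  if (!identical(d, field$dims)) stop("field was built on a different grid")
  if (!identical(as.integer(patch_size), field$patch_size))
    stop("field was built for patch size ", field$patch_size)
  labels <- label_set(library)
  maps <- .cpp_fuse_annf(as.integer(d), lapply(library$labels, `[[`, "labels"),
                         field$vox, field$subject, field$position,
                         field$distance, as.integer(patch_size),
                         params$h_epsilon, as.integer(labels),
                         voting == "patchwise", field$mask)
  new_probability_maps(maps, labels, field$mask)
}

#' Mix probability maps from two patch scales
#'
#' Convex per-voxel combination `p = alpha * p1 + (1 - alpha) * p2` of the
#' small-patch and large-patch probability maps.
#'
#' @param p1,p2 `probability_maps` on the same grid, labels, and mask.
#' @param alpha mixing coefficient in `[0, 1]`.
#' @return A `probability_maps` object.
#' @export
fuse_multiscale <- function(p1, p2, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (!identical(p1$labels, p2$labels)) stop("label sets differ")
  if (!identical(dim(p1$maps), dim(p2$maps))) stop("grids differ")
  if (!identical(p1$mask, p2$mask)) stop("masks differ")
  new_probability_maps(alpha * p1$maps + (1 - alpha) * p2$maps,
                       p1$labels, p1$mask)
}

#' Extract the per-voxel most probable label
#'
#' Masked voxels get the label with the highest probability (ties broken by
#' the lowest label id); voxels outside the mask get 0. When the mask is an
#' anatomical prior (e.g. the intracranial cavity), the background class can
#' be excluded via `ignore` so that every masked voxel receives a structure.
#'
#' @param p a `probability_maps` object.
#' @param affine affine carried over to the output volume.
#' @param ignore label ids excluded from the argmax (e.g. `0L`).
#' @return A [label_volume()].
#' @export
argmax_labels <- function(p, affine = diag(4), ignore = NULL) {
  d <- dim(p$maps)
  m <- matrix(p$maps, nrow = prod(d[1:3]), ncol = d[4])
  if (!is.null(ignore)) {
    drop_cols <- p$labels %in% ignore
    if (all(drop_cols)) stop("cannot ignore every label")
    m[, drop_cols] <- -Inf
  }
  best <- max.col(m, ties.method = "first")  # first = lowest label id
  out <- p$labels[best]
  out[!as.vector(p$mask)] <- 0L
  label_volume(array(as.integer(out), d[1:3]), affine)
}

#' Intracranial cavity extraction by binary two-scale label fusion
#'
#' Runs the same two-scale ANNF fusion engine with a binary (0/1) library
#' over the whole grid and returns the argmax mask. All downstream structure
#' fusion is restricted to this mask.
#'
#' @param subject an [image_volume()].
#' @param icc_library an [atlas_library()] whose labels are 0/1.
#' @param params a [fusion_params()].
#' @return A logical 3-D array (TRUE = intracranial cavity).
#' @export
extract_icc <- function(subject, icc_library, params = fusion_params()) {
  for (l in icc_library$labels)
    if (!all(l$labels %in% c(0L, 1L)))
      stop("ICC library labels must be binary")
  p <- fuse_two_scales(subject, icc_library, mask = NULL, params = params)
  lab <- argmax_labels(p, subject$affine)
  lab$labels == 1L
}

# two patch scales fused per the adaptive mixing rule; shared by ICC and
# structure stages
fuse_two_scales <- function(subject, library, mask, params,
                            voting = "patchwise") {
  ps <- params$patch_sizes
  f1 <- build_annf(subject, library, mask, ps[1], params)
  p1 <- fuse_labels_annf(subject, library, f1, ps[1], params, voting)
  f2 <- build_annf(subject, library, mask, ps[2], params)
  p2 <- fuse_labels_annf(subject, library, f2, ps[2], params, voting)
  fuse_multiscale(p1, p2, params$alpha)
}

#' Write probability maps as a 4-D NIfTI stack
#'
#' The label order of the 4th dimension is recorded in a sidecar CSV
#' (`<path>.labels.csv`).
#'
#' @param p a `probability_maps` object.
#' @param path output `.nii`/`.nii.gz` path.
#' @param affine voxel-to-world transform for the stack.
#' @return `path`, invisibly.
#' @export
write_probability_maps <- function(p, path, affine = diag(4)) {
  img <- RNifti::asNifti(p$maps, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  write.csv(data.frame(volume = seq_along(p$labels) - 1L, label_id = p$labels),
            paste0(path, ".labels.csv"), row.names = FALSE)
  invisible(path)
}
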