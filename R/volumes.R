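#' 3-D intensity volume on a template grid
#'
#' A minimal container for a scalar 3-D image: a voxel grid plus a 4x4
#' voxel-to-world affine (mm). All volumes in a segmentation run are assumed
#' to live on one common template grid (the pipeline expects inputs already
#' affinely registered to it).
#'
#' @param voxels numeric 3-D array of intensities.
#' @param affine 4x4 voxel-to-world transform; defaults to identity (1 mm
#'   isotropic voxels, origin at the first voxel).
#' @return An object of class `image_volume` with elements `voxels` and
#'   `affine`.
#' @export
image_volume <- function(voxels, affine = diag(4)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("expected 3-D volume")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, affine = affine), class = "image_volume")
}

#' 3-D label volume
#'
#' Non-negative integer labels on the same grid as an [image_volume()];
#' 0 is reserved for background.
#'
#' @param labels integer 3-D array of label ids (0 = background).
#' @param affine 4x4 voxel-to-world transform.
#' @param scheme optional [label_scheme()]; when supplied, every nonzero
#'   label must be listed in it.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, affine = diag(4), scheme = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("expected 3-D volume")
  if (any(labels < 0)) stop("labels must be non-negative")
  storage.mode(labels) <- "integer"
  if (!is.null(scheme)) {
    present <- setdiff(unique(as.vector(labels)), 0L)
    unknown <- setdiff(present, scheme$entries$label_id)
    if (length(unknown))
      stop("labels not in scheme: ", paste(unknown, collapse = ", "))
  }
  structure(list(labels = labels, affine = as.matrix(affine)),
            class = "label_volume")
}

vol_dim <- function(v) dim(if (inherits(v, "label_volume")) v$labels else v$voxels)

check_same_grid <- function(a, b) {
  if (!identical(vol_dim(a), vol_dim(b)))
    stop("volumes are not on the same grid: ",
         paste(vol_dim(a), collapse = "x"), " vs ",
         paste(vol_dim(b), collapse = "x"))
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %dx%dx%d voxels, intensity range [%.3g, %.3g]\n",
              d[1], d[2], d[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  ids <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("<label_volume> %dx%dx%d voxels, %d labels\n",
              d[1], d[2], d[3], length(ids)))
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3-D volume.
#' @param labels if `TRUE`, return a [label_volume()] (values rounded to
#'   integer) instead of an [image_volume()].
#' @return An [image_volume()] or [label_volume()].
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(dim(img)) != 3L)
    stop("expected 3-D volume: ", path, " has ", length(dim(img)), " dimensions")
  aff <- matrix(RNifti::xform(img), 4, 4)
  arr <- array(as.numeric(img), dim = dim(img))
  if (labels) label_volume(array(as.integer(round(arr)), dim(arr)), aff)
  else image_volume(arr, aff)
}

#' Write a volume as NIfTI-1
#'
#' Label volumes are stored with an integer datatype so label ids round-trip
#' bit-exactly.
#'
#' @param vol an [image_volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "label_volume")) {
    arr <- vol$labels
    dtype <- "int32"
  } else if (inherits(vol, "image_volume")) {
    arr <- vol$voxels
    dtype <- "double"
  } else stop("expected an image_volume or label_volume")
  img <- RNifti::asNifti(arr, datatype = dtype)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Dice overlap between two label volumes
#'
#' Per-label Dice index `2|A&B| / (|A|+|B|)`. A label absent from both
#' volumes has an undefined overlap and is reported as `NA` rather than 0,
#' so averages are taken over present labels only.
#'
#' @param a,b [label_volume()] objects on the same grid.
#' @param label_ids labels to evaluate; defaults to all nonzero labels
#'   present in either volume.
#' @return A data.frame with columns `label_id` and `dice`.
#' @export
dice <- function(a, b, label_ids = NULL) {
  check_same_grid(a, b)
  la <- as.vector(a$labels)
  lb <- as.vector(b$labels)
  if (is.null(label_ids))
    label_ids <- sort(setdiff(unique(c(la, lb)), 0L))
  label_ids <- as.integer(label_ids)
  d <- vapply(label_ids, function(id) {
    na <- sum(la == id)
    nb <- sum(lb == id)
    if (na + nb == 0L) return(NA_real_)
    2 * sum(la == id & lb == id) / (na + nb)
  }, numeric(1))
  data.frame(label_id = label_ids, dice = d)
}
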