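#' Label scheme: structure ids, anatomy classes, and left/right pairing
#'
#' The labeling protocol is configuration, not a constant: a scheme lists
#' every structure id with its name, hemisphere, tissue class (one of the
#' eight classes CSF, cGM, cWM, sGM, ceGM, ceWM, BS, WML), an optional
#' cerebrum lobe class, and the left/right flip pairs used for library
#' mirroring and asymmetry reporting.
#'
#' @param entries data.frame with columns `label_id`, `name`, `hemisphere`
#'   (`left`, `right`, or `none`), `tissue_class`, `lobe_class` (`NA` when
#'   undefined).
#' @param flip_pairs data.frame with columns `left_id`, `right_id`.
#' @return An object of class `label_scheme`.
#' @export
label_scheme <- function(entries, flip_pairs = NULL) {
  entries <- as.data.frame(entries)
  need <- c("label_id", "name", "hemisphere", "tissue_class", "lobe_class")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop("scheme missing columns: ", paste(miss, collapse = ", "))
  entries$label_id <- as.integer(entries$label_id)
  if (anyDuplicated(entries$label_id))
    stop("duplicate label id: ",
         paste(unique(entries$label_id[duplicated(entries$label_id)]),
               collapse = ", "))
  if (any(entries$label_id <= 0)) stop("label ids must be positive (0 = background)")
  bad <- setdiff(unique(entries$tissue_class), TISSUE_CLASSES)
  if (length(bad)) stop("unknown tissue_class: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(entries$hemisphere), c("left", "right", "none"))
  if (length(bad)) stop("unknown hemisphere: ", paste(bad, collapse = ", "))
  if (is.null(flip_pairs))
    flip_pairs <- data.frame(left_id = integer(), right_id = integer())
  flip_pairs <- as.data.frame(flip_pairs)
  hemi <- function(id) entries$hemisphere[match(id, entries$label_id)]
  for (r in seq_len(nrow(flip_pairs))) {
    l <- flip_pairs$left_id[r]; rt <- flip_pairs$right_id[r]
    if (!(l %in% entries$label_id) || !(rt %in% entries$label_id))
      stop("flip pair references unknown id: ", l, " / ", rt)
    if (!identical(hemi(l), "left") || !identical(hemi(rt), "right"))
      stop("flip pair (", l, ", ", rt, ") must join a left and a right structure")
  }
  structure(list(entries = entries,
                 flip_pairs = data.frame(left_id = as.integer(flip_pairs$left_id),
                                         right_id = as.integer(flip_pairs$right_id))),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("<label_scheme> %d structures, %d flip pairs, tissues: %s\n",
              nrow(x$entries), nrow(x$flip_pairs),
              paste(sort(unique(x$entries$tissue_class)), collapse = ", ")))
  invisible(x)
}

#' Load a label scheme from CSV
#'
#' Expects columns `label_id,name,hemisphere,tissue_class,lobe_class,
#' flip_partner` (`flip_partner` empty for unpaired structures). Flip pairs
#' are assembled from rows whose `flip_partner` is set; each pair needs to be
#' declared consistently from both sides (or from the left side only).
#'
#' @param path CSV file path.
#' @return A [label_scheme()].
#' @export
load_label_scheme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label_id", "name", "hemisphere", "tissue_class", "lobe_class",
            "flip_partner")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("scheme file missing columns: ", paste(miss, collapse = ", "))
  tab$lobe_class[!is.na(tab$lobe_class) & tab$lobe_class == ""] <- NA
  fp <- tab[!is.na(tab$flip_partner) & tab$flip_partner != "", , drop = FALSE]
  pairs <- NULL
  if (nrow(fp)) {
    left <- fp[fp$hemisphere == "left", , drop = FALSE]
    pairs <- data.frame(left_id = as.integer(left$label_id),
                        right_id = as.integer(left$flip_partner))
    # right-side declarations must agree with the left-side ones
    right <- fp[fp$hemisphere == "right", , drop = FALSE]
    for (r in seq_len(nrow(right))) {
      l <- as.integer(right$flip_partner[r]); rt <- as.integer(right$label_id[r])
      hit <- pairs$left_id == l & pairs$right_id == rt
      if (!any(hit)) pairs <- rbind(pairs, data.frame(left_id = l, right_id = rt))
    }
    pairs <- unique(pairs)
  }
  label_scheme(tab[, setdiff(names(tab), "flip_partner")], pairs)
}

#' Write a label scheme to CSV
#'
#' Inverse of [load_label_scheme()].
#'
#' @param scheme a [label_scheme()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_scheme <- function(scheme, path) {
  tab <- scheme$entries
  partner <- rep(NA_integer_, nrow(tab))
  fp <- scheme$flip_pairs
  partner[match(fp$left_id, tab$label_id)] <- fp$right_id
  partner[match(fp$right_id, tab$label_id)] <- fp$left_id
  tab$flip_partner <- partner
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Mirror an image and label volume left-right
#'
#' Flips both grids along the first voxel axis (the left-right axis of the
#' template space, index x -> nx-1-x) and swaps every label with its
#' flip-pair partner; unpaired labels are kept. Used to double an atlas
#' library with the mirrored version of each member.
#'
#' @param image an [image_volume()].
#' @param labels a [label_volume()] on the same grid.
#' @param scheme the [label_scheme()] providing flip pairs.
#' @return A list with elements `image` and `labels`.
#' @export
flip_lr <- function(image, labels, scheme) {
  check_same_grid(image, labels)
  nx <- dim(image$voxels)[1]
  fimg <- image$voxels[nx:1, , , drop = FALSE]
  flab <- labels$labels[nx:1, , , drop = FALSE]
  fp <- scheme$flip_pairs
  if (nrow(fp)) {
    map <- seq_len(max(scheme$entries$label_id, flab))
    map[fp$left_id] <- fp$right_id
    map[fp$right_id] <- fp$left_id
    nz <- flab != 0L
    flab[nz] <- map[flab[nz]]
  }
  list(image = image_volume(fimg, image$affine),
       labels = label_volume(flab, labels$affine))
}
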