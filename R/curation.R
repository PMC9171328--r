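#' Relabeling table
#'
#' A set of `(source_id, target_id)` renumbering/merging rules applied
#' simultaneously to a label volume — the generic form of library-curation
#' renumberings (merging inconsistent labels, folding rare structures into
#' their parent, hemisphere corrections).
#'
#' @param rules data.frame with integer columns `source_id`, `target_id`.
#' @return An object of class `relabel_table`.
#' @export
relabel_table <- function(rules) {
  rules <- as.data.frame(rules)
  if (!all(c("source_id", "target_id") %in% names(rules)))
    stop("rules need source_id and target_id columns")
  rules$source_id <- as.integer(rules$source_id)
  rules$target_id <- as.integer(rules$target_id)
  if (anyDuplicated(rules$source_id)) stop("duplicate source ids")
  # simultaneous application composes to identity only if rules are acyclic:
  # follow each chain through the rule graph
  tgt <- function(id) {
    i <- match(id, rules$source_id)
    if (is.na(i)) NA_integer_ else rules$target_id[i]
  }
  for (s in rules$source_id) {
    seen <- s
    nxt <- tgt(s)
    while (!is.na(nxt)) {
      if (nxt %in% seen) stop("cyclic relabel rules involving id ", s)
      seen <- c(seen, nxt)
      nxt <- tgt(nxt)
    }
  }
  structure(list(rules = rules), class = "relabel_table")
}

#' Read a relabeling table from CSV (`source_id,target_id`)
#' @param path CSV file path.
#' @return A [relabel_table()].
#' @export
load_relabel_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  relabel_table(read.csv(path))
}

#' Apply a relabeling table
#'
#' Every rule is applied simultaneously (sources are looked up in the input,
#' not in partially rewritten output), so total labeled voxel count is
#' conserved exactly.
#'
#' @param labels a [label_volume()].
#' @param table a [relabel_table()].
#' @return The relabeled [label_volume()].
#' @export
apply_relabel <- function(labels, table) {
  lab <- labels$labels
  if (nrow(table$rules)) {
    m <- match(lab, table$rules$source_id)
    hit <- !is.na(m)
    lab[hit] <- table$rules$target_id[m[hit]]
  }
  label_volume(lab, labels$affine)
}

#' Partial-volume map under a linear mixing model
#'
#' The mixing fraction of tissue A vs tissue B at every voxel,
#' `c = (I - median_B) / (median_A - median_B)`, clipped to `[0, 1]`:
#' 1 = pure A, 0 = pure B.
#'
#' @param image an [image_volume()].
#' @param median_a,median_b tissue intensity medians (must differ).
#' @return An object of class `pv_map` (fields `coefficients`, `affine`).
#' @export
partial_volume_map <- function(image, median_a, median_b) {
  if (median_a == median_b) stop("tissue medians must differ")
  cc <- (image$voxels - median_b) / (median_a - median_b)
  cc[cc < 0] <- 0
  cc[cc > 1] <- 1
  structure(list(coefficients = cc, affine = image$affine), class = "pv_map")
}

#' Regularize a partial-volume map with a non-local means filter
#'
#' Weighted average of the coefficient grid with patch-similarity weights
#' (the same distance/weight rule as the fusion engine, applied to the PV
#' grid itself). Being a convex combination, output values stay within the
#' input range, re-clipped to `[0, 1]`.
#'
#' @param pv a [partial_volume_map()] result.
#' @param patch_size odd patch edge length.
#' @param search_radius half-width of the averaging window.
#' @param filter_strength multiplier on the estimated bandwidth `h^2`
#'   (larger = smoother).
#' @param h_epsilon bandwidth stabilizer.
#' @return A regularized `pv_map`.
#' @export
regularize_pv <- function(pv, patch_size = 3L, search_radius = 2L,
                          filter_strength = 1, h_epsilon = 1e-6) {
  cc <- .cpp_nlm(pv$coefficients, as.integer(patch_size),
                 as.integer(search_radius), filter_strength, h_epsilon)
  cc[cc < 0] <- 0
  cc[cc > 1] <- 1
  structure(list(coefficients = cc, affine = pv$affine), class = "pv_map")
}

#' Relabel tissue-interface voxels by partial-volume content
#'
#' Voxels of tissue set A with a 6-connected neighbor in tissue set B (and
#' vice versa) are interface candidates. A candidate switches sets when the
#' opposing PV coefficient exceeds its own (A voxels hold coefficient `c`,
#' B voxels `1 - c`); the new structure id within the destination set is
#' that of the nearest structure of the set (ties to the lowest id). All
#' non-interface voxels are untouched.
#'
#' @param labels a [label_volume()].
#' @param pv the A-vs-B [partial_volume_map()] (possibly regularized).
#' @param tissue_a_ids,tissue_b_ids disjoint structure id sets.
#' @return The corrected [label_volume()].
#' @export
correct_interface <- function(labels, pv, tissue_a_ids, tissue_b_ids) {
  tissue_a_ids <- as.integer(tissue_a_ids)
  tissue_b_ids <- as.integer(tissue_b_ids)
  if (length(intersect(tissue_a_ids, tissue_b_ids)))
    stop("tissue id sets must be disjoint")
  lab <- labels$labels
  if (!identical(dim(lab), dim(pv$coefficients)))
    stop("PV map is not on the label grid")
  inA <- array(lab %in% tissue_a_ids, dim(lab))
  inB <- array(lab %in% tissue_b_ids, dim(lab))
  ifaceA <- inA & neighbors_any(inB)
  ifaceB <- inB & neighbors_any(inA)
  cc <- pv$coefficients
  moveAB <- ifaceA & (1 - cc > cc)   # A voxel dominated by B content
  moveBA <- ifaceB & (cc > 1 - cc)   # B voxel dominated by A content
  if (any(moveAB))
    lab[which(moveAB)] <- nearest_id_of_set(labels$labels, which(moveAB), tissue_b_ids)
  if (any(moveBA))
    lab[which(moveBA)] <- nearest_id_of_set(labels$labels, which(moveBA), tissue_a_ids)
  label_volume(lab, labels$affine)
}

#' Piecewise-linear intensity normalization on tissue medians
#'
#' A continuous, monotone piecewise-linear map taking each measured tissue
#' median exactly to its target (anchors map bit-exactly), linear between
#' anchors and linearly extrapolated beyond the extreme anchors with the
#' adjacent segment's slope. Medians must be strictly increasing in tissue
#' order (typically CSF < GM < WM).
#'
#' @param image an [image_volume()].
#' @param measured_medians,target_medians anchor vectors of equal length
#'   (>= 2), both strictly increasing.
#' @return The normalized [image_volume()].
#' @export
normalize_intensity <- function(image, measured_medians, target_medians) {
  xm <- as.numeric(measured_medians)
  ym <- as.numeric(target_medians)
  if (length(xm) != length(ym) || length(xm) < 2L)
    stop("need matching anchor vectors of length >= 2")
  if (any(diff(xm) <= 0) || any(diff(ym) <= 0))
    stop("tissue medians must be strictly increasing")
  v <- image$voxels
  k <- findInterval(v, xm, all.inside = TRUE)  # segment index, ends extended
  slope <- diff(ym) / diff(xm)
  out <- ym[k] + (v - xm[k]) * slope[k]
  image_volume(array(out, dim(v)), image$affine)
}
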