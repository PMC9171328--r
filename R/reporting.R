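#' Group structure labels into a coarser anatomical scale
#'
#' Replaces each voxel's structure id by its tissue-class id (fixed ids
#' 1..8 in the order CSF, cGM, cWM, sGM, ceGM, ceWM, BS, WML) or its lobe
#' id (assigned in sorted lobe-name order). Voxel counts are conserved per
#' class. Structures lacking the requested class either raise an error
#' (default) or are mapped to background (`na_action = "zero"`, used when
#' grouping cortical lobes on a full segmentation).
#'
#' @param labels a [label_volume()] of structure ids.
#' @param scheme the [label_scheme()].
#' @param scale `"tissue"` or `"lobe"`.
#' @param na_action `"error"` or `"zero"` for structures without the class.
#' @return A [label_volume()] whose `class_table` attribute maps class ids
#'   to names.
#' @export
group_labels <- function(labels, scheme, scale = c("tissue", "lobe"),
                         na_action = c("error", "zero")) {
  scale <- match.arg(scale)
  na_action <- match.arg(na_action)
  e <- scheme$entries
  cls <- if (scale == "tissue") e$tissue_class else e$lobe_class
  present <- setdiff(sort(unique(as.vector(labels$labels))), 0L)
  unknown <- setdiff(present, e$label_id)
  if (length(unknown))
    stop("labels not in scheme: ", paste(unknown, collapse = ", "))
  undef <- present[is.na(cls[match(present, e$label_id)])]
  if (length(undef) && na_action == "error")
    stop("structures without a ", scale, " class: ", paste(undef, collapse = ", "))
  if (scale == "tissue") {
    class_ids <- TISSUE_CLASS_IDS
  } else {
    lobe_names <- sort(unique(stats::na.omit(cls)))
    class_ids <- stats::setNames(seq_along(lobe_names), lobe_names)
  }
  map <- rep(0L, max(e$label_id))
  ok <- !is.na(cls)
  map[e$label_id[ok]] <- as.integer(class_ids[cls[ok]])
  lab <- labels$labels
  nz <- lab != 0L
  lab[nz] <- map[lab[nz]]
  out <- label_volume(lab, labels$affine)
  attr(out, "class_table") <- data.frame(class_id = unname(class_ids),
                                         name = names(class_ids))
  out
}

#' Per-region volumes in template and native space
#'
#' Template-space volume is voxel count times the voxel volume from the
#' affine; native-space volume scales it by the determinant of the
#' native-to-template affine inverse (avoids a second interpolation).
#'
#' @param labels a [label_volume()].
#' @param native_affine_det determinant of the inverse of the native-to-
#'   template transform (> 0); 1 means native = template.
#' @return data.frame with `label_id`, `n_voxels`, `volume_mm3_template`,
#'   `volume_mm3_native`.
#' @export
structure_volumes <- function(labels, native_affine_det = 1) {
  if (native_affine_det <= 0) stop("native_affine_det must be > 0")
  vox_mm3 <- abs(det(labels$affine[1:3, 1:3]))
  ids <- setdiff(sort(unique(as.vector(labels$labels))), 0L)
  n <- vapply(ids, function(i) sum(labels$labels == i), numeric(1))
  data.frame(label_id = ids, n_voxels = n,
             volume_mm3_template = n * vox_mm3,
             volume_mm3_native = n * vox_mm3 * abs(native_affine_det))
}

#' Right-left asymmetry ratios of paired structures
#'
#' `asymmetry_pct = 100 * (right - left) / ((right + left) / 2)`; positive
#' means the right structure is larger. Pairs with both volumes 0 are
#' undefined (`NA`); a pair with one missing member reports the present
#' member's volume against 0.
#'
#' @param volumes a [structure_volumes()] table.
#' @param scheme the [label_scheme()] providing flip pairs.
#' @return data.frame with `left_id`, `right_id`, `asymmetry_pct`.
#' @export
asymmetry_ratios <- function(volumes, scheme) {
  fp <- scheme$flip_pairs
  vol_of <- function(id) {
    i <- match(id, volumes$label_id)
    if (is.na(i)) 0 else volumes$volume_mm3_template[i]
  }
  asym <- vapply(seq_len(nrow(fp)), function(r) {
    l <- vol_of(fp$left_id[r]); rt <- vol_of(fp$right_id[r])
    if (l + rt == 0) return(NA_real_)
    100 * (rt - l) / ((rt + l) / 2)
  }, numeric(1))
  data.frame(left_id = fp$left_id, right_id = fp$right_id,
             asymmetry_pct = asym)
}

#' Summarize a cortical thickness map per region
#'
#' Mean and SD of thickness over each region's voxels with positive
#' thickness; regions with no positive-thickness voxels are omitted.
#'
#' @param thickness_map numeric 3-D array of thickness values (mm).
#' @param labels a [label_volume()] on the same grid.
#' @param regions structure or lobe ids to summarize (default: all present).
#' @return data.frame with `label_id`, `thickness_mean_mm`,
#'   `thickness_sd_mm`, `n_voxels`.
#' @export
thickness_summary <- function(thickness_map, labels, regions = NULL) {
  if (!identical(dim(thickness_map), vol_dim(labels)))
    stop("thickness map is not on the label grid")
  if (is.null(regions))
    regions <- setdiff(sort(unique(as.vector(labels$labels))), 0L)
  rows <- lapply(as.integer(regions), function(id) {
    v <- thickness_map[labels$labels == id & thickness_map > 0]
    if (!length(v)) return(NULL)
    data.frame(label_id = id, thickness_mean_mm = mean(v),
               thickness_sd_mm = if (length(v) > 1) sd(v) else 0,
               n_voxels = length(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label_id = integer(), thickness_mean_mm = numeric(),
                      thickness_sd_mm = numeric(), n_voxels = integer())
  out
}

#' Assemble the multiscale volumetric report
#'
#' One row per region at each scale — ICC, the eight tissues, cerebrum
#' lobes, and individual structures — with template- and native-space
#' volumes, percentage of ICC, right-left asymmetry for paired structures,
#' and per-region cortical thickness when a thickness map is supplied.
#'
#' @param structures segmentation [label_volume()] at the structure scale.
#' @param scheme the [label_scheme()].
#' @param icc_mask logical ICC array (defaults to `structures != 0`).
#' @param native_affine_det see [structure_volumes()].
#' @param thickness_map optional thickness array; thickness columns are
#'   absent when not supplied.
#' @return data.frame of class `volume_report`.
#' @export
volume_report <- function(structures, scheme, icc_mask = NULL,
                          native_affine_det = 1, thickness_map = NULL) {
  e <- scheme$entries
  if (is.null(icc_mask)) icc_mask <- structures$labels != 0L
  vox_mm3 <- abs(det(structures$affine[1:3, 1:3]))
  icc_vol <- sum(icc_mask) * vox_mm3
  row <- function(region, scale, vol, asym = NA_real_)
    data.frame(region = region, scale = scale,
               volume_mm3_template = vol,
               volume_mm3_native = vol * abs(native_affine_det),
               pct_icc = if (icc_vol > 0) 100 * vol / icc_vol else NA_real_,
               asymmetry_pct = asym)
  out <- row("ICC", "ICC", icc_vol)

  tissues <- group_labels(structures, scheme, "tissue")
  tt <- structure_volumes(tissues, native_affine_det)
  for (i in seq_len(nrow(tt)))
    out <- rbind(out, row(TISSUE_CLASSES[tt$label_id[i]], "tissue",
                          tt$volume_mm3_template[i]))

  # lobes: cortical GM structures only
  cortical <- e$label_id[e$tissue_class == "cGM" & !is.na(e$lobe_class)]
  lob_lab <- structures$labels
  lob_lab[!array(lob_lab %in% cortical, dim(lob_lab))] <- 0L
  lobe_rows <- NULL
  if (any(lob_lab != 0L)) {
    lobes <- group_labels(label_volume(lob_lab, structures$affine), scheme, "lobe")
    ct <- attr(lobes, "class_table")
    lv <- structure_volumes(lobes, native_affine_det)
    for (i in seq_len(nrow(lv)))
      out <- rbind(out, row(ct$name[match(lv$label_id[i], ct$class_id)],
                            "lobe", lv$volume_mm3_template[i]))
  }

  sv <- structure_volumes(structures, native_affine_det)
  asym <- asymmetry_ratios(sv, scheme)
  asym_of <- function(id) {
    i <- which(asym$left_id == id | asym$right_id == id)
    if (!length(i)) NA_real_
    else if (asym$left_id[i[1]] == id) -asym$asymmetry_pct[i[1]]
    else asym$asymmetry_pct[i[1]]
  }
  for (i in seq_len(nrow(sv))) {
    id <- sv$label_id[i]
    nm <- e$name[match(id, e$label_id)]
    if (is.na(nm)) nm <- paste0("label_", id)
    out <- rbind(out, row(nm, "structure", sv$volume_mm3_template[i],
                          asym_of(id)))
  }

  if (!is.null(thickness_map)) {
    out$thickness_mean_mm <- NA_real_
    out$thickness_sd_mm <- NA_real_
    th <- thickness_summary(thickness_map, structures, cortical)
    for (i in seq_len(nrow(th))) {
      nm <- e$name[match(th$label_id[i], e$label_id)]
      j <- which(out$region == nm & out$scale == "structure")
      out$thickness_mean_mm[j] <- th$thickness_mean_mm[i]
      out$thickness_sd_mm[j] <- th$thickness_sd_mm[i]
    }
    # lobe-level thickness over grouped cortical labels
    if (!is.null(lobe_rows) || any(lob_lab != 0L)) {
      lobes <- group_labels(label_volume(lob_lab, structures$affine), scheme, "lobe")
      ct <- attr(lobes, "class_table")
      thl <- thickness_summary(thickness_map, lobes)
      for (i in seq_len(nrow(thl))) {
        nm <- ct$name[match(thl$label_id[i], ct$class_id)]
        j <- which(out$region == nm & out$scale == "lobe")
        out$thickness_mean_mm[j] <- thl$thickness_mean_mm[i]
        out$thickness_sd_mm[j] <- thl$thickness_sd_mm[i]
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("volume_report", "data.frame")
  out
}

#' Write a volumetric report as deterministic CSV
#'
#' Row order is fixed (ICC, tissues, lobes, structures, as assembled) and
#' numbers are written in full precision, so identical inputs produce
#' byte-identical files.
#'
#' @param report a [volume_report()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  con <- file(path, open = "wb")  # binary: fixed newlines across platforms
  on.exit(close(con))
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
  writeLines(paste(names(df), collapse = ","), con)
  for (i in seq_len(nrow(df)))
    writeLines(paste(vapply(df[i, ], as.character, character(1)), collapse = ","), con)
  invisible(path)
}

#' Read back a report written by [write_report()]
#' @param path CSV file path.
#' @return A `volume_report` data.frame.
#' @export
read_report <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("volume_report", "data.frame")
  out
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("<volume_report> %d regions (%s)\n", nrow(x),
              paste(unique(x$scale), collapse = ", ")))
  print(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("...", nrow(x) - 12, "more rows\n")
  invisible(x)
}
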