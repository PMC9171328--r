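#' Run the full segmentation pipeline
#'
#' Fixed stage order: intracranial cavity (ICC) extraction by binary
#' two-scale fusion, two-scale ANNF label fusion over the ICC mask,
#' probability mixing across scales, argmax label extraction, optional
#' patch-based ensemble correction, multiscale grouping (tissues, lobes),
#' and report assembly. The subject and library are expected to be
#' denoised, inhomogeneity-corrected, intensity-normalized, and affinely
#' registered to one template grid; [normalize_intensity()] is available as
#' an optional pre-stage, everything else is external.
#'
#' @param subject an [image_volume()].
#' @param library an [atlas_library()] of structure-labeled members.
#' @param scheme the [label_scheme()].
#' @param params a [fusion_params()]; its seed drives every stochastic stage.
#' @param icc_library optional binary-labeled [atlas_library()] for ICC
#'   extraction; by default the structure library with labels binarized.
#' @param pec_models optional list of [pec_train()] models applied after
#'   fusion.
#' @param thickness_map optional cortical thickness array (mm) on the same
#'   grid; consumed, never computed.
#' @param include_flipped also use the left-right mirrored version of every
#'   library member (doubles the effective library).
#' @param native_affine_det native-space scaling for the report.
#' @param out_dir if given, every intermediate volume and the report are
#'   written there (NIfTI / CSV), plus a machine-readable JSON run log with
#'   parameters, seed, and per-stage timings.
#' @param verbose print stage progress.
#' @return An object of class `densefuse_result`: list with `structures`,
#'   `tissues`, `lobes`, `icc`, `prob`, `report`, `params`, `timings`.
#' @export
run_pipeline <- function(subject, library, scheme, params = fusion_params(),
                         icc_library = NULL, pec_models = NULL,
                         thickness_map = NULL, include_flipped = FALSE,
                         native_affine_det = 1, out_dir = NULL,
                         verbose = FALSE) {
  t_all <- proc.time()[["elapsed"]]
  timings <- numeric(0)
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    t0 <- tic()
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- tic() - t0
    say(sprintf("  %-12s %6.1fs", name, timings[[name]]))
    r
  }

  if (include_flipped) library <- mirror_library(library, scheme)

  if (is.null(icc_library)) {
    icc_library <- atlas_library(
      library$images,
      lapply(library$labels, function(l)
        label_volume(array(as.integer(l$labels != 0L), vol_dim(l)), l$affine)))
  }
  icc <- stage("icc", extract_icc(subject, icc_library, params))

  prob <- stage("fusion", fuse_two_scales(subject, library, icc, params))
  # background is excluded: the ICC mask already decides what is brain,
  # so every intracranial voxel takes its best structure label
  structures <- stage("argmax", argmax_labels(prob, subject$affine, ignore = 0L))

  if (!is.null(pec_models)) {
    structures <- stage("pec", {
      out <- structures
      for (m in pec_models) out <- pec_apply(m, subject, out, prob)
      out
    })
  }

  tissues <- stage("grouping", group_labels(structures, scheme, "tissue"))
  e <- scheme$entries
  cortical <- e$label_id[e$tissue_class == "cGM" & !is.na(e$lobe_class)]
  lob_lab <- structures$labels
  lob_lab[!array(lob_lab %in% cortical, dim(lob_lab))] <- 0L
  lobes <- group_labels(label_volume(lob_lab, structures$affine), scheme, "lobe")

  report <- stage("report",
                  volume_report(structures, scheme, icc, native_affine_det,
                                thickness_map))

  res <- structure(list(structures = structures, tissues = tissues,
                        lobes = lobes, icc = icc, prob = prob,
                        report = report, params = params, timings = timings),
                   class = "densefuse_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    aff <- subject$affine
    write_volume(structures, file.path(out_dir, "structures.nii.gz"))
    write_volume(tissues, file.path(out_dir, "tissues.nii.gz"))
    write_volume(lobes, file.path(out_dir, "lobes.nii.gz"))
    write_volume(label_volume(array(as.integer(icc), dim(icc)), aff),
                 file.path(out_dir, "icc.nii.gz"))
    write_probability_maps(prob, file.path(out_dir, "probabilities.nii.gz"), aff)
    write_report(report, file.path(out_dir, "report.csv"))
    log <- list(seed = params$seed,
                params = unclass(params),
                library_size = library$N,
                timings = as.list(timings),
                total_seconds = tic() - t_all)
    writeLines(to_json(log), file.path(out_dir, "run_log.json"))
  }
  res
}

# minimal JSON writer for the run log (names + numbers/strings/lists only)
to_json <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  if (is.list(x)) {
    items <- vapply(seq_along(x), function(i)
      sprintf("%s  \"%s\": %s", pad, names(x)[i], to_json(x[[i]], indent + 2)),
      character(1))
    paste0("{\n", paste(items, collapse = ",\n"), "\n", pad, "}")
  } else if (is.numeric(x) && length(x) == 1) {
    format(x, digits = 15)
  } else if (is.numeric(x)) {
    paste0("[", paste(format(x, digits = 15), collapse = ", "), "]")
  } else {
    paste0("\"", paste(as.character(x), collapse = ","), "\"")
  }
}

#' @export
print.densefuse_result <- function(x, ...) {
  ids <- setdiff(sort(unique(as.vector(x$structures$labels))), 0L)
  cat(sprintf("<densefuse_result> %d structures over %d ICC voxels\n",
              length(ids), sum(x$icc)))
  cat(sprintf("  stages: %s\n",
              paste(sprintf("%s %.1fs", names(x$timings), x$timings),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.densefuse_result <- function(object, ...) {
  print(object)
  print(object$report)
  invisible(object)
}

#' Twice-scanned reproducibility protocol
#'
#' Segments two volumes of the same underlying anatomy independently with
#' identical settings and reports the per-label Dice between the two
#' automatic segmentations — the measurement-repeatability analog of
#' scanning a subject twice.
#'
#' @param subject_a,subject_b two [image_volume()]s of one anatomy.
#' @param library,scheme,params,... passed to [run_pipeline()].
#' @return A list with `dice` (per-label table over labels present in both
#'   runs), `mean_dice`, and the two `densefuse_result`s.
#' @export
run_reproducibility <- function(subject_a, subject_b, library, scheme,
                                params = fusion_params(), ...) {
  check_same_grid(subject_a, subject_b)
  ra <- run_pipeline(subject_a, library, scheme, params, ...)
  rb <- run_pipeline(subject_b, library, scheme, params, ...)
  ids <- intersect(setdiff(unique(as.vector(ra$structures$labels)), 0L),
                   setdiff(unique(as.vector(rb$structures$labels)), 0L))
  d <- dice(ra$structures, rb$structures, sort(ids))
  list(dice = d, mean_dice = mean(d$dice, na.rm = TRUE),
       result_a = ra, result_b = rb)
}
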