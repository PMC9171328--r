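#' Euclidean distance map to a structure contour
#'
#' Distance (in voxels) from every voxel of the grid to the nearest contour
#' voxel of one structure. The contour is the set of structure voxels with
#' at least one 6-connected neighbor outside the structure; contour voxels
#' map to 0. Inside and outside are not sign-distinguished.
#'
#' @param labels a [label_volume()].
#' @param label_id structure id (must be present in the volume).
#' @return A numeric 3-D array of distances.
#' @export
distance_map <- function(labels, label_id) {
  mask <- labels$labels == as.integer(label_id)
  if (!any(mask)) stop("label ", label_id, " absent from the volume")
  contour <- mask & neighbors_any(!mask)
  # a structure filling the whole grid has no contour under 6-connectivity
  if (!any(contour)) contour <- mask
  sqrt(.cpp_edt_sq(array(contour, dim(mask))))
}

#' Corrector feature vectors
#'
#' For each query voxel the 112-feature vector used by the patch-based
#' ensemble corrector: a fully sampled 3x3x3 intensity patch (27), a 7x7x7
#' intensity patch subsampled by skipping two voxels per dimension, i.e.
#' offsets -3/0/+3 (27), the same two patches from the binary automatic
#' segmentation of the corrected structure (27 + 27), the contour distance
#' map value (1), and the world x, y, z coordinates from the affine (3).
#' Borders are handled by edge replication.
#'
#' @param t1 an [image_volume()].
#' @param auto_labels the automatic segmentation ([label_volume()]).
#' @param label_id structure being corrected (segmentation patches are its
#'   binary membership).
#' @param dmap distance map from [distance_map()]; computed if `NULL`.
#' @param voxels n x 3 matrix of 1-based voxel indices (a single voxel may
#'   be given as a length-3 vector).
#' @return An n x 112 numeric matrix.
#' @export
pec_features <- function(t1, auto_labels, label_id, voxels, dmap = NULL) {
  check_same_grid(t1, auto_labels)
  if (is.null(dim(voxels))) voxels <- matrix(voxels, nrow = 1)
  voxels <- as.matrix(voxels)
  d <- vol_dim(t1)
  if (any(voxels < 1) || any(voxels > matrix(d, nrow(voxels), 3, byrow = TRUE)))
    stop("voxel index outside the grid")
  if (is.null(dmap)) dmap <- distance_map(auto_labels, label_id)
  seg <- array(as.double(auto_labels$labels == as.integer(label_id)), d)
  .cpp_pec_features(t1$voxels, seg, dmap,
                    matrix(as.integer(voxels - 1L), ncol = 3), t1$affine)
}

# ---------------------------------------------------------------------------
# Shallow MLP 112 -> 83 -> 55 -> 27 (tanh hidden, sigmoid output), trained
# with Adam on binary cross-entropy. Small enough that plain R matrix math
# is fast; written here because the boosted patch-corrector ensemble IS the
# method, not an off-the-shelf model fit.
# ---------------------------------------------------------------------------

mlp_init <- function(sizes = c(112L, 83L, 55L, 27L)) {
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    s <- sqrt(2 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0, s), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

mlp_forward <- function(net, X) {
  a <- X
  acts <- list(a)
  nl <- length(net$W)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% net$W[[l]], 2, net$b[[l]], "+")
    a <- if (l < nl) tanh(z) else 1 / (1 + exp(-z))
    acts[[l + 1]] <- a
  }
  list(out = a, acts = acts)
}

mlp_predict <- function(net, X) mlp_forward(net, X)$out

mlp_train <- function(X, Y, epochs = 40L, batch = 64L, lr = 1e-3) {
  net <- mlp_init(c(ncol(X), 83L, 55L, ncol(Y)))
  nl <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0L
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch)) {
      sel <- ord[start:min(start + batch - 1L, n)]
      fw <- mlp_forward(net, X[sel, , drop = FALSE])
      m <- length(sel)
      # BCE + sigmoid: output delta is (p - y)
      delta <- (fw$out - Y[sel, , drop = FALSE]) / m
      t <- t + 1L
      for (l in nl:1) {
        gW <- crossprod(fw$acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1)
          delta <- (delta %*% t(net$W[[l]])) * (1 - fw$acts[[l]]^2)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        cor1 <- 1 - beta1^t; cor2 <- 1 - beta2^t
        net$W[[l]] <- net$W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
        net$b[[l]] <- net$b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
      }
    }
  }
  net
}

# voxels within `band` of the automatic structure contour (1-based coords)
band_voxels <- function(auto_labels, label_id, band) {
  dmap <- distance_map(auto_labels, label_id)
  which(dmap <= band, arr.ind = TRUE)
}

#' Train a patch-based ensemble corrector
#'
#' Learns the systematic errors of the automatic segmentation for one
#' structure: a boosted ensemble of 10 shallow networks (112 x 83 x 55 x 27)
#' mapping the 112-feature vector of each voxel near the structure contour
#' to the 3x3x3 binary membership patch of the structure in the manual
#' labels. Networks are trained sequentially on subsets drawn with
#' per-sample selection weights; after each network, the weights of samples
#' the current ensemble misclassifies (any of the 27 patch outputs wrong
#' after 0.5-thresholding) are multiplied by `1 + beta` and renormalized.
#'
#' @param training list of triples, each `list(t1 = image_volume,
#'   auto = label_volume, manual = label_volume)` on one grid.
#' @param label_id structure this one-vs-rest ensemble corrects.
#' @param n_samples training samples drawn per network.
#' @param band half-width (voxels) of the sampling band around the
#'   automatic contour.
#' @param beta boosting weight multiplier for misclassified samples.
#' @param ensemble_size number of networks (10 in the reference design).
#' @param epochs training epochs per network.
#' @param seed random seed (sampling, initialization, minibatch order).
#' @return An object of class `pec_model`.
#' @export
pec_train <- function(training, label_id, n_samples = 3000L, band = 2,
                      beta = 2, ensemble_size = 10L, epochs = 40L, seed = 1L) {
  if (length(training) < 1L) stop("need at least one training triple")
  feats <- list(); targs <- list()
  for (tr in training) {
    check_same_grid(tr$auto, tr$manual)
    if (!any(tr$auto$labels == label_id)) next
    vox <- band_voxels(tr$auto, label_id, band)
    if (nrow(vox) == 0L) next
    feats[[length(feats) + 1L]] <-
      pec_features(tr$t1, tr$auto, label_id, vox)
    manual_bin <- array(as.double(tr$manual$labels == as.integer(label_id)),
                        vol_dim(tr$manual))
    targs[[length(targs) + 1L]] <-
      .cpp_patch3(manual_bin, matrix(as.integer(vox - 1L), ncol = 3))
  }
  if (!length(feats)) stop("empty candidate sample pool for label ", label_id)
  X <- do.call(rbind, feats)
  Y <- do.call(rbind, targs)
  if (length(unique(as.vector(Y))) < 2L)
    warning("degenerate single-class targets for label ", label_id)
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale < 1e-12] <- 1
  Xn <- sweep(sweep(X, 2, center), 2, scale, "/")

  set.seed(seed)
  n <- nrow(Xn)
  w <- rep(1 / n, n)
  nets <- vector("list", ensemble_size)
  ens_sum <- matrix(0, n, ncol(Y))
  for (t in seq_len(ensemble_size)) {
    take <- sample.int(n, size = min(n_samples, n), replace = TRUE, prob = w)
    nets[[t]] <- mlp_train(Xn[take, , drop = FALSE], Y[take, , drop = FALSE],
                           epochs = epochs)
    ens_sum <- ens_sum + mlp_predict(nets[[t]], Xn)
    pred <- (ens_sum / t) >= 0.5
    mis <- rowSums(pred != (Y >= 0.5)) > 0L
    w[mis] <- w[mis] * (1 + beta)
    w <- w / sum(w)
  }
  structure(list(networks = nets, center = center, scale = scale,
                 label_id = as.integer(label_id), band = band, beta = beta,
                 ensemble_size = as.integer(ensemble_size)),
            class = "pec_model")
}

#' @export
print.pec_model <- function(x, ...) {
  cat(sprintf("<pec_model> label %d: ensemble of %d networks (112x83x55x27), band %g voxels\n",
              x$label_id, length(x$networks), x$band))
  invisible(x)
}

#' Apply a patch-based ensemble corrector
#'
#' For every voxel within the model's band of the structure's automatic
#' contour, the ensemble-averaged 27-output patch predictions are
#' accumulated into per-voxel membership votes (overlapping patches
#' averaged). Voxels whose averaged membership crosses 0.5 are toggled in or
#' out of the structure; voxels displaced out of it receive the runner-up
#' fusion label when probability maps are supplied, otherwise the label of
#' the nearest non-structure voxel. All voxels outside the band are
#' unchanged.
#'
#' @param model a [pec_train()] result.
#' @param t1 the subject [image_volume()].
#' @param auto_labels the automatic segmentation to correct.
#' @param prob optional `probability_maps` from the fusion stage, used for
#'   runner-up labels of displaced voxels.
#' @return A corrected [label_volume()].
#' @export
pec_apply <- function(model, t1, auto_labels, prob = NULL) {
  check_same_grid(t1, auto_labels)
  d <- vol_dim(t1)
  id <- model$label_id
  if (!any(auto_labels$labels == id)) return(auto_labels)
  vox <- band_voxels(auto_labels, id, model$band)
  X <- pec_features(t1, auto_labels, id, vox)
  Xn <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  pred <- matrix(0, nrow(Xn), 27)
  for (net in model$networks) pred <- pred + mlp_predict(net, Xn)
  pred <- pred / length(model$networks)
  sc <- .cpp_scatter_patch3(pred, matrix(as.integer(vox - 1L), ncol = 3),
                            as.integer(d))
  member <- array(FALSE, d)
  seen <- sc$count > 0
  member[seen] <- (sc$sum[seen] / sc$count[seen]) >= 0.5
  # correction is local: only the band may change
  in_band <- array(FALSE, d)
  in_band[vox] <- TRUE
  lab <- auto_labels$labels
  add <- in_band & member & lab != id
  drop_ <- in_band & !member & lab == id
  lab[add] <- id
  if (any(drop_)) {
    idx <- which(drop_)
    if (!is.null(prob)) {
      m <- matrix(prob$maps, nrow = prod(d), ncol = length(prob$labels))
      m[, prob$labels == id] <- -Inf
      lab[idx] <- prob$labels[max.col(m[idx, , drop = FALSE], ties.method = "first")]
    } else {
      others <- auto_labels$labels
      others[others == id] <- 0L
      ids <- setdiff(sort(unique(as.vector(others))), 0L)
      if (length(ids)) lab[idx] <- nearest_id_of_set(others, idx, ids)
      else lab[idx] <- 0L
    }
  }
  label_volume(lab, auto_labels$affine)
}

#' Save / load a corrector model as portable text
#'
#' Serializes per-network weight matrices, the feature-normalization
#' statistics, and the model constants into a single versioned JSON-like
#' plain-text file (dput format).
#'
#' @param model a `pec_model`.
#' @param path output file.
#' @return `path` (write) or the restored `pec_model` (read).
#' @export
write_pec_model <- function(model, path) {
  obj <- unclass(model)
  obj$format_version <- 1L
  dput(obj, file = path,
       control = c("keepNA", "keepInteger", "showAttributes", "hexNumeric"))
  invisible(path)
}

#' @rdname write_pec_model
#' @export
read_pec_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- dget(path)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported corrector model format")
  obj$format_version <- NULL
  structure(obj, class = "pec_model")
}
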