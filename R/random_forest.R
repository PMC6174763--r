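#' @title Random-forest voxel classification
#'
#' @description
#' Automatic voxel-wise segmentation of reconstructed sweep volumes with a
#' random forest of 12 binary decision trees of depth 10. Each voxel is
#' described by 30 image features drawn from four families — Gaussian
#' blurs, gradients, Laplacians and multi-resolution resampling: 15
#' features at native resolution (raw intensity; blurs at sigma 1, 2, 4;
#' per-axis gradients and gradient magnitude at sigma 1, 2; Laplacian at
#' sigma 1, 2; the local mean over a 15-voxel cubic window) and the same
#' 15 recomputed on a 2x downsampled copy and resampled back. Each tree is
#' grown on a bootstrap resample with a random feature subset per split;
#' the forest probability is the arithmetic mean of the per-tree leaf
#' probabilities.
#'
#' @name random_forest
NULL

FEATURE_NAMES <- c("raw", "blur1", "blur2", "blur4",
                   "gx1", "gy1", "gz1", "gmag1", "gx2", "gy2", "gz2", "gmag2",
                   "lap1", "lap2", "win15_mean")

# Central difference along one axis of a 3D array, reflected borders.
cdiff3 <- function(v, axis) {
  dm <- dim(v); n <- dm[axis]
  lo <- c(1, seq_len(n - 1)); hi <- c(seq_len(n - 1) + 1, n)
  sl <- function(ii) switch(axis, v[ii, , , drop = FALSE], v[, ii, , drop = FALSE], v[, , ii, drop = FALSE])
  (sl(hi) - sl(lo)) / 2
}

# Second central difference f(x+1) - 2 f(x) + f(x-1), reflected borders.
sdiff3 <- function(v, axis) {
  dm <- dim(v); n <- dm[axis]
  lo <- c(1, seq_len(n - 1)); hi <- c(seq_len(n - 1) + 1, n)
  sl <- function(ii) switch(axis, v[ii, , , drop = FALSE], v[, ii, , drop = FALSE], v[, , ii, drop = FALSE])
  sl(hi) - 2 * v + sl(lo)
}

# Box mean over a cubic window of side `side` via integral sums, reflected edges.
box_mean3 <- function(v, side) {
  r <- (side - 1) %/% 2
  out <- array(0, dim(v))
  # separable box filter, one axis at a time
  for (axis in 1:3) {
    n <- dim(v)[axis]
    acc <- array(0, dim(v))
    for (o in -r:r) {
      ii <- pmin(pmax(seq_len(n) + o, 1L), n)
      acc <- acc + switch(axis, v[ii, , , drop = FALSE], v[, ii, , drop = FALSE], v[, , ii, drop = FALSE])
    }
    v <- acc / side
  }
  v
}

feature_stack_native <- function(vol) {
  out <- vector("list", 15)
  names(out) <- FEATURE_NAMES
  out$raw <- vol
  b1 <- gaussian_blur(vol, 1); b2 <- gaussian_blur(vol, 2); b4 <- gaussian_blur(vol, 4)
  out$blur1 <- b1; out$blur2 <- b2; out$blur4 <- b4
  for (s in c(1, 2)) {
    b <- if (s == 1) b1 else b2
    gx <- cdiff3(b, 1); gy <- cdiff3(b, 2); gz <- cdiff3(b, 3)
    out[[paste0("gx", s)]] <- gx
    out[[paste0("gy", s)]] <- gy
    out[[paste0("gz", s)]] <- gz
    out[[paste0("gmag", s)]] <- sqrt(gx^2 + gy^2 + gz^2)
    lap <- 0
    for (ax in 1:3) lap <- lap + sdiff3(b, ax)
    out[[paste0("lap", s)]] <- lap
  }
  out$win15_mean <- box_mean3(vol, 15)
  out
}

# 2x2x2 average pooling (edges clipped for odd extents).
downsample2 <- function(vol) {
  dm <- dim(vol)
  d2 <- pmax(dm %/% 2L, 1L)
  base <- lapply(1:3, function(ax) (seq_len(d2[ax]) - 1L) * 2L + 1L)
  acc <- array(0, d2)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
    acc <- acc + vol[pmin(base[[1]] + di, dm[1]),
                     pmin(base[[2]] + dj, dm[2]),
                     pmin(base[[3]] + dk, dm[3]), drop = FALSE]
  acc / 8
}

upsample_nn <- function(vol, target_dim) {
  idx <- lapply(1:3, function(ax) pmin((seq_len(target_dim[ax]) + 1L) %/% 2L, dim(vol)[ax]))
  vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Voxel feature volumes
#'
#' Computes the full 30-feature stack once for a volume; [voxel_features()]
#' samples it per voxel.
#'
#' @param vol 3D numeric array of intensities.
#' @return named list of 30 arrays matching `dim(vol)`.
#' @export
feature_volumes <- function(vol) {
  stopifnot(length(dim(vol)) == 3)
  native <- feature_stack_native(vol)
  ds <- feature_stack_native(downsample2(vol))
  ds_up <- lapply(ds, upsample_nn, target_dim = dim(vol))
  names(ds_up) <- paste0("ds2_", FEATURE_NAMES)
  c(native, ds_up)
}

#' Feature vector of one voxel
#'
#' @param vol 3D numeric array.
#' @param voxel integer length-3 `(i, j, k)`, 1-based.
#' @param fv optional precomputed [feature_volumes()] of `vol`.
#' @return named numeric length-30 vector.
#' @export
voxel_features <- function(vol, voxel, fv = feature_volumes(vol)) {
  stopifnot(length(voxel) == 3, all(voxel >= 1), all(voxel <= dim(vol)))
  vapply(fv, function(a) a[voxel[1], voxel[2], voxel[3]], numeric(1))
}

#' Labelled intensity volume
#'
#' @param intensity 3D numeric array.
#' @param labels 3D 0/1 array of the same shape.
#' @param spacing voxel spacing in mm, length 3.
#' @return list of class `labelled_volume`.
#' @export
labelled_volume <- function(intensity, labels, spacing) {
  stopifnot(identical(dim(intensity), dim(labels)), all(labels %in% c(0, 1)),
            length(spacing) == 3, all(spacing > 0))
  structure(list(intensity = intensity, labels = labels, spacing = as.numeric(spacing)),
            class = "labelled_volume")
}

#' Random-forest configuration
#'
#' @param n_trees forest size (default 12).
#' @param depth maximum tree depth (default 10).
#' @param samples_per_volume voxels sampled per class per training volume
#'   (default 20000; class-balanced).
#' @param mtry features tried per split (default `ceiling(sqrt(30)) = 6`).
#' @param seed RNG seed.
#' @return list of class `rfc_config`.
#' @export
rfc_config <- function(n_trees = 12L, depth = 10L, samples_per_volume = 20000L,
                       mtry = 6L, seed = 1L) {
  stopifnot(n_trees >= 1, depth >= 1, samples_per_volume >= 2, mtry >= 1)
  structure(list(n_trees = as.integer(n_trees), depth = as.integer(depth),
                 samples_per_volume = as.integer(samples_per_volume),
                 mtry = as.integer(mtry), seed = as.integer(seed)),
            class = "rfc_config")
}

# Class-balanced voxel sample (indices) from one labelled volume.
sample_voxels <- function(lv, per_class, seed) {
  set.seed(seed)
  fg <- which(lv$labels == 1); bg <- which(lv$labels == 0)
  if (!length(fg) || !length(bg)) stop("training volume must contain both classes")
  c(sample(fg, min(per_class, length(fg))), sample(bg, min(per_class, length(bg))))
}

#' Train the random-forest voxel classifier
#'
#' @param volumes list of [labelled_volume()]s (each with both classes).
#' @param cfg an [rfc_config()].
#' @return list of class `rfc_model` with the fitted \pkg{ranger}
#'   probability forest, the config, and the out-of-bag error.
#' @export
train_rfc <- function(volumes, cfg = rfc_config()) {
  if (!length(volumes)) stop("no training volumes")
  tabs <- vector("list", length(volumes))
  for (v in seq_along(volumes)) {
    lv <- volumes[[v]]
    fv <- feature_volumes(lv$intensity)
    idx <- sample_voxels(lv, cfg$samples_per_volume, derive_seed(cfg$seed, v))
    X <- vapply(fv, function(a) a[idx], numeric(length(idx)))
    tabs[[v]] <- data.frame(X, label = factor(lv$labels[idx], levels = c(0, 1)))
  }
  tab <- do.call(rbind, tabs)
  if (length(unique(tab$label)) < 2) stop("training data contains a single class")
  fit <- ranger::ranger(label ~ ., data = tab, num.trees = cfg$n_trees,
                        max.depth = cfg$depth, mtry = cfg$mtry,
                        probability = TRUE, replace = TRUE, seed = cfg$seed,
                        num.threads = 1)
  structure(list(forest = fit, cfg = cfg, oob_error = fit$prediction.error),
            class = "rfc_model")
}

#' Voxel-wise foreground probability volume
#'
#' The forest probability is the mean of the per-tree leaf probabilities.
#'
#' @param model an `rfc_model`.
#' @param vol 3D numeric array.
#' @param per_tree return the per-tree probability matrix as an attribute
#'   (`voxels x trees`), for auditing the ensemble average.
#' @return 3D array of probabilities in `[0, 1]`.
#' @export
predict_rfc <- function(model, vol, per_tree = FALSE) {
  fv <- feature_volumes(vol)
  X <- data.frame(vapply(fv, as.vector, numeric(length(vol))))
  pr <- predict(model$forest, X, num.threads = 1)$predictions[, "1"]
  out <- array(pr, dim(vol))
  if (per_tree) {
    pa <- predict(model$forest, X, predict.all = TRUE, num.threads = 1)$predictions
    cls <- match("1", colnames(model$forest$predictions))
    attr(out, "per_tree") <- matrix(pa[, cls, ], nrow = dim(pa)[1])
  }
  out
}

#' Threshold a probability volume into a binary label volume
#'
#' @param prob 3D array of probabilities.
#' @param threshold foreground iff probability >= threshold (default 0.5).
#' @param largest_component keep only the largest 6-connected 3D component.
#' @return 3D 0/1 integer array; monotone in `threshold`.
#' @export
probability_to_mask <- function(prob, threshold = 0.5, largest_component = FALSE) {
  lab <- array(as.integer(prob >= threshold), dim(prob))
  if (largest_component && any(lab > 0)) {
    cc <- label_components_3d6(lab > 0)
    sizes <- tabulate(cc[cc > 0])
    lab <- array(as.integer(cc == which.max(sizes)), dim(prob))
  }
  lab
}

# 6-connected 3D component labelling (BFS).
label_components_3d6 <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  cur <- 0L
  for (seed in which(mask)) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed; lab[seed] <- cur
    while (length(frontier)) {
      i <- ((frontier - 1L) %% dm[1]) + 1L
      j <- (((frontier - 1L) %/% dm[1]) %% dm[2]) + 1L
      k <- ((frontier - 1L) %/% (dm[1] * dm[2])) + 1L
      nb <- integer(0)
      for (d in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))) {
        i2 <- i + d[1]; j2 <- j + d[2]; k2 <- k + d[3]
        ok <- i2 >= 1 & i2 <= dm[1] & j2 >= 1 & j2 <= dm[2] & k2 >= 1 & k2 <= dm[3]
        if (any(ok)) nb <- c(nb, (k2[ok] - 1L) * dm[1] * dm[2] + (j2[ok] - 1L) * dm[1] + i2[ok])
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

#' Cross-validate the voxel classifier over volumes
#'
#' Volumes are partitioned into `k_folds` folds; for each fold the forest
#' is trained on the remaining volumes and evaluated on the held-out ones
#' with the 3D Dice coefficient.
#'
#' @param volumes list of [labelled_volume()]s.
#' @param k_folds number of folds, `2 <= k_folds <= length(volumes)`.
#' @param cfg an [rfc_config()].
#' @return data.frame with columns `fold`, `volume`, `dice`; attributes
#'   `mean_dice` and `sd_dice`.
#' @export
cross_validate <- function(volumes, k_folds, cfg = rfc_config()) {
  n <- length(volumes)
  if (k_folds < 2) stop("k_folds must be at least 2 (no held-out data otherwise)")
  if (k_folds > n) stop("k_folds exceeds the number of volumes")
  fold_of <- rep(seq_len(k_folds), length.out = n)
  res <- list()
  for (f in seq_len(k_folds)) {
    train_idx <- which(fold_of != f); test_idx <- which(fold_of == f)
    model <- train_rfc(volumes[train_idx], cfg)
    for (ti in test_idx) {
      prob <- predict_rfc(model, volumes[[ti]]$intensity)
      pred <- probability_to_mask(prob)
      res[[length(res) + 1]] <- data.frame(fold = f, volume = ti,
                                           dice = dice(pred, volumes[[ti]]$labels))
    }
  }
  out <- do.call(rbind, res)
  attr(out, "mean_dice") <- mean(out$dice)
  attr(out, "sd_dice") <- sd(out$dice)
  out
}
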