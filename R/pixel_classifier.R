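#' @title Pixel-based classifier (decision trees on local texture features)
#'
#' @description
#' Segments frames from three local pixel features: the coefficient of
#' variation `C_v = sigma/mu` over the 4-neighbourhood (plus centre, 5
#' pixels) and over the 8-neighbourhood (plus centre, 9 pixels), and the
#' mean of the smaller (5-pixel) neighbourhood. `sigma` is the population
#' standard deviation; `C_v` is defined as 0 where `mu = 0`. Training
#' samples come from small patches around user clicks inside and outside
#' the thyroid; a bagged ensemble of Gini decision trees is trained on
#' them and applied to every pixel, and the largest 8-connected component
#' (after a 3x3 morphological closing) is kept as the final segmentation.
#'
#' @name pixel_classifier
NULL

# Feature matrices for a whole frame (reflected borders): cv4, cv8, mean4.
frame_features <- function(img) {
  offs4 <- list(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  offs8 <- c(offs4, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  acc <- function(offs) {
    s <- 0; s2 <- 0
    for (o in offs) {
      v <- shift_reflect(img, o[1], o[2])
      s <- s + v; s2 <- s2 + v^2
    }
    n <- length(offs)
    mu <- s / n
    sig <- sqrt(pmax(s2 / n - mu^2, 0))
    list(mu = mu, sig = sig)
  }
  a4 <- acc(offs4); a8 <- acc(offs8)
  list(cv4 = ifelse(a4$mu == 0, 0, a4$sig / a4$mu),
       cv8 = ifelse(a8$mu == 0, 0, a8$sig / a8$mu),
       mean4 = a4$mu)
}

#' Local texture features at one pixel
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param row,col 0-based pixel coordinates (border pixels use reflected
#'   padding).
#' @return named numeric vector `(cv4, cv8, mean4)`.
#' @export
compute_features <- function(img, row, col) {
  h <- nrow(img); w <- ncol(img)
  if (row < 0 || row > h - 1 || col < 0 || col > w - 1)
    stop("pixel (", row, ", ", col, ") out of bounds")
  f <- frame_features(img)
  i <- row + 1; j <- col + 1
  c(cv4 = f$cv4[i, j], cv8 = f$cv8[i, j], mean4 = f$mean4[i, j])
}

#' Click-based training annotations
#'
#' @param inside,outside matrices with columns `(frame, row, col)`
#'   (0-based), clicks inside / outside the thyroid.
#' @return list of class `click_set`.
#' @export
click_set <- function(inside, outside) {
  inside <- matrix(as.numeric(inside), ncol = 3)
  outside <- matrix(as.numeric(outside), ncol = 3)
  if (!nrow(inside) || !nrow(outside))
    stop("both inside and outside click lists must be non-empty")
  structure(list(inside = inside, outside = outside), class = "click_set")
}

#' Build a labelled feature table from clicks
#'
#' For each click, the features of all pixels in a
#' `(2 patch_radius + 1)^2` patch around it (clipped to the frame) are
#' collected and labelled with the click's class.
#'
#' @param sweep a [tracked_sweep()].
#' @param clicks a [click_set()].
#' @param patch_radius patch half-size in pixels (default 5).
#' @return data.frame with columns `cv4`, `cv8`, `mean4`,
#'   `label` (factor 0/1).
#' @export
build_training_set <- function(sweep, clicks, patch_radius = 5L) {
  feats_cache <- list()
  get_feats <- function(fi) {
    key <- as.character(fi)
    if (is.null(feats_cache[[key]]))
      feats_cache[[key]] <<- frame_features(sweep$frames[[fi + 1]]$image)
    feats_cache[[key]]
  }
  rows <- list()
  collect <- function(tab, lab) {
    for (i in seq_len(nrow(tab))) {
      fi <- tab[i, 1]
      if (fi < 0 || fi > length(sweep$frames) - 1) stop("click frame ", fi, " outside the sweep")
      f <- get_feats(fi)
      img <- sweep$frames[[fi + 1]]$image
      rs <- max(0, tab[i, 2] - patch_radius):min(nrow(img) - 1, tab[i, 2] + patch_radius)
      cs <- max(0, tab[i, 3] - patch_radius):min(ncol(img) - 1, tab[i, 3] + patch_radius)
      g <- expand.grid(r = rs + 1, c = cs + 1)
      rows[[length(rows) + 1]] <<- data.frame(
        cv4 = f$cv4[cbind(g$r, g$c)], cv8 = f$cv8[cbind(g$r, g$c)],
        mean4 = f$mean4[cbind(g$r, g$c)], label = lab)
    }
  }
  collect(clicks$inside, 1L)
  collect(clicks$outside, 0L)
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = c(0, 1))
  stopifnot(all(is.finite(out$cv4)), all(is.finite(out$cv8)), all(is.finite(out$mean4)))
  out
}

#' Train a bagged decision-tree ensemble
#'
#' Each tree is a Gini-split CART fit (via \pkg{rpart}) on a bootstrap
#' resample of the training table; prediction probability is the
#' arithmetic mean of the per-tree leaf probabilities.
#'
#' @param table data.frame from [build_training_set()].
#' @param n_trees ensemble size (default 10).
#' @param max_depth maximum tree depth (default 8).
#' @param seed RNG seed for the bootstrap.
#' @return list of class `tree_model`.
#' @export
train_trees <- function(table, n_trees = 10L, max_depth = 8L, seed = 1L) {
  if (length(unique(table$label)) < 2)
    stop("training table contains a single class")
  set.seed(seed)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    boot <- table[sample.int(nrow(table), replace = TRUE), , drop = FALSE]
    if (length(unique(boot$label)) < 2) boot <- table # degenerate resample
    trees[[t]] <- rpart::rpart(label ~ cv4 + cv8 + mean4, data = boot, method = "class",
                               control = rpart::rpart.control(cp = 0, minsplit = 4,
                                                              maxdepth = max_depth,
                                                              xval = 0))
  }
  structure(list(trees = trees, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "tree_model")
}

#' Per-pixel class probability under a tree ensemble
#'
#' @param model a `tree_model`.
#' @param feats data.frame with `cv4`, `cv8`, `mean4`.
#' @return numeric vector of foreground probabilities (mean of per-tree
#'   leaf probabilities).
#' @export
predict_trees <- function(model, feats) {
  p <- 0
  for (tr in model$trees) p <- p + predict(tr, feats, type = "prob")[, "1"]
  as.numeric(p) / model$n_trees
}

#' Classify one frame pixelwise
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param model a `tree_model` from [train_trees()].
#' @param threshold probability threshold for the foreground label.
#' @return 0/1 integer mask.
#' @export
classify_frame <- function(img, model, threshold = 0.5) {
  f <- frame_features(img)
  feats <- data.frame(cv4 = as.vector(f$cv4), cv8 = as.vector(f$cv8),
                      mean4 = as.vector(f$mean4))
  p <- predict_trees(model, feats)
  matrix(as.integer(p >= threshold), nrow(img), ncol(img))
}

#' Morphological cleanup: keep the largest connected component
#'
#' A 3x3 closing bridges 1-pixel gaps, then only the largest 8-connected
#' component survives. An empty mask stays empty.
#'
#' @param mask 0/1 integer matrix.
#' @return 0/1 integer matrix that is a single component (or empty).
#' @export
largest_component <- function(mask) {
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  closed <- EBImage::closing(mask > 0, EBImage::makeBrush(3, "box"))
  lab <- label_components8(closed > 0)
  sizes <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(sizes)), nrow(mask), ncol(mask))
}

#' Segment a whole sweep with the pixel-based classifier
#'
#' One model is trained from all clicks across their frames and applied to
#' every frame, followed by [largest_component()] cleanup per frame.
#'
#' @param sweep a [tracked_sweep()].
#' @param clicks a [click_set()].
#' @param cfg list: `n_trees` (10), `max_depth` (8), `patch_radius` (5),
#'   `seed` (1), `threshold` (0.5).
#' @return list of 0/1 masks, one per frame.
#' @export
segment_sweep_pbc <- function(sweep, clicks, cfg = list()) {
  cfg <- utils::modifyList(list(n_trees = 10L, max_depth = 8L, patch_radius = 5L,
                                seed = 1L, threshold = 0.5), cfg)
  tab <- build_training_set(sweep, clicks, cfg$patch_radius)
  model <- train_trees(tab, cfg$n_trees, cfg$max_depth, cfg$seed)
  lapply(sweep$frames, function(fr)
    largest_component(classify_frame(fr$image, model, cfg$threshold)))
}
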