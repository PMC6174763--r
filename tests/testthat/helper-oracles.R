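# Shared fixtures and independent brute-force oracles.

# Small sweep study conditions: 20 frames of 96x96 px at 0.25 mm/px, 1 mm
# steps, imaging the central portion of the lobe so every frame (including
# frame 0, where the user initializes) shows a sizable cross-section. Used
# for the per-method sweep studies; the finer package default emulates
# clinical sampling of a whole lobe.
sweep_spec96 <- function(seed = 1, wobble = 0, speckle = 0.3, n_frames = 20L) {
  phantom_spec(semi_axes_mm = c(8, 6, 11), lobe_centre_mm = c(0, 0, 9.5),
               speckle_scale = speckle, n_frames = n_frames, frame_step_mm = 1,
               pixel_spacing_mm = c(0.25, 0.25), frame_size = c(96L, 96L),
               wobble_mm = wobble, seed = seed)
}

# Rasterized disc mask (1-based centre in pixels).
mk_disc <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  g <- expand.grid(row = 1:n, col = 1:n)
  matrix(as.integer((g$row - cy)^2 + (g$col - cx)^2 <= r^2), n, n)
}

# Two-level disc image with optional multiplicative Rayleigh speckle.
disc_image <- function(n = 128, r = 25, lo = 40, hi = 180, speckle = 0, seed = 42) {
  img <- ifelse(mk_disc(n, r) > 0, lo, hi)
  if (speckle > 0) {
    set.seed(seed)
    ray <- matrix(sqrt(-2 * log(runif(n * n))) * sqrt(2 / pi), n, n)
    img <- pmin(pmax(img * (1 + speckle * (ray - 1)), 0), 255)
  }
  img
}

# Brute-force Dice by pixel loop.
dice_bf <- function(X, Y) {
  inter <- 0; sx <- 0; sy <- 0
  for (i in seq_along(X)) {
    sx <- sx + (X[i] > 0); sy <- sy + (Y[i] > 0)
    inter <- inter + (X[i] > 0 && Y[i] > 0)
  }
  if (sx + sy == 0) 1 else 2 * inter / (sx + sy)
}

# Brute-force symmetric Hausdorff over foreground coordinates.
hausdorff_bf <- function(X, Y, spacing = rep(1, length(dim(X)))) {
  cx <- which(X > 0, arr.ind = TRUE); cy <- which(Y > 0, arr.ind = TRUE)
  cx <- sweep(cx, 2, spacing, "*"); cy <- sweep(cy, 2, spacing, "*")
  dmat <- sqrt(pmax(outer(rowSums(cx^2), rowSums(cy^2), "+") - 2 * cx %*% t(cy), 0))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Brute-force squared Euclidean distance to the nearest TRUE pixel.
sedt_bf <- function(mask, spacing = rep(1, length(dim(mask)))) {
  src <- which(mask, arr.ind = TRUE)
  src <- sweep(matrix(src, ncol = length(dim(mask))), 2, spacing, "*")
  all_idx <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
  pts <- sweep(all_idx, 2, spacing, "*")
  d <- pmax(outer(rowSums(pts^2), rowSums(src^2), "+") - 2 * pts %*% t(src), 0)
  array(apply(d, 1, min), dim(mask))
}

# Gradient magnitude with one-sided differences at the array edge.
grad_mag <- function(phi) {
  n1 <- nrow(phi); n2 <- ncol(phi)
  div1 <- matrix(2, n1, n2); div1[1, ] <- 1; div1[n1, ] <- 1
  gy <- (rbind(phi[2:n1, ], phi[n1, ]) - rbind(phi[1, ], phi[1:(n1 - 1), ])) / div1
  div2 <- matrix(2, n1, n2); div2[, 1] <- 1; div2[, n2] <- 1
  gx <- (cbind(phi[, 2:n2], phi[, n2]) - cbind(phi[, 1], phi[, 1:(n2 - 1)])) / div2
  sqrt(gx^2 + gy^2)
}

# Analytic signed distance to a circle, sampled on an n x n grid (0-based
# centre coordinates), negative inside.
analytic_disc_sdf <- function(n, r, cy = (n - 1) / 2, cx = (n - 1) / 2) {
  g <- expand.grid(row = 0:(n - 1), col = 0:(n - 1))
  matrix(sqrt((g$row - cy)^2 + (g$col - cx)^2) - r, n, n)
}

# Minimum GrabCut energy by exhaustive enumeration of unknown-pixel labels,
# for the GMMs the first iteration uses.
grabcut_energy_optimum <- function(img, tri) {
  ne <- thyrosweep:::nlink_edges(nrow(img), ncol(img))
  z <- as.vector(img)
  pr <- graph_params(50, beta_from_image(img))
  w_n <- nlink_weight(z[ne$pairs[, 1]], z[ne$pairs[, 2]], ne$dist, pr)
  gm <- fit_gmms(img, tri)
  gm <- list(fg = thyrosweep:::refit_gmm(gm$fg, z[as.vector(tri != 0)]),
             bg = thyrosweep:::refit_gmm(gm$bg, z[as.vector(tri == 0)]))
  d_fg <- thyrosweep:::neg_log(thyrosweep:::gmm_density(gm$fg, z))
  d_bg <- thyrosweep:::neg_log(thyrosweep:::gmm_density(gm$bg, z))
  unknown <- which(tri == 1)
  best <- Inf
  for (b in 0:(2^length(unknown) - 1)) {
    lab <- as.vector(tri == 2)
    lab[unknown] <- bitwAnd(b, 2^(seq_along(unknown) - 1)) > 0
    e <- thyrosweep:::labels_energy(lab, unknown, d_fg, d_bg, ne$pairs, w_n)
    best <- min(best, e)
  }
  best
}

# Random mask with at least one foreground pixel.
random_mask <- function(nr, nc, p = 0.3) {
  m <- matrix(as.integer(runif(nr * nc) < p), nr, nc)
  if (!any(m > 0)) m[sample(nr * nc, 1)] <- 1L
  m
}
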