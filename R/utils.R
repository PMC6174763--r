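# Internal array helpers shared across modules.

#' @importFrom stats median rnorm runif sd
NULL

# Reflect-pad a matrix by `r` pixels on every side.
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(r >= 1, nr > 1 || r == 0, nc > 1 || r == 0)
  ri <- c(rev(seq_len(min(r, nr - 1)) + 1L), seq_len(nr), nr - seq_len(min(r, nr - 1)))
  ci <- c(rev(seq_len(min(r, nc - 1)) + 1L), seq_len(nc), nc - seq_len(min(r, nc - 1)))
  if (length(ri) != nr + 2 * r || length(ci) != nc + 2 * r)
    stop("image too small for reflection padding of radius ", r)
  m[ri, ci, drop = FALSE]
}

# Shift a matrix by (dr, dc) with reflected borders.
shift_reflect <- function(m, dr, dc) {
  r <- max(abs(dr), abs(dc))
  if (r == 0) return(m)
  p <- pad_reflect(m, r)
  p[(1 + r + dr):(nrow(m) + r + dr), (1 + r + dc):(ncol(m) + r + dc), drop = FALSE]
}

# Central differences with reflected borders (unit grid spacing).
central_diff <- function(m, axis) {
  if (axis == 1) (shift_reflect(m, 1, 0) - shift_reflect(m, -1, 0)) / 2
  else           (shift_reflect(m, 0, 1) - shift_reflect(m, 0, -1)) / 2
}

# 1D squared Euclidean distance transform (lower envelope of parabolas,
# Felzenszwalb & Huttenlocher) with physical sample spacing `h`.
dt1d_sq <- function(f, h = 1) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  k <- 1L
  x <- (seq_len(n) - 1) * h
  for (q in 2:n) {
    if (!is.finite(f[q])) next
    repeat {
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      if (s <= z[k]) { k <- k - 1L; if (k == 0L) { k <- 1L; v[1L] <- q; z[1L] <- -Inf; z[2L] <- Inf; break } }
      else { k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf; break }
    }
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    p <- v[k]
    d[q] <- (x[q] - x[p])^2 + f[p]
  }
  d
}

# Squared Euclidean distance to the nearest TRUE element of a logical
# 2D or 3D array, with per-axis physical spacing.
sedt <- function(mask, spacing = rep(1, length(dim(mask)))) {
  dm <- dim(mask)
  stopifnot(length(dm) %in% c(2L, 3L), length(spacing) == length(dm), all(spacing > 0))
  if (!any(mask)) stop("distance transform of an empty set is undefined")
  f <- array(ifelse(mask, 0, Inf), dm)
  if (length(dm) == 2L) {
    for (j in seq_len(dm[2])) f[, j] <- dt1d_sq(f[, j], spacing[1])
    for (i in seq_len(dm[1])) f[i, ] <- dt1d_sq(f[i, ], spacing[2])
  } else {
    for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) f[, j, k] <- dt1d_sq(f[, j, k], spacing[1])
    for (i in seq_len(dm[1])) for (k in seq_len(dm[3])) f[i, , k] <- dt1d_sq(f[i, , k], spacing[2])
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) f[i, j, ] <- dt1d_sq(f[i, j, ], spacing[3])
  }
  f
}

# 8-connected component labelling of a logical matrix (BFS, frontier-vectorised).
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx_todo <- which(mask)
  cur <- 0L
  off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  for (seed in idx_todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier)) {
      fr <- ((frontier - 1L) %% nr) + 1L
      fc <- ((frontier - 1L) %/% nr) + 1L
      nb <- integer(0)
      for (o in seq_len(nrow(off))) {
        r2 <- fr + off[o, 1]; c2 <- fc + off[o, 2]
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
        if (any(ok)) nb <- c(nb, (c2[ok] - 1L) * nr + r2[ok])
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# Separable Gaussian smoothing of a 2D or 3D array, reflected borders,
# sigma in grid units.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  dm <- dim(x)
  conv_axis <- function(a, axis) {
    n <- dm[axis]
    # kernel radius truncated to what reflection padding supports
    r <- min(max(1L, ceiling(3 * sigma)), n - 1L)
    k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
    ii <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
    out <- array(0, dm)
    for (t in seq_along(k)) {
      sl <- ii[t:(t + n - 1L)]
      piece <- switch(axis,
                      if (length(dm) == 2L) a[sl, , drop = FALSE] else a[sl, , , drop = FALSE],
                      if (length(dm) == 2L) a[, sl, drop = FALSE] else a[, sl, , drop = FALSE],
                      a[, , sl, drop = FALSE])
      out <- out + k[t] * piece
    }
    out
  }
  for (ax in seq_along(dm)) x <- conv_axis(x, ax)
  x
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt) %% 2147483587)
}
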