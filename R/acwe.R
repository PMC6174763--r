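#' @title Active contours without edges (Chan-Vese)
#'
#' @description
#' Region-based level-set segmentation. The evolving contour is the zero
#' level set of a signed distance function `phi` (negative inside — the
#' package-wide sign convention). Two forces drive the evolution: a region
#' force derived from the image, whose pointwise form is
#' `(I - mu_in)^2 - (I - mu_out)^2` with `mu_in`/`mu_out` the mean
#' intensities inside/outside the contour, and a curvature force
#' `(phi_x^2 phi_yy + phi_y^2 phi_xx - 2 phi_x phi_y phi_xy) /
#' (phi_x^2 + phi_y^2)^(3/2)` computed with central differences. The update
#' is the explicit Euler step
#' `phi <- phi + dt * (alpha * F_curv + F_img / max|F_img|)` with the
#' CFL-safe step `dt = 1 / (max|phi_t| + epsilon)`, so the front never moves
#' more than one pixel per iteration. Evolution runs a fixed number of
#' iterations chosen by the user as an accuracy/time trade-off.
#'
#' Across a tracked sweep the segmentation of frame *k* initializes frame
#' *k+1*: the centroid of the current mask is carried through the tracking
#' matrices into the next image plane and a rectangle of the original
#' user-drawn size is placed there (see [propagate_init()]).
#'
#' @name acwe
NULL

#' ACWE configuration
#'
#' @param alpha curvature (smoothing) weight, >= 0.
#' @param epsilon CFL safeguard added to the step-size denominator, > 0.
#' @param iterations number of evolution steps, >= 1.
#' @param reinit_every re-initialize `phi` to a signed distance function
#'   every this many iterations.
#' @param preprocess list passed to [preprocess_frame()] by
#'   [segment_sweep_acwe()]; set to `NULL` to skip preprocessing.
#' @return list of class `acwe_config`.
#' @export
acwe_config <- function(alpha = 0.2, epsilon = 1e-5, iterations = 300L,
                        reinit_every = 50L, preprocess = list()) {
  stopifnot(alpha >= 0, epsilon > 0, iterations >= 1, reinit_every >= 1)
  structure(list(alpha = alpha, epsilon = epsilon,
                 iterations = as.integer(iterations),
                 reinit_every = as.integer(reinit_every),
                 preprocess = preprocess),
            class = "acwe_config")
}

#' Rectangle initialization
#'
#' A rectangle is described by its (possibly fractional, 0-based) centre and
#' integer half-sizes; it covers pixels with `|row - centre_row| <=
#' half_height` and `|col - centre_col| <= half_width`.
#'
#' @param centre numeric length-2, 0-based `(row, col)`.
#' @param half_height,half_width non-negative integers.
#' @return list of class `rect_init`.
#' @export
rect_init <- function(centre, half_height, half_width) {
  stopifnot(length(centre) == 2, is.finite(centre), half_height >= 0, half_width >= 0)
  structure(list(centre = as.numeric(centre),
                 half_height = as.integer(half_height),
                 half_width = as.integer(half_width)),
            class = "rect_init")
}

#' Rasterize a rectangle initialization to a binary mask
#'
#' Clipping to the frame is reported with a warning, never silent; a
#' rectangle fully outside the frame is an error.
#'
#' @param rect a [rect_init()].
#' @param dim frame dimensions `(height, width)`.
#' @return 0/1 integer matrix.
#' @export
rect_to_mask <- function(rect, dim) {
  h <- dim[1]; w <- dim[2]
  r0 <- rect$centre[1] - rect$half_height; r1 <- rect$centre[1] + rect$half_height
  c0 <- rect$centre[2] - rect$half_width;  c1 <- rect$centre[2] + rect$half_width
  if (r1 < 0 || r0 > h - 1 || c1 < 0 || c0 > w - 1)
    stop("init rectangle lies fully outside the ", h, "x", w, " frame")
  if (r0 < 0 || r1 > h - 1 || c0 < 0 || c1 > w - 1)
    warning("init rectangle clipped to the frame")
  rows <- 0:(h - 1); cols <- 0:(w - 1)
  m <- outer(abs(rows - rect$centre[1]) <= rect$half_height,
             abs(cols - rect$centre[2]) <= rect$half_width, "&")
  matrix(as.integer(m), h, w)
}

#' Signed distance function from a binary mask
#'
#' Exact Euclidean distance to the region boundary — the contour running
#' between opposite-label pixels, represented by the midpoints of
#' 4-adjacent foreground/background pixel pairs — signed negative inside
#' the mask and positive outside. Distances are computed with an exact
#' Euclidean distance transform on a 2x-refined grid so the boundary sits
#' on grid nodes; flipping the mask exactly negates `phi`, and
#' `|grad phi| = 1` holds across the boundary (eikonal property).
#'
#' @param mask 0/1 matrix with at least one pixel of each class.
#' @return numeric matrix `phi` (pixels), negative inside.
#' @export
make_sdf <- function(mask) {
  fg <- mask > 0
  if (!any(fg) || all(fg))
    stop("mask must contain both foreground and background pixels")
  nr <- nrow(mask); nc <- ncol(mask)
  # boundary midpoints on the 2x grid: pixel (i, j) sits at node (2i-1, 2j-1)
  up <- matrix(FALSE, 2L * nr, 2L * nc)
  iv <- which(fg[-nr, , drop = FALSE] != fg[-1, , drop = FALSE], arr.ind = TRUE)
  ih <- which(fg[, -nc, drop = FALSE] != fg[, -1, drop = FALSE], arr.ind = TRUE)
  if (nrow(iv)) up[cbind(2L * iv[, 1], 2L * iv[, 2] - 1L)] <- TRUE
  if (nrow(ih)) up[cbind(2L * ih[, 1] - 1L, 2L * ih[, 2])] <- TRUE
  d2 <- sqrt(sedt(up, c(0.5, 0.5)))
  d <- matrix(d2[cbind(rep(2L * seq_len(nr) - 1L, nc),
                       rep(2L * seq_len(nc) - 1L, each = nr))], nr, nc)
  ifelse(fg, -d, d)
}

#' Region (image) force of the Chan-Vese model
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param phi level-set matrix (negative inside).
#' @return list with `field` (matrix `(I-mu_in)^2 - (I-mu_out)^2`), `mu_in`
#'   and `mu_out`.
#' @export
image_force <- function(img, phi) {
  inside <- phi < 0
  if (!any(inside) || all(inside))
    stop("both regions (phi < 0, phi >= 0) must be non-empty")
  mu_in <- mean(img[inside]); mu_out <- mean(img[!inside])
  list(field = (img - mu_in)^2 - (img - mu_out)^2, mu_in = mu_in, mu_out = mu_out)
}

#' Curvature force of the level-set
#'
#' Mean curvature of the level sets of `phi`, central differences with
#' reflected borders; the denominator is stabilized by `1e-8`.
#'
#' @param phi level-set matrix.
#' @return numeric matrix of curvature values.
#' @export
curvature_force <- function(phi) {
  px <- central_diff(phi, 2); py <- central_diff(phi, 1)
  pxx <- shift_reflect(phi, 0, 1) - 2 * phi + shift_reflect(phi, 0, -1)
  pyy <- shift_reflect(phi, 1, 0) - 2 * phi + shift_reflect(phi, -1, 0)
  pxy <- central_diff(central_diff(phi, 1), 2)
  num <- px^2 * pyy + py^2 * pxx - 2 * px * py * pxy
  den <- (px^2 + py^2)^1.5 + 1e-8
  num / den
}

#' Evolve a contour on one frame
#'
#' Runs exactly `cfg$iterations` explicit Euler steps of the Chan-Vese
#' evolution (see [acwe]) from a rectangle or mask initialization,
#' re-initializing `phi` to a signed distance function every
#' `cfg$reinit_every` steps. On a constant image the (normalized) image
#' force is treated as zero. If one region vanishes during evolution the
#' contour is gone and the current labelling is returned.
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param init 0/1 matrix or [rect_init()] with both regions non-empty.
#' @param cfg an [acwe_config()].
#' @return 0/1 integer mask (`phi < 0`), with attribute `max_cfl` — the
#'   largest `dt * max|phi_t|` observed (always < 1).
#' @export
evolve <- function(img, init, cfg = acwe_config()) {
  assert_grey_image(img)
  if (inherits(init, "rect_init")) init <- rect_to_mask(init, dim(img))
  if (!identical(dim(init), dim(img))) stop("init and image dimensions differ")
  phi <- make_sdf(init)
  max_cfl <- 0
  for (it in seq_len(cfg$iterations)) {
    inside <- phi < 0
    if (!any(inside) || all(inside)) break
    fi <- image_force(img, phi)
    fmax <- max(abs(fi$field))
    f_img <- if (fmax > 0) fi$field / fmax else 0 * fi$field
    phi_t <- cfg$alpha * curvature_force(phi) + f_img
    mt <- max(abs(phi_t))
    dt <- 1 / (mt + cfg$epsilon)
    cfl <- dt * mt
    stopifnot(cfl < 1)
    max_cfl <- max(max_cfl, cfl)
    phi <- phi + dt * phi_t
    if (it %% cfg$reinit_every == 0L && any(phi < 0) && !all(phi < 0))
      phi <- make_sdf(matrix(as.integer(phi < 0), nrow(phi), ncol(phi)))
  }
  structure(matrix(as.integer(phi < 0), nrow(img), ncol(img)), max_cfl = max_cfl)
}

#' Propagate an initialization to the next frame
#'
#' The centroid of the previous frame's mask is mapped to tracker space
#' through the previous frame's tracking matrix and back into the next
#' frame's pixel grid (anatomy is taken as fixed in tracker space, so only
#' the in-plane component of the inter-frame motion moves the point; pure
#' out-of-plane displacement leaves the pixel position unchanged). A
#' rectangle of the same user-drawn half-sizes is centred there.
#'
#' @param prev_mask non-empty 0/1 matrix on `prev_frame`.
#' @param prev_frame,next_frame [tracked_frame()]s.
#' @param rect the reference [rect_init()] whose half-sizes are kept.
#' @return a [rect_init()] on the next frame.
#' @export
propagate_init <- function(prev_mask, prev_frame, next_frame, rect) {
  idx <- which(prev_mask > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("previous mask is empty; cannot propagate initialization")
  cen <- colMeans(idx) - 1 # 0-based (row, col)
  p <- pixel_to_world(prev_frame, cen[1], cen[2])
  q <- world_to_pixel(next_frame, p)
  out <- rect_init(c(q$row, q$col), rect$half_height, rect$half_width)
  h <- nrow(next_frame$image); w <- ncol(next_frame$image)
  if (q$row + rect$half_height < 0 || q$row - rect$half_height > h - 1 ||
      q$col + rect$half_width < 0 || q$col - rect$half_width > w - 1)
    stop("propagated rectangle fully outside the frame: tracking/segmentation divergence")
  out
}

#' Segment a whole sweep with ACWE
#'
#' Each frame is preprocessed (per `cfg$preprocess`) and evolved; frame
#' *k+1*'s rectangle comes from [propagate_init()] on frame *k*'s result. A
#' frame whose propagation or evolution degenerates is recorded as an empty
#' mask and propagation restarts from the last successful frame. Failure on
#' the first frame aborts.
#'
#' @param sweep a [tracked_sweep()].
#' @param first_init [rect_init()] for frame 0.
#' @param cfg an [acwe_config()].
#' @return list of 0/1 masks, one per frame.
#' @export
segment_sweep_acwe <- function(sweep, first_init, cfg = acwe_config()) {
  n <- length(sweep$frames)
  masks <- vector("list", n)
  last_ok <- NULL # list(index, mask)
  rect <- first_init
  for (k in seq_len(n)) {
    fr <- sweep$frames[[k]]
    img <- if (is.null(cfg$preprocess)) fr$image else preprocess_frame(fr$image, cfg$preprocess)
    res <- tryCatch({
      init <- if (k == 1) first_init else propagate_init(last_ok$mask, sweep$frames[[last_ok$index]], fr, rect)
      m <- evolve(img, init, cfg)
      if (!any(m > 0)) stop("evolution collapsed to an empty mask")
      m
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (k == 1) stop("ACWE failed on the first frame: ", conditionMessage(res))
      warning("frame ", k - 1, ": ", conditionMessage(res), "; recorded empty, propagation restarts")
      masks[[k]] <- matrix(0L, nrow(fr$image), ncol(fr$image))
    } else {
      masks[[k]] <- res
      last_ok <- list(index = k, mask = res)
    }
  }
  masks
}
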