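#' @title Synthetic tracked-sweep phantom
#'
#' @description
#' Generates ultrasound-like speckle sweeps of an ellipsoidal "thyroid
#' lobe" with exact ground truth: frame *k* images the plane
#' `z = k * frame_step_mm`; the echo map is `echogenicity_in` inside the
#' ellipsoid cross-section and `echogenicity_out` outside, softened by a
#' 2-px Gaussian edge, and is multiplied by fully developed speckle —
#' unit-mean Rayleigh noise blended as `1 + s (N - 1)` so that
#' `speckle_scale = 0` is exactly noiseless. Tracking matrices are
#' identity rotations with translation `(0, 0, k * frame_step_mm)`
#' (optionally wobbled in-plane to exercise propagation), ground-truth
#' masks are the exact ellipse cross-sections, and the analytic volume is
#' `4/3 pi a b c`.
#'
#' @name phantom
NULL

#' Phantom specification
#'
#' @param semi_axes_mm ellipsoid semi-axes `(a, b, c)` in mm; `a` along x
#'   (image columns), `b` along y (rows), `c` along z (sweep direction).
#' @param lobe_centre_mm world position of the ellipsoid centre.
#' @param echogenicity_in,echogenicity_out tissue brightness inside /
#'   outside the lobe, in `(0, 255)`. Thyroid parenchyma is darker than
#'   the surrounding strap muscle interfaces in the emulated acquisitions.
#' @param speckle_scale speckle strength `s >= 0` (0 = noiseless).
#' @param n_frames,frame_step_mm sweep length and inter-frame spacing; the
#'   sweep must span the ellipsoid.
#' @param pixel_spacing_mm mm per pixel `(row, col)`.
#' @param frame_size `(height, width)` in pixels.
#' @param wobble_mm sd of random in-plane tracking translations (0 = pure
#'   linear sweep).
#' @param seed RNG seed; fixed seed gives a bit-identical sweep.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes_mm = c(7, 5.5, 8.3),
                         lobe_centre_mm = c(0, 0, 8.8),
                         echogenicity_in = 60, echogenicity_out = 150,
                         speckle_scale = 0.3,
                         n_frames = 40L, frame_step_mm = 0.45,
                         pixel_spacing_mm = c(0.075, 0.075),
                         frame_size = c(256L, 256L),
                         wobble_mm = 0, seed = 1L) {
  stopifnot(all(semi_axes_mm > 0), all(c(echogenicity_in, echogenicity_out) > 0),
            all(c(echogenicity_in, echogenicity_out) < 255),
            speckle_scale >= 0, n_frames >= 2, frame_step_mm > 0,
            all(pixel_spacing_mm > 0), all(frame_size >= 8), wobble_mm >= 0)
  if (lobe_centre_mm[3] - semi_axes_mm[3] > (n_frames - 1) * frame_step_mm ||
      lobe_centre_mm[3] + semi_axes_mm[3] < 0)
    stop("ellipsoid does not intersect any frame plane")
  structure(list(semi_axes_mm = semi_axes_mm, lobe_centre_mm = lobe_centre_mm,
                 echogenicity_in = echogenicity_in, echogenicity_out = echogenicity_out,
                 speckle_scale = speckle_scale, n_frames = as.integer(n_frames),
                 frame_step_mm = frame_step_mm, pixel_spacing_mm = pixel_spacing_mm,
                 frame_size = as.integer(frame_size), wobble_mm = wobble_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# In-plane (x, y) mm coordinate grids of a frame (image centre at origin).
frame_xy_mm <- function(spec) {
  h <- spec$frame_size[1]; w <- spec$frame_size[2]
  x <- (0:(w - 1) - (w - 1) / 2) * spec$pixel_spacing_mm[2]
  y <- (0:(h - 1) - (h - 1) / 2) * spec$pixel_spacing_mm[1]
  list(x = matrix(x, h, w, byrow = TRUE), y = matrix(y, h, w))
}

#' Generate a synthetic tracked sweep with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `sweep` (a [tracked_sweep()]), `gt_masks` (exact
#'   ellipse cross-sections) and `analytic_volume_cm3` (`4/3 pi a b c`).
#' @export
generate_sweep <- function(spec) {
  set.seed(spec$seed)
  g <- frame_xy_mm(spec)
  a <- spec$semi_axes_mm[1]; b <- spec$semi_axes_mm[2]; cc <- spec$semi_axes_mm[3]
  ctr <- spec$lobe_centre_mm
  frames <- vector("list", spec$n_frames)
  gt <- vector("list", spec$n_frames)
  any_hit <- FALSE
  for (k in seq_len(spec$n_frames)) {
    z <- (k - 1) * spec$frame_step_mm
    wob <- if (spec$wobble_mm > 0) rnorm(2, 0, spec$wobble_mm) else c(0, 0)
    trk <- diag(4); trk[1:3, 4] <- c(wob[1], wob[2], z)
    # world in-plane position of each pixel in this (possibly wobbled) frame
    xw <- g$x + wob[1]; yw <- g$y + wob[2]
    q <- ((xw - ctr[1]) / a)^2 + ((yw - ctr[2]) / b)^2 + ((z - ctr[3]) / cc)^2
    mask <- matrix(as.integer(q <= 1), spec$frame_size[1], spec$frame_size[2])
    if (any(mask > 0)) any_hit <- TRUE
    echo <- ifelse(mask > 0, spec$echogenicity_in, spec$echogenicity_out)
    echo <- gaussian_blur(echo, 2)
    img <- echo
    if (spec$speckle_scale > 0) {
      # unit-mean Rayleigh: sigma * sqrt(-2 ln U) with sigma = sqrt(2/pi)
      ray <- matrix(sqrt(-2 * log(runif(length(echo)))) * sqrt(2 / pi),
                    spec$frame_size[1], spec$frame_size[2])
      img <- echo * (1 + spec$speckle_scale * (ray - 1))
    }
    img <- pmin(pmax(img, 0), 255)
    frames[[k]] <- tracked_frame(img, trk, spec$pixel_spacing_mm)
    gt[[k]] <- mask
  }
  if (!any_hit) stop("ellipsoid does not intersect any frame")
  list(sweep = tracked_sweep(frames, id = sprintf("phantom-seed%d", spec$seed)),
       gt_masks = gt,
       analytic_volume_cm3 = 4 / 3 * pi * a * b * cc / 1000)
}

#' Voxelize the phantom directly onto a 3D grid
#'
#' @param spec a [phantom_spec()].
#' @param voxel_mm isotropic voxel size (default 0.5 mm).
#' @return a [labelled_volume()]; intensities carry the same echo map and
#'   speckle model as the 2D frames, labels are the exact digitized
#'   ellipsoid.
#' @export
generate_labelled_volume <- function(spec, voxel_mm = 0.5) {
  set.seed(derive_seed(spec$seed, 7L))
  g <- frame_xy_mm(spec)
  xr <- range(g$x); yr <- range(g$y)
  zmax <- (spec$n_frames - 1) * spec$frame_step_mm
  xs <- seq(xr[1], xr[2], by = voxel_mm)
  ys <- seq(yr[1], yr[2], by = voxel_mm)
  zs <- seq(0, zmax, by = voxel_mm)
  dm <- c(length(xs), length(ys), length(zs))
  a <- spec$semi_axes_mm[1]; b <- spec$semi_axes_mm[2]; cc <- spec$semi_axes_mm[3]
  ctr <- spec$lobe_centre_mm
  X <- array(rep(xs, times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(ys, each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(zs, each = dm[1] * dm[2]), dm)
  q <- ((X - ctr[1]) / a)^2 + ((Y - ctr[2]) / b)^2 + ((Z - ctr[3]) / cc)^2
  labels <- array(as.integer(q <= 1), dm)
  echo <- ifelse(labels > 0, spec$echogenicity_in, spec$echogenicity_out)
  echo <- gaussian_blur(echo, 2 * min(spec$pixel_spacing_mm) / voxel_mm)
  vol <- echo
  if (spec$speckle_scale > 0) {
    ray <- array(sqrt(-2 * log(runif(length(echo)))) * sqrt(2 / pi), dm)
    vol <- echo * (1 + spec$speckle_scale * (ray - 1))
  }
  vol <- pmin(pmax(vol, 0), 255)
  labelled_volume(vol, labels, rep(voxel_mm, 3))
}

#' Deterministic stand-in user annotations for a phantom sweep
#'
#' Derives from the ground truth (i) a first-frame rectangle — the
#' bounding box of the frame-0 mask dilated by 20% —, (ii) a scribble set
#' every `every_n` frames with a horizontal foreground stroke through the
#' mask centroid and a rectangular background ring 30% outside the
#' bounding box, and (iii) 3 inside plus 3 outside clicks.
#'
#' @param spec a [phantom_spec()].
#' @param gt ground-truth output of [generate_sweep()] (regenerated when
#'   omitted).
#' @param every_n annotate every `every_n`-th frame (default 10).
#' @return list with `rect` ([rect_init()]), `scribbles` (list of
#'   [scribbles()]), `clicks` ([click_set()]).
#' @export
default_annotations <- function(spec, gt = NULL, every_n = 10L) {
  if (is.null(gt)) gt <- generate_sweep(spec)
  masks <- gt$gt_masks
  h <- spec$frame_size[1]; w <- spec$frame_size[2]
  bbox <- function(m) {
    idx <- which(m > 0, arr.ind = TRUE)
    rbind(range(idx[, 1]) - 1, range(idx[, 2]) - 1) # rows: (r0 r1), (c0 c1), 0-based
  }
  first_nonempty <- which(vapply(masks, function(m) any(m > 0), logical(1)))[1]
  if (is.na(first_nonempty)) stop("phantom ground truth is empty on every frame")
  bb <- bbox(masks[[first_nonempty]])
  cen <- rowMeans(bb)
  hh <- ceiling((bb[1, 2] - bb[1, 1]) / 2 * 1.2); hw <- ceiling((bb[2, 2] - bb[2, 1]) / 2 * 1.2)
  rect <- rect_init(cen, max(hh, 2), max(hw, 2))

  ann_frames <- seq(0, spec$n_frames - 1, by = every_n)
  scr <- list()
  for (fi in ann_frames) {
    m <- masks[[fi + 1]]
    if (!any(m > 0)) next
    bbf <- bbox(m); cf <- rowMeans(bbf)
    half_w <- (bbf[2, 2] - bbf[2, 1]) / 2
    stroke <- cbind(rep(round(cf[1]), 2), round(c(cf[2] - half_w / 2, cf[2] + half_w / 2)))
    ring_r <- pmin(pmax(c(bbf[1, 1], bbf[1, 2]) + c(-1, 1) * 0.3 * (bbf[1, 2] - bbf[1, 1] + 1) / 2, 0), h - 1)
    ring_c <- pmin(pmax(c(bbf[2, 1], bbf[2, 2]) + c(-1, 1) * 0.3 * (bbf[2, 2] - bbf[2, 1] + 1) / 2, 0), w - 1)
    ring <- rbind(c(ring_r[1], ring_c[1]), c(ring_r[1], ring_c[2]),
                  c(ring_r[2], ring_c[2]), c(ring_r[2], ring_c[1]),
                  c(ring_r[1], ring_c[1]))
    scr[[length(scr) + 1]] <- scribbles(list(stroke), round(ring), fi)
  }
  mid <- which(vapply(masks, sum, numeric(1)) == max(vapply(masks, sum, numeric(1))))[1]
  bbm <- bbox(masks[[mid]]); cm <- round(rowMeans(bbm))
  inside <- cbind(mid - 1, rbind(cm,
                                 cm + c(round((bbm[1, 2] - bbm[1, 1]) / 6), 0),
                                 cm - c(0, round((bbm[2, 2] - bbm[2, 1]) / 6))))
  margin <- 8
  outside <- cbind(mid - 1, rbind(c(margin, margin), c(margin, w - 1 - margin),
                                  c(h - 1 - margin, margin)))
  clicks <- click_set(inside, outside)
  list(rect = rect, scribbles = scr, clicks = clicks)
}
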