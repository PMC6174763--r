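#' @title Evaluation metrics and sweep-to-volume reconstruction
#'
#' @description
#' Segmentations are compared with the Dice coefficient
#' `2|X n Y| / (|X| + |Y|)` and the Hausdorff distance (the greatest
#' distance from a point of one set to its nearest point in the other;
#' the symmetric form `max(h(X,Y), h(Y,X))` is reported and the directed
#' pair exposed). A stack of per-frame masks plus its tracking matrices is
#' reconstructed into a voxel grid by inter-frame shape interpolation:
#' between consecutive slices the two frames' signed distance functions
#' are blended linearly along the sweep and a gap voxel is foreground
#' where the blended signed distance is negative. The thyroid volume is
#' the occupied-voxel count times the voxel volume, in cm^3.
#'
#' @name metrics_volume
NULL

#' Dice coefficient
#'
#' @param X,Y 0/1 arrays (masks or voxel grids) of identical shape.
#' @return `2|X n Y| / (|X| + |Y|)` in `[0, 1]`; two empty sets compare
#'   as 1.
#' @export
dice <- function(X, Y) {
  if (inherits(X, "voxel_grid")) X <- X$occupancy
  if (inherits(Y, "voxel_grid")) Y <- Y$occupancy
  if (!identical(dim(X), dim(Y))) stop("shape mismatch between X and Y")
  sx <- sum(X > 0); sy <- sum(Y > 0)
  if (sx + sy == 0) return(1)
  2 * sum(X > 0 & Y > 0) / (sx + sy)
}

#' Hausdorff distance between two masks or voxel grids
#'
#' Distances run between foreground pixel/voxel centres, scaled per axis
#' by `spacing` (mm).
#'
#' @param X,Y non-empty 0/1 arrays of identical shape.
#' @param spacing per-axis spacing in mm (length 2 or 3, matching the
#'   arrays).
#' @return symmetric Hausdorff distance in mm, with attribute `directed`
#'   holding the pair `c(xy, yx)`.
#' @export
hausdorff <- function(X, Y, spacing = rep(1, length(dim(X)))) {
  if (inherits(X, "voxel_grid")) { spacing <- X$spacing; X <- X$occupancy }
  if (inherits(Y, "voxel_grid")) Y <- Y$occupancy
  if (!identical(dim(X), dim(Y))) stop("shape mismatch between X and Y")
  if (!any(X > 0) || !any(Y > 0)) stop("Hausdorff distance needs two non-empty sets")
  dX <- sqrt(sedt(X > 0, spacing)); dY <- sqrt(sedt(Y > 0, spacing))
  h_xy <- max(dY[X > 0]) # sup over X of distance to Y
  h_yx <- max(dX[Y > 0])
  structure(max(h_xy, h_yx), directed = c(xy = h_xy, yx = h_yx))
}

#' Voxel grid container
#'
#' @param occupancy 3D 0/1 array, dimensions ordered `(x, y, z)`.
#' @param spacing voxel spacing in mm, length 3.
#' @param origin world position (mm) of the centre of voxel `(1,1,1)`.
#' @return list of class `voxel_grid`.
#' @export
voxel_grid <- function(occupancy, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(occupancy)) == 3, length(spacing) == 3, all(spacing > 0),
            length(origin) == 3)
  structure(list(occupancy = occupancy, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

# Bilinear sample of matrix V at fractional 1-based (r, c); outside -> fill.
bilinear_sample <- function(V, r, c, fill) {
  nr <- nrow(V); nc <- ncol(V)
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (any(ok)) {
    r0 <- pmin(floor(r[ok]), nr - 1); c0 <- pmin(floor(c[ok]), nc - 1)
    fr <- r[ok] - r0; fc <- c[ok] - c0
    v00 <- V[cbind(r0, c0)]; v10 <- V[cbind(r0 + 1, c0)]
    v01 <- V[cbind(r0, c0 + 1)]; v11 <- V[cbind(r0 + 1, c0 + 1)]
    out[ok] <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
      v01 * (1 - fr) * fc + v11 * fr * fc
  }
  out
}

# SDF of a mask, or a large positive constant when the mask is empty.
mask_sdf_or_far <- function(mask) {
  if (any(mask > 0) && !all(mask > 0)) make_sdf(mask)
  else if (all(mask > 0)) -make_sdf(1L - mask)
  else matrix(1e6, nrow(mask), ncol(mask))
}

#' Reconstruct a voxel grid from per-frame masks
#'
#' Frames are ordered along the sweep direction (the line of image-centre
#' positions); each voxel layer between two consecutive frames gets the
#' linear blend of their mask signed distance functions, sampled at the
#' voxel's in-plane position in each frame, and is occupied where the
#' blend is negative. Non-monotone frame positions trigger a warning and
#' a nearest-frame ordering fallback.
#'
#' @param masks list of 0/1 masks, one per frame.
#' @param sweep the [tracked_sweep()] the masks live on.
#' @param voxel_mm isotropic voxel size in mm (default 0.5).
#' @return a [voxel_grid()] covering the swept frames.
#' @export
reconstruct_volume <- function(masks, sweep, voxel_mm = 0.5) {
  n <- length(sweep$frames)
  if (length(masks) != n) stop("need one mask per frame (", n, "), got ", length(masks))
  stopifnot(voxel_mm > 0)
  centres <- t(vapply(sweep$frames, frame_centre_world, numeric(3)))
  dirv <- centres[n, ] - centres[1, ]
  if (sqrt(sum(dirv^2)) < 1e-9) stop("sweep has no net motion; cannot define a sweep direction")
  dirv <- dirv / sqrt(sum(dirv^2))
  s <- as.numeric(centres %*% dirv)
  if (any(diff(s) <= 0)) {
    warning("frame positions non-monotone along the sweep; reordering by position")
    ord <- order(s)
    sweep <- tracked_sweep(sweep$frames[ord], sweep$id)
    masks <- masks[ord]
    centres <- centres[ord, , drop = FALSE]
    s <- s[ord]
  }
  h <- nrow(sweep$frames[[1]]$image); w <- ncol(sweep$frames[[1]]$image)
  corners_px <- rbind(c(0, 0), c(0, w - 1), c(h - 1, 0), c(h - 1, w - 1))
  pts <- do.call(rbind, lapply(sweep$frames, function(fr)
    t(apply(corners_px, 1, function(rc) pixel_to_world(fr, rc[1], rc[2])))))
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  dims <- pmax(ceiling((hi - lo) / voxel_mm), 1L)
  # cell-centred sampling: voxel i covers [lo + (i-1) v, lo + i v]
  origin <- lo + voxel_mm / 2
  sdfs <- lapply(masks, mask_sdf_or_far)
  occ <- array(0L, dims)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * voxel_mm
  ys <- origin[2] + (seq_len(dims[2]) - 1) * voxel_mm
  gx <- rep(xs, times = dims[2]); gy <- rep(ys, each = dims[1])
  sample_frame_sdf <- function(fi, zw) {
    fr <- sweep$frames[[fi]]
    Ti <- solve(fr$tracking)
    P <- rbind(gx, gy, zw, 1)
    Q <- Ti %*% P
    rr <- Q[2, ] / fr$pixel_spacing[1] + (h - 1) / 2 + 1
    cc <- Q[1, ] / fr$pixel_spacing[2] + (w - 1) / 2 + 1
    # SDFs are in pixel units; only the sign of the blend is consumed
    bilinear_sample(sdfs[[fi]], rr, cc, fill = 1e6)
  }
  for (k in seq_len(dims[3])) {
    zw <- origin[3] + (k - 1) * voxel_mm
    # layer position along the sweep, taken at the layer's in-plane centre
    sz <- sum(dirv * c(mean(xs), mean(ys), zw))
    if (sz < s[1] - 1e-9 || sz > s[n] + 1e-9) next
    b <- findInterval(sz, s, rightmost.closed = TRUE)
    b <- min(max(b, 1L), n - 1L)
    tblend <- if (s[b + 1] > s[b]) (sz - s[b]) / (s[b + 1] - s[b]) else 0
    tblend <- min(max(tblend, 0), 1)
    v <- (1 - tblend) * sample_frame_sdf(b, zw) + tblend * sample_frame_sdf(b + 1, zw)
    # voxels exactly on the blended zero level set (ties, e.g. the
    # one-pixel growth ring between aligned rasterized sections) are
    # split evenly by a deterministic checkerboard to avoid biasing the
    # interpolated shape toward either bracketing section
    tie <- abs(v) < 1e-9
    chk <- outer(seq_len(dims[1]), seq_len(dims[2]), "+") %% 2L == 0L
    occ[, , k] <- as.integer(v < 0 | (tie & chk))
  }
  voxel_grid(occ, rep(voxel_mm, 3), origin)
}

#' Volume of a voxel grid
#'
#' @param grid a [voxel_grid()].
#' @return occupied-voxel count times voxel volume, in cm^3.
#' @export
compute_volume <- function(grid) {
  sum(grid$occupancy > 0) * prod(grid$spacing) / 1000
}

#' Evaluate a sweep segmentation against ground truth
#'
#' @param masks,gt_masks lists of per-frame 0/1 masks.
#' @param sweep the [tracked_sweep()].
#' @param voxel_mm reconstruction voxel size (mm).
#' @return list of class `metric_report`: `dice` (mean per-slice),
#'   `dice_3d`, `hausdorff_mm` (3D symmetric, with the directed pair as an
#'   attribute), `hausdorff_2d_mean_mm` (mean per-slice, slices where both
#'   masks are non-empty), `volume_cm3`, `volume_gt_cm3`, and `per_slice`
#'   (data.frame with per-slice Dice).
#' @export
evaluate_sweep <- function(masks, gt_masks, sweep, voxel_mm = 0.5) {
  n <- length(sweep$frames)
  if (length(masks) != n || length(gt_masks) != n)
    stop("mask count mismatch: sweep has ", n, " frames, got ", length(masks),
         " predictions and ", length(gt_masks), " ground-truth masks")
  sp <- sweep$frames[[1]]$pixel_spacing
  d_slice <- vapply(seq_len(n), function(k) dice(masks[[k]], gt_masks[[k]]), numeric(1))
  h_slice <- vapply(seq_len(n), function(k) {
    if (any(masks[[k]] > 0) && any(gt_masks[[k]] > 0))
      as.numeric(hausdorff(masks[[k]], gt_masks[[k]], sp)) else NA_real_
  }, numeric(1))
  g_pred <- reconstruct_volume(masks, sweep, voxel_mm)
  g_gt <- reconstruct_volume(gt_masks, sweep, voxel_mm)
  h3 <- if (any(g_pred$occupancy > 0) && any(g_gt$occupancy > 0))
    hausdorff(g_pred, g_gt) else structure(NA_real_, directed = c(xy = NA, yx = NA))
  structure(list(dice = mean(d_slice),
                 dice_3d = dice(g_pred, g_gt),
                 hausdorff_mm = h3,
                 hausdorff_2d_mean_mm = mean(h_slice, na.rm = TRUE),
                 volume_cm3 = compute_volume(g_pred),
                 volume_gt_cm3 = compute_volume(g_gt),
                 per_slice = data.frame(frame = seq_len(n) - 1L, dice = d_slice,
                                        hausdorff_mm = h_slice)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: mean slice Dice %.4f | 3D Dice %.4f | Hausdorff %.2f mm | volume %.3f cm^3 (gt %.3f)\n",
              x$dice, x$dice_3d, as.numeric(x$hausdorff_mm), x$volume_cm3, x$volume_gt_cm3))
  invisible(x)
}

#' Write / read a MetaImage volume
#'
#' Minimal MetaImage (.mhd + .raw) support for interchange: unsigned 8-bit
#' element type, x-fastest element order matching the `(x, y, z)` array
#' layout of [voxel_grid()].
#'
#' @param grid a [voxel_grid()] (or 3D 0/1 array for `write_mhd` with
#'   `spacing`).
#' @param path path of the `.mhd` header; the `.raw` sits alongside.
#' @param spacing,origin used when `grid` is a bare array.
#' @return `read_mhd` returns a [voxel_grid()].
#' @export
write_mhd <- function(grid, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!inherits(grid, "voxel_grid")) grid <- voxel_grid(grid, spacing, origin)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  dm <- dim(grid$occupancy)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dm, collapse = " ")),
           paste("ElementSpacing =", paste(format(grid$spacing, digits = 12), collapse = " ")),
           paste("Offset =", paste(format(grid$origin, digits = 12), collapse = " ")),
           "ElementType = MET_UCHAR",
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  v <- grid$occupancy
  bytes <- if (all(v %in% c(0, 1))) as.integer(v) * 255L
           else as.integer(round(pmin(pmax(v, 0), 255)))
  writeBin(as.raw(bytes), file.path(dirname(path), raw_name))
  invisible(path)
}

#' @rdname write_mhd
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  val <- function(k) kv[[match(k, keys)]][2]
  dm <- as.integer(strsplit(val("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(val("ElementSpacing"), "\\s+")[[1]])
  org <- if ("Offset" %in% keys) as.numeric(strsplit(val("Offset"), "\\s+")[[1]]) else c(0, 0, 0)
  stopifnot(val("ElementType") == "MET_UCHAR")
  raw_path <- file.path(dirname(path), val("ElementDataFile"))
  v <- readBin(raw_path, "raw", n = prod(dm))
  vals <- array(as.integer(v), dm)
  occ <- array(as.integer(vals >= 128), dm)
  out <- voxel_grid(occ, sp, org)
  attr(out, "values") <- vals # raw 8-bit intensities, for non-mask volumes
  out
}
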