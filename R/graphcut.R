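#' @title GrabCut-style iterative graph-cut segmentation
#'
#' @description
#' Semi-automatic segmentation seeded by user scribbles: foreground strokes
#' mark definite thyroid, a closed background ring marks the surrounding
#' tissue. Pixels outside the ring are definite background, pixels inside
#' (minus the strokes) are unknown. Greyscale Gaussian mixture models
#' (initialized by Orchard-Bouman binary-split clustering) describe the two
#' classes; each iteration re-assigns pixels to mixture components, refits
#' the GMMs, builds a graph whose N-links carry the contrast penalty
#' `gamma/dist(m,n) * exp(-beta (z_m - z_n)^2)` (8-neighbourhood,
#' `gamma = 50`, `beta = 1/(2 <(z_m - z_n)^2>)`) and whose T-links carry
#' `-log` likelihoods under the opposite class's GMM, then relabels the
#' unknown pixels by a minimum s-t cut. Iterations stop when the labelling
#' is unchanged or after `n_iters` rounds. Scribble seeds never change side.
#'
#' @name graphcut
NULL

TRIMAP_BG <- 0L
TRIMAP_UNKNOWN <- 1L
TRIMAP_FG <- 2L

#' Scribble annotation for one frame
#'
#' @param fg_strokes list of n-by-2 matrices of 0-based `(row, col)` points
#'   (polylines), definite foreground.
#' @param bg_ring n-by-2 matrix, a closed polyline enclosing the foreground
#'   (auto-closed if the last point differs from the first).
#' @param frame_index 0-based index of the annotated frame.
#' @return list of class `scribbles`.
#' @export
scribbles <- function(fg_strokes, bg_ring, frame_index = 0L) {
  fg_strokes <- lapply(fg_strokes, function(s) {
    s <- as.matrix(s); stopifnot(ncol(s) == 2); s
  })
  bg_ring <- as.matrix(bg_ring)
  stopifnot(ncol(bg_ring) == 2, nrow(bg_ring) >= 3)
  structure(list(fg_strokes = fg_strokes, bg_ring = bg_ring,
                 frame_index = as.integer(frame_index)),
            class = "scribbles")
}

#' Graph-cut parameters
#'
#' @param gamma contrast-term weight (default 50).
#' @param beta contrast decay; `NULL` (default) computes it from the image
#'   with [beta_from_image()].
#' @param k number of GMM components per class (reduced for small classes).
#' @return list of class `graph_params`.
#' @export
graph_params <- function(gamma = 50, beta = NULL, k = 5L) {
  stopifnot(gamma > 0, is.null(beta) || beta >= 0, k >= 1)
  structure(list(gamma = gamma, beta = beta, k = as.integer(k), neighbourhood = 8L),
            class = "graph_params")
}

# Rasterize a polyline (0-based points) into 1-based pixel indices of an
# h x w grid, densely enough that the path is 8-connected.
rasterize_path <- function(pts, h, w) {
  out <- NULL
  n <- nrow(pts)
  if (n == 1) segs <- list(c(1, 1)) else segs <- lapply(seq_len(n - 1), function(i) c(i, i + 1))
  for (s in segs) {
    a <- pts[s[1], ]; b <- pts[s[2], ]
    steps <- max(2, ceiling(max(abs(b - a))) * 2 + 1)
    t <- seq(0, 1, length.out = steps)
    out <- rbind(out, cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
  }
  rc <- round(out)
  if (any(rc[, 1] < 0 | rc[, 1] > h - 1 | rc[, 2] < 0 | rc[, 2] > w - 1))
    stop("scribble path leaves the ", h, "x", w, " frame")
  unique((rc[, 2]) * h + rc[, 1] + 1) # column-major 1-based index
}

#' Build a trimap from scribbles
#'
#' Pixels 4-connected to the frame border without crossing the ring are
#' definite background; foreground-stroke pixels are definite foreground;
#' everything else (ring pixels included) is unknown.
#'
#' @param scr a [scribbles()] object.
#' @param frame_shape `(height, width)`.
#' @return integer matrix with values 0 (BG), 1 (UNKNOWN), 2 (FG).
#' @export
trimap_from_scribbles <- function(scr, frame_shape) {
  h <- frame_shape[1]; w <- frame_shape[2]
  ring <- scr$bg_ring
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring_idx <- rasterize_path(ring, h, w)
  ring_mask <- matrix(FALSE, h, w); ring_mask[ring_idx] <- TRUE
  # flood the complement from the border (4-connected)
  outside <- flood_from_border(!ring_mask)
  tri <- matrix(TRIMAP_UNKNOWN, h, w)
  tri[outside] <- TRIMAP_BG
  interior <- !outside & !ring_mask
  if (!any(interior)) stop("background ring does not enclose any region")
  for (st in scr$fg_strokes) {
    si <- rasterize_path(st, h, w)
    if (any(outside[si])) stop("foreground stroke lies outside the background ring")
    tri[si] <- TRIMAP_FG
  }
  tri
}

# 4-connected flood fill of TRUE pixels reachable from the border.
flood_from_border <- function(open) {
  nr <- nrow(open); nc <- ncol(open)
  reach <- matrix(FALSE, nr, nc)
  border <- unique(c(which(open[1, ]) * nr - nr + 1, which(open[nr, ]) * nr,
                     which(open[, 1]), (which(open[, nc]) + (nc - 1) * nr)))
  frontier <- border[open[border]]
  reach[frontier] <- TRUE
  while (length(frontier)) {
    fr <- ((frontier - 1L) %% nr) + 1L
    fc <- ((frontier - 1L) %/% nr) + 1L
    nb <- c((fc - 1L) * nr + pmax(fr - 1L, 1L), (fc - 1L) * nr + pmin(fr + 1L, nr),
            (pmax(fc - 1L, 1L) - 1L) * nr + fr, (pmin(fc + 1L, nc) - 1L) * nr + fr)
    nb <- unique(nb)
    nb <- nb[open[nb] & !reach[nb]]
    reach[nb] <- TRUE
    frontier <- nb
  }
  reach
}

#' Contrast decay from image statistics
#'
#' `beta = 1 / (2 <(z_m - z_n)^2>)`, the average running over all
#' 8-neighbour pixel pairs (each unordered pair once); 0 when the image is
#' constant.
#'
#' @param img numeric matrix with at least 2 pixels.
#' @return non-negative scalar.
#' @export
beta_from_image <- function(img) {
  if (length(img) < 2) stop("image must have at least 2 pixels")
  d2 <- neighbour_diffs_sq(img)
  m <- mean(d2)
  if (m == 0) 0 else 1 / (2 * m)
}

# Squared intensity differences over all 8-neighbour pairs.
neighbour_diffs_sq <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- numeric(0)
  if (nr > 1) out <- c(out, as.vector((img[-1, , drop = FALSE] - img[-nr, , drop = FALSE])^2))
  if (nc > 1) out <- c(out, as.vector((img[, -1, drop = FALSE] - img[, -nc, drop = FALSE])^2))
  if (nr > 1 && nc > 1) {
    out <- c(out, as.vector((img[-1, -1, drop = FALSE] - img[-nr, -nc, drop = FALSE])^2))
    out <- c(out, as.vector((img[-nr, -1, drop = FALSE] - img[-1, -nc, drop = FALSE])^2))
  }
  out
}

#' N-link weight between two neighbouring pixels
#'
#' @param z_m,z_n pixel intensities.
#' @param dist pixel distance, 1 or `sqrt(2)`.
#' @param params a [graph_params()] with `beta` set.
#' @return `(gamma/dist) * exp(-beta (z_m - z_n)^2)`.
#' @export
nlink_weight <- function(z_m, z_n, dist, params) {
  (params$gamma / dist) * exp(-params$beta * (z_m - z_n)^2)
}

# Orchard-Bouman binary-split clustering of scalar samples into <= k groups.
orchard_bouman <- function(x, k) {
  clusters <- list(x)
  popvar <- function(v) if (length(v) > 1) mean((v - mean(v))^2) else 0
  while (length(clusters) < k) {
    vars <- vapply(clusters, popvar, numeric(1))
    i <- which.max(vars)
    if (vars[i] <= 0) break
    cl <- clusters[[i]]; m <- mean(cl)
    a <- cl[cl <= m]; b <- cl[cl > m]
    if (!length(a) || !length(b)) break
    clusters[[i]] <- a
    clusters[[length(clusters) + 1L]] <- b
  }
  clusters
}

make_gmm <- function(clusters, n_total) {
  w <- vapply(clusters, length, integer(1)) / n_total
  mu <- vapply(clusters, mean, numeric(1))
  v <- pmax(vapply(clusters, function(cl) mean((cl - mean(cl))^2), numeric(1)), 1e-3)
  structure(list(weights = w, means = mu, vars = v), class = "gmm")
}

#' Fit foreground/background GMMs from a trimap
#'
#' Unknown and definite-foreground pixels seed the foreground class,
#' definite-background pixels the background class; each class is split
#' into at most `k` components by Orchard-Bouman clustering and a Gaussian
#' is fit per component with mixture weight equal to component occupancy.
#'
#' @param img numeric matrix.
#' @param trimap integer matrix from [trimap_from_scribbles()].
#' @param k components per class.
#' @return list with elements `fg` and `bg`, each of class `gmm`
#'   (`weights`, `means`, `vars`; variances floored at `1e-3`).
#' @export
fit_gmms <- function(img, trimap, k = 5L) {
  fg <- img[trimap != TRIMAP_BG]
  bg <- img[trimap == TRIMAP_BG]
  if (!length(fg) || !length(bg)) stop("both classes must be non-empty")
  list(fg = make_gmm(orchard_bouman(fg, min(k, length(fg))), length(fg)),
       bg = make_gmm(orchard_bouman(bg, min(k, length(bg))), length(bg)))
}

# Mixture density of scalar intensities under a gmm.
gmm_density <- function(gmm, z) {
  out <- 0
  for (j in seq_along(gmm$weights))
    out <- out + gmm$weights[j] * stats::dnorm(z, gmm$means[j], sqrt(gmm$vars[j]))
  out
}

# One component-assignment + refit round (ties to the lower component index).
refit_gmm <- function(gmm, z) {
  ll <- vapply(seq_along(gmm$weights), function(j)
    gmm$weights[j] * stats::dnorm(z, gmm$means[j], sqrt(gmm$vars[j])), numeric(length(z)))
  assign <- max.col(matrix(ll, ncol = length(gmm$weights)), ties.method = "first")
  clusters <- split(z, assign)
  make_gmm(clusters, length(z))
}

# 8-neighbour edge list (1-based column-major pixel ids) with distances.
nlink_edges <- function(nr, nc) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  e <- list(); d <- list()
  if (nr > 1) { e[[length(e) + 1]] <- cbind(as.vector(idx[-nr, ]), as.vector(idx[-1, ])); d[[length(d) + 1]] <- 1 }
  if (nc > 1) { e[[length(e) + 1]] <- cbind(as.vector(idx[, -nc]), as.vector(idx[, -1])); d[[length(d) + 1]] <- 1 }
  if (nr > 1 && nc > 1) {
    e[[length(e) + 1]] <- cbind(as.vector(idx[-nr, -nc]), as.vector(idx[-1, -1])); d[[length(d) + 1]] <- sqrt(2)
    e[[length(e) + 1]] <- cbind(as.vector(idx[-1, -nc]), as.vector(idx[-nr, -1])); d[[length(d) + 1]] <- sqrt(2)
  }
  list(pairs = do.call(rbind, e),
       dist = rep(unlist(d), vapply(e, nrow, integer(1))))
}

neg_log <- function(p) -log(pmax(p, 1e-300))

#' GrabCut segmentation of one frame
#'
#' See [graphcut] for the model. The returned mask carries an `energy`
#' attribute: the Gibbs energy (unknown-pixel data terms plus cut N-links)
#' after each iteration, which is non-increasing.
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param trimap integer matrix from [trimap_from_scribbles()].
#' @param params a [graph_params()].
#' @param n_iters maximum GrabCut iterations, >= 1.
#' @return 0/1 integer mask (trimap FG forced 1, BG forced 0).
#' @export
grabcut_segment <- function(img, trimap, params = graph_params(), n_iters = 5L) {
  if (n_iters < 1) stop("n_iters must be >= 1")
  assert_grey_image(img)
  stopifnot(identical(dim(trimap), dim(img)))
  nr <- nrow(img); nc <- ncol(img); N <- nr * nc
  beta <- if (is.null(params$beta)) beta_from_image(img) else params$beta
  pr <- graph_params(params$gamma, beta, params$k)

  nl <- nlink_edges(nr, nc)
  z <- as.vector(img)
  w_n <- nlink_weight(z[nl$pairs[, 1]], z[nl$pairs[, 2]], nl$dist, pr)
  K <- 1 + 8 * pr$gamma

  unknown <- which(trimap == TRIMAP_UNKNOWN)
  labels <- as.vector(trimap != TRIMAP_BG) # TRUE = foreground
  gmms <- fit_gmms(img, trimap, pr$k)
  energies <- numeric(0)

  source_id <- N + 1L; sink_id <- N + 2L
  tl_pairs <- rbind(cbind(source_id, seq_len(N)), cbind(seq_len(N), sink_id))
  all_pairs <- rbind(nl$pairs, tl_pairs)
  g <- igraph::make_graph(as.vector(t(all_pairs)), n = N + 2L, directed = FALSE)

  for (it in seq_len(n_iters)) {
    gmms <- list(fg = refit_gmm(gmms$fg, z[labels]), bg = refit_gmm(gmms$bg, z[!labels]))
    d_fg <- neg_log(gmm_density(gmms$fg, z)) # cost of labelling fg
    d_bg <- neg_log(gmm_density(gmms$bg, z))
    # -log likelihoods can be negative (densities above 1); shifting both
    # terminal links of a pixel by a common constant adds the same amount
    # to every cut, so the argmin is unchanged and capacities stay >= 0
    shift <- max(0, -min(d_fg, d_bg))
    w_src <- d_bg + shift; w_snk <- d_fg + shift # to fg terminal: -log bg likelihood
    w_src[trimap == TRIMAP_FG] <- K; w_snk[trimap == TRIMAP_FG] <- 0
    w_src[trimap == TRIMAP_BG] <- 0; w_snk[trimap == TRIMAP_BG] <- K
    # integer-quantized capacities: equivalent cuts at 1e-6 energy
    # granularity, and vastly faster for the push-relabel solver than
    # raw floating-point capacities of wide dynamic range
    mf <- igraph::max_flow(g, source = source_id, target = sink_id,
                           capacity = round(c(w_n, w_src, w_snk) * 1e6))
    new_labels <- rep(FALSE, N)
    part_fg <- setdiff(as.integer(mf$partition1), c(source_id, sink_id))
    if (!(source_id %in% as.integer(mf$partition1)))
      part_fg <- setdiff(as.integer(mf$partition2), c(source_id, sink_id))
    new_labels[part_fg] <- TRUE
    new_labels[trimap == TRIMAP_FG] <- TRUE
    new_labels[trimap == TRIMAP_BG] <- FALSE
    cut <- labels_energy(new_labels, unknown, d_fg, d_bg, nl$pairs, w_n)
    # monotone-descent safeguard: after a GMM refit the proposed labelling
    # can carry marginally higher energy; keep the previous labelling and
    # stop instead of accepting an uphill move
    if (length(energies) && cut > energies[length(energies)]) break
    energies <- c(energies, cut)
    converged <- identical(new_labels, labels) && it > 1
    labels <- new_labels
    if (converged || !length(unknown)) break
  }
  structure(matrix(as.integer(labels), nr, nc), energy = energies)
}

# Gibbs energy: data terms of unknown pixels + N-links cut by the labelling.
labels_energy <- function(labels, unknown, d_fg, d_bg, pairs, w_n) {
  data_term <- sum(ifelse(labels[unknown], d_fg[unknown], d_bg[unknown]))
  cut_links <- labels[pairs[, 1]] != labels[pairs[, 2]]
  data_term + sum(w_n[cut_links])
}

#' Interpolate scribbles onto an unannotated frame
#'
#' Every scribble point is carried through tracker space into the target
#' frame's pixel grid (the same world-fixed-anatomy rule as
#' [propagate_init()]) and clipped to the frame. When a second annotated
#' frame brackets the target, the stroke centroids of the two translated
#' sets are blended linearly in frame index and the nearer frame's stroke
#' shapes are used.
#'
#' @param scr_a [scribbles()] on an annotated frame.
#' @param sweep the [tracked_sweep()].
#' @param target_index 0-based target frame.
#' @param scr_b optional bracketing [scribbles()] on the other side.
#' @return [scribbles()] for the target frame.
#' @export
interpolate_scribbles <- function(scr_a, sweep, target_index, scr_b = NULL) {
  n <- length(sweep$frames)
  if (target_index < 0 || target_index > n - 1) stop("target frame outside the sweep")
  if (target_index == scr_a$frame_index) return(scr_a)
  if (!is.null(scr_b) && target_index == scr_b$frame_index) return(scr_b)
  trans <- function(scr) {
    src <- sweep$frames[[scr$frame_index + 1L]]
    dst <- sweep$frames[[target_index + 1L]]
    h <- nrow(dst$image); w <- ncol(dst$image)
    map_pts <- function(pts) {
      out <- t(apply(pts, 1, function(rc) {
        p <- pixel_to_world(src, min(max(rc[1], 0), nrow(src$image) - 1),
                            min(max(rc[2], 0), ncol(src$image) - 1))
        q <- world_to_pixel(dst, p)
        c(q$row, q$col)
      }))
      out[, 1] <- pmin(pmax(out[, 1], 0), h - 1)
      out[, 2] <- pmin(pmax(out[, 2], 0), w - 1)
      out
    }
    scribbles(lapply(scr$fg_strokes, map_pts), map_pts(scr$bg_ring), target_index)
  }
  out <- trans(scr_a)
  if (!is.null(scr_b)) {
    out_b <- trans(scr_b)
    t <- (target_index - scr_a$frame_index) / (scr_b$frame_index - scr_a$frame_index)
    cen <- function(s) colMeans(do.call(rbind, c(s$fg_strokes, list(s$bg_ring))))
    rms <- function(s) {
      p <- do.call(rbind, c(s$fg_strokes, list(s$bg_ring)))
      sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2)))
    }
    target_cen <- (1 - t) * cen(out) + t * cen(out_b)
    # blend the annotation size too: the cross-section area changes along
    # the sweep, and a ring frozen at the nearer frame's size stops
    # enclosing (or stops constraining) the target section
    target_r <- (1 - t) * rms(out) + t * rms(out_b)
    nearer <- if (abs(target_index - scr_a$frame_index) <= abs(target_index - scr_b$frame_index)) out else out_b
    sc <- if (rms(nearer) > 0) target_r / rms(nearer) else 1
    mv <- function(p) sweep(sweep(p, 2, cen(nearer)) * sc, 2, target_cen, "+")
    h <- nrow(sweep$frames[[target_index + 1L]]$image)
    w <- ncol(sweep$frames[[target_index + 1L]]$image)
    clip <- function(p) cbind(pmin(pmax(p[, 1], 0), h - 1), pmin(pmax(p[, 2], 0), w - 1))
    out <- scribbles(lapply(nearer$fg_strokes, function(p) clip(mv(p))),
                     clip(mv(nearer$bg_ring)), target_index)
  }
  rng <- apply(out$bg_ring, 2, range)
  if (prod(rng[2, ] - rng[1, ] + 1) < 9)
    stop("interpolated background ring degenerate (area < 9 px)")
  out
}

#' Segment a whole sweep with graph cut
#'
#' Frames carrying an annotation use it directly; other frames get
#' scribbles interpolated from the nearest annotated frame(s) (the
#' bracketing pair when one exists on each side, emulating user interaction
#' every few slices). Deterministic given inputs.
#'
#' @param sweep a [tracked_sweep()].
#' @param annotations list of [scribbles()] (distinct `frame_index`es).
#' @param params a [graph_params()].
#' @param n_iters GrabCut iterations per frame.
#' @return list of 0/1 masks, one per frame.
#' @export
segment_sweep_graphcut <- function(sweep, annotations, params = graph_params(),
                                   n_iters = 5L) {
  n <- length(sweep$frames)
  ann_idx <- vapply(annotations, function(a) a$frame_index, integer(1))
  if (anyDuplicated(ann_idx)) stop("duplicate annotated frame indices")
  masks <- vector("list", n)
  for (k in seq_len(n)) {
    tgt <- k - 1L
    if (tgt %in% ann_idx) {
      scr <- annotations[[match(tgt, ann_idx)]]
    } else {
      below <- ann_idx[ann_idx < tgt]; above <- ann_idx[ann_idx > tgt]
      a <- if (length(below)) annotations[[match(max(below), ann_idx)]]
           else annotations[[match(min(above), ann_idx)]]
      b <- if (length(below) && length(above)) annotations[[match(min(above), ann_idx)]]
           else NULL
      scr <- interpolate_scribbles(a, sweep, tgt, b)
    }
    img <- sweep$frames[[k]]$image
    tri <- trimap_from_scribbles(scr, dim(img))
    masks[[k]] <- grabcut_segment(img, tri, params, n_iters)
  }
  masks
}
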