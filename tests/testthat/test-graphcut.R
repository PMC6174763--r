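test_that("trimap construction matches a flood-fill partition", {
  # square ring at rows/cols 2..7 (0-based) in 10x10, fg pixel (5,5)
  ring <- rbind(c(2, 2), c(2, 7), c(7, 7), c(7, 2), c(2, 2))
  scr <- scribbles(list(rbind(c(5, 5))), ring, 0L)
  tri <- trimap_from_scribbles(scr, c(10, 10))
  expect_equal(sum(tri == 2), 1)                # FG = the stroke pixel
  expect_equal(sum(tri == 0), 100 - 36)         # BG = outside the ring
  expect_equal(sum(tri == 1), 36 - 1)           # UNKNOWN = rest (ring incl.)
  # oracle: background is exactly what a border flood fill reaches
  ring_mask <- matrix(FALSE, 10, 10)
  ring_mask[thyrosweep:::rasterize_path(ring, 10, 10)] <- TRUE
  reach <- thyrosweep:::flood_from_border(!ring_mask)
  expect_true(all((tri == 0) == reach))

  # ring on the frame border: no background pixels remain
  border_ring <- rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0), c(0, 0))
  tri2 <- trimap_from_scribbles(scribbles(list(rbind(c(5, 5))), border_ring, 0L), c(10, 10))
  expect_equal(sum(tri2 == 0), 0)
  expect_equal(sum(tri2 == 2), 1)

  # stroke outside the ring violates the invariant
  expect_error(trimap_from_scribbles(scribbles(list(rbind(c(0, 0))), ring, 0L), c(10, 10)),
               "outside")
})

test_that("beta follows the Boykov-Jolly expectation convention", {
  expect_equal(beta_from_image(matrix(7, 5, 5)), 0)
  # two-pixel image {0, 10}: mean squared difference 100
  expect_equal(beta_from_image(matrix(c(0, 10), 1, 2)), 1 / 200)
  # checkerboard {0,255}: enumerate neighbour pairs by hand
  cb <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2) * 255)
  d2 <- c((cb[-6, ] - cb[-1, ])^2, (cb[, -6] - cb[, -1])^2,
          (cb[-6, -6] - cb[-1, -1])^2, (cb[-1, -6] - cb[-6, -1])^2)
  expect_equal(beta_from_image(cb), 1 / (2 * mean(d2)))
})

test_that("N-link weights follow the contrast model", {
  pr <- graph_params(gamma = 50, beta = 0.01)
  expect_equal(nlink_weight(80, 80, 1, pr), 50)
  expect_equal(nlink_weight(80, 80, sqrt(2), pr), 50 / sqrt(2))
  expect_equal(nlink_weight(10, 30, 1, pr), 50 * exp(-0.01 * 400))
  pr0 <- graph_params(gamma = 50, beta = 0)
  expect_equal(nlink_weight(0, 255, 1, pr0), nlink_weight(100, 100, 1, pr0))
})

test_that("Orchard-Bouman GMM fitting recovers known mixtures", {
  # identical pixels, k = 1: single component at the variance floor
  g1 <- fit_gmms(matrix(c(rep(100, 20), rep(0, 5)), 5, 5),
                 matrix(c(rep(1L, 20), rep(0L, 5)), 5, 5), k = 1)
  expect_equal(g1$fg$means, 100)
  expect_equal(g1$fg$vars, 1e-3)
  expect_equal(sum(g1$fg$weights), 1)

  # two well-separated populations, k = 2
  set.seed(8)
  vals <- c(rnorm(100, 50, 5), rnorm(100, 200, 5))
  img <- matrix(c(vals, rep(0, 25)), 15, 15)
  tri <- matrix(c(rep(1L, 200), rep(0L, 25)), 15, 15)
  g <- fit_gmms(pmin(pmax(img, 0), 255), tri, k = 2)
  expect_equal(sort(g$fg$means), c(50, 200), tolerance = 2 / 50)
  expect_equal(sum(g$fg$weights), 1, tolerance = 1e-9)
  expect_true(all(g$fg$weights >= 0))
  # k larger than the class is reduced, not an error
  g_small <- fit_gmms(matrix(c(1, 2, 3, 200), 2, 2),
                      matrix(c(1L, 1L, 0L, 0L), 2, 2), k = 5)
  expect_lte(length(g_small$fg$weights), 2)
})

test_that("grabcut_segment honours seeds and needs nothing to infer without unknowns", {
  img <- matrix(c(rep(40, 8), rep(200, 8)), 4, 4)
  tri <- matrix(c(rep(2L, 8), rep(0L, 8)), 4, 4)
  out <- grabcut_segment(img, tri, n_iters = 5)
  expect_equal(matrix(as.integer(out), 4, 4), matrix(c(rep(1L, 8), rep(0L, 8)), 4, 4))
  expect_length(attr(out, "energy"), 1)
  expect_error(grabcut_segment(img, tri, n_iters = 0), "n_iters")
})

test_that("min-cut labelling attains the exhaustive-enumeration optimum", {
  set.seed(9)
  for (trial in 1:20) {
    nr <- sample(2:3, 1); nc <- sample(2:4, 1); N <- nr * nc
    img <- matrix(sample(0:255, N, TRUE), nr, nc)
    tri <- matrix(1L, nr, nc)
    tri[sample(N, 1)] <- 2L
    tri[sample(which(tri != 2), 1)] <- 0L
    m <- grabcut_segment(img, tri, n_iters = 1)
    # equality at the solver's 1e-6 capacity quantization granularity
    expect_equal(attr(m, "energy")[1], grabcut_energy_optimum(img, tri),
                 tolerance = 1e-4)
  }
})

test_that("grabcut separates a planted intensity boundary", {
  img <- disc_image(128, 30, lo = 60, hi = 170, speckle = 0.15, seed = 10)
  ring <- rbind(c(15, 15), c(15, 112), c(112, 112), c(112, 15), c(15, 15))
  stroke <- rbind(c(64, 50), c(64, 78))
  tri <- trimap_from_scribbles(scribbles(list(stroke), ring, 0L), c(128, 128))
  out <- grabcut_segment(img, tri)
  expect_gte(dice(out, mk_disc(128, 30)), 0.95)
  expect_true(all(diff(attr(out, "energy")) <= 1e-6))
  # seeds keep their side
  expect_true(all(out[tri == 2] == 1))
  expect_true(all(out[tri == 0] == 0))
})

test_that("scribble interpolation translates, blends and respects endpoints", {
  spec <- sweep_spec96()
  gen <- generate_sweep(spec)
  ann <- default_annotations(spec, gen, every_n = 10)
  sw <- gen$sweep

  # target equals an annotated frame: returned verbatim
  expect_identical(interpolate_scribbles(ann$scribbles[[1]], sw, ann$scribbles[[1]]$frame_index),
                   ann$scribbles[[1]])

  # identity in-plane tracking: scribbles carried unchanged
  out <- interpolate_scribbles(ann$scribbles[[1]], sw, 3)
  expect_equal(out$bg_ring, ann$scribbles[[1]]$bg_ring, tolerance = 1e-9)
  expect_equal(out$frame_index, 3L)

  # pure in-plane translation: rigid shift by the pixel-converted
  # displacement (fixed anatomy moves opposite to the probe)
  fr1 <- sw$frames[[1]]
  trk <- diag(4); trk[1, 4] <- 0.5 # +0.5 mm in x at 0.25 mm/px -> -2 px in col
  sw2 <- tracked_sweep(list(fr1, tracked_frame(fr1$image, trk, fr1$pixel_spacing)))
  out <- interpolate_scribbles(ann$scribbles[[1]], sw2, 1)
  expect_equal(out$bg_ring[, 2], ann$scribbles[[1]]$bg_ring[, 2] - 2, tolerance = 1e-9)
  expect_equal(out$bg_ring[, 1], ann$scribbles[[1]]$bg_ring[, 1], tolerance = 1e-9)

  # bracketing annotations: blended ring sits between the two in size
  mid <- interpolate_scribbles(ann$scribbles[[1]], sw, 5, ann$scribbles[[2]])
  area <- function(s) prod(apply(s$bg_ring, 2, function(v) diff(range(v))))
  expect_gt(area(mid), area(ann$scribbles[[1]]))
  expect_lt(area(mid), area(ann$scribbles[[2]]))
})

test_that("graph-cut sweep segmentation is deterministic and complete", {
  spec <- sweep_spec96()
  gen <- generate_sweep(spec)
  ann <- default_annotations(spec, gen, every_n = 10)
  masks <- segment_sweep_graphcut(gen$sweep, ann$scribbles)
  expect_length(masks, 20)
  masks2 <- segment_sweep_graphcut(gen$sweep, ann$scribbles)
  expect_identical(lapply(masks, as.integer), lapply(masks2, as.integer))
  # annotated frames equal the per-frame segmentation
  k <- ann$scribbles[[2]]$frame_index + 1
  tri <- trimap_from_scribbles(ann$scribbles[[2]], dim(gen$sweep$frames[[k]]$image))
  direct <- grabcut_segment(gen$sweep$frames[[k]]$image, tri)
  expect_identical(as.integer(masks[[k]]), as.integer(direct))
})
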