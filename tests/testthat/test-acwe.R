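test_that("make_sdf matches brute-force boundary distances", {
  # single-pixel foreground at (5,5) 0-based in 11x11
  m <- matrix(0L, 11, 11); m[6, 6] <- 1L
  phi <- make_sdf(m)
  expect_lt(phi[6, 6], 0)
  expect_lte(abs(phi[6, 7]), 1)
  expect_lte(abs(phi[7, 6]), 1)
  expect_lt(abs(phi[1, 1] - sqrt(50)), 1) # within 1 px of the centre distance

  # half-plane: |phi| equals the row distance to the split line
  hp <- matrix(0L, 10, 8); hp[1:4, ] <- 1L
  phi <- make_sdf(hp)
  for (r in 1:10) expect_equal(phi[r, 3], r - 4.5)

  # flipping the mask negates phi (boundary is shared)
  set.seed(7)
  m <- random_mask(12, 12)
  if (all(m > 0)) m[1, 1] <- 0L
  expect_equal(make_sdf(1L - m), -make_sdf(m))

  # |phi| agrees with brute-force distance to the midpoint boundary within
  # half a pixel everywhere, on random masks
  for (i in 1:3) {
    m <- random_mask(9, 9, 0.4)
    if (all(m > 0)) m[1, 1] <- 0L
    phi <- make_sdf(m)
    d_in <- sqrt(sedt_bf(m > 0)); d_out <- sqrt(sedt_bf(m == 0))
    expect_true(all(abs(abs(phi) - ifelse(m > 0, d_out, d_in)) <= 0.5 + 1e-9))
  }

  expect_error(make_sdf(matrix(1L, 4, 4)), "both")
  expect_error(make_sdf(matrix(0L, 4, 4)), "both")
})

test_that("signed distance fields satisfy the eikonal property", {
  d <- mk_disc(128, 20)
  phi <- make_sdf(d)
  gm <- grad_mag(phi)
  expect_gte(mean(gm >= 0.9 & gm <= 1.1), 0.99)
})

test_that("image_force implements the two-region Chan-Vese force", {
  phi <- make_sdf(mk_disc(32, 8))
  cst <- matrix(50, 32, 32)
  f <- image_force(cst, phi)
  expect_equal(f$mu_in, 50); expect_equal(f$mu_out, 50)
  expect_true(all(f$field == 0))

  # binary image matching the phi regions exactly
  img <- ifelse(phi < 0, 30, 200)
  f <- image_force(img, phi)
  expect_equal(f$mu_in, 30); expect_equal(f$mu_out, 200)
  expect_equal(f$field, (img - 30)^2 - (img - 200)^2)
  expect_true(all(f$field[phi < 0] < 0)) # inside pixels pulled inside

  # swapping the regions negates the field
  f2 <- image_force(img, -phi)
  expect_equal(f2$field, -f$field)

  expect_error(image_force(cst, phi + 1e6), "non-empty")
})

test_that("curvature_force recovers analytic level-set curvature", {
  # straight edge: zero curvature away from borders
  g <- expand.grid(row = 0:31, col = 0:31)
  hp <- matrix(g$row - 15.5, 32, 32)
  k <- curvature_force(hp)
  expect_lt(max(abs(k[3:30, 3:30])), 1e-6)

  # disc of radius 20: curvature 1/20 on the zero set within 10%
  phi <- analytic_disc_sdf(128, 20)
  k <- curvature_force(phi)
  zero <- abs(phi) <= 0.71
  expect_lt(max(abs(k[zero] - 0.05)) / 0.05, 0.10)

  # scale invariance: doubling phi leaves level-set curvature unchanged
  expect_equal(curvature_force(2 * phi)[zero], k[zero], tolerance = 1e-6)
})

test_that("evolve segments a two-level disc and respects the CFL bound", {
  img <- disc_image(128, 25)
  res <- evolve(img, rect_init(c(63, 63), 18, 18), acwe_config(iterations = 200))
  expect_gte(dice(res, mk_disc(128, 25)), 0.99)
  expect_lt(attr(res, "max_cfl"), 1)

  # constant image with alpha = 0: init is a fixed point
  init <- rect_to_mask(rect_init(c(20, 20), 6, 8), c(48, 48))
  out <- evolve(matrix(90, 48, 48), init, acwe_config(alpha = 0, iterations = 50))
  expect_equal(matrix(as.integer(out), 48, 48), init)

  # deterministic
  r1 <- evolve(img, rect_init(c(63, 63), 18, 18), acwe_config(iterations = 60))
  r2 <- evolve(img, rect_init(c(63, 63), 18, 18), acwe_config(iterations = 60))
  expect_identical(as.integer(r1), as.integer(r2))

  # converged region means on a noiseless two-level disc
  f <- image_force(img, make_sdf(matrix(as.integer(res), 128, 128)))
  expect_lt(abs(f$mu_in - 40), 1)
  expect_lt(abs(f$mu_out - 180), 1)

  expect_error(evolve(img, matrix(1L, 128, 128)), "both")
})

test_that("propagate_init carries the centroid through tracker space", {
  img <- matrix(100, 40, 40)
  mask <- mk_disc(40, 6, cy = 21, cx = 21) # centroid at (20, 20) 0-based
  rect <- rect_init(c(20, 20), 5, 5)
  id <- tracked_frame(img, diag(4), c(0.1, 0.1))

  # identical matrices: centre stays on the previous centroid
  out <- propagate_init(mask, id, id, rect)
  expect_equal(out$centre, c(20, 20))
  expect_equal(out$half_height, 5L); expect_equal(out$half_width, 5L)

  # in-plane translation (+0.5, 0, 0) mm at 0.1 mm/px: fixed anatomy moves
  # -5 px in columns in the next frame
  trk <- diag(4); trk[1, 4] <- 0.5
  nxt <- tracked_frame(img, trk, c(0.1, 0.1))
  out <- propagate_init(mask, id, nxt, rect)
  expect_equal(out$centre, c(20, 15))

  # pure out-of-plane displacement leaves the centre unchanged
  trkz <- diag(4); trkz[3, 4] <- 2
  out <- propagate_init(mask, id, tracked_frame(img, trkz, c(0.1, 0.1)), rect)
  expect_equal(out$centre, c(20, 20))

  # rectangle fully outside -> divergence error
  trk_far <- diag(4); trk_far[1, 4] <- 50
  expect_error(propagate_init(mask, id, tracked_frame(img, trk_far, c(0.1, 0.1)), rect),
               "divergence")
  expect_error(propagate_init(matrix(0L, 40, 40), id, id, rect), "empty")
})

test_that("ACWE tracks the lobe across a phantom sweep", {
  spec <- sweep_spec96()
  gen <- generate_sweep(spec)
  ann <- default_annotations(spec, gen)
  masks <- suppressWarnings(
    segment_sweep_acwe(gen$sweep, ann$rect, acwe_config(iterations = 400)))
  expect_length(masks, 20)
  expect_gte(mean(mapply(dice, masks, gen$gt_masks)), 0.90)
})

test_that("segment_sweep_acwe returns one mask per frame deterministically", {
  img <- disc_image(48, 10, speckle = 0.2)
  fr <- tracked_frame(img, diag(4), c(0.25, 0.25))
  trk <- diag(4); trk[3, 4] <- 1
  sw <- tracked_sweep(list(fr, tracked_frame(img, trk, c(0.25, 0.25))))
  cfg <- acwe_config(iterations = 120)
  m1 <- segment_sweep_acwe(sw, rect_init(c(23.5, 23.5), 8, 8), cfg)
  expect_length(m1, 2)
  expect_identical(as.integer(m1[[1]]), as.integer(m1[[2]]))
  m2 <- segment_sweep_acwe(sw, rect_init(c(23.5, 23.5), 8, 8), cfg)
  expect_identical(lapply(m1, as.integer), lapply(m2, as.integer))
})
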