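test_that("dice matches set enumeration", {
  m <- mk_disc(16, 4)
  expect_equal(dice(m, m), 1)
  a <- matrix(0L, 8, 8); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 8, 8); b[5:6, 5:6] <- 1L
  expect_equal(dice(a, b), 0)
  # |X|=4, |Y|=6, overlap 3
  x <- matrix(0L, 4, 4); x[1, 1:4] <- 1L
  y <- matrix(0L, 4, 4); y[1, 2:4] <- 1L; y[2, 1:3] <- 1L
  expect_equal(dice(x, y), 0.6)
  expect_equal(dice(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  expect_equal(dice(x, y), dice(y, x))
  expect_error(dice(x, matrix(0L, 5, 5)), "shape")
})

test_that("hausdorff matches hand computation and exposes the directed pair", {
  a <- matrix(0L, 12, 12); a[1, 1] <- 1L
  b <- matrix(0L, 12, 12); b[4, 5] <- 1L # offset (3, 4): distance 5
  expect_equal(as.numeric(hausdorff(a, b)), 5)
  expect_equal(as.numeric(hausdorff(a, a)), 0)

  # asymmetric case: directed distances differ, symmetric takes the max
  x <- matrix(0L, 12, 12); x[1, 1] <- 1L
  y <- matrix(0L, 12, 12); y[1, 1] <- 1L; y[1, 11] <- 1L
  h <- hausdorff(x, y)
  expect_equal(unname(attr(h, "directed")), c(0, 10))
  expect_equal(as.numeric(h), 10)

  # anisotropic spacing scales axes independently
  expect_equal(as.numeric(hausdorff(a, b, spacing = c(2, 0.5))), sqrt(36 + 4))
  expect_error(hausdorff(a, matrix(0L, 12, 12)), "non-empty")
})

test_that("dice and hausdorff agree with brute force on random pairs", {
  set.seed(17)
  for (i in 1:25) {
    nr <- sample(4:16, 1); nc <- sample(4:16, 1)
    X <- random_mask(nr, nc); Y <- random_mask(nr, nc)
    sp <- runif(2, 0.2, 2)
    expect_equal(dice(X, Y), dice_bf(X, Y), tolerance = 1e-12)
    expect_equal(as.numeric(hausdorff(X, Y, sp)), hausdorff_bf(X, Y, sp),
                 tolerance = 1e-12)
  }
})

test_that("hausdorff satisfies the metric axioms on point sets", {
  set.seed(18)
  for (i in 1:10) {
    A <- random_mask(6, 6, 0.2); B <- random_mask(6, 6, 0.2); C <- random_mask(6, 6, 0.2)
    hab <- as.numeric(hausdorff(A, B)); hba <- as.numeric(hausdorff(B, A))
    hac <- as.numeric(hausdorff(A, C)); hcb <- as.numeric(hausdorff(C, B))
    expect_equal(hab, hba, tolerance = 1e-12)             # symmetry
    expect_equal(as.numeric(hausdorff(A, A)), 0)          # identity
    expect_lte(hab, hac + hcb + 1e-9)                     # triangle inequality
  }
})

test_that("exact distance transforms agree with brute force in 2D and 3D", {
  set.seed(19)
  m2 <- random_mask(7, 9, 0.2) > 0
  sp2 <- c(0.7, 1.3)
  expect_equal(thyrosweep:::sedt(m2, sp2), sedt_bf(m2, sp2), tolerance = 1e-9)
  m3 <- array(runif(5 * 6 * 4) < 0.2, c(5, 6, 4))
  if (!any(m3)) m3[2, 2, 2] <- TRUE
  sp3 <- c(0.5, 1, 2)
  expect_equal(thyrosweep:::sedt(m3, sp3), sedt_bf(m3, sp3), tolerance = 1e-9)
})

test_that("compute_volume converts voxel counts to cm^3", {
  occ <- array(0L, c(10, 10, 10)); occ[1:10, 1:10, 1:10] <- 1L
  expect_equal(compute_volume(voxel_grid(occ, c(1, 1, 1))), 1)
  expect_equal(compute_volume(voxel_grid(array(0L, c(4, 4, 4)), c(1, 1, 1))), 0)
  # linear in count, invariant under grid translation
  g1 <- voxel_grid(occ, c(0.5, 0.5, 0.5), origin = c(0, 0, 0))
  g2 <- voxel_grid(occ, c(0.5, 0.5, 0.5), origin = c(10, -3, 7))
  expect_equal(compute_volume(g1), compute_volume(g2))
  expect_equal(compute_volume(g1), 1000 * 0.125 / 1000)
})

test_that("digitized ellipsoid volume approaches the analytic value", {
  spec <- phantom_spec(semi_axes_mm = c(10, 7.5, 5), lobe_centre_mm = c(0, 0, 8.8),
                       frame_size = c(288L, 288L), speckle_scale = 0)
  lv <- generate_labelled_volume(spec, voxel_mm = 0.25)
  vol <- sum(lv$labels) * 0.25^3 / 1000
  expect_equal(vol, 4 / 3 * pi * 10 * 7.5 * 5 / 1000, tolerance = 0.02)
})

test_that("reconstruction interpolates slices and handles degenerate stacks", {
  # two identical circular masks 1 mm apart: intermediate layers equal the circle
  mask <- mk_disc(48, 10)
  img <- matrix(100, 48, 48)
  trk <- diag(4); trk[3, 4] <- 1
  sw <- tracked_sweep(list(tracked_frame(img, diag(4), c(0.5, 0.5)),
                           tracked_frame(img, trk, c(0.5, 0.5))))
  g <- reconstruct_volume(list(mask, mask), sw, 0.5)
  areas <- apply(g$occupancy, 3, sum)
  expect_true(all(areas == areas[1]))
  expect_equal(areas[1] * 0.25, sum(mask) * 0.25, tolerance = 0.05)

  # empty masks give an empty grid
  g0 <- reconstruct_volume(list(matrix(0L, 48, 48), matrix(0L, 48, 48)), sw, 0.5)
  expect_equal(sum(g0$occupancy), 0)

  # shrinking circle: intermediate radius between the two (SDF blend)
  small <- mk_disc(48, 5)
  g2 <- reconstruct_volume(list(mask, small), sw, 0.25)
  mid_areas <- apply(g2$occupancy, 3, sum) * 0.0625 # mm^2
  a_big <- sum(mask) * 0.25; a_small <- sum(small) * 0.25
  interior <- mid_areas[mid_areas > 0]
  expect_true(all(interior <= a_big * 1.05 & interior >= a_small * 0.95))
  expect_true(any(interior < a_big * 0.95 & interior > a_small * 1.05))
})

test_that("evaluate_sweep reports consistent metrics", {
  spec <- sweep_spec96()
  gen <- generate_sweep(spec)
  rep <- evaluate_sweep(gen$gt_masks, gen$gt_masks, gen$sweep, 0.5)
  expect_equal(rep$dice, 1)
  expect_equal(rep$dice_3d, 1)
  expect_equal(as.numeric(rep$hausdorff_mm), 0)
  expect_equal(rep$volume_cm3, rep$volume_gt_cm3)

  # mean Dice equals the hand-average of per-slice Dice
  masks <- lapply(gen$gt_masks, function(m) {
    m2 <- m; m2[1:5, ] <- 0L; m2
  })
  rep2 <- evaluate_sweep(masks, gen$gt_masks, gen$sweep, 0.5)
  expect_equal(rep2$dice,
               mean(mapply(dice, masks, gen$gt_masks)))
  expect_true(rep2$dice <= 1 && rep2$dice_3d <= 1 && as.numeric(rep2$hausdorff_mm) >= 0)
  expect_error(evaluate_sweep(masks[1:3], gen$gt_masks, gen$sweep, 0.5), "mismatch")
})

test_that("MetaImage volumes round-trip", {
  dir <- withr::local_tempdir()
  set.seed(20)
  occ <- array(as.integer(runif(6 * 5 * 4) < 0.4), c(6, 5, 4))
  g <- voxel_grid(occ, c(0.5, 0.5, 1), origin = c(-1, 2, 0.5))
  p <- file.path(dir, "vol.mhd")
  write_mhd(g, p)
  back <- read_mhd(p)
  expect_equal(back$occupancy, occ)
  expect_equal(back$spacing, g$spacing)
  expect_equal(back$origin, g$origin)
  # intensity volumes keep their 8-bit values
  iv <- array(sample(0:255, 24, TRUE), c(4, 3, 2))
  write_mhd(voxel_grid(iv, c(1, 1, 1)), file.path(dir, "int.mhd"))
  vals <- attr(read_mhd(file.path(dir, "int.mhd")), "values")
  expect_equal(as.vector(vals), as.vector(iv))
})
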