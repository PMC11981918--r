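test_that("mesh_from_label contours a labeled volume faithfully", {
  # solid cube: mesh volume within 5% of voxel-count volume
  labs <- array(0L, c(26, 26, 26))
  labs[4:23, 4:23, 4:23] <- 7L
  vol <- label_volume(labs, c(64, 64, 40))
  m <- mesh_from_label(vol, 7)
  expect_true(is_watertight(m))
  vx_vol <- 20^3 * prod(c(64, 64, 40))
  expect_equal(mesh_volume(m), vx_vol, tolerance = 0.05)

  # two components: only the larger one is retained
  labs2 <- array(0L, c(30, 12, 12))
  labs2[2:11, 2:11, 2:11] <- 3L      # 1000 voxels
  labs2[25:29, 5:6, 5:6] <- 3L       # 20 voxels, disconnected
  vol2 <- label_volume(labs2, c(64, 64, 40))
  m2 <- mesh_from_label(vol2, 3)
  expect_equal(mesh_volume(m2), 1000 * prod(c(64, 64, 40)), tolerance = 0.05)

  expect_error(mesh_from_label(vol, 99), "absent")
})

test_that("shrink wrap is a tight envelope, exact on convex input", {
  sp <- fx_sphere_phantom()
  # convex fixed point: two-sided Hausdorff well under 2 voxel diagonals
  d_out <- perisoma:::`.cpp_point_mesh_distance`(
    sp$mesh$vertices, sp$wrap$vertices, sp$wrap$faces)
  d_in <- perisoma:::`.cpp_point_mesh_distance`(
    sp$wrap$vertices, sp$mesh$vertices, sp$mesh$faces)
  expect_lt(max(d_out, d_in), 2 * sqrt(64^2 + 64^2 + 40^2))

  ph <- fx_fold_phantom()
  # envelope contract: wrap contains the mesh, and wrap volume >= mesh volume
  expect_gt(mesh_volume(ph$wrap), mesh_volume(ph$mesh))
  ctr <- mesh_centroid(ph$mesh)
  r_mesh <- sqrt(rowSums(sweep(ph$mesh$vertices, 2, ctr)^2))
  r_wrap <- sqrt(rowSums(sweep(ph$wrap$vertices, 2, ctr)^2))
  expect_true(all(r_wrap >= r_mesh - 1e-6))
  # wrap follows the input closely outside the folds
  outside <- ph$folds$vertex_depth_nm < 1
  expect_gt(mean(outside), 0.5)

  # idempotence: wrapping the wrap moves vertices by at most a few nm
  w2 <- shrink_wrap(ph$wrap)
  expect_lt(max(abs(w2$vertices - ph$wrap$vertices)), 5)

  expect_error(shrink_wrap(surface_mesh(matrix(0, 0, 3),
                                        matrix(0L, 0, 3))), "degenerate")
})

test_that("fold features recover planted infolding fractions", {
  sp <- fx_sphere_phantom()
  expect_equal(fold_features(sp$mesh, sp$wrap)$fold_fraction, 0)

  ph <- fx_fold_phantom()
  expect_lt(abs(ph$folds$fold_fraction - ph$true_fold_fraction), 0.02)
  expect_lte(ph$folds$fold_area_um2, mesh_area(ph$mesh) / 1e6)

  # pockets shallower than the 150-nm threshold measure zero
  shallow <- make_nucleus_phantom(5, 3, fold_depth_nm = 100,
                                  fold_area_fraction = 0.1, seed = 2)
  f <- fold_features(shallow$mesh, shrink_wrap(shallow$mesh))
  expect_equal(f$fold_fraction, 0)

  # a wrap from a different mesh is rejected
  expect_error(fold_features(sp$mesh, ph$wrap), "not produced")
})

test_that("fold fraction is invariant under rigid motion and grows with depth", {
  ph <- make_nucleus_phantom(5, 6, 900, 0.12, seed = 5)
  rot <- withr::with_seed(8, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
  moved <- surface_mesh(ph$mesh$vertices %*% rot + 12345, ph$mesh$faces)
  f1 <- fold_features(ph$mesh, shrink_wrap(ph$mesh))$fold_fraction
  f2 <- fold_features(moved, shrink_wrap(moved))$fold_fraction
  expect_equal(f1, f2, tolerance = 1e-6)

  # deeper pockets at fixed planted fraction: measured fraction does not drop
  fracs <- vapply(c(400, 900, 1800), function(depth) {
    p <- make_nucleus_phantom(5, 6, depth, 0.12, seed = 5)
    fold_features(p$mesh, shrink_wrap(p$mesh))$fold_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) > -0.01))
})

test_that("nucleus_features reports the six features in closed form", {
  sp <- fx_sphere_phantom()
  ref <- depth_reference(axis = "y", pia_nm = 0)
  nf <- nucleus_features(sp$mesh, ref, wrap = sp$wrap)
  expect_equal(nf$nucleus_volume, 4 / 3 * pi * 125, tolerance = 0.05)
  expect_equal(nf$nucleus_area, 4 * pi * 25, tolerance = 0.05)
  # area-to-volume of a sphere of radius r is 3/r (here r = 5 µm)
  expect_equal(nf$nucleus_area_to_volume, 3 / 5, tolerance = 0.05)
  expect_equal(nf$nucleus_fold_fraction, 0)
  # depth: centroid sits at y ~ 0, so shift the mesh to 200 µm
  shifted <- surface_mesh(sweep(sp$mesh$vertices, 2, c(0, 2e5, 0), "+"),
                          sp$mesh$faces)
  nf2 <- nucleus_features(shifted, ref)
  expect_equal(nf2$nucleus_depth, 200, tolerance = 0.01)

  expect_error(nucleus_features(surface_mesh(matrix(0, 3, 3),
                                             matrix(c(1L, 2L, 3L), 1)), ref),
               "degenerate")
})
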