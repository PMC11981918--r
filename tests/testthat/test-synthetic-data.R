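test_that("nucleus phantoms honor the requested fold geometry", {
  # convex case: a bare sphere with zero planted fraction
  ph0 <- make_nucleus_phantom(radius_um = 5, n_folds = 0, seed = 1)
  expect_true(is_watertight(ph0$mesh))
  expect_equal(ph0$true_fold_fraction, 0)
  expect_equal(mesh_volume(ph0$mesh) / 1e9, 4 / 3 * pi * 125, tolerance = 0.01)

  # planted fraction is tracked analytically within 0.02
  ph <- fx_fold_phantom()
  expect_true(is_watertight(ph$mesh))
  expect_lt(abs(ph$true_fold_fraction - 0.2), 0.02)

  # determinism: same spec and seed give identical meshes
  a <- make_nucleus_phantom(5, 3, 800, 0.1, seed = 42)
  b <- make_nucleus_phantom(5, 3, 800, 0.1, seed = 42)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$true_fold_fraction, b$true_fold_fraction)

  # folds shallower than the detection depth contribute no tracked area
  shallow <- make_nucleus_phantom(5, 3, fold_depth_nm = 100,
                                  fold_area_fraction = 0.1, seed = 2)
  expect_equal(shallow$true_fold_fraction, 0)
})

test_that("voxel cell phantoms control voids, synapses and volume", {
  cv <- fx_cell_volume()
  # bounding-box error fraction equals the request
  expect_equal(bbox_error_fraction(cv$cell, cv$center_nm, 12), 0.1,
               tolerance = 0.005)
  # synapse table rows target the soma label
  expect_equal(nrow(cv$synapses), 10)
  expect_true(all(cv$synapses$post_id == cv$soma_id))
  # synapses lie on the soma surface
  d <- sqrt(rowSums(sweep(as.matrix(cv$synapses[, c("x_nm", "y_nm", "z_nm")]),
                          2, cv$center_nm)^2))
  expect_equal(d, rep(8000, 10), tolerance = 1e-6)

  # no voids when none requested
  cv0 <- make_cell_volume(5, 8, 0, 0, c(256, 256, 160), seed = 1,
                          box_halfwidth_um = 10)
  expect_lt(bbox_error_fraction(cv0$cell, cv0$center_nm, 10), 0.01)

  # voxel-count volume of an 8-µm soma at the reference 64x64x40 nm grid
  cv64 <- make_cell_volume(5, 8, 0, 0, c(64, 64, 40), seed = 1,
                           box_halfwidth_um = 9)
  vx <- sum(cv64$cell$labels == cv64$soma_id) * prod(c(64, 64, 40)) / 1e9
  expect_equal(vx, 4 / 3 * pi * 8^3, tolerance = 0.05)

  expect_error(make_cell_volume(5, 8, 0, 0, box_halfwidth_um = 6),
               "too small")
})

test_that("PSS phantoms have the advertised geometry", {
  # empty mix gives an empty list
  expect_length(make_pss_phantoms(c(spine = 0)), 0)

  corpus <- fx_pss_corpus()
  expect_length(corpus$phantoms, 30)
  for (p in corpus$phantoms) {
    expect_true(is_watertight(p$mesh))
    # every mesh fits a 3,500-nm synapse-region cutout
    expect_lt(max(sqrt(rowSums(sweep(p$mesh$vertices, 2,
                                     p$synapse_point)^2))), 7001)
  }

  # spine necks are thin relative to heads: chord diameters probed with
  # direct horizontal ray casts, independent of the segmentation code
  chord_diameter <- function(mesh, z) {
    t1 <- perisoma:::`.cpp_ray_mesh_hits`(matrix(c(1500, 0, z), 1),
                                          matrix(c(-1, 0, 0), 1),
                                          mesh$vertices, mesh$faces)
    t2 <- perisoma:::`.cpp_ray_mesh_hits`(matrix(c(-1500, 0, z), 1),
                                          matrix(c(1, 0, 0), 1),
                                          mesh$vertices, mesh$faces)
    3000 - t1 - t2
  }
  sp <- corpus$phantoms[corpus$classes == "spine"][1:5]
  for (p in sp) {
    neck_z <- (p$nominal$shaft_r + p$nominal$neck_top) / 2
    neck_diam <- chord_diameter(p$mesh, neck_z)
    head_diam <- chord_diameter(p$mesh, p$head_center[3])
    expect_lt(neck_diam, head_diam / 3 + 1)
  }

  # shafts are uniform: coefficient of variation of probed thickness < 0.15
  sh <- corpus$phantoms[corpus$classes == "shaft"][[1]]$mesh
  th <- perisoma:::`.cpp_face_thickness`(
    sh$vertices, sh$faces, seq_len(nrow(sh$faces)), 30L, 60, 1L)
  th <- th[is.finite(th)]
  expect_lt(sd(th) / mean(th), 0.15)
})

test_that("cohorts plant class structure and connectivity motifs", {
  # empty cohort
  empty <- make_cohort(0, c(a = 1), list(a = list(mean = rep(0, 13),
                                                  cov = rep(1, 13))))
  expect_equal(nrow(empty$features), 0)
  expect_equal(nrow(empty$synapses), 0)

  coh <- fx_cohort()
  expect_equal(nrow(coh$features), 400)
  # planted chandelier bookkeeping: the realized AIS fraction is as asked
  ch <- coh$planted[coh$planted$motif == "chandelier", ]
  expect_equal(ch$planted_fraction, 0.8)
  lab_somata <- dplyr::mutate(coh$somata, label = coh$labels$label)
  prof <- targeting_profile(coh$synapses[coh$synapses$pre_id == ch$cell_id, ],
                            lab_somata)
  expect_equal(chandelier_score(prof)$ais_fraction, 0.8, tolerance = 1e-9)

  # two classes separated by 10 SD are near-perfectly classifiable
  m2 <- list(a = list(mean = setNames(rep(0, 13), perisomatic_feature_names()),
                      cov = rep(1, 13)),
             b = list(mean = setNames(c(10, rep(0, 12)),
                                      perisomatic_feature_names()),
                      cov = rep(1, 13)))
  coh2 <- make_cohort(200, c(a = 0.5, b = 0.5), m2, seed = 7)
  lvl <- train_level(coh2$features[, -1], coh2$labels$label,
                     candidate_families = "knn", n_draws = 2, cv_folds = 5,
                     seed = 1)
  expect_gte(lvl$best$accuracy, 0.99)

  # degenerate (non-PSD) covariance is rejected
  bad <- list(a = list(mean = setNames(rep(0, 13), perisomatic_feature_names()),
                       cov = diag(13) - 2))
  expect_error(make_cohort(10, c(a = 1), bad, seed = 1),
               "degenerate covariance")

  # determinism
  c1 <- make_cohort(50, c(a = 0.5, b = 0.5), m2, seed = 3)
  c2 <- make_cohort(50, c(a = 0.5, b = 0.5), m2, seed = 3)
  expect_identical(c1$features, c2$features)
})
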