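test_that("synapse region meshes are bounded, connected cutouts", {
  cyl <- fx_long_cylinder()
  # synapse mid-cylinder on the side: cutout spans at most 2 x 3,500 nm
  # (plus one face ring: selection is by faces with a vertex in range)
  region <- synapse_region_mesh(cyl, c(0, 0, 400))
  expect_lte(diff(range(region$vertices[, 1])), 7000 + 4 * 50)

  # radius larger than the phantom returns the whole component
  all_of_it <- synapse_region_mesh(cyl, c(0, 0, 400), radius_nm = 50000)
  expect_equal(nrow(all_of_it$faces), nrow(cyl$faces))

  # two nearby branches not surface-connected: only the synapse-bearing one
  two <- perisoma:::mesh_from_implicit(function(p) {
    a <- perisoma:::dist_point_segment(p, c(-2000, 0, 0), c(2000, 0, 0)) <= 300
    b <- perisoma:::dist_point_segment(p, c(-2000, 900, 0), c(2000, 900, 0)) <= 300
    a | b
  }, c(-2400, -700, -700), c(2400, 1600, 700), 50)
  region2 <- synapse_region_mesh(two, c(0, -300, 0))
  expect_lt(max(region2$vertices[, 2]), 400)  # second branch absent

  expect_error(synapse_region_mesh(cyl, c(0, 0, 50000)), "nm")
})

test_that("thickness segmentation separates necks from bulbs", {
  # uniform cylinder: a single segment
  cyl <- fx_long_cylinder()
  region <- synapse_region_mesh(cyl, c(0, 0, 400))
  seg <- segment_by_thickness(region, seed = 2)
  expect_equal(nrow(seg$segments), 1L)

  # dumbbell with neck a quarter of the bulbs: neck separated
  db <- fx_dumbbell()
  segdb <- segment_by_thickness(db, seed = 2)
  expect_gte(nrow(segdb$segments), 2L)
  cen <- perisoma:::face_centroids(db)
  neck_faces <- abs(cen[, 1]) < 300 &
    sqrt(cen[, 2]^2 + cen[, 3]^2) < 200
  bulb_faces <- abs(cen[, 1]) > 900
  neck_labels <- unique(segdb$labels[neck_faces])
  expect_false(any(neck_labels %in% segdb$labels[bulb_faces]))
  # and the probed thickness itself reflects the 4x geometry
  expect_lt(median(segdb$thickness[neck_faces]),
            median(segdb$thickness[bulb_faces]) / 2)
})

test_that("PSS extraction isolates heads, shaft stretches and soma patches", {
  corpus <- fx_pss_corpus()
  areas <- vapply(corpus$pss, mesh_area, numeric(1))
  cls <- corpus$classes

  # spine synapse: PSS contains the head, not the shaft beyond the branch
  for (i in which(cls == "spine")[1:5]) {
    p <- corpus$phantoms[[i]]
    pssm <- corpus$pss[[i]]
    expect_lt(max(abs(pssm$vertices[, 1])), 2.5 * p$nominal$head_r)
    expect_gte(max(pssm$vertices[, 3]), p$synapse_point[3] - 50)
    # contains vertices around the head center
    expect_true(any(abs(pssm$vertices[, 3] - p$head_center[3]) <
                      p$nominal$head_r))
  }
  # shaft synapse: the PSS is the shaft stretch itself (no branch split)
  for (i in which(cls == "shaft")[1:3]) {
    expect_gt(diff(range(corpus$pss[[i]]$vertices[, 1])), 2000)
  }
  # soma patches dwarf every spine PSS
  expect_gt(min(areas[cls == "soma_patch"]), max(areas[cls == "spine"]))
})

test_that("pose normalization is exact under rigid motion", {
  corpus <- fx_pss_corpus()
  m <- corpus$pss[[1]]
  cloud <- normalize_pose(m, 256, seed = 5)
  expect_equal(dim(cloud), c(256L, 3L))
  expect_equal(colMeans(cloud), c(0, 0, 0), tolerance = 1e-9)

  rot <- withr::with_seed(3, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
  moved <- surface_mesh(m$vertices %*% rot + 5000, m$faces)
  cloud2 <- normalize_pose(moved, 256, seed = 5)
  expect_equal(cloud2, cloud, tolerance = 1e-6)

  # resampling stability on a mirror-symmetric shape: axis scales agree
  sym <- fx_dumbbell()
  c1 <- normalize_pose(sym, 512, seed = 1)
  c2 <- normalize_pose(sym, 512, seed = 99)
  expect_equal(apply(c1, 2, sd), apply(c2, 2, sd), tolerance = 0.05)
})

test_that("encoders emit fixed-size, class-separable latents", {
  corpus <- fx_pss_corpus()
  enc <- shape_descriptor_encoder()
  lat <- encode_shapes(enc, corpus$clouds)
  expect_equal(ncol(lat), 1024L)
  # identical clouds give identical latents
  expect_identical(encode_shapes(enc, corpus$clouds[[1]]),
                   encode_shapes(enc, corpus$clouds[[1]]))

  probe_acc <- function(lat) {
    mean(vapply(1:5, function(f) {
      te <- seq(f, nrow(lat), by = 5)
      fit <- suppressWarnings(e1071::svm(x = lat[-te, , drop = FALSE],
                                         y = corpus$classes[-te],
                                         kernel = "linear"))
      mean(predict(fit, lat[te, , drop = FALSE]) == corpus$classes[te])
    }, numeric(1)))
  }
  expect_gte(probe_acc(lat), 0.9)

  ae <- train_autoencoder(corpus$clouds, latent_size = 1024, epochs = 40,
                          seed = 2)
  expect_equal(ncol(encode_shapes(ae, corpus$clouds[[1]])), 1024L)
  # training loss decreases from the first epoch to the last
  expect_lt(tail(ae$loss, 1), ae$loss[1])
  expect_true(all(diff(ae$loss) < 1e-8))
  expect_gte(probe_acc(encode_shapes(ae, corpus$clouds)), 0.9)
  # determinism under seed
  ae2 <- train_autoencoder(corpus$clouds, latent_size = 1024, epochs = 40,
                           seed = 2)
  expect_identical(ae$W, ae2$W)

  expect_error(train_autoencoder(corpus$clouds, latent_size = 0), "positive")
})

test_that("the shape dictionary is a deterministic k-means codebook", {
  dict <- fx_dictionary()
  expect_equal(nrow(dict$dictionary$centres), 30L)

  # k distinct points with k requested clusters: centres are the points
  pts <- matrix(seq_len(12), 4, 3) * 10
  d4 <- build_dictionary(pts, k = 4, seed = 1, nstart = 5)
  expect_equal(sort(d4$centres[, 1]), sort(pts[, 1]))
  # each point is assigned to its own centre
  expect_equal(sort(assign_clusters(d4, pts)), 1:4)

  # same seed, same centres
  da <- build_dictionary(dict$latents, k = 10, seed = 9, nstart = 5)
  db <- build_dictionary(dict$latents, k = 10, seed = 9, nstart = 5)
  expect_identical(da$centres, db$centres)

  expect_error(build_dictionary(matrix(1, 10, 4), k = 5), "distinct")
})

test_that("spatial shape histograms conserve counts in 30 x 4 bins", {
  empty <- spatial_histogram(integer(0), numeric(0))
  expect_equal(sum(empty$counts), 0)
  expect_length(empty$flattened, 120)

  withr::with_seed(4, {
    cl <- sample(1:30, 57, TRUE)
    d <- runif(57, 0, 60)
  })
  h <- spatial_histogram(cl, d)
  expect_equal(sum(h$counts), 57)
  expect_length(h$flattened, 120)
  # row sums partition the total by cluster
  expect_equal(as.vector(rowSums(h$counts)), as.vector(tabulate(cl, 30)))

  # all PSSs in cluster 3 at 5 µm: all mass at (3, bin 1)
  h3 <- spatial_histogram(rep(3L, 8), rep(5, 8))
  expect_equal(h3$counts[3, 1], 8L)
  expect_equal(sum(h3$counts), 8)
  expect_equal(h3$flattened[(3 - 1) * 4 + 1], 8L)

  # bins are half-open with the last bin closed
  edge <- spatial_histogram(c(1L, 1L), c(15, 60))
  expect_equal(edge$counts[1, 2], 1L)
  expect_equal(edge$counts[1, 4], 1L)

  expect_error(spatial_histogram(1L, 61), "radial range")
})

test_that("spiny and smooth cells produce distinguishable histograms", {
  corpus <- fx_pss_corpus()
  dict <- fx_dictionary()
  cl_all <- assign_clusters(dict$dictionary, dict$latents)
  spine_pool <- cl_all[corpus$classes == "spine"]
  shaft_pool <- cl_all[corpus$classes == "shaft"]
  spine_clusters <- unique(spine_pool)
  spiny_mass <- function(pool_a, pool_b, w) {
    withr::with_seed(w, {
      cl <- c(sample(pool_a, 5, TRUE), sample(pool_b, 3, TRUE))
      h <- spatial_histogram(cl, runif(8, 0, 60))
    })
    sum(h$counts[spine_clusters, ]) / sum(h$counts)
  }
  spiny <- vapply(1:20, function(w) spiny_mass(spine_pool, shaft_pool, w),
                  numeric(1))
  smooth <- vapply(21:40, function(w) spiny_mass(shaft_pool, shaft_pool, w),
                   numeric(1))
  expect_lt(wilcox.test(spiny, smooth)$p.value, 0.01)
})

test_that("the per-cell PSS pipeline composes end to end", {
  corpus <- fx_pss_corpus()
  dict <- fx_dictionary()
  p <- corpus$phantoms[[1]]
  syn <- as_synapse_table(tibble::tibble(
    pre_id = 1L, post_id = 2L, x_nm = p$synapse_point[1],
    y_nm = p$synapse_point[2], z_nm = p$synapse_point[3], size_vx = 50L))
  out <- cell_pss_histogram(p$mesh, syn, nucleus_centroid_nm = c(0, 0, 30000),
                            encoder = dict$encoder,
                            dictionary = dict$dictionary, n_points = 256)
  expect_equal(sum(out$histogram$counts), 1)
  expect_equal(nrow(out$descriptors), 1)
  expect_true(out$descriptors$distance_um <= 60)
})
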