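# Shared, lazily built fixtures. Everything is generated in code from seeds;
# expensive objects (wrapped phantoms, voxel volumes, extracted shape
# corpora, trained cascades) are built once per test run and reused.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# deep nucleus phantom with ~20% planted infolding, plus its wrap
fx_fold_phantom <- function() fixture("fold_phantom", {
  ph <- make_nucleus_phantom(radius_um = 5, n_folds = 6, fold_depth_nm = 1200,
                             fold_area_fraction = 0.2, seed = 3)
  ph$wrap <- shrink_wrap(ph$mesh)
  ph$folds <- fold_features(ph$mesh, ph$wrap)
  ph
})

fx_sphere_phantom <- function() fixture("sphere_phantom", {
  ph <- make_nucleus_phantom(radius_um = 5, n_folds = 0, seed = 1)
  ph$wrap <- shrink_wrap(ph$mesh)
  ph
})

# clean voxel cell (nucleus in soma, synapses, 10% void context)
fx_cell_volume <- function() fixture("cell_volume", {
  make_cell_volume(nucleus_radius_um = 5, soma_radius_um = 8,
                   n_soma_synapses = 10, error_void_fraction = 0.1,
                   resolution_nm = c(128, 128, 80), seed = 2,
                   box_halfwidth_um = 12)
})

# cell with a planted 2-voxel missing slab and a planted distant fragment
fx_defect_volume <- function() fixture("defect_volume", {
  make_cell_volume(nucleus_radius_um = 5, soma_radius_um = 8,
                   n_soma_synapses = 0, error_void_fraction = 0,
                   resolution_nm = c(128, 128, 80), seed = 3,
                   box_halfwidth_um = 12,
                   gap_z_voxels = 2, fragment_gap_voxels = 14,
                   fragment_radius_voxels = 2)
})

# a small extracted-PSS corpus: phantoms -> region -> segmentation -> PSS ->
# pose-normalized clouds, with true classes
fx_pss_corpus <- function() fixture("pss_corpus", {
  ph <- make_pss_phantoms(c(spine = 10, shaft = 10, soma_patch = 10), seed = 9)
  pss <- lapply(ph, function(p) {
    region <- synapse_region_mesh(p$mesh, p$synapse_point)
    seg <- segment_by_thickness(region, seed = 7)
    extract_pss(region, seg, p$synapse_point)
  })
  clouds <- lapply(pss, normalize_pose, n_points = 512, seed = 5)
  list(phantoms = ph, pss = pss, clouds = clouds,
       classes = factor(vapply(ph, `[[`, character(1), "true_class")))
})

fx_dictionary <- function() fixture("dictionary", {
  corpus <- fx_pss_corpus()
  enc <- shape_descriptor_encoder()
  lat <- encode_shapes(enc, corpus$clouds)
  list(encoder = enc, latents = lat,
       dictionary = build_dictionary(lat, k = 30, seed = 3, nstart = 10))
})

# well-separated labeled cohort with planted axons, plus its trained cascade
fx_cohort <- function() fixture("cohort", {
  classes <- c("error", "astrocyte", "microglia", "23P", "4P", "5P-NP",
               "BC", "MC")
  props <- setNames(rep(1 / 8, 8), classes)
  model <- make_separated_model(classes, separation = 6, seed = 1,
                                pss_classes = c("23P", "4P", "5P-NP", "BC", "MC"))
  coh <- make_cohort(400, props, model, seed = 11, planted_axons = list(
    list(motif = "chandelier", count = 1, ais_fraction = 0.8, n_outputs = 120),
    list(motif = "np_targeting", count = 1, np_fraction = 0.5, n_outputs = 100)))
  zs <- zscore_features(coh$features[, -1])
  coh$standardized <- dplyr::bind_cols(coh$features[, 1],
                                       tibble::as_tibble(zs$scaled))
  coh
})

fx_hierarchy <- function() fixture("hierarchy", {
  coh <- fx_cohort()
  train_hierarchy(coh$standardized, coh$labels, n_draws = 4, cv_folds = 3,
                  seed = 5,
                  candidate_families = c("svm_linear", "random_forest", "knn"))
})

# a long cylinder mesh for region-extent checks
fx_long_cylinder <- function() fixture("long_cylinder", {
  inside <- function(p) {
    perisoma:::dist_point_segment(p, c(-5000, 0, 0), c(5000, 0, 0)) <= 400
  }
  perisoma:::mesh_from_implicit(inside, c(-5500, -550, -550),
                                c(5500, 550, 550), 50)
})

# dumbbell: two bulbs (r = 500) joined by a thin neck (r = 125)
fx_dumbbell <- function() fixture("dumbbell", {
  inside <- function(p) {
    b1 <- sqrt(rowSums(sweep(p, 2, c(-900, 0, 0))^2)) <= 500
    b2 <- sqrt(rowSums(sweep(p, 2, c(900, 0, 0))^2)) <= 500
    nk <- perisoma:::dist_point_segment(p, c(-900, 0, 0), c(900, 0, 0)) <= 125
    b1 | b2 | nk
  }
  perisoma:::mesh_from_implicit(inside, rep(-1550, 3), rep(1550, 3), 25)
})
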