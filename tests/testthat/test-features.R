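test_that("the object filter applies its three steps in order, strictly", {
  obj <- tibble::tibble(cell_id = 1:3, volume_um3 = c(10, 30, 100),
                        bbox_error_fraction = c(0, 0, 0.5))
  rep1 <- filter_objects(obj)
  expect_equal(rep1$kept_ids, 2L)
  expect_equal(rep1$n_removed_small, 1)
  expect_equal(rep1$n_removed_error_fraction, 1)

  # boundary cases are strict: exactly 25 µm^3 and exactly 20% survive
  edge <- tibble::tibble(cell_id = 1:2, volume_um3 = c(25, 25),
                         bbox_error_fraction = c(0.20, 0.2000001))
  rep2 <- filter_objects(edge)
  expect_equal(rep2$kept_ids, 1L)

  # nothing filtered when everything passes
  ok <- tibble::tibble(cell_id = 1:4, volume_um3 = rep(30, 4),
                       bbox_error_fraction = rep(0.1, 4))
  expect_equal(filter_objects(ok)$kept_ids, 1:4)

  # predicted-error removal runs last and the counts reconcile
  rep3 <- filter_objects(ok, predicted_error_ids = c(2, 4))
  expect_equal(rep3$kept_ids, c(1L, 3L))
  expect_equal(rep3$n_input,
               length(rep3$kept_ids) + rep3$n_removed_small +
                 rep3$n_removed_error_fraction + rep3$n_removed_predicted_error)

  expect_error(filter_objects(tibble::tibble(cell_id = 1)), "missing")
})

test_that("z-slab normalization removes per-slab gains", {
  # constant feature: everything becomes 1
  expect_equal(z_slab_normalize(rep(7, 5), c(0, 100, 900, 1700, 2500)),
               rep(1, 5))
  # two slabs with means 2 and 4: a value of 4 in the second slab gives 1
  v <- z_slab_normalize(c(2, 2, 4, 4), c(0, 100, 900, 1000))
  expect_equal(v, c(1, 1, 1, 1))
  v2 <- z_slab_normalize(c(1, 3, 2, 6), c(0, 100, 900, 1000))
  expect_equal(v2, c(0.5, 1.5, 0.5, 1.5))
  # single cell per slab degenerates to 1 with a warning
  expect_warning(z_slab_normalize(c(3, 9), c(0, 900)), "single")
  expect_error(z_slab_normalize(c(0, 0), c(0, 100)), "zero mean")

  # planted multiplicative slab gains are removed: ranks recover
  withr::with_seed(11, {
    n <- 2000
    z <- runif(n, 0, 8000)  # 10 slabs, ~200 cells each
    truth <- rlnorm(n, 5, 0.4)
    gains <- runif(11, 0.5, 2)
    observed <- truth * gains[floor(z / 800) + 1]
  })
  fixed <- z_slab_normalize(observed, z)
  expect_gte(cor(fixed, truth, method = "spearman"), 0.99)
})

test_that("z-scoring uses population sd and is idempotent", {
  zs <- zscore_features(cbind(a = c(1, 3), b = c(5, 5 + 2e-8)))
  expect_equal(unname(zs$scaled[, "a"]), c(-1, 1))
  zs2 <- zscore_features(zs$scaled)
  expect_equal(zs2$scaled, zs$scaled, tolerance = 1e-9)

  expect_warning(out <- zscore_features(cbind(a = 1:5, b = rep(2, 5))),
                 "constant")
  expect_equal(out$dropped, "b")
  expect_error(zscore_features(matrix(1, 1, 3)), "at least 2")
})

test_that("assembly joins nucleus, soma and PSS blocks by cell", {
  feat_names <- perisomatic_feature_names()
  nuc <- tibble::tibble(cell_id = 1:3)
  for (f in feat_names[1:6]) nuc[[f]] <- rnorm(3, 10)
  nuc$centroid_z_nm <- c(100, 300, 500)  # one 800-nm slab
  soma <- tibble::tibble(cell_id = c(1:3, 9L))
  for (f in feat_names[7:13]) soma[[f]] <- rnorm(4, 5)
  out <- assemble_features(nuc, soma)
  expect_equal(nrow(out$standardized), 3)
  # 13 standardized feature columns before any PSS block
  expect_equal(ncol(out$standardized) - 1, 13)
  expect_equal(out$report$missing_nucleus, 9L)
  # standardized block has mean 0, population sd 1 per column
  m <- as.matrix(out$standardized[, -1])
  expect_equal(unname(colMeans(m)), rep(0, 13), tolerance = 1e-9)
  expect_equal(unname(sqrt(colMeans(m^2))), rep(1, 13), tolerance = 1e-9)

  # disjoint ids: empty result, reported
  out2 <- assemble_features(nuc, dplyr::mutate(soma, cell_id = 21:24))
  expect_equal(nrow(out2$standardized), 0)
  expect_equal(out2$report$missing_soma, 1:3)

  # partial PSS block is joined where present and flagged elsewhere
  pss <- tibble::tibble(cell_id = 1:2)
  for (i in 1:120) pss[[sprintf("pss_%03d", i)]] <- c(i, i + 5)
  out3 <- assemble_features(nuc, soma, pss)
  expect_equal(out3$report$missing_pss, 3L)

  expect_error(assemble_features(dplyr::bind_rows(nuc, nuc[1, ]), soma),
               "duplicate")
})
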