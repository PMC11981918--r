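# direct hypergeometric enumeration; the independent oracle for Fisher tests
fisher_oracle <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  kk <- max(0, k - n):min(k, m)
  dens <- dhyper(kk, m, n, k)
  sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("nearest neighbours match brute force and break ties by id", {
  # two points: the other point is the single neighbour
  two <- tibble::tibble(cell_id = 1:2, f1 = c(0, 1), f2 = c(0, 0))
  expect_equal(nearest_neighbors(two, 1, k = 1)$cell_id, 2L)

  # a duplicate of the query ranks first at distance zero
  withr::with_seed(3, x <- matrix(rnorm(40), 10))
  dup <- tibble::tibble(cell_id = 1:11, as.data.frame(rbind(x, x[4, ])))
  nn <- nearest_neighbors(dup, 4, k = 3)
  expect_equal(nn$cell_id[1], 11L)
  expect_equal(nn$distance[1], 0)

  # 100 random points: exact agreement with an all-pairs sort
  withr::with_seed(9, m <- matrix(rnorm(100 * 7), 100))
  feats <- dplyr::bind_cols(tibble::tibble(cell_id = 1:100),
                            tibble::as_tibble(as.data.frame(m)))
  for (q in c(1, 37, 100)) {
    got <- nearest_neighbors(feats, q, k = 20)
    d <- sqrt(colSums((t(m) - m[q, ])^2))
    ord <- order(d, seq_len(100))
    brute <- setdiff(ord, q)[1:20]
    expect_equal(got$cell_id, brute)
    expect_equal(got$distance, sort(d[brute]))
  }
  expect_error(nearest_neighbors(two, 1, k = 2), "smaller")
  expect_error(nearest_neighbors(two, 99, k = 1), "not found")
})

test_that("targeting angles follow the pia convention exactly", {
  somata <- tibble::tibble(cell_id = 1L, x_nm = 0, y_nm = 0, z_nm = 0,
                           label = "23P")
  syn_at <- function(dx, dy, dz) tibble::tibble(
    pre_id = 9L, post_id = 1L, x_nm = dx, y_nm = dy, z_nm = dz, size_vx = 1L)
  # displaced along +depth (+y): directly below the soma, phi = 180
  p <- targeting_profile(syn_at(0, 30000, 0), somata)
  expect_equal(p$phi, 180)
  expect_equal(p$r_um, 30)
  # toward the pia: phi = 0
  expect_equal(targeting_profile(syn_at(0, -1000, 0), somata)$phi, 0)
  # perpendicular: phi = 90
  expect_equal(targeting_profile(syn_at(5000, 0, 0), somata)$phi, 90)
  # unknown target soma is flagged
  p2 <- targeting_profile(syn_at(0, 1, 0),
                          dplyr::mutate(somata, cell_id = 2L))
  expect_false(p2$known_target)
})

test_that("chandelier calls use the strict 40% AIS-window rule", {
  somata <- tibble::tibble(cell_id = 1:50, x_nm = 0, y_nm = 0, z_nm = 0)
  mk_prof <- function(n_ais, n_other) {
    phi <- c(runif(n_ais, 161, 179), runif(n_other, 10, 150))
    r <- c(runif(n_ais, 5, 50), runif(n_other, 5, 50)) * 1000
    syn <- tibble::tibble(pre_id = 9L,
                          post_id = sample(1:50, n_ais + n_other, TRUE),
                          x_nm = r * sin(phi * pi / 180),
                          y_nm = -r * cos(phi * pi / 180),  # phi from -y (pia)
                          z_nm = 0, size_vx = 1L)
    targeting_profile(syn, somata)
  }
  withr::with_seed(2, {
    all_ais <- mk_prof(120, 0)
    at_40 <- mk_prof(48, 72)
    over_40 <- mk_prof(49, 71)
  })
  s1 <- chandelier_score(all_ais)
  expect_equal(s1$ais_fraction, 1)
  expect_true(s1$is_chandelier)
  # exactly 40% is not a chandelier under the strict rule
  s2 <- chandelier_score(at_40)
  expect_equal(s2$ais_fraction, 0.4)
  expect_false(s2$is_chandelier)
  expect_true(chandelier_score(over_40)$is_chandelier)
  expect_warning(chandelier_score(all_ais[1:10, ]), "100")
  expect_error(chandelier_score(all_ais[0, ]), "no outputs")
})

test_that("NP-targeting fractions sum to one and use the inclusive rule", {
  somata <- tibble::tibble(cell_id = 1:10, x_nm = 0, y_nm = 0, z_nm = 0,
                           label = c(rep("5P-NP", 4), rep("23P", 6)))
  mk <- function(targets) targeting_profile(tibble::tibble(
    pre_id = 9L, post_id = targets, x_nm = 1000, y_nm = 0, z_nm = 0,
    size_vx = 1L), somata)
  # 4 of 10 outputs onto 5P-NP
  tf <- target_fractions(mk(c(1:4, 5:10)))
  expect_equal(sum(tf$fractions), 1)
  expect_equal(tf$fractions[["5P-NP"]], 0.4)
  expect_true(tf$np_preferring)
  # exactly 30%: preferring under the inclusive rule, not under the strict
  tf30 <- target_fractions(mk(c(1:3, rep(5L, 7))))
  expect_equal(tf30$fractions[["5P-NP"]], 0.3)
  expect_true(tf30$np_preferring)
  expect_false(target_fractions(mk(c(1:3, rep(5L, 7))), strict = TRUE)$np_preferring)
  expect_error(target_fractions(mk(integer(0))), "no labeled")
})

test_that("Fisher enrichment equals exact enumeration", {
  # printed-count examples
  expect_equal(fisher_enrichment(16, 4, 0, 20)$p_two_tailed,
               fisher_oracle(16, 4, 0, 20), tolerance = 1e-12)
  expect_equal(fisher_enrichment(13, 7, 2, 141)$p_two_tailed,
               fisher_oracle(13, 7, 2, 141), tolerance = 1e-12)
  # symmetric tables have p = 1
  expect_equal(fisher_enrichment(10, 10, 10, 10)$p_two_tailed, 1)
  expect_equal(fisher_enrichment(1, 0, 0, 1)$p_two_tailed, 1)
  # random grid with margins up to 200
  withr::with_seed(6, tabs <- replicate(60, as.vector(
    rmultinom(1, sample(20:200, 1), runif(4, 0.05, 1)))))
  for (i in seq_len(ncol(tabs))) {
    t4 <- tabs[, i]
    if (any(t4[c(1, 2)] + t4[c(3, 4)] == 0) || any(t4[c(1, 3)] + t4[c(2, 4)] == 0)) next
    expect_equal(fisher_enrichment(t4[1], t4[2], t4[3], t4[4])$p_two_tailed,
                 fisher_oracle(t4[1], t4[2], t4[3], t4[4]), tolerance = 1e-12)
  }
  expect_error(fisher_enrichment(0, 0, 1, 1), "margins")
})

test_that("proofreading deltas are exact set arithmetic", {
  expect_equal(proofreading_deltas(1:4, 1:4),
               list(removed = 0, added = 0, maintained = 1))
  expect_equal(proofreading_deltas(1:3, 4:6),
               list(removed = 1, added = 1, maintained = 0))
  expect_equal(proofreading_deltas(1:4, 3:5),
               list(removed = 0.5, added = 1 / 3, maintained = 0.5))
  expect_error(proofreading_deltas(integer(0), integer(0)), "empty")
})

test_that("radial extent is the interpolated 97th percentile", {
  expect_equal(radial_extent(rep(10, 5)), 10)
  expect_equal(radial_extent(1:100), 97.03)
  expect_equal(radial_extent(2 * (1:100)), 2 * 97.03)
  syn <- tibble::tibble(pre_id = 1L, post_id = 2L, x_nm = c(3000, 4000),
                        y_nm = 0, z_nm = 0, size_vx = 1L)
  expect_equal(radial_extent(syn, c(0, 0, 0)),
               unname(quantile(c(3, 4), 0.97)))
  expect_error(radial_extent(numeric(0)), "no input")
})

test_that("truncation estimates compare border distance to median extent", {
  expect_equal(truncation_estimate(c(100, 120, 140), c(500, 600)), 0)
  expect_equal(truncation_estimate(c(100, 120, 140), c(0, 0)), 1)
  # planted: half the cells below the median extent
  expect_equal(truncation_estimate(rep(121, 9), c(50, 60, 119, 120.9, 200,
                                                  300, 400, 500)), 0.5)
})

test_that("density maps scale 50-µm bins to cells per mm^2", {
  pred <- tibble::tibble(cell_id = 1:7, leaf_label = c(rep("23P", 5),
                                                       rep("BC", 2)))
  pos <- tibble::tibble(cell_id = 1:7,
                        x_nm = c(rep(10000, 5), 60000, 110000),
                        z_nm = rep(10000, 7))
  dm <- subclass_density_map(pred, pos)
  # 5 cells of one class in a single 50-µm bin = 2,000 per mm^2
  expect_equal(dm$density_per_mm2[dm$leaf_label == "23P"], 2000)
  # conservation: bin counts sum to the cohort size
  expect_equal(sum(dm$n), 7)
  # an absent class has no rows (an all-zero map)
  expect_false("MC" %in% dm$leaf_label)
})
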