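make_blobs <- function(n, sep, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("a", "b"), each = n / 2)
    x <- matrix(rnorm(n * 4), n, 4)
    x[y == "b", 1] <- x[y == "b", 1] + sep
  })
  list(x = x, y = y)
}

test_that("randomized level search finds near-perfect separable models", {
  d <- make_blobs(160, sep = 10)
  lvl <- train_level(d$x, d$y, candidate_families = c("knn", "svm_linear"),
                     n_draws = 3, cv_folds = 5, seed = 2)
  expect_gte(lvl$best$accuracy, 0.99)
  expect_equal(sort(unique(as.character(predict_level(lvl, d$x)))),
               c("a", "b"))
  # report covers every family x draw
  expect_equal(nrow(lvl$cv), 6)

  # shuffled labels fall to chance (within 3 binomial SEs of 1/2)
  sh <- withr::with_seed(5, sample(d$y))
  lvl_sh <- train_level(d$x, sh, candidate_families = "knn", n_draws = 2,
                        cv_folds = 5, seed = 2)
  se <- sqrt(0.25 / 160)
  expect_lt(abs(lvl_sh$best$accuracy - 0.5), 3 * se + 0.05)

  # determinism: identical seed, identical selection and report
  again <- train_level(d$x, d$y, candidate_families = c("knn", "svm_linear"),
                       n_draws = 3, cv_folds = 5, seed = 2)
  expect_identical(again$family, lvl$family)
  expect_identical(again$params, lvl$params)
  expect_equal(again$cv$accuracy, lvl$cv$accuracy)

  # classes smaller than the fold count reduce folds with a warning
  tiny <- make_blobs(12, sep = 10)
  expect_warning(train_level(tiny$x, tiny$y, candidate_families = "knn",
                             n_draws = 1, cv_folds = 10, seed = 1),
                 "folds")
  expect_error(train_level(d$x, rep("a", 160)), "2 classes")
})

test_that("the cascade routes every cell to exactly one leaf", {
  coh <- fx_cohort()
  h <- fx_hierarchy()
  pred <- predict_cascade(h, coh$standardized)
  expect_equal(nrow(pred), 400)
  expect_true(all(nchar(pred$leaf_label) > 0))
  # recovery of planted leaf labels under strong separation
  ev <- evaluate_predictions(pred, coh$labels$label)
  expect_gte(ev$weighted_accuracy, 0.95)
  # error-labeled cells are not routed deeper
  err <- pred$leaf_label == "error"
  expect_true(all(pred$path[err] == "root/error"))
  # non-neuronal cells never reach neuronal leaves
  nn <- pred$leaf_label %in% c("astrocyte", "microglia")
  expect_true(all(startsWith(pred$path[nn], "root/non-neuron")))

  # cells routed inhibitory with an incomplete PSS block are flagged pending
  broken <- coh$standardized
  inh_cells <- coh$labels$cell_id[coh$labels$label %in% c("BC", "MC")]
  broken[broken$cell_id %in% inh_cells, grep("^pss_", names(broken))] <- NA
  pred2 <- predict_cascade(h, broken)
  expect_gt(sum(pred2$pending), 0)
  expect_true(all(pred2$leaf_label[pred2$pending] == "inhibitory"))
})

test_that("misplaced excitatory cells are recovered from the PSS space", {
  coh <- fx_cohort()
  h <- fx_hierarchy()
  exc <- coh$standardized[coh$labels$label %in% c("23P", "4P", "5P-NP"), ]
  rr <- reroute_misplaced_excitatory(exc, h)
  expect_gte(mean(rr$rerouted), 0.9)
  expect_true(all(rr$new_label[rr$rerouted] %in%
                    cell_taxonomy()$children$excitatory))

  inh <- coh$standardized[coh$labels$label %in% c("BC", "MC"), ]
  rr2 <- reroute_misplaced_excitatory(inh, h)
  expect_equal(sum(rr2$rerouted), 0)

  rr3 <- reroute_misplaced_excitatory(coh$standardized[0, ], h)
  expect_equal(nrow(rr3), 0)
})

test_that("weighted accuracy is the frequency-weighted mean recall", {
  # perfect predictions
  ev <- evaluate_predictions(c("23P", "BC"), c("23P", "BC"))
  expect_equal(ev$weighted_accuracy, 1)
  expect_true(all(diag(ev$confusion) == 1))

  # all-one-class predictor on two balanced classes scores 0.5
  ev2 <- evaluate_predictions(rep("23P", 10), rep(c("23P", "BC"), 5))
  expect_equal(ev2$weighted_accuracy, 0.5)

  # hand-built recalls (1.0, 0.5, 0.0) at frequencies (0.5, 0.3, 0.2)
  ref <- c(rep("23P", 10), rep("4P", 6), rep("5P-IT", 4))
  prd <- c(rep("23P", 10), rep("4P", 3), rep("23P", 3), rep("4P", 4))
  ev3 <- evaluate_predictions(prd, ref)
  expect_equal(ev3$weighted_accuracy, 0.65)

  expect_error(evaluate_predictions("zebra", "23P"), "outside taxonomy")
})

test_that("a saved and reloaded cascade predicts identically", {
  coh <- fx_cohort()
  h <- fx_hierarchy()
  path <- tempfile(fileext = ".rds")
  saveRDS(h, path)
  h2 <- readRDS(path)
  p1 <- predict_cascade(h, coh$standardized)
  p2 <- predict_cascade(h2, coh$standardized)
  expect_identical(p1, p2)
})

test_that("tidy and glance summarize fitted hierarchies", {
  h <- fx_hierarchy()
  td <- tidy(h)
  expect_true(all(c("level", "family", "cv_accuracy") %in% names(td)))
  expect_equal(nrow(td), length(h$levels))
  gl <- glance(h)
  expect_equal(gl$n_levels, length(h$levels))
  expect_true(gl$has_reroute)
})
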