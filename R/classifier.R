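default_families <- function() {
  c("svm_linear", "svm_rbf", "knn", "random_forest", "decision_tree",
    "neural_net")
}

draw_params <- function(family, n_features) {
  switch(family,
    svm_linear = list(cost = 10^runif(1, -2, 2)),
    svm_rbf = list(cost = 10^runif(1, -2, 2), gamma = 10^runif(1, -3, 1)),
    knn = list(k = sample(1:25, 1)),
    random_forest = list(ntree = sample(100:500, 1),
                         mtry = sample(seq_len(max(1, floor(sqrt(n_features) * 2))), 1)),
    decision_tree = list(cp = 10^runif(1, -4, -1),
                         minsplit = sample(2:20, 1)),
    neural_net = list(size = sample(2:16, 1), decay = 10^runif(1, -4, 0)),
    stop("unknown model family: ", family))
}

fit_family <- function(family, params, x, y) {
  df <- as.data.frame(x)
  switch(family,
    svm_linear = e1071::svm(x = df, y = y, kernel = "linear",
                            cost = params$cost, scale = FALSE),
    svm_rbf = e1071::svm(x = df, y = y, kernel = "radial", cost = params$cost,
                         gamma = params$gamma, scale = FALSE),
    knn = list(train = df, cl = y, k = min(params$k, nrow(df))),
    random_forest = randomForest::randomForest(
      x = df, y = y, ntree = params$ntree,
      mtry = min(params$mtry, ncol(df))),
    decision_tree = rpart::rpart(
      y ~ ., data = cbind(df, y = y), method = "class",
      control = rpart::rpart.control(cp = params$cp,
                                     minsplit = params$minsplit)),
    neural_net = nnet::nnet(y ~ ., data = cbind(df, y = y),
                            size = params$size, decay = params$decay,
                            maxit = 200, trace = FALSE,
                            MaxNWts = 20000))
}

predict_family <- function(family, fit, x, classes) {
  df <- as.data.frame(x)
  out <- switch(family,
    svm_linear = predict(fit, df),
    svm_rbf = predict(fit, df),
    knn = class::knn(fit$train, df, fit$cl, k = fit$k),
    random_forest = predict(fit, df),
    decision_tree = predict(fit, df, type = "class"),
    neural_net = {
      if (length(classes) == 2) {
        # nnet uses a single logistic output for 2 classes
        p <- predict(fit, df)
        factor(classes[1 + (p[, 1] > 0.5)], levels = classes)
      } else {
        factor(predict(fit, df, type = "class"), levels = classes)
      }
    })
  factor(as.character(out), levels = classes)
}

macro_f1 <- function(truth, pred) {
  classes <- levels(truth)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

#' Train one level of the hierarchical cascade
#'
#' Randomized model search: for each candidate family (linear and RBF
#' support vector machines, nearest neighbours, random forest, decision
#' tree, single-hidden-layer neural network), `n_draws` hyperparameter draws
#' are scored by stratified k-fold cross-validation; the winner is the draw
#' with the best accuracy, ties broken by macro F1 and then by family order.
#' The winning configuration is refit on all data. Deterministic under
#' `seed`.
#'
#' @param features numeric matrix or data frame (rows = cells).
#' @param labels class labels (character or factor).
#' @param candidate_families subset of
#'   `c("svm_linear", "svm_rbf", "knn", "random_forest", "decision_tree",
#'   "neural_net")`.
#' @param n_draws hyperparameter draws per family, default 50.
#' @param cv_folds cross-validation folds, default 10; reduced with a
#'   warning when a class has fewer members.
#' @param seed integer seed.
#' @return A `perisoma_level`: list with the refit `fit`, `family`,
#'   `params`, `classes`, `feature_names`, `cv` (per-draw report tibble),
#'   `best` (accuracy/F1) and `folds` (per-cell fold assignment).
#' @export
train_level <- function(features, labels, candidate_families = default_families(),
                        n_draws = 50, cv_folds = 10, seed = 1L) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2) stop("need at least 2 classes at this level")
  min_class <- min(table(y))
  k <- cv_folds
  if (min_class < cv_folds) {
    k <- max(2, min_class)
    warning("smallest class has ", min_class, " members; using ", k, " folds")
  }
  withr::with_seed(seed, {
    fold <- stratified_folds(y, k)
    report <- list()
    for (family in candidate_families) {
      for (d in seq_len(n_draws)) {
        params <- draw_params(family, ncol(x))
        preds <- factor(rep(NA_character_, length(y)), levels = levels(y))
        ok <- TRUE
        for (fi in seq_len(k)) {
          te <- fold == fi
          fit <- try(suppressWarnings(
            fit_family(family, params, x[!te, , drop = FALSE], y[!te])),
            silent = TRUE)
          if (inherits(fit, "try-error")) { ok <- FALSE; break }
          preds[te] <- predict_family(family, fit, x[te, , drop = FALSE],
                                      levels(y))
        }
        acc <- if (ok) mean(preds == y, na.rm = TRUE) else NA_real_
        f1 <- if (ok) macro_f1(y, preds) else NA_real_
        report[[length(report) + 1]] <- tibble::tibble(
          family = family, draw = d, accuracy = acc, f1 = f1,
          params = list(params))
      }
    }
    cv <- dplyr::bind_rows(report)
    ranked <- cv[order(-cv$accuracy, -cv$f1,
                       match(cv$family, candidate_families), cv$draw), ]
    best <- ranked[1, ]
    if (!is.finite(best$accuracy)) stop("no model family could be fit")
    fit <- suppressWarnings(fit_family(best$family, best$params[[1]], x, y))
  })
  structure(list(fit = fit, family = best$family, params = best$params[[1]],
                 classes = levels(y), feature_names = colnames(x),
                 cv = cv, best = list(accuracy = best$accuracy, f1 = best$f1),
                 folds = fold),
            class = "perisoma_level")
}

#' @export
print.perisoma_level <- function(x, ...) {
  cat(sprintf("<perisoma_level: %s over {%s}; CV accuracy %.3f, F1 %.3f>\n",
              x$family, paste(x$classes, collapse = ", "),
              x$best$accuracy, x$best$f1))
  invisible(x)
}

#' Predict with a trained cascade level
#'
#' @param level a `perisoma_level`.
#' @param features matrix/data frame with the level's feature columns.
#' @return Factor of predicted labels.
#' @export
predict_level <- function(level, features) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x <- x[, level$feature_names, drop = FALSE]
  predict_family(level$family, level$fit, x, level$classes)
}

core_feature_cols <- function(tbl) {
  intersect(perisomatic_feature_names(), names(tbl))
}

pss_feature_cols <- function(tbl) grep("^pss_", names(tbl), value = TRUE)

#' Train the five-model hierarchical cascade
#'
#' Fits the object model (neuron / non-neuron / error), the non-neuronal
#' subclass model, the neuron class model (excitatory / inhibitory), the
#' excitatory subclass model - all on nucleus + soma features - and the
#' inhibitory subclass model on nucleus + soma + PSS features. When the
#' training table carries PSS features for both neuron classes, a binary
#' excitatory-vs-inhibitory model on the PSS-augmented features is also fit
#' to support [reroute_misplaced_excitatory()].
#'
#' @param features standardized feature tibble: `cell_id`, the 13
#'   perisomatic columns, optionally `pss_*` columns.
#' @param labels tibble with `cell_id` and leaf `label` (see
#'   [cell_taxonomy()]).
#' @param taxonomy a [cell_taxonomy()].
#' @param candidate_families,n_draws,cv_folds,seed passed to [train_level()].
#' @return A `perisoma_hierarchy` with one `perisoma_level` per populated
#'   node.
#' @export
train_hierarchy <- function(features, labels, taxonomy = cell_taxonomy(),
                            candidate_families = default_families(),
                            n_draws = 50, cv_folds = 10, seed = 1L) {
  dat <- dplyr::inner_join(features, labels, by = "cell_id")
  core <- core_feature_cols(dat)
  pss <- pss_feature_cols(dat)
  for (lb in unique(dat$label)) level_label(taxonomy, lb, "root")  # validate
  node_specs <- list(
    object = list(node = "root", cols = core, subset = rep(TRUE, nrow(dat))),
    nonneuronal = list(node = "non-neuron", cols = core, subset = NULL),
    neuron_class = list(node = "neuron", cols = core, subset = NULL),
    excitatory = list(node = "excitatory", cols = core, subset = NULL),
    inhibitory = list(node = "inhibitory", cols = c(core, pss), subset = NULL))
  levels_out <- list()
  i <- 0
  for (nm in names(node_specs)) {
    i <- i + 1
    spec <- node_specs[[nm]]
    target <- vapply(dat$label, level_label, character(1),
                     taxonomy = taxonomy, node = spec$node)
    rows <- !is.na(target)
    if (nm == "inhibitory" && length(pss) > 0) {
      rows <- rows & stats::complete.cases(dat[, pss])
    }
    if (sum(rows) == 0 || length(unique(target[rows])) < 2) {
      levels_out[[nm]] <- NULL
      next
    }
    cols <- spec$cols[colSums(!is.na(dat[rows, spec$cols, drop = FALSE])) > 0]
    levels_out[[nm]] <- train_level(dat[rows, cols, drop = FALSE],
                                    target[rows],
                                    candidate_families = candidate_families,
                                    n_draws = n_draws, cv_folds = cv_folds,
                                    seed = split_seed(seed, i))
  }
  reroute <- NULL
  if (length(pss) > 0) {
    neuron_cls <- vapply(dat$label, level_label, character(1),
                         taxonomy = taxonomy, node = "neuron")
    rows <- !is.na(neuron_cls) & stats::complete.cases(dat[, pss])
    if (length(unique(neuron_cls[rows])) == 2) {
      reroute <- withr::with_seed(split_seed(seed, 99), suppressWarnings(
        e1071::svm(x = as.data.frame(dat[rows, c(core, pss)]),
                   y = factor(neuron_cls[rows],
                              levels = c("excitatory", "inhibitory")),
                   kernel = "linear", cost = 1, probability = TRUE,
                   scale = FALSE)))
    }
  }
  structure(list(levels = levels_out, taxonomy = taxonomy,
                 core_features = core, pss_features = pss, reroute = reroute),
            class = "perisoma_hierarchy")
}

#' @export
print.perisoma_hierarchy <- function(x, ...) {
  cat("<perisoma_hierarchy>\n")
  for (nm in names(x$levels)) {
    cat(sprintf("  %-13s", nm))
    print(x$levels[[nm]])
  }
  invisible(x)
}

#' Route cells through the hierarchical cascade
#'
#' Every cell receives exactly one leaf label or `error`; objects predicted
#' as errors at the first level are routed no further. Cells routed to the
#' inhibitory subclass model without a complete PSS block are flagged
#' `pending` rather than silently dropped.
#'
#' @param model a `perisoma_hierarchy`.
#' @param features standardized feature tibble with `cell_id`.
#' @return Tibble with `cell_id`, `leaf_label`, `path` and `pending`.
#' @export
predict_cascade <- function(model, features) {
  n <- nrow(features)
  core <- model$core_features
  missing_core <- setdiff(core, names(features))
  if (length(missing_core) > 0) {
    stop("features missing required columns: ",
         paste(missing_core, collapse = ", "))
  }
  xcore <- features[, core, drop = FALSE]
  lvl1 <- as.character(predict_level(model$levels$object, xcore))
  leaf <- character(n)
  path <- character(n)
  pending <- logical(n)
  leaf[lvl1 == "error"] <- "error"
  path[lvl1 == "error"] <- "root/error"

  route_leafward <- function(rows, level_name, prefix) {
    lv <- model$levels[[level_name]]
    if (is.null(lv)) {
      leaf[rows] <<- sub(".*/", "", prefix)
      path[rows] <<- prefix
      return(invisible())
    }
    cols <- lv$feature_names
    have <- all(cols %in% names(features))
    if (!have || (level_name == "inhibitory" &&
                  !all(stats::complete.cases(features[rows, cols])))) {
      complete <- if (have) stats::complete.cases(features[rows, cols]) else
        rep(FALSE, length(rows))
      pending[rows[!complete]] <<- TRUE
      leaf[rows[!complete]] <<- sub(".*/", "", prefix)
      path[rows[!complete]] <<- prefix
      rows <- rows[complete]
      if (length(rows) == 0) return(invisible())
    }
    pred <- as.character(predict_level(lv, features[rows, cols, drop = FALSE]))
    leaf[rows] <<- pred
    path[rows] <<- paste0(prefix, "/", pred)
    invisible()
  }

  nn <- which(lvl1 == "non-neuron")
  if (length(nn) > 0) route_leafward(nn, "nonneuronal", "root/non-neuron")
  nr <- which(lvl1 == "neuron")
  if (length(nr) > 0) {
    if (is.null(model$levels$neuron_class)) {
      leaf[nr] <- "neuron"; path[nr] <- "root/neuron"
    } else {
      cls <- as.character(predict_level(model$levels$neuron_class,
                                        features[nr, , drop = FALSE][, model$levels$neuron_class$feature_names]))
      exc <- nr[cls == "excitatory"]
      inh <- nr[cls == "inhibitory"]
      if (length(exc) > 0) route_leafward(exc, "excitatory", "root/neuron/excitatory")
      if (length(inh) > 0) route_leafward(inh, "inhibitory", "root/neuron/inhibitory")
    }
  }
  tibble::tibble(cell_id = features$cell_id, leaf_label = leaf, path = path,
                 pending = pending)
}

#' Re-route misplaced excitatory cells out of the inhibitory branch
#'
#' In the PSS-augmented feature space, excitatory cells that were routed as
#' inhibitory separate cleanly (their proximal dendrites are spiny). Cells
#' whose posterior probability of being excitatory exceeds `threshold` under
#' the binary PSS-augmented model are re-routed through the excitatory
#' subclass model; all reassignments are returned.
#'
#' @param cells standardized feature tibble (must include the PSS block) of
#'   cells currently predicted inhibitory.
#' @param model a `perisoma_hierarchy` with a trained reroute model.
#' @param threshold posterior threshold, default 0.5.
#' @return Tibble with `cell_id`, `p_excitatory`, `rerouted` and
#'   `new_label` (NA for cells kept inhibitory).
#' @export
reroute_misplaced_excitatory <- function(cells, model, threshold = 0.5) {
  if (nrow(cells) == 0) {
    return(tibble::tibble(cell_id = integer(), p_excitatory = numeric(),
                          rerouted = logical(), new_label = character()))
  }
  if (is.null(model$reroute)) {
    stop("hierarchy has no PSS-augmented excitatory/inhibitory model")
  }
  cols <- c(model$core_features, model$pss_features)
  pr <- predict(model$reroute, as.data.frame(cells[, cols]), probability = TRUE)
  p_exc <- attr(pr, "probabilities")[, "excitatory"]
  rerouted <- p_exc > threshold
  new_label <- rep(NA_character_, nrow(cells))
  if (any(rerouted) && !is.null(model$levels$excitatory)) {
    lv <- model$levels$excitatory
    new_label[rerouted] <- as.character(
      predict_level(lv, cells[rerouted, lv$feature_names, drop = FALSE]))
  }
  tibble::tibble(cell_id = cells$cell_id, p_excitatory = unname(p_exc),
                 rerouted = rerouted, new_label = new_label)
}

#' Weighted-accuracy evaluation of predictions
#'
#' Weighted accuracy is the class-frequency-weighted mean of per-class
#' recall, with weights taken from the reference labels (the sampling rate
#' of each class); also returns per-class precision/recall/F1 and the
#' confusion matrix (rows = reference).
#'
#' @param predictions vector of predicted labels, or a [predict_cascade()]
#'   tibble.
#' @param reference vector of reference labels aligned to `predictions`.
#' @param class_weights optional named weights overriding reference
#'   frequencies.
#' @param taxonomy taxonomy used to validate labels; `NULL` to skip.
#' @return A list with `weighted_accuracy`, `per_class` (tibble) and
#'   `confusion` (matrix).
#' @export
evaluate_predictions <- function(predictions, reference, class_weights = NULL,
                                 taxonomy = cell_taxonomy()) {
  if (is.data.frame(predictions)) predictions <- predictions$leaf_label
  predictions <- as.character(predictions)
  reference <- as.character(reference)
  stopifnot(length(predictions) == length(reference))
  if (!is.null(taxonomy)) {
    known <- unique(c(taxonomy$leaves, names(taxonomy$children),
                      unlist(taxonomy$children)))
    bad <- setdiff(unique(c(predictions, reference)), known)
    if (length(bad) > 0) {
      stop("label outside taxonomy: ", paste(bad, collapse = ", "))
    }
  }
  classes <- sort(unique(reference))
  confusion <- table(reference = factor(reference, classes),
                     predicted = factor(predictions,
                                        sort(unique(c(predictions, classes)))))
  per_class <- dplyr::bind_rows(lapply(classes, function(cl) {
    tp <- sum(predictions == cl & reference == cl)
    fp <- sum(predictions == cl & reference != cl)
    fn <- sum(predictions != cl & reference == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- tp / (tp + fn)
    f1 <- if (!is.na(precision) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble::tibble(class = cl, n = tp + fn, precision = precision,
                   recall = recall, f1 = f1)
  }))
  w <- if (is.null(class_weights)) {
    per_class$n / sum(per_class$n)
  } else {
    unname(class_weights[per_class$class] / sum(class_weights[per_class$class]))
  }
  list(weighted_accuracy = sum(w * per_class$recall),
       per_class = per_class,
       confusion = unclass(confusion))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.perisoma_level <- function(x, ...) {
  dplyr::mutate(x$cv,
                params = vapply(.data$params, function(p) {
                  paste(names(p), signif(unlist(p), 3), sep = "=",
                        collapse = ", ")
                }, character(1)))
}

#' @export
glance.perisoma_level <- function(x, ...) {
  tibble::tibble(family = x$family, n_classes = length(x$classes),
                 cv_accuracy = x$best$accuracy, cv_f1 = x$best$f1)
}

#' @export
tidy.perisoma_hierarchy <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$levels), function(nm) {
    dplyr::mutate(glance(x$levels[[nm]]), level = nm, .before = 1)
  }))
}

#' @export
glance.perisoma_hierarchy <- function(x, ...) {
  tibble::tibble(
    n_levels = length(x$levels),
    mean_cv_accuracy = mean(vapply(x$levels, function(l) l$best$accuracy,
                                   numeric(1))),
    has_pss = length(x$pss_features) > 0,
    has_reroute = !is.null(x$reroute))
}
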