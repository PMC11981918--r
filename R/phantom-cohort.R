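#' Synthetic cohorts with planted class structure and connectivity motifs
#'
#' Draws per-cell perisomatic feature vectors from class-conditional Gaussian
#' models, assigns soma positions, and plants axons with known connectivity
#' motifs: chandelier-like axons that place a controlled fraction of their
#' outputs in the axon-initial-segment angular window (160-180 degrees,
#' within 60 µm of the target soma), and axons that place a controlled
#' fraction of outputs onto cells labeled `5P-NP`.
#'
#' The depth axis follows image-style conventions: depth increases along +y,
#' so "directly above a soma" (toward the pia) is -y.
#'
#' @param n_cells number of cells.
#' @param class_proportions named numeric vector of class fractions; must sum
#'   to 1.
#' @param feature_model named list, one entry per class, each with `mean`
#'   (length-13 named vector, see [perisomatic_feature_names()]), `cov`
#'   (13 x 13 covariance, or a variance vector), and optionally
#'   `pss_profile` (length-120 probability vector) plus `pss_n` (expected
#'   synapse count) to generate a PSS histogram block.
#' @param planted_axons list of motifs; each motif is a list with `motif`
#'   (`"chandelier"` or `"np_targeting"`), `count`, `n_outputs`, and
#'   `ais_fraction` or `np_fraction`.
#' @param seed integer seed.
#' @return A list with `features` (tibble, `cell_id` + 13 features + any PSS
#'   columns), `labels` (tibble `cell_id`, `label`), `somata` (tibble
#'   `cell_id`, `x_nm`, `y_nm`, `z_nm`), `synapses` (outputs of planted
#'   axons), and `planted` (bookkeeping tibble with the realized fractions).
#' @export
make_cohort <- function(n_cells, class_proportions, feature_model,
                        planted_axons = list(), seed = 1L) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8)
  feat_names <- perisomatic_feature_names()
  empty <- list(
    features = tibble::tibble(cell_id = integer()),
    labels = tibble::tibble(cell_id = integer(), label = character()),
    somata = tibble::tibble(cell_id = integer(), x_nm = numeric(),
                            y_nm = numeric(), z_nm = numeric()),
    synapses = as_synapse_table(tibble::tibble(
      pre_id = integer(), post_id = integer(), x_nm = numeric(),
      y_nm = numeric(), z_nm = numeric(), size_vx = integer())),
    planted = tibble::tibble(cell_id = integer(), motif = character(),
                             planted_fraction = numeric()))
  if (n_cells == 0) return(empty)

  classes <- names(class_proportions)
  stopifnot(all(classes %in% names(feature_model)))
  withr::with_seed(split_seed(seed, 3), {
    labels <- sample(classes, n_cells, replace = TRUE, prob = class_proportions)
    feats <- matrix(NA_real_, n_cells, length(feat_names),
                    dimnames = list(NULL, feat_names))
    pss_rows <- NULL
    has_pss <- any(vapply(feature_model, function(m) !is.null(m$pss_profile), logical(1)))
    if (has_pss) pss_rows <- matrix(0, n_cells, 120)
    for (cls in classes) {
      rows <- which(labels == cls)
      if (length(rows) == 0) next
      m <- feature_model[[cls]]
      cv <- m$cov
      if (is.null(dim(cv))) cv <- diag(cv, length(feat_names))
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev))) {
        stop("degenerate covariance for class ", cls)
      }
      mu <- m$mean[feat_names]
      feats[rows, ] <- MASS::mvrnorm(length(rows), mu, cv)
      if (has_pss) {
        prof <- m$pss_profile
        if (is.null(prof)) prof <- rep(1 / 120, 120)
        nsyn <- m$pss_n %||% 120
        for (r in rows) {
          pss_rows[r, ] <- as.vector(stats::rmultinom(1, nsyn, prof))
        }
      }
    }
    somata <- tibble::tibble(
      cell_id = seq_len(n_cells),
      x_nm = runif(n_cells, 0, 4e5),
      y_nm = runif(n_cells, 0, 8e5),  # depth axis
      z_nm = runif(n_cells, 0, 4e5))
  })

  features <- tibble::as_tibble(cbind(tibble::tibble(cell_id = seq_len(n_cells)),
                                      as.data.frame(feats)))
  if (!is.null(pss_rows)) {
    colnames(pss_rows) <- sprintf("pss_%03d", 1:120)
    features <- dplyr::bind_cols(features, tibble::as_tibble(pss_rows))
  }
  labels_tbl <- tibble::tibble(cell_id = seq_len(n_cells), label = labels)

  syn <- list()
  planted <- list()
  if (length(planted_axons) > 0) {
    withr::with_seed(split_seed(seed, 4), {
      next_syn <- 1L
      for (pa in planted_axons) {
        motif <- pa$motif
        count <- pa$count %||% 1L
        n_out <- pa$n_outputs %||% 120L
        for (rep_i in seq_len(count)) {
          src_pool <- if (motif == "chandelier") {
            labels_tbl$cell_id[labels %in% c("BC", "BPC", "MC", "NGC")]
          } else labels_tbl$cell_id
          src_pool <- setdiff(src_pool, vapply(planted, `[[`, 0L, "cell_id"))
          if (length(src_pool) == 0) src_pool <- labels_tbl$cell_id
          src <- src_pool[sample.int(length(src_pool), 1)]
          if (motif == "chandelier") {
            f <- pa$ais_fraction %||% 0.8
            n_ais <- round(f * n_out)
            tgt_pool <- labels_tbl$cell_id[!labels_tbl$cell_id %in% src]
            tgt <- sample(tgt_pool, n_out, replace = TRUE)
            phi <- c(runif(n_ais, 160, 180), runif(n_out - n_ais, 0, 155))
            r_um <- c(runif(n_ais, 5, 55), runif(n_out - n_ais, 5, 90))
            s <- synapse_positions_at_angle(somata, tgt, phi, r_um)
            syn[[length(syn) + 1]] <- tibble::tibble(
              pre_id = src, post_id = tgt, x_nm = s[, 1], y_nm = s[, 2],
              z_nm = s[, 3], size_vx = 100L)
            planted[[length(planted) + 1]] <- list(
              cell_id = src, motif = motif, planted_fraction = n_ais / n_out)
          } else if (motif == "np_targeting") {
            f <- pa$np_fraction %||% 0.5
            np_ids <- labels_tbl$cell_id[labels == "5P-NP"]
            other_ids <- labels_tbl$cell_id[labels != "5P-NP"]
            if (length(np_ids) == 0) stop("no 5P-NP cells to target")
            n_np <- round(f * n_out)
            tgt <- c(sample(np_ids, n_np, replace = TRUE),
                     sample(other_ids, n_out - n_np, replace = TRUE))
            phi <- runif(n_out, 0, 180)
            r_um <- runif(n_out, 5, 80)
            s <- synapse_positions_at_angle(somata, tgt, phi, r_um)
            syn[[length(syn) + 1]] <- tibble::tibble(
              pre_id = src, post_id = tgt, x_nm = s[, 1], y_nm = s[, 2],
              z_nm = s[, 3], size_vx = 100L)
            planted[[length(planted) + 1]] <- list(
              cell_id = src, motif = motif, planted_fraction = n_np / n_out)
          } else stop("unknown motif: ", motif)
          next_syn <- next_syn + n_out
        }
      }
    })
  }
  synapses <- if (length(syn) > 0) {
    as_synapse_table(dplyr::bind_rows(syn))
  } else empty$synapses
  planted_tbl <- if (length(planted) > 0) {
    dplyr::bind_rows(lapply(planted, tibble::as_tibble))
  } else empty$planted

  list(features = features, labels = labels_tbl, somata = somata,
       synapses = synapses, planted = planted_tbl)
}

# place synapses at angle phi (degrees, 0 = toward the pia = -y) and radius
# r (µm) from each target soma, with random azimuth in the x-z plane
synapse_positions_at_angle <- function(somata, target_ids, phi_deg, r_um) {
  tgt <- somata[match(target_ids, somata$cell_id), ]
  phi <- phi_deg * pi / 180
  az <- runif(length(target_ids), 0, 2 * pi)
  r_nm <- r_um * 1000
  cbind(tgt$x_nm + r_nm * sin(phi) * cos(az),
        tgt$y_nm - r_nm * cos(phi),   # phi = 0 is -y (pial side)
        tgt$z_nm + r_nm * sin(phi) * sin(az))
}

#' Class-conditional Gaussian feature model with controlled separation
#'
#' Builds a `feature_model` for [make_cohort()] in which class means are
#' random directions in feature space scaled so that every pair of classes is
#' at least `separation` standard deviations apart (unit covariance). The
#' qualitative trends of real cortical cohorts are imposed on top: non-neurons
#' get smaller nuclei, inhibitory classes higher soma synapse density and
#' infolding, error objects much smaller volumes.
#'
#' @param classes character vector of class labels (taxonomy leaves).
#' @param separation minimum pairwise distance between class means, in SD
#'   units.
#' @param seed integer seed.
#' @param pss_classes classes that should carry a PSS histogram block; each
#'   gets a distinct random shape profile (`spine`-heavy for excitatory
#'   classes, `shaft`-heavy otherwise).
#' @return A named list usable as `feature_model` in [make_cohort()].
#' @export
make_separated_model <- function(classes, separation = 6, seed = 1L,
                                 pss_classes = character()) {
  nf <- length(perisomatic_feature_names())
  withr::with_seed(split_seed(seed, 5), {
    repeat {
      mu <- matrix(rnorm(length(classes) * nf), length(classes), nf)
      mu <- mu / sqrt(rowSums(mu^2)) * separation / sqrt(2) * 1.2
      if (length(classes) == 1 || min(dist(mu)) >= separation) break
    }
    rownames(mu) <- classes
    model <- lapply(setNames(classes, classes), function(cls) {
      m <- mu[cls, ]
      names(m) <- perisomatic_feature_names()
      # qualitative trends on interpretable axes
      if (cls %in% c("astrocyte", "microglia", "oligodendrocyte", "OPC", "pericyte")) {
        m["nucleus_volume"] <- m["nucleus_volume"] - separation / 2
        m["soma_synapse_density"] <- m["soma_synapse_density"] - separation / 2
      }
      if (cls %in% c("BC", "BPC", "MC", "NGC")) {
        m["soma_synapse_density"] <- m["soma_synapse_density"] + separation / 2
        m["nucleus_fold_fraction"] <- m["nucleus_fold_fraction"] + separation / 2
      }
      if (cls == "error") {
        m["nucleus_volume"] <- m["nucleus_volume"] - separation
        m["soma_volume"] <- m["soma_volume"] - separation
      }
      out <- list(mean = m, cov = rep(1, nf))
      if (cls %in% pss_classes) {
        prof <- rep(1, 120)
        spiny <- cls %in% c("23P", "4P", "5P-IT", "5P-ET", "5P-NP", "6P-IT",
                            "6P-CT", "excitatory")
        hot <- if (spiny) 1:40 else 61:100
        prof[hot] <- prof[hot] + 25 * runif(length(hot))
        out$pss_profile <- prof / sum(prof)
        out$pss_n <- 150
      }
      out
    })
  })
  model
}
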