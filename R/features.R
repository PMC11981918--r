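#' Three-step object filter
#'
#' Sequentially removes detected objects that are (1) smaller than
#' `min_volume_um3` (strictly less than 25 µm^3 by default - small nucleolus
#' fragments), (2) surrounded by more than `max_error_fraction` (strictly
#' greater than 20%) of error/void voxels in their 15-µm bounding box, and
#' (3) predicted as errors by the object classifier, when such predictions
#' are supplied. Steps apply in order, so each removal count refers to the
#' survivors of the previous step.
#'
#' @param objects data frame with at least `cell_id`, `volume_um3` and
#'   `bbox_error_fraction` columns.
#' @param predicted_error_ids optional vector of cell ids flagged by the
#'   object classifier.
#' @param min_volume_um3 volume threshold (µm^3), strict, default 25.
#' @param max_error_fraction void-context threshold, strict, default 0.20.
#' @return A `filter_report`: list with counts per step and `kept_ids`;
#'   also a `kept` tibble of surviving rows.
#' @export
filter_objects <- function(objects, predicted_error_ids = NULL,
                           min_volume_um3 = 25, max_error_fraction = 0.20) {
  required <- c("cell_id", "volume_um3", "bbox_error_fraction")
  missing <- setdiff(required, names(objects))
  if (length(missing) > 0) {
    stop("objects table is missing: ", paste(missing, collapse = ", "))
  }
  objects <- tibble::as_tibble(objects)
  n_input <- nrow(objects)
  s1 <- objects[!(objects$volume_um3 < min_volume_um3), , drop = FALSE]
  n_small <- n_input - nrow(s1)
  s2 <- s1[!(s1$bbox_error_fraction > max_error_fraction), , drop = FALSE]
  n_err <- nrow(s1) - nrow(s2)
  s3 <- s2[!(s2$cell_id %in% (predicted_error_ids %||% integer())), , drop = FALSE]
  n_pred <- nrow(s2) - nrow(s3)
  structure(list(n_input = n_input,
                 n_removed_small = n_small,
                 n_removed_error_fraction = n_err,
                 n_removed_predicted_error = n_pred,
                 kept_ids = s3$cell_id,
                 kept = s3),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report: %d in; removed %d (< volume), ",
                     "%d (void context), %d (predicted error); %d kept>\n"),
              x$n_input, x$n_removed_small, x$n_removed_error_fraction,
              x$n_removed_predicted_error, length(x$kept_ids)))
  invisible(x)
}

#' Sectioning-artifact normalization by z slab
#'
#' Section-thickness variation imposes abrupt multiplicative shifts on size
#' features along the sectioning (z) axis. Values are divided by the mean of
#' their 800-nm slab (slab index = `floor(coordinate / slab_width_nm)`),
#' which removes a per-slab gain while preserving within-slab structure.
#'
#' @param values numeric feature values.
#' @param slab_coordinates_nm z coordinate of each value (nm).
#' @param slab_width_nm slab width (nm), default 800.
#' @return Normalized values (same length).
#' @export
z_slab_normalize <- function(values, slab_coordinates_nm, slab_width_nm = 800) {
  stopifnot(length(values) == length(slab_coordinates_nm))
  slab <- floor(slab_coordinates_nm / slab_width_nm)
  mu <- tapply(values, slab, mean)
  if (any(mu == 0)) stop("slab with zero mean; cannot normalize")
  if (any(tapply(values, slab, length) == 1)) {
    warning("slab(s) containing a single cell normalize to exactly 1")
  }
  values / as.numeric(mu[as.character(slab)])
}

#' Per-feature z-scoring across cells
#'
#' Standardizes each column to mean 0, sd 1 (population sd, i.e. divisor
#' `n`). Constant columns are dropped with a warning. The returned means and
#' sds allow applying the identical transform to new cells.
#'
#' @param x numeric matrix or data frame of features (rows = cells).
#' @return A list with `scaled` (matrix), `means`, `sds` and `dropped`
#'   (names of constant columns).
#' @export
zscore_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 cells to z-score")
  n <- nrow(x)
  mu <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2, mu)^2))  # population sd
  keep <- sds > 0
  dropped <- colnames(x)[!keep]
  if (length(dropped) > 0) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
  }
  scaled <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sds[keep], "/")
  list(scaled = scaled, means = mu[keep], sds = sds[keep], dropped = dropped)
}

#' Assemble per-cell perisomatic feature vectors
#'
#' Inner-joins the nucleus and soma feature tables by `cell_id` (cells
#' missing soma features are reported, not silently dropped), optionally
#' attaches the 120-column PSS histogram block, and builds the standardized
#' block by applying the two normalizations in order: z-slab gain removal on
#' size features (with derived ratios recomputed afterwards), then cohort
#' z-scoring of every feature.
#'
#' @param nucleus_tbl tibble from [nucleus_features()] rows plus `cell_id`.
#' @param soma_tbl tibble from [soma_features()] rows plus `cell_id`.
#' @param pss_tbl optional tibble: `cell_id` plus 120 `pss_*` columns.
#' @param slab_width_nm z-slab width (nm); set `NULL` to skip slab
#'   normalization (e.g. for synthetic cohorts with no sectioning axis).
#' @return A `perisomatic_features` object: list with `raw` (joined tibble),
#'   `standardized` (tibble `cell_id` + z-scored columns), `transform`
#'   (means/sds), and `report` (ids missing from either table).
#' @export
assemble_features <- function(nucleus_tbl, soma_tbl, pss_tbl = NULL,
                              slab_width_nm = 800) {
  if (anyDuplicated(nucleus_tbl$cell_id) || anyDuplicated(soma_tbl$cell_id)) {
    stop("duplicate cell_id in input tables")
  }
  joined <- dplyr::inner_join(tibble::as_tibble(nucleus_tbl),
                              tibble::as_tibble(soma_tbl), by = "cell_id")
  report <- list(
    missing_soma = setdiff(nucleus_tbl$cell_id, soma_tbl$cell_id),
    missing_nucleus = setdiff(soma_tbl$cell_id, nucleus_tbl$cell_id),
    missing_pss = character(0))
  if (!is.null(pss_tbl)) {
    pss_cols <- grep("^pss_", names(pss_tbl), value = TRUE)
    report$missing_pss <- setdiff(joined$cell_id, pss_tbl$cell_id)
    joined <- dplyr::left_join(joined, pss_tbl[, c("cell_id", pss_cols)],
                               by = "cell_id")
  }
  if (nrow(joined) == 0) {
    return(structure(list(raw = joined, standardized = joined,
                          transform = NULL, report = report),
                     class = "perisomatic_features"))
  }
  feat <- joined
  size_feats <- c("nucleus_volume", "nucleus_area", "nucleus_fold_area",
                  "soma_volume", "soma_area")
  if (!is.null(slab_width_nm) && "centroid_z_nm" %in% names(feat)) {
    for (f in intersect(size_feats, names(feat))) {
      feat[[f]] <- z_slab_normalize(feat[[f]], feat$centroid_z_nm, slab_width_nm)
    }
    # recompute derived ratios from the gain-corrected sizes
    if (all(c("nucleus_area", "nucleus_volume") %in% names(feat))) {
      feat$nucleus_area_to_volume <- feat$nucleus_area / feat$nucleus_volume
    }
    if (all(c("soma_area", "soma_volume") %in% names(feat))) {
      feat$soma_area_to_volume <- feat$soma_area / feat$soma_volume
      feat$soma_synapse_density <- feat$soma_synapse_count / feat$soma_area
    }
    if (all(c("nucleus_volume", "soma_volume") %in% names(feat))) {
      feat$nucleus_to_soma_volume_ratio <- feat$nucleus_volume / feat$soma_volume
    }
  }
  num_cols <- setdiff(names(feat)[vapply(feat, is.numeric, logical(1))],
                      c("cell_id", "centroid_x_nm", "centroid_y_nm",
                        "centroid_z_nm"))
  block <- as.matrix(feat[, num_cols, drop = FALSE])
  block[is.na(block)] <- 0  # absent PSS block contributes nothing
  zs <- zscore_features(block)
  standardized <- dplyr::bind_cols(tibble::tibble(cell_id = joined$cell_id),
                                   tibble::as_tibble(zs$scaled))
  structure(list(raw = joined, standardized = standardized,
                 transform = zs[c("means", "sds", "dropped")],
                 report = report),
            class = "perisomatic_features")
}

#' @export
print.perisomatic_features <- function(x, ...) {
  cat(sprintf("<perisomatic_features: %d cells x %d standardized features>\n",
              nrow(x$standardized), ncol(x$standardized) - 1))
  invisible(x)
}
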