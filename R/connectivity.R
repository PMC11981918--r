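#' Nearest neighbours in the standardized perisomatic feature space
#'
#' k-d tree search for the `k` cells closest to a query cell by Euclidean
#' distance in the z-scored feature space; the query itself is excluded and
#' exact distance ties break toward the lower cell id.
#'
#' @param features standardized feature tibble with `cell_id`, or a numeric
#'   matrix with rownames as ids.
#' @param query_id id of the query cell (must be present).
#' @param k number of neighbours, default 20.
#' @return Tibble with `cell_id` and `distance`, ordered.
#' @export
nearest_neighbors <- function(features, query_id, k = 20) {
  if (is.data.frame(features)) {
    ids <- features$cell_id
    x <- as.matrix(features[, setdiff(names(features), "cell_id")])
  } else {
    x <- as.matrix(features)
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  qi <- match(query_id, ids)
  if (is.na(qi)) stop("query id not found")
  if (k >= nrow(x)) stop("k must be smaller than the number of cells")
  # over-fetch to resolve distance ties deterministically by id
  m <- min(nrow(x), k + 11)
  nn <- RANN::nn2(x, x[qi, , drop = FALSE], k = m)
  idx <- setdiff(as.vector(nn$nn.idx), qi)
  d <- sqrt(colSums((t(x[idx, , drop = FALSE]) - x[qi, ])^2))
  ord <- order(d, ids[idx])
  idx <- idx[ord][seq_len(k)]
  tibble::tibble(cell_id = ids[idx], distance = sort(d)[seq_len(k)])
}

#' Synapse-to-soma angular targeting profile
#'
#' For every output synapse of an axon, measures the angle `phi` between the
#' pia direction and the vector from the target soma centroid to the
#' synapse (`phi = 0` directly above the target soma on its pial side,
#' `phi = 180` directly below, where the axon initial segment sits) and the
#' Euclidean distance `r`. Synapses whose target soma is unknown are flagged
#' and excluded from fraction-based statistics.
#'
#' @param outputs synapse table of the axon's output synapses (post_id =
#'   target cell).
#' @param somata tibble with `cell_id`, `x_nm`, `y_nm`, `z_nm` and
#'   optionally `label`.
#' @param depth_axis unit direction of increasing cortical depth
#'   (pia to white matter); default `c(0, 1, 0)`, image-style +y.
#' @return A `targeting_profile` tibble: `synapse_id`, `target_id`, `phi`
#'   (degrees), `r_um`, `target_label`, `known_target`.
#' @export
targeting_profile <- function(outputs, somata, depth_axis = c(0, 1, 0)) {
  syn <- as_synapse_table(outputs)
  depth_axis <- depth_axis / sqrt(sum(depth_axis^2))
  if (nrow(syn) == 0) {
    out <- tibble::tibble(synapse_id = integer(), target_id = integer(),
                          phi = numeric(), r_um = numeric(),
                          target_label = character(),
                          known_target = logical())
    class(out) <- c("targeting_profile", class(out))
    return(out)
  }
  tgt <- match(syn$post_id, somata$cell_id)
  known <- !is.na(tgt)
  v <- as.matrix(syn[, c("x_nm", "y_nm", "z_nm")]) -
    as.matrix(somata[ifelse(known, tgt, 1), c("x_nm", "y_nm", "z_nm")])
  r <- sqrt(rowSums(v^2))
  # phi measured from the pia-pointing direction (-depth axis)
  cosphi <- (v %*% (-depth_axis)) / pmax(r, .Machine$double.eps)
  phi <- acos(pmin(pmax(drop(cosphi), -1), 1)) * 180 / pi
  out <- tibble::tibble(
    synapse_id = syn$synapse_id,
    target_id = syn$post_id,
    phi = ifelse(known, phi, NA_real_),
    r_um = ifelse(known, r / 1000, NA_real_),
    target_label = if ("label" %in% names(somata)) {
      ifelse(known, somata$label[tgt], NA_character_)
    } else NA_character_,
    known_target = known)
  class(out) <- c("targeting_profile", class(out))
  out
}

#' Chandelier score from a targeting profile
#'
#' The fraction of output synapses in the axon-initial-segment window
#' (angles 160-180 degrees, within 60 µm of the target soma). An axon with
#' strictly more than 40% of its outputs in the angular window is called a
#' chandelier cell.
#'
#' @param profile a [targeting_profile()].
#' @param angle_window degrees, default `c(160, 180)`.
#' @param r_max_um distance cap (µm), default 60.
#' @param threshold chandelier fraction threshold (strict), default 0.40.
#' @param min_outputs minimum recommended output count (axons are extended
#'   until at least 100 outputs in practice); fewer triggers a warning.
#' @return A list with `ais_fraction`, `is_chandelier` and `n_outputs`.
#' @export
chandelier_score <- function(profile, angle_window = c(160, 180),
                             r_max_um = 60, threshold = 0.40,
                             min_outputs = 100) {
  p <- profile[profile$known_target, , drop = FALSE]
  n <- nrow(p)
  if (n == 0) stop("profile has no outputs with known targets")
  if (n < min_outputs) {
    warning("only ", n, " output synapses; the targeting profile may be ",
            "unreliable below ", min_outputs)
  }
  ais <- p$phi >= angle_window[1] & p$phi <= angle_window[2] &
    p$r_um <= r_max_um
  frac <- sum(ais) / n
  list(ais_fraction = frac, is_chandelier = frac > threshold, n_outputs = n)
}

#' Output fractions by target subclass
#'
#' Fraction of an axon's outputs onto each predicted target subclass; an
#' axon placing at least 30% of its outputs onto `5P-NP` cells carries the
#' near-projecting-targeting connectivity preference (set
#' `strict = TRUE` for the strictly-greater reading).
#'
#' @param profile a [targeting_profile()] with target labels.
#' @param np_label label counted for the preference, default `"5P-NP"`.
#' @param np_threshold fraction threshold, default 0.30.
#' @param strict if `TRUE`, require strictly greater than the threshold.
#' @return A list with `fractions` (named, summing to 1) and `np_preferring`.
#' @export
target_fractions <- function(profile, np_label = "5P-NP", np_threshold = 0.30,
                             strict = FALSE) {
  p <- profile[profile$known_target & !is.na(profile$target_label), ,
               drop = FALSE]
  if (nrow(p) == 0) stop("profile has no labeled targets")
  fr <- table(p$target_label) / nrow(p)
  fractions <- setNames(as.numeric(fr), names(fr))
  np <- if (np_label %in% names(fractions)) fractions[[np_label]] else 0
  list(fractions = fractions,
       np_preferring = if (strict) np > np_threshold else np >= np_threshold)
}

#' Two-tailed Fisher exact enrichment test
#'
#' Exact hypergeometric test on a 2x2 table `[[a, b], [c, d]]`; the
#' two-tailed p-value is the total probability of all tables with the fixed
#' margins whose probability does not exceed the observed table's
#' (probability-mass method).
#'
#' @param a,b,c,d non-negative integer cell counts; `a/(a+b)` vs `c/(c+d)`
#'   is the comparison of interest.
#' @return An `enrichment_result`: list with `table`, `p_two_tailed` and
#'   `odds_ratio` (conditional MLE).
#' @export
fisher_enrichment <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  tab <- matrix(as.integer(counts), 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("Fisher test requires positive margins")
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  structure(list(table = tab, p_two_tailed = ft$p.value,
                 odds_ratio = unname(ft$estimate)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment: [[%d,%d],[%d,%d]] p = %.3g, OR = %.3g>\n",
              x$table[1, 1], x$table[1, 2], x$table[2, 1], x$table[2, 2],
              x$p_two_tailed, x$odds_ratio))
  invisible(x)
}

#' Synapse turnover across proofreading
#'
#' Compares a cell's synapse sets before and after proofreading by synapse
#' id: `removed = |before \ after| / |before|`,
#' `added = |after \ before| / |after|`,
#' `maintained = |before intersect after| / |before|`.
#'
#' @param before,after synapse tables (or vectors of synapse ids).
#' @return A list with `removed`, `added`, `maintained`.
#' @export
proofreading_deltas <- function(before, after) {
  ids <- function(x) if (is.data.frame(x)) as_synapse_table(x)$synapse_id else x
  b <- unique(ids(before))
  a <- unique(ids(after))
  if (length(b) == 0 && length(a) == 0) stop("both synapse sets are empty")
  list(removed = if (length(b)) length(setdiff(b, a)) / length(b) else 0,
       added = if (length(a)) length(setdiff(a, b)) / length(a) else 0,
       maintained = if (length(b)) length(intersect(b, a)) / length(b) else 0)
}

#' Dendritic radial extent
#'
#' The 97th percentile (linear interpolation between order statistics) of
#' the distances from a cell's input synapses to its soma.
#'
#' @param synapses input synapse table, or a numeric vector of distances in
#'   µm.
#' @param soma_position_nm soma centroid (nm); ignored when distances are
#'   given directly.
#' @param percentile percentile used, default 97.
#' @return Radial extent in µm.
#' @export
radial_extent <- function(synapses, soma_position_nm = NULL, percentile = 97) {
  d_um <- if (is.data.frame(synapses)) {
    syn <- as_synapse_table(synapses)
    if (nrow(syn) == 0) stop("no input synapses")
    p <- as.matrix(syn[, c("x_nm", "y_nm", "z_nm")])
    sqrt(rowSums(sweep(p, 2, soma_position_nm)^2)) / 1000
  } else {
    if (length(synapses) == 0) stop("no input synapses")
    synapses
  }
  unname(quantile(d_um, percentile / 100, type = 7))
}

#' Fraction of cells with potential dendritic truncation
#'
#' A cell is potentially truncated when its minimum distance to a volume
#' border is below the cohort's median radial dendritic extent.
#'
#' @param radial_extents_um radial extents of a proofread reference cohort
#'   (µm).
#' @param border_distances_um per-cell minimum distance to a volume border
#'   (µm).
#' @return Fraction in `[0, 1]`.
#' @export
truncation_estimate <- function(radial_extents_um, border_distances_um) {
  stopifnot(length(radial_extents_um) > 0, length(border_distances_um) > 0)
  mean(border_distances_um < median(radial_extents_um))
}

#' Predicted subclass density map
#'
#' Bins cells into square bins in the x-z plane (50 µm by default) and
#' scales counts to cells per square millimetre.
#'
#' @param predictions tibble with `cell_id` and `leaf_label` (e.g. from
#'   [predict_cascade()]).
#' @param positions tibble with `cell_id`, `x_nm`, `z_nm`.
#' @param bin_um bin side (µm), default 50.
#' @return Tibble with `leaf_label`, `bin_x`, `bin_z`, `n` and
#'   `density_per_mm2`.
#' @export
subclass_density_map <- function(predictions, positions, bin_um = 50) {
  dat <- dplyr::inner_join(tibble::as_tibble(predictions),
                           tibble::as_tibble(positions), by = "cell_id")
  bin_nm <- bin_um * 1000
  dat$bin_x <- floor(dat$x_nm / bin_nm)
  dat$bin_z <- floor(dat$z_nm / bin_nm)
  area_mm2 <- (bin_um / 1000)^2
  dat |>
    dplyr::count(.data$leaf_label, .data$bin_x, .data$bin_z) |>
    dplyr::mutate(density_per_mm2 = .data$n / area_mm2)
}
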