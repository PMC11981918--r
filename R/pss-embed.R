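#' Pose-normalized surface point cloud
#'
#' Samples exactly `n_points` uniformly over the mesh surface, centers the
#' cloud, and rotates it into its principal axes with a deterministic sign
#' convention (non-negative third moment per axis, right-handed frame).
#' Scale is preserved. Because sampling uses the mesh's own face order and a
#' fixed seed, rigidly rotated copies of a mesh canonicalize to the same
#' cloud.
#'
#' @param pss_mesh a [surface_mesh()].
#' @param n_points number of points, default 1024.
#' @param seed integer seed for the surface sampling.
#' @return An `n_points` x 3 matrix (nm).
#' @export
normalize_pose <- function(pss_mesh, n_points = 1024, seed = 1L) {
  if (nrow(pss_mesh$faces) == 0) stop("empty mesh")
  p <- sample_surface_points(pss_mesh, n_points, seed = seed)
  p <- sweep(p, 2, colMeans(p))
  eg <- eigen(cov(p), symmetric = TRUE)
  rot <- eg$vectors  # columns ordered by decreasing variance
  q <- p %*% rot
  s <- c(1, 1, 1)
  for (a in 1:2) {
    sk <- mean(q[, a]^3)
    s[a] <- if (abs(sk) > 1e-6 * mean(q[, a]^2)^1.5) sign(sk) else {
      sign(q[which.max(abs(q[, a])), a])
    }
  }
  # third sign chosen so the overall frame stays right-handed
  s[3] <- sign(det(rot)) * s[1] * s[2]
  sweep(q, 2, s, "*")
}

#' Shape encoders for postsynaptic shapes
#'
#' Two interchangeable encoders map pose-normalized point clouds to a fixed
#' latent vector (default length 1,024):
#'
#' * `shape_descriptor_encoder()` - a deterministic classical descriptor:
#'   per-axis scales and eigenvalue ratios, raw moments up to order three, a
#'   radial histogram and a pairwise-distance (D2) histogram, zero-padded to
#'   the latent size. No training required; the default for CPU-bound runs.
#' * `train_autoencoder()` - a tied-weight linear autoencoder trained by
#'   gradient descent on a stable flattening of each cloud (per-axis extents
#'   plus an 8x8x8 occupancy-density grid); its training loss decreases
#'   monotonically from the first epoch and training is deterministic under
#'   the seed.
#'
#' @param latent_size latent dimension, default 1024.
#' @return A `pss_encoder` object; apply it with [encode_shapes()].
#' @export
shape_descriptor_encoder <- function(latent_size = 1024) {
  stopifnot(latent_size > 0)
  structure(list(type = "descriptor", latent_size = as.integer(latent_size)),
            class = "pss_encoder")
}

#' @rdname shape_descriptor_encoder
#' @param point_clouds list of `n x 3` matrices, all with the same `n`.
#' @param epochs gradient-descent epochs.
#' @param seed integer seed.
#' @export
train_autoencoder <- function(point_clouds, latent_size = 1024, epochs = 40,
                              seed = 1L) {
  if (latent_size <= 0) stop("latent_size must be positive")
  if (length(point_clouds) < 2) stop("need at least 2 point clouds")
  n <- nrow(point_clouds[[1]])
  X <- do.call(rbind, lapply(point_clouds, function(p) flatten_cloud(p)))
  center <- colMeans(X)
  X <- sweep(X, 2, center)
  scale_ <- sqrt(mean(X^2))
  X <- X / scale_
  d <- ncol(X)
  withr::with_seed(split_seed(seed, 7), {
    W <- matrix(rnorm(d * latent_size, sd = 1e-2), d, latent_size)
  })
  lr <- 0.45 * nrow(X) / sum(X^2)
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    Z <- X %*% W
    R <- Z %*% t(W) - X
    loss[ep] <- mean(R^2)
    grad <- (crossprod(X, R %*% W) + crossprod(R, Z)) * (2 / nrow(X))
    W <- W - lr * grad
  }
  structure(list(type = "autoencoder", latent_size = as.integer(latent_size),
                 W = W, center = center, scale = scale_, n_points = n,
                 loss = loss),
            class = "pss_encoder")
}

# stable fixed-length flattening of a pose-normalized cloud: per-axis
# extents (µm) plus an 8x8x8 occupancy-density grid over the bounding box
flatten_cloud <- function(p, grid = 8) {
  ext <- apply(abs(p), 2, max)
  q <- sweep(p, 2, 2 * pmax(ext, .Machine$double.eps), "/") + 0.5
  idx <- pmin(floor(q * grid), grid - 1)
  counts <- tabulate(1 + idx[, 1] + grid * idx[, 2] + grid^2 * idx[, 3],
                     nbins = grid^3) / nrow(p)
  c(ext / 1000, counts * 50)
}

#' @export
print.pss_encoder <- function(x, ...) {
  cat(sprintf("<pss_encoder (%s): latent size %d>\n", x$type, x$latent_size))
  invisible(x)
}

#' Encode point clouds into latent vectors
#'
#' @param encoder a `pss_encoder`.
#' @param point_clouds one `n x 3` matrix or a list of them.
#' @return A matrix with one latent row per cloud.
#' @export
encode_shapes <- function(encoder, point_clouds) {
  if (is.matrix(point_clouds)) point_clouds <- list(point_clouds)
  out <- t(vapply(point_clouds, function(p) encode_one(encoder, p),
                  numeric(encoder$latent_size)))
  out
}

encode_one <- function(encoder, p) {
  if (encoder$type == "autoencoder") {
    x <- (flatten_cloud(p) - encoder$center) / encoder$scale
    return(drop(x %*% encoder$W))
  }
  descriptor_features(p, encoder$latent_size)
}

descriptor_features <- function(p, latent_size) {
  n <- nrow(p)
  r <- sqrt(rowSums(p^2))
  rmax <- max(r, .Machine$double.eps)
  sds <- apply(p, 2, sd)
  ev <- sort(eigen(cov(p), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  ratios <- if (ev[1] > 0) ev[2:3] / ev[1] else c(0, 0)
  rad_hist <- tabulate(pmin(floor(r / rmax * 32) + 1, 32), 32) / n
  sub <- p[seq_len(min(n, 256)), , drop = FALSE]
  dd <- as.vector(dist(sub))
  dmax <- max(dd, .Machine$double.eps)
  d2_hist <- tabulate(pmin(floor(dd / dmax * 64) + 1, 64), 64) / length(dd)
  moments <- c()
  scale_ <- max(sds[1], .Machine$double.eps)
  ps <- p / scale_
  for (tot in 2:3) {
    for (a in 0:tot) for (b in 0:(tot - a)) {
      c_ <- tot - a - b
      moments <- c(moments, mean(ps[, 1]^a * ps[, 2]^b * ps[, 3]^c_))
    }
  }
  feat <- c(rmax / 1000, sds / 1000, ratios, rad_hist, d2_hist, moments)
  out <- numeric(latent_size)
  out[seq_len(min(length(feat), latent_size))] <- feat[seq_len(min(length(feat), latent_size))]
  out
}

#' Bag-of-shapes dictionary from latent vectors
#'
#' k-means (k = 30 by default) over the latent embedding of a shape corpus;
#' cluster centres are the dictionary words into which new shapes are binned
#' by nearest-centre assignment.
#'
#' @param latents matrix of latent vectors (rows = shapes).
#' @param k number of dictionary centres, default 30.
#' @param seed integer seed.
#' @param nstart k-means restarts, default 50.
#' @param ordering optional display permutation of the centres.
#' @return A `shape_dictionary` with `centres`, `ordering` and `trained_on`.
#' @export
build_dictionary <- function(latents, k = 30, seed = 1L, nstart = 50,
                             ordering = seq_len(k)) {
  latents <- as.matrix(latents)
  distinct <- unique(latents)
  if (nrow(distinct) < k) {
    stop("need at least ", k, " distinct latent vectors, got ", nrow(distinct))
  }
  centres <- if (nrow(distinct) == k) {
    # exact solution: every distinct latent is its own centre
    distinct
  } else {
    withr::with_seed(split_seed(seed, 8), {
      kmeans(latents, centers = k, nstart = nstart, iter.max = 100)$centers
    })
  }
  structure(list(centres = centres, ordering = as.integer(ordering),
                 trained_on = sprintf("%d latents, k-means x%d restarts",
                                      nrow(latents), nstart)),
            class = "shape_dictionary")
}

#' @export
print.shape_dictionary <- function(x, ...) {
  cat(sprintf("<shape_dictionary: %d centres (%s)>\n",
              nrow(x$centres), x$trained_on))
  invisible(x)
}

#' Assign latent vectors to dictionary clusters
#'
#' Nearest centre by Euclidean distance; ties break to the lowest centre
#' index.
#'
#' @param dictionary a [build_dictionary()] result.
#' @param latents matrix of latent vectors.
#' @return Integer cluster ids in `1..k`.
#' @export
assign_clusters <- function(dictionary, latents) {
  latents <- as.matrix(latents)
  cen <- dictionary$centres
  d2 <- outer(rowSums(latents^2), rep(1, nrow(cen))) -
    2 * latents %*% t(cen) + outer(rep(1, nrow(latents)), rowSums(cen^2))
  max.col(-d2, ties.method = "first")
}

#' Spatial shape histogram (30 shapes x 4 radial bins)
#'
#' Counts PSSs by dictionary cluster and distance from the nucleus centre in
#' 15-µm radial bins to 60 µm; bins are half-open `[lo, hi)` with the last
#' bin closed. Flattening is row-major over clusters (cluster 1 bins 1-4,
#' then cluster 2, ...), giving the 120-dimensional per-cell descriptor.
#'
#' @param clusters integer cluster assignment per PSS (1..k).
#' @param distance_um distance of each PSS synapse from the nucleus centre
#'   (µm); values beyond the last edge are an error.
#' @param k number of dictionary clusters, default 30.
#' @param edges radial bin edges in µm, default `c(0, 15, 30, 45, 60)`.
#' @return A `spatial_shape_histogram`: list with `counts` (k x bins) and
#'   `flattened` (length `k * bins`).
#' @export
spatial_histogram <- function(clusters, distance_um, k = 30,
                              edges = c(0, 15, 30, 45, 60)) {
  stopifnot(length(clusters) == length(distance_um))
  nb <- length(edges) - 1
  counts <- matrix(0L, k, nb,
                   dimnames = list(paste0("shape", seq_len(k)),
                                   paste0("r", seq_len(nb))))
  if (length(clusters) > 0) {
    if (any(distance_um > edges[nb + 1]) || any(distance_um < edges[1])) {
      stop("PSS distance outside the radial range ", edges[1], "-",
           edges[nb + 1], " µm")
    }
    if (any(clusters < 1 | clusters > k)) stop("cluster id outside 1..k")
    b <- findInterval(distance_um, edges, rightmost.closed = TRUE)
    b <- pmin(b, nb)
    for (i in seq_along(clusters)) {
      counts[clusters[i], b[i]] <- counts[clusters[i], b[i]] + 1L
    }
  }
  structure(list(counts = counts, flattened = as.vector(t(counts))),
            class = "spatial_shape_histogram")
}

#' @export
print.spatial_shape_histogram <- function(x, ...) {
  cat(sprintf("<spatial_shape_histogram: %d x %d, %d PSSs>\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Full PSS feature pipeline for one cell
#'
#' Runs region extraction, thickness segmentation, PSS extraction, pose
#' normalization and encoding for every synapse of a cell within
#' `max_radius_um` of the nucleus centre, then bins the results into the
#' spatial shape histogram.
#'
#' @param cell_surface the cell [surface_mesh()].
#' @param synapses synapse table rows targeting this cell.
#' @param nucleus_centroid_nm nucleus centre (nm).
#' @param encoder a `pss_encoder`.
#' @param dictionary a `shape_dictionary`.
#' @param max_radius_um PSS radius cap (µm), default 60.
#' @param n_points points per cloud for pose normalization.
#' @param seed integer seed.
#' @return A list with `histogram` (a [spatial_histogram()]) and
#'   `descriptors` (tibble: synapse_id, cluster, distance_um).
#' @export
cell_pss_histogram <- function(cell_surface, synapses, nucleus_centroid_nm,
                               encoder, dictionary, max_radius_um = 60,
                               n_points = 1024, seed = 1L) {
  syn <- as_synapse_table(synapses)
  pos <- as.matrix(syn[, c("x_nm", "y_nm", "z_nm")])
  dist_um <- sqrt(rowSums(sweep(pos, 2, nucleus_centroid_nm)^2)) / 1000
  keep <- dist_um <= max_radius_um
  recs <- list()
  for (i in which(keep)) {
    region <- synapse_region_mesh(cell_surface, pos[i, ])
    segm <- segment_by_thickness(region, seed = split_seed(seed, i))
    pss <- extract_pss(region, segm, pos[i, ])
    cloud <- normalize_pose(pss, n_points = n_points, seed = split_seed(seed, i + 1))
    lat <- encode_shapes(encoder, cloud)
    recs[[length(recs) + 1]] <- tibble::tibble(
      synapse_id = syn$synapse_id[i],
      cluster = assign_clusters(dictionary, lat),
      distance_um = dist_um[i])
  }
  desc <- if (length(recs) > 0) dplyr::bind_rows(recs) else {
    tibble::tibble(synapse_id = integer(), cluster = integer(),
                   distance_um = numeric())
  }
  list(histogram = spatial_histogram(desc$cluster, desc$distance_um,
                                     k = nrow(dictionary$centres)),
       descriptors = desc)
}
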