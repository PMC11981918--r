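#' Synapse region mesh
#'
#' Cuts the sub-mesh of all faces having a vertex within `radius_nm` of the
#' synapse location (default 3,500 nm) and keeps the connected component that
#' contains the synapse-nearest vertex.
#'
#' @param cell_surface the cell [surface_mesh()].
#' @param synapse_location length-3 position (nm).
#' @param radius_nm cutout radius (nm), default 3500.
#' @param surface_tol_nm maximum allowed synapse-to-surface distance (nm).
#' @return A [surface_mesh()].
#' @export
synapse_region_mesh <- function(cell_surface, synapse_location,
                                radius_nm = 3500, surface_tol_nm = 500) {
  vd <- sqrt(rowSums(sweep(cell_surface$vertices, 2, synapse_location)^2))
  f <- cell_surface$faces
  sel <- vd[f[, 1]] <= radius_nm | vd[f[, 2]] <= radius_nm | vd[f[, 3]] <= radius_nm
  if (!any(sel)) stop("no face within ", radius_nm, " nm of the synapse")
  dsurf <- .cpp_point_mesh_distance(matrix(synapse_location, 1),
                                    cell_surface$vertices, cell_surface$faces)
  if (dsurf > surface_tol_nm) {
    stop("synapse is ", round(dsurf), " nm from the surface (tolerance ",
         surface_tol_nm, " nm)")
  }
  sub <- subset_faces(cell_surface, sel)
  comp <- .cpp_face_components(sub$faces, nrow(sub$vertices))
  svd_ <- sqrt(rowSums(sweep(sub$vertices, 2, synapse_location)^2))
  near_v <- which.min(svd_)
  face_has <- sub$faces[, 1] == near_v | sub$faces[, 2] == near_v |
    sub$faces[, 3] == near_v
  keep_comp <- comp[which(face_has)[1]]
  subset_faces(sub, comp == keep_comp)
}

# face adjacency via shared manifold edges: nf x 3 matrix, 0 = no neighbor
face_adjacency <- function(mesh) {
  .cpp_face_adjacency(mesh$faces, nrow(mesh$vertices))
}

#' Segment a region mesh by local thickness
#'
#' Estimates per-face local thickness with a shape-diameter probe (a cone of
#' rays cast opposite the face normal; cosine-corrected lengths reduced by
#' the median), soft-clusters faces on log-thickness with a 1-D Gaussian
#' mixture (components chosen by BIC, then merged while their mean thickness
#' ratio is below `merge_ratio`), smooths labels by mode filtering over face
#' adjacency so boundaries settle at thickness transitions, and splits the
#' result into edge-connected segments. Segments smaller than `min_faces`
#' are absorbed into their largest neighbor.
#'
#' @param region_mesh a [surface_mesh()], typically from
#'   [synapse_region_mesh()].
#' @param n_rays rays per face for the thickness probe.
#' @param cone_half_deg cone half-angle (degrees).
#' @param max_components maximum thickness modes considered.
#' @param merge_ratio thickness ratio under which two modes are merged.
#' @param smooth_iters label mode-filter iterations.
#' @param min_faces minimum segment size.
#' @param max_probe_faces thickness is ray-probed on at most this many faces
#'   and interpolated over the face graph elsewhere (local thickness is
#'   smooth at the face scale).
#' @param seed integer seed (thickness probe ray pattern and mixture fit).
#' @return A `pss_segmentation`: list with `labels` (per face), `thickness`
#'   (per face, nm) and `segments`, a tibble with `segment`, `n_faces`,
#'   `area_nm2`, `mean_thickness_nm`.
#' @export
segment_by_thickness <- function(region_mesh, n_rays = 30, cone_half_deg = 60,
                                 max_components = 4, merge_ratio = 1.6,
                                 smooth_iters = 3, min_faces = 12,
                                 max_probe_faces = 8000, seed = 1L) {
  nf <- nrow(region_mesh$faces)
  if (nf == 0) stop("empty region mesh")
  nrm <- face_normals(region_mesh)
  if (any(!is.finite(nrm))) stop("degenerate face normals")
  adj <- face_adjacency(region_mesh)
  probe <- if (nf > max_probe_faces) {
    withr::with_seed(split_seed(seed, 11), sort(sample.int(nf, max_probe_faces)))
  } else seq_len(nf)
  th <- .cpp_face_thickness(region_mesh$vertices, region_mesh$faces,
                            as.integer(probe), as.integer(n_rays),
                            cone_half_deg, as.integer(seed))
  # spread probed thickness over the face graph
  for (it in 1:100) {
    nas <- is.na(th)
    if (!any(nas)) break
    nbv <- matrix(th[ifelse(adj > 0, adj, NA)], nrow = nf)
    fill <- rowMeans(nbv, na.rm = TRUE)
    th[nas & is.finite(fill)] <- fill[nas & is.finite(fill)]
  }
  bad <- !is.finite(th) | th <= 0
  th[bad] <- median(th[!bad])
  lth <- log(th)

  # mixture on a subsample, classification of all faces
  fit_idx <- if (nf > 3000) {
    withr::with_seed(split_seed(seed, 6), sample.int(nf, 3000))
  } else seq_len(nf)
  fit <- suppressWarnings(
    mclust::Mclust(lth[fit_idx], G = 1:max_components, modelNames = "V",
                   verbose = FALSE))
  if (is.null(fit)) {
    cls <- rep(1L, nf)
    means <- mean(lth)
  } else {
    means <- as.numeric(fit$parameters$mean)
    cls <- predict(fit, newdata = lth)$classification
  }
  # merge modes whose thickness ratio is below merge_ratio
  ord <- order(means)
  group <- integer(length(means))
  g <- 0
  last <- -Inf
  for (i in ord) {
    if (means[i] - last > log(merge_ratio)) g <- g + 1
    group[i] <- g
    last <- means[i]
  }
  cls <- group[cls]

  # mode-filter smoothing over face adjacency, then edge-connected splitting
  cls <- .cpp_mode_smooth(adj, as.integer(cls), as.integer(smooth_iters))
  seg <- .cpp_label_face_components(adj, cls)
  # absorb tiny segments into their dominant neighbor
  repeat {
    sizes <- tabulate(seg)
    small <- which(sizes > 0 & sizes < min_faces)
    if (length(small) == 0 || length(unique(seg)) == 1) break
    changed <- FALSE
    for (s in small) {
      faces_s <- which(seg == s)
      nb <- as.vector(adj[faces_s, , drop = FALSE])
      nb_segs <- setdiff(unique(seg[nb[nb > 0]]), s)
      if (length(nb_segs) == 0) next
      seg[faces_s] <- nb_segs[which.max(sizes[nb_segs])]
      changed <- TRUE
    }
    if (!changed) break
  }
  seg <- match(seg, sort(unique(seg)))

  areas <- face_matrix_areas(region_mesh$vertices, region_mesh$faces)
  segments <- tibble::tibble(
    segment = sort(unique(seg)),
    n_faces = as.integer(tabulate(seg)[sort(unique(seg))]),
    area_nm2 = as.numeric(tapply(areas, seg, sum)),
    mean_thickness_nm = as.numeric(tapply(th, seg, mean)))
  structure(list(labels = seg, thickness = th, segments = segments,
                 mesh = region_mesh),
            class = "pss_segmentation")
}

#' @export
print.pss_segmentation <- function(x, ...) {
  cat(sprintf("<pss_segmentation: %d segments over %d faces>\n",
              nrow(x$segments), length(x$labels)))
  print(x$segments)
  invisible(x)
}

#' Extract the postsynaptic shape from a segmented region mesh
#'
#' Identifies the main shaft as the segment with the largest area-weighted
#' thickness (the local-skeleton trunk of the region), then takes the PSS as
#' the union of segments reachable from the synapse-bearing segment without
#' crossing the shaft - a spine head plus neck for spine synapses. When the
#' synapse lands on the shaft itself the PSS is that shaft stretch; for
#' somatic patches the single large segment is returned. If segmentation
#' bookkeeping fails the synapse-bearing segment alone is returned with
#' `attr(mesh, "flagged") = TRUE`.
#'
#' @param region_mesh the synapse region mesh.
#' @param segmentation result of [segment_by_thickness()] on `region_mesh`.
#' @param synapse_location length-3 position (nm).
#' @return A [surface_mesh()]; the PSS always contains the synapse-nearest
#'   vertex.
#' @export
extract_pss <- function(region_mesh, segmentation, synapse_location) {
  seg <- segmentation$labels
  segs <- segmentation$segments
  vd <- sqrt(rowSums(sweep(region_mesh$vertices, 2, synapse_location)^2))
  near_v <- which.min(vd)
  f <- region_mesh$faces
  face_has <- f[, 1] == near_v | f[, 2] == near_v | f[, 3] == near_v
  s0 <- seg[which(face_has)[1]]
  shaft <- segs$segment[which.max(segs$area_nm2 * segs$mean_thickness_nm)]
  if (s0 == shaft || nrow(segs) == 1) {
    return(subset_faces(region_mesh, seg == s0))
  }
  res <- try({
    adj <- face_adjacency(region_mesh)
    # segment adjacency graph, shaft removed
    fid <- rep(seq_len(nrow(adj)), 3)
    nb <- as.vector(adj)
    ok <- nb > 0
    edges <- unique(cbind(seg[fid[ok]], seg[nb[ok]]))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    keep_nodes <- setdiff(segs$segment, shaft)
    g <- igraph::graph_from_data_frame(
      as.data.frame(edges[edges[, 1] %in% keep_nodes &
                            edges[, 2] %in% keep_nodes, , drop = FALSE]),
      directed = FALSE,
      vertices = data.frame(name = keep_nodes))
    comp <- igraph::components(g)
    member <- comp$membership[as.character(keep_nodes)]
    side <- keep_nodes[member == member[match(as.character(s0), names(member))]]
    subset_faces(region_mesh, seg %in% side)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    out <- subset_faces(region_mesh, seg == s0)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  res
}
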