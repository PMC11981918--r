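#' Extract the surface mesh of one label from a volume
#'
#' Contours the binary mask of `label` at the voxel resolution of the volume
#' and keeps the largest connected component, the standard mesh-extraction
#' step for nucleus and soma segmentations.
#'
#' @param vol a [label_volume()].
#' @param label segment id present in the volume.
#' @return A closed, outward-oriented [surface_mesh()] in nm coordinates.
#' @export
mesh_from_label <- function(vol, label) {
  mask <- vol$labels == as.integer(label)
  if (!any(mask)) stop("label ", label, " absent from volume")
  raw <- .cpp_surface_net(as.integer(mask), dim(vol$labels),
                          vol$resolution_nm, vol$offset_nm)
  orient_outward(largest_component(surface_mesh(raw$vertices, raw$faces)))
}

#' Shrink-wrap envelope of a mesh
#'
#' Computes an outer envelope that follows the mesh everywhere except across
#' the mouths of invaginations, which it bridges; the reference surface
#' against which infolding depth is measured. The envelope starts from the
#' radial function of the convex support hull about the mesh centroid and is
#' then relaxed inward like a rubber band: each vertex radius moves toward
#' the mean of its graph neighbors but never below the mesh surface. At
#' convergence the wrap coincides with the mesh over convex regions and
#' spans invagination mouths with a tight membrane. The construction is
#' idempotent and equivariant under rigid motions.
#'
#' @param mesh a [surface_mesh()]; should be closed (the largest component is
#'   taken otherwise).
#' @param relax_iter rubber-band relaxation iterations, default 300.
#' @param support_dirs maximum number of support directions used for the
#'   initial hull radial function.
#' @return A `surface_mesh` with the same connectivity as the input.
#' @export
shrink_wrap <- function(mesh, relax_iter = 300, support_dirs = 4000) {
  if (nrow(mesh$faces) == 0 || mesh_area(mesh) <= 0) {
    stop("cannot wrap a degenerate mesh")
  }
  if (!is_watertight(mesh)) {
    mesh <- largest_component(mesh)
    if (!is_watertight(mesh)) {
      warning("mesh is not closed; wrapping the largest component as-is")
    }
  }
  ctr <- mesh_centroid(mesh)
  rel <- sweep(mesh$vertices, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  dirs <- rel / pmax(r, .Machine$double.eps)
  nv <- nrow(mesh$vertices)

  # radial function of the support hull: along each vertex ray, the nearest
  # intersection with the support half-spaces {x . e <= h(e)}
  keep <- if (nv > support_dirs) {
    as.integer(round(seq(1, nv, length.out = support_dirs)))
  } else seq_len(nv)
  E <- dirs[keep, , drop = FALSE]
  h <- apply(rel %*% t(E), 2, max)  # support function at each direction
  rho <- numeric(nv)
  chunk <- max(1, floor(2e7 / length(keep)))
  for (start in seq(1, nv, by = chunk)) {
    idx <- start:min(start + chunk - 1, nv)
    ce <- dirs[idx, , drop = FALSE] %*% t(E)
    tt <- sweep(1 / pmax(ce, 0.05), 2, h, "*")
    rho[idx] <- pmin(apply(tt, 1, min), max(h) * 20)
  }
  rho <- pmax(rho, r)

  # rubber-band deflation: move toward the neighbor mean, pinned at the mesh
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)], f[, 2:1], f[, 3:2], f[, c(1, 3)])
  nbr_list <- split(e[, 2], e[, 1])
  maxdeg <- max(lengths(nbr_list))
  nbr <- matrix(rep(seq_len(nv), maxdeg), nv, maxdeg)
  for (v in seq_along(nbr_list)) {
    ns <- unique(nbr_list[[v]])
    nbr[as.integer(names(nbr_list)[v]), seq_along(ns)] <- ns
  }
  deg <- rowSums(nbr != matrix(rep(seq_len(nv), maxdeg), nv, maxdeg)) + 1
  for (it in seq_len(relax_iter)) {
    acc <- rho
    for (j in seq_len(maxdeg)) acc <- acc + rho[nbr[, j]]
    avg <- (acc - (maxdeg + 1 - deg) * rho) / deg
    rho <- pmax(r, pmin(rho, avg))
  }
  wrap <- surface_mesh(sweep(dirs * rho, 2, ctr, "+"), mesh$faces)
  attr(wrap, "source_signature") <- mesh_signature(mesh)
  wrap
}

mesh_signature <- function(mesh) {
  c(nrow(mesh$vertices), nrow(mesh$faces),
    round(sum(abs(mesh$vertices))), round(sum(mesh$vertices^2) / 1e6))
}

#' Infolding area from a mesh and its shrink-wrap
#'
#' Per-vertex unsigned distances from the nucleus mesh to the wrap surface
#' are thresholded: a vertex strictly deeper than `threshold_nm` (default
#' 150 nm) lies within an infolding, and a face counts as folded when all
#' three of its vertices do.
#'
#' @param mesh nucleus [surface_mesh()].
#' @param wrap envelope produced by [shrink_wrap()] from `mesh`.
#' @param threshold_nm infolding depth threshold (nm), strict.
#' @return A list with `fold_area_um2`, `fold_fraction` and the per-vertex
#'   `vertex_depth_nm`.
#' @export
fold_features <- function(mesh, wrap, threshold_nm = 150) {
  sig <- attr(wrap, "source_signature")
  if (!is.null(sig) && !isTRUE(all.equal(sig, mesh_signature(mesh)))) {
    stop("wrap was not produced from this mesh")
  }
  d <- .cpp_point_mesh_distance(mesh$vertices, wrap$vertices, wrap$faces)
  folded_v <- d > threshold_nm
  f <- mesh$faces
  folded_face <- folded_v[f[, 1]] & folded_v[f[, 2]] & folded_v[f[, 3]]
  areas <- face_matrix_areas(mesh$vertices, f)
  fold_area <- sum(areas[folded_face])
  list(fold_area_um2 = fold_area / 1e6,
       fold_fraction = fold_area / sum(areas),
       vertex_depth_nm = d)
}

#' Depth reference plane
#'
#' Flat-pia convention: cortical depth is the distance from the pial plane
#' along a named axis.
#'
#' @param axis depth axis, one of "x", "y", "z" (default "y", image-style).
#' @param pia_nm coordinate of the pial surface along that axis (nm).
#' @param direction +1 if depth increases with the coordinate, -1 otherwise.
#' @return A `depth_reference` object.
#' @export
depth_reference <- function(axis = "y", pia_nm = 0, direction = 1) {
  stopifnot(axis %in% c("x", "y", "z"), direction %in% c(-1, 1))
  structure(list(axis = match(axis, c("x", "y", "z")), pia_nm = pia_nm,
                 direction = direction), class = "depth_reference")
}

point_depth_um <- function(ref, point_nm) {
  (point_nm[ref$axis] - ref$pia_nm) * ref$direction / 1000
}

#' The six nucleus features
#'
#' Nucleus volume, surface area, area-to-volume ratio, infolded surface area,
#' infolded area fraction, and cortical depth of the nucleus centroid.
#'
#' @param mesh nucleus [surface_mesh()].
#' @param depth_ref a [depth_reference()].
#' @param wrap optional precomputed [shrink_wrap()] envelope.
#' @param fold_threshold_nm infolding depth threshold (nm).
#' @return One-row tibble with columns `nucleus_volume` (µm^3),
#'   `nucleus_area` (µm^2), `nucleus_area_to_volume` (1/µm),
#'   `nucleus_fold_area` (µm^2), `nucleus_fold_fraction`, `nucleus_depth`
#'   (µm), plus the centroid in nm.
#' @export
nucleus_features <- function(mesh, depth_ref = depth_reference(),
                             wrap = NULL, fold_threshold_nm = 150) {
  area_nm2 <- mesh_area(mesh)
  if (!is.finite(area_nm2) || area_nm2 <= 0) stop("degenerate nucleus mesh")
  vol_nm3 <- abs(mesh_volume(mesh))
  if (is.null(wrap)) wrap <- shrink_wrap(mesh)
  folds <- fold_features(mesh, wrap, fold_threshold_nm)
  ctr <- mesh_centroid(mesh)
  tibble::tibble(
    nucleus_volume = vol_nm3 / 1e9,
    nucleus_area = area_nm2 / 1e6,
    nucleus_area_to_volume = (area_nm2 / 1e6) / (vol_nm3 / 1e9),
    nucleus_fold_area = folds$fold_area_um2,
    nucleus_fold_fraction = folds$fold_fraction,
    nucleus_depth = point_depth_um(depth_ref, ctr),
    centroid_x_nm = ctr[1], centroid_y_nm = ctr[2], centroid_z_nm = ctr[3])
}
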