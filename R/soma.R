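#' Match a nucleus to its surrounding soma segment
#'
#' The soma is the segmentation id occupying more than 80% of the one-voxel
#' shell around the nucleus mask (strict threshold). Returns `NA` when no
#' label reaches the threshold, in which case the cell is excluded
#' downstream.
#'
#' @param cell_vol dense segmentation as a [label_volume()].
#' @param nucleus_mask a [label_volume()] on the same grid whose non-zero
#'   voxels are the nucleus, or a logical/integer array.
#' @param threshold shell occupancy fraction required (strict), default 0.8.
#' @return Integer segment id, or `NA_integer_` if unmatched.
#' @export
match_soma_id <- function(cell_vol, nucleus_mask, threshold = 0.8) {
  mask <- if (inherits(nucleus_mask, "label_volume")) nucleus_mask$labels else nucleus_mask
  stopifnot(all(dim(mask) == dim(cell_vol$labels)))
  m <- as.integer(mask != 0)
  if (!any(m == 1L)) stop("nucleus mask is empty")
  dil <- .cpp_binary_dilate(m, dim(cell_vol$labels), 1L)
  shell <- dil == 1L & m == 0L
  ids <- cell_vol$labels[array(shell, dim(cell_vol$labels))]
  tab <- sort(table(ids), decreasing = TRUE)
  frac <- tab[1] / length(ids)
  if (frac > threshold) as.integer(names(tab)[1]) else NA_integer_
}

#' Cleaned somatic cutout mesh
#'
#' Crops a cube of `radius_um` half-width around the nucleus centroid,
#' binarizes the soma segment, and applies the cleaning sequence: binary
#' dilation by `dilate_voxels`, filling of all cavities, binary erosion by
#' `erode_voxels` (all 6-connected, in voxel units), then contours the mask
#' and keeps the largest connected component. Dilation+fill bridges missing
#' sections; disconnected merged fragments are dropped with the smaller
#' components. Cutouts that extend past the volume border are flagged with
#' `attr(mesh, "truncated")`.
#'
#' @param cell_vol dense segmentation as a [label_volume()].
#' @param soma_id matched segment id.
#' @param nucleus_centroid_nm cutout center (nm).
#' @param radius_um cutout half-width (µm), default 15.
#' @param dilate_voxels,erode_voxels cleaning parameters (voxels), defaults
#'   5 and 3.
#' @return A [surface_mesh()] in nm coordinates.
#' @export
soma_cutout_mesh <- function(cell_vol, soma_id, nucleus_centroid_nm,
                             radius_um = 15, dilate_voxels = 5,
                             erode_voxels = 3) {
  d <- dim(cell_vol$labels)
  lo_raw <- floor((nucleus_centroid_nm - radius_um * 1000 - cell_vol$offset_nm) /
                    cell_vol$resolution_nm) + 1
  hi_raw <- ceiling((nucleus_centroid_nm + radius_um * 1000 - cell_vol$offset_nm) /
                      cell_vol$resolution_nm)
  lo <- pmax(1, lo_raw)
  hi <- pmin(d, hi_raw)
  truncated <- any(lo_raw < 1) || any(hi_raw > d)
  sub <- cell_vol$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mask <- as.integer(sub == as.integer(soma_id))
  if (!any(mask == 1L)) stop("soma id ", soma_id, " absent from the cutout")
  dims <- dim(sub)
  mask <- .cpp_binary_dilate(mask, dims, as.integer(dilate_voxels))
  mask <- .cpp_fill_holes(mask, dims)
  mask <- .cpp_binary_erode(mask, dims, as.integer(erode_voxels))
  offset <- cell_vol$offset_nm + (lo - 1) * cell_vol$resolution_nm
  raw <- .cpp_surface_net(mask, dims, cell_vol$resolution_nm, offset)
  mesh <- orient_outward(largest_component(surface_mesh(raw$vertices, raw$faces)))
  attr(mesh, "truncated") <- truncated
  mesh
}

#' The seven soma features
#'
#' Soma volume, area, area-to-volume ratio, somatic synapse count and
#' density, the nucleus-to-soma volume ratio and the nucleus-soma centroid
#' offset. A synapse is somatic when its post id matches the soma, it lies
#' within `cutout_radius_um` of the nucleus centroid, and it sits within
#' `surface_tol_nm` of the cutout mesh surface.
#'
#' @param soma_mesh cleaned cutout from [soma_cutout_mesh()].
#' @param nucleus_feats one-row tibble from [nucleus_features()].
#' @param synapses a synapse table (see [as_synapse_table()]).
#' @param soma_id segment id of the soma.
#' @param cutout_radius_um somatic cutout radius (µm), default 15.
#' @param surface_tol_nm synapse-to-surface association tolerance (nm),
#'   default 500.
#' @return One-row tibble with columns `soma_volume` (µm^3), `soma_area`
#'   (µm^2), `soma_area_to_volume` (1/µm), `soma_synapse_count`,
#'   `soma_synapse_density` (per µm^2), `nucleus_to_soma_volume_ratio` and
#'   `centroid_offset` (µm).
#' @export
soma_features <- function(soma_mesh, nucleus_feats, synapses, soma_id,
                          cutout_radius_um = 15, surface_tol_nm = 500) {
  area_nm2 <- mesh_area(soma_mesh)
  if (!is.finite(area_nm2) || area_nm2 <= 0) stop("degenerate soma mesh")
  vol_nm3 <- abs(mesh_volume(soma_mesh))
  nuc_ctr <- c(nucleus_feats$centroid_x_nm, nucleus_feats$centroid_y_nm,
               nucleus_feats$centroid_z_nm)
  syn <- as_synapse_table(synapses)
  syn <- syn[syn$post_id == soma_id, , drop = FALSE]
  n_syn <- 0L
  if (nrow(syn) > 0) {
    p <- as.matrix(syn[, c("x_nm", "y_nm", "z_nm")])
    within_r <- sqrt(rowSums(sweep(p, 2, nuc_ctr)^2)) <= cutout_radius_um * 1000
    near_surface <- rep(FALSE, nrow(p))
    if (any(within_r)) {
      dsurf <- .cpp_point_mesh_distance(p[within_r, , drop = FALSE],
                                        soma_mesh$vertices, soma_mesh$faces)
      near_surface[within_r] <- dsurf <= surface_tol_nm
    }
    n_syn <- sum(within_r & near_surface)
  }
  soma_ctr <- mesh_centroid(soma_mesh)
  area_um2 <- area_nm2 / 1e6
  vol_um3 <- vol_nm3 / 1e9
  tibble::tibble(
    soma_volume = vol_um3,
    soma_area = area_um2,
    soma_area_to_volume = area_um2 / vol_um3,
    soma_synapse_count = as.integer(n_syn),
    soma_synapse_density = n_syn / area_um2,
    nucleus_to_soma_volume_ratio = nucleus_feats$nucleus_volume / vol_um3,
    centroid_offset = sqrt(sum((soma_ctr - nuc_ctr)^2)) / 1000)
}
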