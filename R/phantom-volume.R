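#' Voxelized cell phantom: nucleus-in-soma with surface synapses
#'
#' Rasterizes a concentric nucleus/soma sphere pair into labeled voxel
#' volumes (point-in-sphere test at voxel centers), scatters synapses on the
#' soma surface, and optionally plants segmentation defects: error/void
#' voxels (label 0) at a controlled bounding-box fraction, a missing z-slab
#' through the soma (lost sections), and a disconnected fragment carrying the
#' soma label (false merger elsewhere in the volume).
#'
#' @param nucleus_radius_um nucleus radius (µm); must be below
#'   `soma_radius_um`.
#' @param soma_radius_um soma radius (µm).
#' @param n_soma_synapses number of synapses to place on the soma surface.
#' @param error_void_fraction target fraction of label-0 voxels in the
#'   bounding box, in `[0, 1)`; voids are placed outside the soma.
#' @param resolution_nm voxel size, length-3 (nm).
#' @param seed integer seed.
#' @param box_halfwidth_um half-width of the cubic volume (µm); the default
#'   15 matches the somatic cutout radius.
#' @param soma_id,nucleus_id,other_id labels used for the soma segment, the
#'   nucleus, and surrounding tissue.
#' @param gap_z_voxels if positive, a slab of this many voxel planes through
#'   the soma center is relabeled as tissue (simulates missing sections).
#' @param fragment_gap_voxels if positive, plant a small blob with the soma
#'   label separated from the soma surface by this many voxels.
#' @param fragment_radius_voxels radius of the planted fragment, in voxels.
#' @return A list with `cell` and `nucleus` ([label_volume()]s), `synapses`
#'   (a synapse table), `center_nm`, `soma_id` and `nucleus_id`.
#' @export
make_cell_volume <- function(nucleus_radius_um = 5, soma_radius_um = 8,
                             n_soma_synapses = 50,
                             error_void_fraction = 0,
                             resolution_nm = c(128, 128, 80),
                             seed = 1L,
                             box_halfwidth_um = 15,
                             soma_id = 10L, nucleus_id = 1L, other_id = 2L,
                             gap_z_voxels = 0, fragment_gap_voxels = 0,
                             fragment_radius_voxels = 1) {
  stopifnot(soma_radius_um > nucleus_radius_um, all(resolution_nm > 0),
            error_void_fraction >= 0, error_void_fraction < 1)
  if (soma_radius_um > box_halfwidth_um) {
    stop("volume too small to contain the soma")
  }
  half_nm <- box_halfwidth_um * 1000
  dims <- pmax(ceiling(2 * half_nm / resolution_nm), 3)
  center <- dims / 2 * resolution_nm  # box center in nm (offset = 0)
  ax <- lapply(1:3, function(a) {
    ((seq_len(dims[a]) - 0.5) * resolution_nm[a] - center[a])^2
  })
  r2 <- array(0, dims)
  r2 <- r2 + ax[[1]]
  r2 <- r2 + rep(ax[[2]], each = dims[1])
  r2 <- r2 + rep(ax[[3]], each = dims[1] * dims[2])

  soma_mask <- r2 <= (soma_radius_um * 1000)^2
  labs <- array(other_id, dims)
  labs[soma_mask] <- soma_id

  if (gap_z_voxels > 0) {
    kz <- round(dims[3] / 2)
    slab <- kz + seq_len(gap_z_voxels) - ceiling(gap_z_voxels / 2)
    labs[, , slab] <- other_id
  }
  if (fragment_gap_voxels > 0) {
    # blob on the +x axis, separated from the soma surface along x
    gap_nm <- fragment_gap_voxels * resolution_nm[1]
    frag_r_nm <- fragment_radius_voxels * resolution_nm[1]
    fc <- center + c(soma_radius_um * 1000 + gap_nm + frag_r_nm, 0, 0)
    fx <- ((seq_len(dims[1]) - 0.5) * resolution_nm[1] - fc[1])^2
    f2 <- array(0, dims)
    f2 <- f2 + fx
    f2 <- f2 + rep(ax[[2]], each = dims[1])
    f2 <- f2 + rep(ax[[3]], each = dims[1] * dims[2])
    labs[f2 <= frag_r_nm^2] <- soma_id
  }

  withr::with_seed(split_seed(seed, 2), {
    if (error_void_fraction > 0) {
      n_void <- round(error_void_fraction * prod(dims))
      bg <- which(labs == other_id)
      if (n_void > length(bg)) {
        stop("error_void_fraction too large for the non-soma volume")
      }
      labs[sample(bg, n_void)] <- 0L
    }
    dirs <- matrix(rnorm(3 * n_soma_synapses), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pos <- sweep(dirs * soma_radius_um * 1000, 2, center, "+")
    synapses <- tibble::tibble(
      pre_id = 1000L + seq_len(n_soma_synapses),
      post_id = as.integer(soma_id),
      x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3],
      size_vx = pmax(1L, as.integer(round(exp(rnorm(n_soma_synapses, 5, 0.5))))))
  })
  if (n_soma_synapses == 0) {
    synapses <- tibble::tibble(pre_id = integer(), post_id = integer(),
                               x_nm = numeric(), y_nm = numeric(),
                               z_nm = numeric(), size_vx = integer())
  }

  nuc <- array(0L, dims)
  nuc[r2 <= (nucleus_radius_um * 1000)^2] <- nucleus_id

  list(cell = label_volume(labs, resolution_nm),
       nucleus = label_volume(nuc, resolution_nm),
       synapses = as_synapse_table(synapses),
       center_nm = center, soma_id = as.integer(soma_id),
       nucleus_id = as.integer(nucleus_id))
}

#' Fraction of error/void voxels around a nucleus
#'
#' Fraction of label-0 voxels in the cubic bounding box of the stated
#' half-width around a center point; the quantity thresholded by the object
#' filter (cells with more than 20% void context are dropped).
#'
#' @param vol a [label_volume()].
#' @param center_nm box center (nm).
#' @param halfwidth_um box half-width (µm), default 15.
#' @return Fraction in `[0, 1]`.
#' @export
bbox_error_fraction <- function(vol, center_nm, halfwidth_um = 15) {
  d <- dim(vol$labels)
  lo <- pmax(1, floor((center_nm - halfwidth_um * 1000 - vol$offset_nm) /
                        vol$resolution_nm) + 1)
  hi <- pmin(d, ceiling((center_nm + halfwidth_um * 1000 - vol$offset_nm) /
                          vol$resolution_nm))
  sub <- vol$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  mean(sub == 0L)
}
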