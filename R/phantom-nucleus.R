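#' Nucleus phantom with analytically known infolding fraction
#'
#' Builds a spherical nucleus mesh with `n_folds` crater-shaped
#' invaginations: each fold displaces the surface radially inward by
#' `fold_depth_nm` over a flat floor, with steep logistic walls
#' (`delta(theta) = depth * plogis((theta0 - theta) / w)`). The floor
#' half-angle is solved so that the surface fraction displaced deeper than
#' `detection_depth_nm` equals `fold_area_fraction / n_folds` per fold. A
#' crater profile (rather than a smooth dimple) is used because an
#' invagination must be genuinely concave for any envelope to span its
#' mouth: a depression shallower than its own spherical sagitta is still a
#' convex surface and has no measurable infolding.
#'
#' The floor angle is calibrated (by bisection on the generated mesh) so
#' that the detected area fraction of the deformed surface matches the
#' request, and the returned `true_fold_fraction` is the exact area fraction
#' of mesh faces whose vertices are displaced beyond the detection depth -
#' an analytic oracle for infolding quantification that is independent of
#' any envelope construction.
#'
#' @param radius_um nucleus radius in micrometres.
#' @param n_folds number of invaginations.
#' @param fold_depth_nm inward displacement of each fold floor (nm).
#' @param fold_area_fraction target total fraction of surface area displaced
#'   deeper than `detection_depth_nm`, in `[0, 1]`.
#' @param mesh_resolution_nm approximate target edge length of the mesh (nm).
#' @param seed integer seed; the same spec and seed give identical meshes.
#' @param detection_depth_nm depth defining "inside a fold" for the analytic
#'   ground truth (default 150 nm, the infolding detection depth).
#' @return A list with elements `mesh` (a [surface_mesh()]),
#'   `true_fold_fraction`, and `fold_centers` (unit directions).
#' @export
make_nucleus_phantom <- function(radius_um = 5, n_folds = 0,
                                 fold_depth_nm = 500,
                                 fold_area_fraction = 0,
                                 mesh_resolution_nm = 200,
                                 seed = 1L,
                                 detection_depth_nm = 150) {
  stopifnot(radius_um > 0, n_folds >= 0,
            fold_area_fraction >= 0, fold_area_fraction <= 1)
  r_nm <- radius_um * 1000
  subdiv <- max(2, min(6, ceiling(log2(r_nm * 1.0514 / mesh_resolution_nm))))
  sphere <- icosphere(subdiv)
  v_unit <- sphere$vertices
  centers <- matrix(numeric(0), 0, 3)
  delta <- rep(0, nrow(v_unit))
  detected <- function(d) {
    # area fraction of the deformed mesh displaced beyond the detection
    # depth (face counted when all three vertices are displaced)
    verts <- v_unit * (r_nm - d)
    fa <- face_matrix_areas(verts, sphere$faces)
    fv <- d > detection_depth_nm
    f <- sphere$faces
    sum(fa[fv[f[, 1]] & fv[f[, 2]] & fv[f[, 3]]]) / sum(fa)
  }
  if (n_folds > 0 && fold_area_fraction > 0) {
    centers <- fold_directions(n_folds, seed)
    per_fold <- fold_area_fraction / n_folds
    theta_t <- acos(1 - 2 * per_fold)
    # near-step walls (a tenth of an edge wide): a smooth wall leaves a
    # convex upper-wall band that sits on the envelope and is never
    # measurable
    wall <- (1.0514 / 2^subdiv) / 10
    ang <- acos(pmin(pmax(v_unit %*% t(centers), -1), 1))  # nv x n_folds
    deform <- function(t0) {
      d <- rowSums(fold_depth_nm * stats::plogis((t0 - ang) / wall))
      pmin(d, 0.8 * r_nm)
    }
    if (fold_depth_nm > detection_depth_nm) {
      mouth <- theta_t + 3 * wall
      sagitta <- r_nm * (1 - cos(mouth))
      if (fold_depth_nm < sagitta + 1.5 * detection_depth_nm) {
        warning("fold depth ", fold_depth_nm, " nm is shallow against the ",
                "fold mouth sagitta (", round(sagitta), " nm); pockets this ",
                "wide are barely concave and envelope-based infolding ",
                "measurements will under-read them")
      }
      # calibrate the floor angle so the detected fraction hits the request
      lo <- 0.1 * theta_t
      hi <- min(2 * theta_t + 3 * wall, pi / 2.5)
      for (it in 1:24) {
        mid <- (lo + hi) / 2
        if (detected(deform(mid)) < fold_area_fraction) lo <- mid else hi <- mid
      }
      delta <- deform((lo + hi) / 2)
    } else {
      delta <- deform(theta_t)
    }
  }
  verts <- v_unit * (r_nm - delta)
  mesh <- surface_mesh(verts, sphere$faces)
  if (!is_watertight(mesh)) stop("phantom generation produced an open mesh")
  list(mesh = mesh, true_fold_fraction = detected(delta),
       fold_centers = centers)
}

# well-separated unit fold directions: a seeded random rotation of an
# octahedral (n <= 6) or icosahedral (n <= 12) / subdivided (n <= 32) frame
fold_directions <- function(n, seed) {
  base <- if (n <= 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1),
          c(0, 0, -1))
  } else if (n <= 12) {
    icosphere(0)$vertices
  } else if (n <= 32) {
    icosphere(1)$vertices
  } else {
    stop("at most 32 folds are supported")
  }
  rot <- withr::with_seed(split_seed(seed, 1), {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
  base[seq_len(n), , drop = FALSE] %*% rot
}

#' Check that a mesh is closed
#'
#' A mesh is watertight here if every undirected edge is shared by exactly
#' two faces with opposite orientation.
#'
#' @param mesh a [surface_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  rkey <- paste(he[, 2], he[, 1])
  !anyDuplicated(key) && all(key %in% rkey)
}
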