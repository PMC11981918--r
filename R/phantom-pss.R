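#' Postsynaptic-shape phantom meshes
#'
#' Generates watertight phantom meshes for the three canonical postsynaptic
#' compartment shapes, each with its synapse location and ground-truth class:
#'
#' * `spine` - a thin-necked head (head diameter 440 nm, neck diameter
#'   120 nm) sitting on a dendritic shaft (capsule, diameter 900 nm), with
#'   the synapse on the head apex;
#' * `shaft` - the bare dendritic capsule with the synapse on its side;
#' * `soma_patch` - a large sphere (radius 2.2 µm) standing in for a patch of
#'   somatic membrane, synapse on the surface.
#'
#' Shapes are rasterized from their implicit union and contoured, so each
#' mesh is a single closed component, and every mesh fits a 3,500-nm synapse
#' region cutout. A mild per-instance size jitter (+/-10%) makes corpora
#' non-degenerate for embedding and clustering.
#'
#' @param class_mix named integer vector or list, e.g.
#'   `c(spine = 5, shaft = 2, soma_patch = 1)`.
#' @param seed integer seed.
#' @param jitter relative size jitter per instance (default 0.1).
#' @return A list of records, each with `mesh`, `true_class` and
#'   `synapse_point` (nm).
#' @export
make_pss_phantoms <- function(class_mix, seed = 1L, jitter = 0.1) {
  class_mix <- unlist(class_mix)
  stopifnot(all(class_mix >= 0))
  bad <- setdiff(names(class_mix), c("spine", "shaft", "soma_patch"))
  if (length(bad) > 0) stop("unknown phantom class: ", paste(bad, collapse = ", "))
  out <- list()
  idx <- 0
  for (cls in names(class_mix)) {
    for (i in seq_len(class_mix[[cls]])) {
      idx <- idx + 1
      s <- split_seed(seed, idx * 13 + match(cls, c("spine", "shaft", "soma_patch")))
      g <- withr::with_seed(s, 1 + runif(1, -jitter, jitter))
      out[[idx]] <- switch(cls,
        spine = pss_spine_phantom(g),
        shaft = pss_shaft_phantom(g),
        soma_patch = pss_soma_patch_phantom(g))
      out[[idx]]$true_class <- cls
    }
  }
  out
}

# rasterize an implicit inside() predicate over a voxel grid and contour it
mesh_from_implicit <- function(inside_fn, lo_nm, hi_nm, voxel_nm) {
  dims <- pmax(ceiling((hi_nm - lo_nm) / voxel_nm), 2)
  ax <- lapply(1:3, function(a) lo_nm[a] + (seq_len(dims[a]) - 0.5) * voxel_nm)
  pts <- cbind(rep(ax[[1]], times = dims[2] * dims[3]),
               rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
               rep(ax[[3]], each = dims[1] * dims[2]))
  mask <- array(as.integer(inside_fn(pts)), dims)
  raw <- .cpp_surface_net(as.vector(mask), dims, rep(voxel_nm, 3), lo_nm)
  orient_outward(largest_component(surface_mesh(raw$vertices, raw$faces)))
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  t <- pmin(pmax((sweep(p, 2, a) %*% ab) / sum(ab^2), 0), 1)
  q <- sweep(drop(t) %o% ab, 2, a, "+")
  sqrt(rowSums((p - q)^2))
}

pss_spine_phantom <- function(g = 1) {
  shaft_r <- 450 * g
  neck_r <- 60 * g
  head_r <- 220 * g
  neck_top <- shaft_r + 500 * g
  head_c <- c(0, 0, neck_top + head_r - 40 * g)
  inside <- function(p) {
    shaft <- dist_point_segment(p, c(-1600 * g, 0, 0), c(1600 * g, 0, 0)) <= shaft_r
    neck <- dist_point_segment(p, c(0, 0, 0), c(0, 0, neck_top)) <= neck_r
    head <- sqrt(rowSums(sweep(p, 2, head_c)^2)) <= head_r
    shaft | neck | head
  }
  pad <- 120
  lo <- c(-1600 * g - shaft_r - pad, -shaft_r - pad, -shaft_r - pad)
  hi <- c(1600 * g + shaft_r + pad, shaft_r + pad, head_c[3] + head_r + pad)
  list(mesh = mesh_from_implicit(inside, lo, hi, 30),
       synapse_point = c(0, 0, head_c[3] + head_r),
       head_center = head_c,
       nominal = list(shaft_r = shaft_r, neck_r = neck_r, head_r = head_r,
                      neck_top = neck_top))
}

pss_shaft_phantom <- function(g = 1) {
  shaft_r <- 450 * g
  inside <- function(p) {
    dist_point_segment(p, c(-1600 * g, 0, 0), c(1600 * g, 0, 0)) <= shaft_r
  }
  pad <- 120
  lo <- c(-1600 * g - shaft_r - pad, -shaft_r - pad, -shaft_r - pad)
  hi <- -lo
  list(mesh = mesh_from_implicit(inside, lo, hi, 40),
       synapse_point = c(0, 0, shaft_r))
}

pss_soma_patch_phantom <- function(g = 1) {
  r <- 2200 * g
  inside <- function(p) sqrt(rowSums(p^2)) <= r
  pad <- 150
  lo <- rep(-r - pad, 3)
  hi <- -lo
  list(mesh = mesh_from_implicit(inside, lo, hi, 80),
       synapse_point = c(0, 0, r))
}
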