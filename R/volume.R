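#' Labeled voxel volumes
#'
#' A `label_volume` wraps a 3-D integer array of segment labels together with
#' the voxel resolution (nm per voxel along x, y, z) and the spatial offset of
#' the array origin (nm). The coordinate of the center of voxel
#' `(i, j, k)` (1-based) is `offset + (c(i, j, k) - 0.5) * resolution`.
#' Label 0 is reserved for error/void voxels.
#'
#' @param labels 3-D integer array of segment ids.
#' @param resolution_nm numeric length-3, nm per voxel.
#' @param offset_nm numeric length-3, nm position of the array origin.
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, resolution_nm, offset_nm = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3, length(resolution_nm) == 3,
            all(resolution_nm > 0), length(offset_nm) == 3)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels,
                 resolution_nm = as.numeric(resolution_nm),
                 offset_nm = as.numeric(offset_nm)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume: %s voxels at %s nm, %d labels>\n",
              paste(dim(x$labels), collapse = "x"),
              paste(x$resolution_nm, collapse = "x"),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

# nm coordinates of the centers of the voxels selected by a logical/array index
voxel_centers <- function(vol, which_idx) {
  d <- dim(vol$labels)
  idx <- which_idx - 1L
  i <- idx %% d[1]
  j <- (idx %/% d[1]) %% d[2]
  k <- idx %/% (d[1] * d[2])
  cbind(vol$offset_nm[1] + (i + 0.5) * vol$resolution_nm[1],
        vol$offset_nm[2] + (j + 0.5) * vol$resolution_nm[2],
        vol$offset_nm[3] + (k + 0.5) * vol$resolution_nm[3])
}

#' Read and write label volumes
#'
#' Volumes are stored as a gzipped little-endian stream of 32-bit labels with
#' a JSON sidecar (`<path>.json`) recording dimensions, resolution and offset.
#'
#' @param vol a [label_volume()].
#' @param path file path for the voxel stream.
#' @return `write_label_volume()` returns `path` invisibly;
#'   `read_label_volume()` returns a `label_volume`.
#' @export
write_label_volume <- function(vol, path) {
  meta <- list(dim = dim(vol$labels), resolution_nm = vol$resolution_nm,
               offset_nm = vol$offset_nm)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(vol$labels), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  n <- prod(meta$dim)
  labs <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  label_volume(array(labs, dim = meta$dim), meta$resolution_nm, meta$offset_nm)
}

#' Synapse tables
#'
#' Validates and normalizes a synapse table to the canonical columns
#' `pre_id`, `post_id`, `x_nm`, `y_nm`, `z_nm`, `size_vx`, plus an optional
#' `synapse_id`.
#'
#' @param x a data frame with the columns above.
#' @return A tibble with canonical column order.
#' @export
as_synapse_table <- function(x) {
  required <- c("pre_id", "post_id", "x_nm", "y_nm", "z_nm", "size_vx")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("synapse table is missing columns: ", paste(missing, collapse = ", "))
  }
  x <- tibble::as_tibble(x)
  if (!"synapse_id" %in% names(x)) {
    x$synapse_id <- seq_len(nrow(x))
  }
  dplyr::select(x, "synapse_id", dplyr::all_of(required), dplyr::everything())
}

#' @rdname as_synapse_table
#' @param path CSV file path.
#' @export
read_synapse_table <- function(path) {
  as_synapse_table(read.csv(path))
}

#' @rdname as_synapse_table
#' @param synapses a synapse table.
#' @export
write_synapse_table <- function(synapses, path) {
  write.csv(as_synapse_table(synapses), path, row.names = FALSE)
  invisible(path)
}
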