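#' Cell-type taxonomy for the hierarchical cascade
#'
#' The routing tree used by the five-model cascade:
#'
#' * level 1 (object model): `neuron`, `non-neuron`, `error`
#' * non-neuronal subclasses: `astrocyte`, `microglia`, `oligodendrocyte`,
#'   `OPC`, `pericyte`
#' * neuron classes: `excitatory`, `inhibitory`
#' * excitatory subclasses: `23P`, `4P`, `5P-IT`, `5P-ET`, `5P-NP`, `6P-IT`,
#'   `6P-CT`
#' * inhibitory subclasses: `BC` (basket), `BPC` (bipolar), `MC`
#'   (Martinotti/non-Martinotti), `NGC` (neurogliaform)
#'
#' @return A `perisoma_taxonomy` object: a list with `children` (the routing
#'   graph), `leaves` and `leaf_path` (leaf to root-path lookup).
#' @export
cell_taxonomy <- function() {
  children <- list(
    root = c("neuron", "non-neuron", "error"),
    `non-neuron` = c("astrocyte", "microglia", "oligodendrocyte", "OPC", "pericyte"),
    neuron = c("excitatory", "inhibitory"),
    excitatory = c("23P", "4P", "5P-IT", "5P-ET", "5P-NP", "6P-IT", "6P-CT"),
    inhibitory = c("BC", "BPC", "MC", "NGC"))
  all_nodes <- unique(c("root", unlist(children)))
  leaves <- setdiff(all_nodes, names(children))
  leaf_path <- lapply(setNames(leaves, leaves), function(leaf) {
    path <- leaf
    repeat {
      parent <- names(children)[vapply(children, function(ch) path[1] %in% ch, logical(1))]
      if (length(parent) == 0) break
      path <- c(parent, path)
    }
    path
  })
  structure(list(children = children, leaves = leaves, leaf_path = leaf_path),
            class = "perisoma_taxonomy")
}

#' @export
print.perisoma_taxonomy <- function(x, ...) {
  cat("<perisoma_taxonomy>\n")
  for (parent in names(x$children)) {
    cat(" ", parent, "->", paste(x$children[[parent]], collapse = ", "), "\n")
  }
  invisible(x)
}

# label of `leaf` at the level directly below `node`, or NA if not under it
level_label <- function(taxonomy, leaf, node) {
  path <- taxonomy$leaf_path[[leaf]]
  if (is.null(path)) stop("label outside taxonomy: ", leaf)
  pos <- match(node, path)
  if (is.na(pos) || pos == length(path)) NA_character_ else path[pos + 1]
}

#' Names of the 13 perisomatic scalar features
#'
#' Six nucleus features followed by seven soma features, the column order
#' used by assembled feature tables.
#'
#' @return Character vector of length 13.
#' @export
perisomatic_feature_names <- function() {
  c("nucleus_volume", "nucleus_area", "nucleus_area_to_volume",
    "nucleus_fold_area", "nucleus_fold_fraction", "nucleus_depth",
    "soma_volume", "soma_area", "soma_area_to_volume",
    "soma_synapse_count", "soma_synapse_density",
    "nucleus_to_soma_volume_ratio", "centroid_offset")
}
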