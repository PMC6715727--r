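#' Write a synapse table as SONATA-style edge files
#'
#' Writes one tab-separated edge table with the SONATA edge-group column
#' layout (`source_node_id`, `target_node_id`, `segment_id`,
#' `offset`, `x`, `y`, `z`, `projection`), a JSON sidecar with counts and
#' provenance, and one MatrixMarket sparse neuron-by-neuron connection
#' matrix per target region (entry = synapse count). The round trip
#' through [read_edge_output()] is lossless.
#'
#' @param table a `synapse_table` (needs `source_neuron`,
#'   `target_neuron`, `segment_id`, `offset`, `x`, `y`, `z`; `region` for
#'   the per-region matrices; optional `projection`).
#' @param dir output directory (created).
#' @param n_neurons total neuron count (matrix dimension); default the
#'   max neuron id present.
#' @return invisibly, the paths written.
#' @export
write_edge_output <- function(table, dir, n_neurons = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(table$projection)) {
    table$projection <- rep("proj", nrow(table))
  }
  edges <- data.frame(
    source_node_id = table$source_neuron,
    target_node_id = table$target_neuron,
    segment_id = table$segment_id,
    offset = table$offset,
    x = table$x, y = table$y, z = table$z,
    projection = table$projection)
  edge_path <- file.path(dir, "edges.tsv")
  utils::write.table(edges, edge_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (is.null(n_neurons)) {
    n_neurons <- max(0, table$source_neuron, table$target_neuron)
  }
  paths <- edge_path
  for (r in sort(unique(table$region))) {
    sub <- table[table$region == r, , drop = FALSE]
    m <- Matrix::sparseMatrix(i = sub$source_neuron, j = sub$target_neuron,
                              x = 1, dims = c(n_neurons, n_neurons))
    p <- file.path(dir, sprintf("connectivity_region_%s.mtx", r))
    Matrix::writeMM(m, p)
    paths <- c(paths, p)
  }
  meta <- list(n_edges = nrow(edges), n_neurons = n_neurons,
               regions = sort(unique(table$region)),
               columns = names(edges))
  meta_path <- file.path(dir, "edges.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta_path))
}

#' @rdname write_edge_output
#' @export
read_edge_output <- function(dir) {
  edges <- utils::read.table(file.path(dir, "edges.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "edges.json"),
                              simplifyVector = TRUE)
  mats <- list()
  for (r in meta$regions) {
    p <- file.path(dir, sprintf("connectivity_region_%s.mtx", r))
    if (file.exists(p)) mats[[as.character(r)]] <- Matrix::readMM(p)
  }
  list(edges = edges, meta = meta, matrices = mats)
}
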