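#' Build the spot adjacency graph
#'
#' Connects grid-adjacent (rook neighbourhood) spots within each array;
#' no edges cross arrays. The graph drives the intrinsic conditional
#' autoregressive (ICAR) spatial prior and the neighborhood enrichment
#' permutations.
#'
#' @param ds A `spatial_dataset` whose spots carry integer `row`/`col`
#'   coordinates and `array_id`.
#' @return A `spot_graph`: list with `edges` (two-column integer matrix of
#'   spot indices, `from < to`), `n` spots, and the spot/array bookkeeping
#'   needed downstream.
#' @export
build_spot_graph <- function(ds) {
  stopifnot(inherits(ds, "spatial_dataset"))
  sm <- ds$spot_meta
  key <- paste(sm$array_id, sm$row, sm$col)
  if (anyDuplicated(key)) {
    abort("duplicate grid coordinates within an array")
  }
  pos <- setNames(seq_len(nrow(sm)), key)
  from <- integer(0); to <- integer(0)
  for (d in list(c(0, 1), c(1, 0))) {
    nb <- paste(sm$array_id, sm$row + d[1], sm$col + d[2])
    hit <- which(nb %in% names(pos))
    from <- c(from, hit)
    to <- c(to, unname(pos[nb[hit]]))
  }
  edges <- cbind(pmin(from, to), pmax(from, to))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(
    list(edges = edges, n = nrow(sm), array_id = sm$array_id,
         spot_id = sm$spot_id),
    class = "spot_graph"
  )
}

#' @export
print.spot_graph <- function(x, ...) {
  cat("<spot_graph> ", x$n, " spots, ", nrow(x$edges), " edges, ",
      length(unique(x$array_id)), " arrays\n", sep = "")
  invisible(x)
}

# sparse symmetric adjacency from a spot_graph
graph_adjacency <- function(graph) {
  e <- graph$edges
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(graph$n, graph$n))
}

# proper vertex colouring so the ICAR field can be updated in parallel
# blocks (no two neighbours share a colour); grids are 2-colourable
graph_coloring <- function(graph) {
  adj <- lapply(seq_len(graph$n), function(i) integer(0))
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  color <- integer(graph$n)
  for (v in seq_len(graph$n)) {
    used <- color[adj[[v]]]
    color[v] <- min(setdiff(seq_len(max(used, 0) + 1L), used))
  }
  color
}
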