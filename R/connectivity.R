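#' Extract core habitat nodes from a land-cover raster
#'
#' Wetland cells are masked, labelled into 8-connected components, and a
#' component is retained as a core node when its area strictly exceeds
#' `min_area` and it contains at least one occurrence record (point-in-cell
#' test). These occupied patches are the endpoints of the least-cost-path
#' analysis.
#'
#' @param raster a categorical [raster_grid()].
#' @param occurrences data frame with columns `x`, `y` (all available
#'   occurrence records, road encounters plus wetland occupancy records).
#' @param min_area minimum patch area in m^2, exclusive (default 10000 = 1 ha).
#' @param codes wetland class codes (default [wetland_codes()]).
#' @return A tibble of core nodes: `node_id`, `area`, `n_cells`, `cells`
#'   (list-column), `n_records`.
#' @export
extract_core_nodes <- function(raster, occurrences, min_area = 10000,
                               codes = wetland_codes()) {
  patches <- wetland_patches(raster, codes = codes)
  if (nrow(patches) == 0) return(empty_nodes())
  occurrences <- tibble::as_tibble(occurrences)
  occ_rc <- coord_to_cell(raster, occurrences$x, occurrences$y)
  occ_key <- paste(occ_rc[, 1], occ_rc[, 2])
  n_rec <- purrr::map_int(patches$cells, function(cells) {
    sum(occ_key %in% paste(cells[, 1], cells[, 2]))
  })
  keep <- patches$area > min_area & n_rec > 0
  nodes <- patches[keep, c("area", "n_cells", "cells")]
  if (nrow(nodes) == 0) return(empty_nodes())
  nodes$n_records <- n_rec[keep]
  nodes$node_id <- seq_len(nrow(nodes))
  dplyr::relocate(nodes, "node_id")
}

empty_nodes <- function() {
  tibble::tibble(node_id = integer(), area = numeric(), n_cells = integer(),
                 cells = list(), n_records = integer())
}

# Build the 8-connected lattice graph of a resistance raster. Edge weight
# between adjacent cells a, b = (r_a + r_b) / 2 * cell_size * (sqrt(2) if
# diagonal). Nodata cells are isolated (impassable).
resistance_graph <- function(resistance) {
  stopifnot(inherits(resistance, "raster_grid"))
  v <- resistance$values
  if (any(v < 0, na.rm = TRUE)) stop("negative resistance", call. = FALSE)
  nr <- nrow(v); nc <- ncol(v); cs <- resistance$cell_size
  idx <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list(); weights <- list()
  offs <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(-1, 1, sqrt(2)))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]; fac <- o[3]
    if (max(1, 1 - dr) > min(nr, nr - dr) ||
        max(1, 1 - dc) > min(nc, nc - dc)) next
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cls <- max(1, 1 - dc):min(nc, nc - dc)
    from <- idx[rs, cls, drop = FALSE]
    to <- idx[rs + dr, cls + dc, drop = FALSE]
    wa <- v[rs, cls, drop = FALSE]; wb <- v[rs + dr, cls + dc, drop = FALSE]
    ok <- !is.na(wa) & !is.na(wb)
    edges[[length(edges) + 1L]] <- rbind(from[ok], to[ok])
    weights[[length(weights) + 1L]] <- (wa[ok] + wb[ok]) / 2 * cs * fac
  }
  el <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(el))
  igraph::E(g)$weight <- unlist(weights)
  list(g = g, nr = nr, nc = nc)
}

cells_to_index <- function(cells, nr) (cells[, 2] - 1L) * nr + cells[, 1]

#' Cost-weighted distance raster
#'
#' Accumulated least-cost distance (Dijkstra over the 8-connected cell graph)
#' from a set of source cells over a resistance surface. Moving between
#' adjacent cells costs the mean of their resistances times the cell size
#' (times sqrt(2) diagonally). Nodata cells are impassable; unreachable cells
#' are `Inf`.
#'
#' @param resistance a [raster_grid()] of nonnegative resistance values.
#' @param sources matrix of source cells (columns row, col).
#' @param graph optional prebuilt graph from repeated calls (internal reuse).
#' @return A [raster_grid()] of accumulated cost (0 at sources).
#' @export
cost_distance <- function(resistance, sources, graph = NULL) {
  if (is.null(graph)) graph <- resistance_graph(resistance)
  src <- cells_to_index(sources, graph$nr)
  if (all(is.na(resistance$values[sources]))) {
    stop("all source cells are nodata", call. = FALSE)
  }
  src <- src[!is.na(resistance$values[sources])]
  d <- igraph::distances(graph$g, v = src, algorithm = "dijkstra")
  acc <- apply(d, 2, min)
  out <- resistance
  out$values <- matrix(acc, graph$nr, graph$nc)
  out$values[is.na(resistance$values)] <- NA
  out
}

#' Least-cost path between two core nodes
#'
#' Multi-source/multi-target Dijkstra: the minimal-cost cell path between any
#' cell of node A and any cell of node B, realized by attaching zero-weight
#' virtual terminals to each cell set. Returns the cell-center polyline, the
#' total cost-weighted distance, and the Euclidean path length.
#'
#' @param resistance a [raster_grid()] of nonnegative resistances.
#' @param cells_a,cells_b matrices of member cells (columns row, col).
#' @param graph optional prebuilt graph (internal reuse).
#' @return A list: `path` (n x 2 coordinate matrix), `cells` (row/col matrix),
#'   `cost`, `length`.
#' @export
least_cost_path <- function(resistance, cells_a, cells_b, graph = NULL) {
  if (is.null(graph)) graph <- resistance_graph(resistance)
  n <- graph$nr * graph$nc
  ia <- cells_to_index(cells_a, graph$nr)
  ib <- cells_to_index(cells_b, graph$nr)
  g2 <- igraph::add_vertices(graph$g, 2)
  va <- n + 1L; vb <- n + 2L
  new_edges <- c(rbind(va, ia), rbind(vb, ib))
  g2 <- igraph::add_edges(g2, new_edges,
                          attr = list(weight = rep(0, length(ia) + length(ib))))
  sp <- igraph::shortest_paths(g2, from = va, to = vb, mode = "all",
                               output = "both")
  vpath <- as.integer(sp$vpath[[1]])
  if (length(vpath) == 0) {
    return(list(path = NULL, cells = NULL, cost = Inf, length = NA_real_))
  }
  cost <- sum(igraph::E(g2)$weight[as.integer(sp$epath[[1]])])
  cells_idx <- setdiff(vpath, c(va, vb))
  rows <- ((cells_idx - 1L) %% graph$nr) + 1L
  cols <- ((cells_idx - 1L) %/% graph$nr) + 1L
  path <- cell_center(resistance, rows, cols)
  len <- if (nrow(path) > 1) polyline_length(path) else 0
  list(path = path, cells = cbind(row = rows, col = cols),
       cost = cost, length = len)
}

#' Select node pairs by cost-weighted Voronoi adjacency
#'
#' Runs a multi-source cost-distance from every node simultaneously and
#' allocates each reachable cell to its cost-nearest node (ties to the lower
#' `node_id`). Two nodes are paired when their allocation regions share a
#' cell edge — the cost-weighted nearest-neighbor graph used to decide which
#' node pairs get a least-cost path.
#'
#' @param nodes a core-node tibble from [extract_core_nodes()].
#' @param resistance a [raster_grid()] of resistances.
#' @param graph optional prebuilt graph (internal reuse).
#' @return A tibble of pairs: `node_a`, `node_b` (node_a < node_b). The cell
#'   allocation matrix is attached as attribute `allocation`; unreachable
#'   nodes are reported in attribute `unreached`.
#' @export
select_pairs <- function(nodes, resistance, graph = NULL) {
  if (is.null(graph)) graph <- resistance_graph(resistance)
  k <- nrow(nodes)
  if (k < 2) {
    out <- tibble::tibble(node_a = integer(), node_b = integer())
    attr(out, "allocation") <- NULL
    return(out)
  }
  n <- graph$nr * graph$nc
  g2 <- igraph::add_vertices(graph$g, k)
  new_edges <- integer(0)
  for (i in seq_len(k)) {
    idx <- cells_to_index(nodes$cells[[i]], graph$nr)
    new_edges <- c(new_edges, rbind(n + i, idx))
  }
  g2 <- igraph::add_edges(g2, new_edges,
                          attr = list(weight = rep(0, length(new_edges) / 2)))
  d <- igraph::distances(g2, v = n + seq_len(k), to = seq_len(n),
                         algorithm = "dijkstra")
  reachable <- apply(d, 2, function(col) any(is.finite(col)))
  alloc_vec <- rep(0L, n)
  alloc_vec[reachable] <- apply(d[, reachable, drop = FALSE], 2, which.min)
  alloc <- matrix(alloc_vec, graph$nr, graph$nc)
  pairs <- list()
  for (shift in list(c(1, 0), c(0, 1))) {
    a <- alloc[seq_len(graph$nr - shift[1]), seq_len(graph$nc - shift[2])]
    b <- alloc[(1 + shift[1]):graph$nr, (1 + shift[2]):graph$nc]
    touch <- a > 0 & b > 0 & a != b
    if (any(touch)) {
      pairs[[length(pairs) + 1L]] <- cbind(pmin(a[touch], b[touch]),
                                           pmax(a[touch], b[touch]))
    }
  }
  pr <- if (length(pairs) > 0) unique(do.call(rbind, pairs)) else
    matrix(integer(0), ncol = 2)
  out <- tibble::tibble(node_a = nodes$node_id[pr[, 1]],
                        node_b = nodes$node_id[pr[, 2]])
  out <- dplyr::arrange(out, .data$node_a, .data$node_b)
  attr(out, "allocation") <- alloc
  attr(out, "unreached") <- nodes$node_id[vapply(seq_len(k), function(i) {
    !any(alloc == i)
  }, logical(1))]
  out
}

#' Corridor (cost-surface) raster for a node pair
#'
#' `CWD_a + CWD_b - LCP_cost` per cell: zero exactly on optimal paths between
#' the nodes, increasing with the detour cost a route through that cell would
#' incur. This is the display surface for movement corridors.
#'
#' @inheritParams least_cost_path
#' @return A [raster_grid()] of corridor values (>= 0).
#' @export
corridor_raster <- function(resistance, cells_a, cells_b, graph = NULL) {
  if (is.null(graph)) graph <- resistance_graph(resistance)
  cwd_a <- cost_distance(resistance, cells_a, graph = graph)
  cwd_b <- cost_distance(resistance, cells_b, graph = graph)
  lcp <- least_cost_path(resistance, cells_a, cells_b, graph = graph)
  out <- resistance
  out$values <- cwd_a$values + cwd_b$values - lcp$cost
  # clamp tiny negative rounding noise
  out$values[!is.na(out$values) & out$values < 0 & out$values > -1e-6] <- 0
  out
}

#' Compute least-cost paths for all adjacent node pairs
#'
#' Convenience wrapper: builds the resistance graph once, selects node pairs
#' by cost-weighted Voronoi adjacency, and traces the least-cost path for
#' each pair.
#'
#' @param nodes core nodes from [extract_core_nodes()].
#' @param resistance a [raster_grid()] of resistances.
#' @return A tibble: `node_a`, `node_b`, `cost`, `length`, `path`
#'   (list-column of coordinate matrices).
#' @export
connect_nodes <- function(nodes, resistance) {
  graph <- resistance_graph(resistance)
  pairs <- select_pairs(nodes, resistance, graph = graph)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(node_a = integer(), node_b = integer(),
                          cost = numeric(), length = numeric(), path = list()))
  }
  lcps <- purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- nodes$cells[[which(nodes$node_id == pairs$node_a[i])]]
    b <- nodes$cells[[which(nodes$node_id == pairs$node_b[i])]]
    least_cost_path(resistance, a, b, graph = graph)
  })
  pairs$cost <- purrr::map_dbl(lcps, "cost")
  pairs$length <- purrr::map_dbl(lcps, "length")
  pairs$path <- purrr::map(lcps, "path")
  pairs[is.finite(pairs$cost), ]
}
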