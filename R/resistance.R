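# Landscape distance matrices: geographic, environmental, least-cost
# habitat resistance, and commute (circuit) resistance.
#
# The habitat-probability raster is used directly as a conductance surface
# (identity transform; the common choice when an SDM stands in for
# permeability). Cells with zero habitat or nodata are impassable.

#' Build the habitat transition graph
#'
#' Conductance per cell equals its habitat probability. Adjacent cells
#' (8-neighborhood by default) are joined by an edge of conductance equal to
#' the mean of the two cell conductances — the arithmetic-mean transition
#' rule — with cost `(1 / edge conductance) * inter-center distance` (1 for
#' rook moves, sqrt(2) for diagonals, in cell units). A geometric-mean rule
#' is available.
#'
#' @param habitat [grid_raster()] with values in `[0, 1]` or nodata
#' @param neighbors 8 (default) or 4
#' @param rule "arithmetic" (default) or "geometric" edge-conductance rule
#' @return object of class `transition_graph`: igraph graph over passable
#'   cells plus the cell index bookkeeping
#' @export
build_transition <- function(habitat, neighbors = 8,
                             rule = c("arithmetic", "geometric")) {
  rule <- match.arg(rule)
  stopifnot(neighbors %in% c(4, 8))
  v <- habitat$values
  if (any(v[!is.na(v)] < 0 | v[!is.na(v)] > 1))
    stop("habitat values must lie in [0, 1] or be nodata")
  nr <- nrow(v); nc <- ncol(v)
  passable <- !is.na(v) & v > 0
  if (!any(passable)) stop("fully impassable raster")
  id <- matrix(NA_integer_, nr, nc)
  id[passable] <- seq_len(sum(passable))
  offs <- rbind(c(0, 1, 1), c(1, 0, 1),
                if (neighbors == 8) rbind(c(1, 1, sqrt(2)), c(1, -1, sqrt(2))))
  edges <- list(); costs <- list(); k <- 0
  for (o in seq_len(nrow(offs))) {
    dr <- offs[o, 1]; dc <- offs[o, 2]; len <- offs[o, 3]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    from <- id[r1, c1, drop = FALSE]
    to <- id[r1 + dr, c1 + dc, drop = FALSE]
    cond <- if (rule == "arithmetic")
      (v[r1, c1, drop = FALSE] + v[r1 + dr, c1 + dc, drop = FALSE]) / 2
    else sqrt(v[r1, c1, drop = FALSE] * v[r1 + dr, c1 + dc, drop = FALSE])
    ok <- !is.na(from) & !is.na(to) & cond > 0
    if (!any(ok)) next
    k <- k + 1
    edges[[k]] <- rbind(from[ok], to[ok])
    costs[[k]] <- len / cond[ok]
  }
  el <- do.call(cbind, edges)
  w <- unlist(costs)
  gr <- igraph::make_empty_graph(n = sum(passable), directed = FALSE)
  gr <- igraph::add_edges(gr, as.vector(el))
  igraph::E(gr)$weight <- w
  structure(list(graph = gr, id = id, habitat = habitat,
                 neighbors = neighbors, rule = rule),
            class = "transition_graph")
}

# Map location rows/cols (or x/y) to graph vertex indices.
locate_vertices <- function(tr, locations) {
  if (all(c("row", "col") %in% names(locations))) {
    rc <- cbind(locations$row, locations$col)
  } else {
    cc <- cell_at(tr$habitat, locations[, c("x", "y")])
    rc <- cbind(cc$row, cc$col)
  }
  vid <- tr$id[rc]
  if (any(is.na(vid)))
    stop("location(s) on impassable cells: ",
         paste(which(is.na(vid)), collapse = ", "))
  vid
}

#' Least-cost distance matrix between locations
#'
#' Exact shortest-path accumulated costs on the transition graph
#' (Dijkstra via igraph). Disconnected pairs get `Inf` with a warning.
#'
#' @param tr a [build_transition()] graph
#' @param locations data.frame with row/col (grid indices) or x/y
#'   (projected coordinates) and an `id` column
#' @return [pairwise_matrix()] of kind "least_cost"
#' @export
least_cost_matrix <- function(tr, locations) {
  vid <- locate_vertices(tr, locations)
  m <- igraph::distances(tr$graph, v = vid, to = vid)
  dimnames(m) <- list(locations$id, locations$id)
  if (any(is.infinite(m)))
    warning(sum(is.infinite(m[upper.tri(m)])),
            " location pair(s) are disconnected (infinite distance)")
  pairwise_matrix(m, "least_cost")
}

#' Accumulated least-cost surface from one origin
#'
#' @param tr a [build_transition()] graph
#' @param origin single-row data.frame (row/col or x/y)
#' @return [grid_raster()] of accumulated cost (`NA` on impassable or
#'   unreachable cells)
#' @export
accumulated_cost_surface <- function(tr, origin) {
  vid <- locate_vertices(tr, origin[1, , drop = FALSE])
  d <- igraph::distances(tr$graph, v = vid)[1, ]
  v <- tr$habitat$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[!is.na(tr$id)] <- d[tr$id[!is.na(tr$id)]]
  out[is.infinite(out)] <- NA
  grid_raster(out, xll = tr$habitat$xll, yll = tr$habitat$yll,
              cellsize = tr$habitat$cellsize, crs = tr$habitat$crs)
}

#' Commute (circuit) distance matrix between locations
#'
#' Commute distance = effective resistance between the two nodes times the
#' total edge volume of the graph, computed from sparse Laplacian solves
#' with edge conductances `1 / cost`. Equivalent to the circuit-theoretic
#' resistance distance up to the constant volume factor. Intended for
#' desk-scale grids (<= ~1e4 cells).
#'
#' @inheritParams least_cost_matrix
#' @return [pairwise_matrix()] of kind "commute"
#' @export
commute_matrix <- function(tr, locations) {
  vid <- locate_vertices(tr, locations)
  gr <- tr$graph
  comp <- igraph::components(gr)
  if (length(unique(comp$membership[vid])) > 1)
    stop("locations fall in disconnected components; commute distance undefined")
  keep <- which(comp$membership == comp$membership[vid[1]])
  sub <- igraph::induced_subgraph(gr, keep)
  vmap <- match(vid, keep)
  el <- igraph::as_edgelist(sub, names = FALSE)
  w <- 1 / igraph::E(sub)$weight
  n <- igraph::vcount(sub)
  A <- Matrix::sparseMatrix(i = c(el[, 1], el[, 2]),
                            j = c(el[, 2], el[, 1]),
                            x = c(w, w), dims = c(n, n))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  ground <- if (vmap[1] != n) n else n - 1L
  keep2 <- setdiff(seq_len(n), ground)
  Lg <- L[keep2, keep2]
  pos <- match(vmap, keep2)  # NA for the grounded node
  rhs <- matrix(0, n - 1L, length(vmap))
  rhs[cbind(pos[!is.na(pos)], which(!is.na(pos)))] <- 1
  X <- as.matrix(Matrix::solve(methods::as(Lg, "CsparseMatrix"), rhs))
  K <- length(vid)
  R <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    xi_i <- if (is.na(pos[i])) 0 else X[pos[i], i]
    xj_j <- if (is.na(pos[j])) 0 else X[pos[j], j]
    xi_j <- if (is.na(pos[j])) 0 else X[pos[j], i]
    xj_i <- if (is.na(pos[i])) 0 else X[pos[i], j]
    R[i, j] <- xi_i + xj_j - xi_j - xj_i
  }
  vol <- 2 * sum(w)
  m <- vol * (R + t(R)) / 2
  dimnames(m) <- list(locations$id, locations$id)
  pairwise_matrix(m, "commute")
}

#' Geographic (Euclidean) distance matrix
#'
#' @param coords data.frame with projected `x`, `y` and an `id` column
#' @return [pairwise_matrix()] of kind "geographic"
#' @export
geographic_distance_matrix <- function(coords) {
  xy <- as.matrix(coords[, c("x", "y")])
  if (any(!is.finite(xy))) stop("non-finite coordinates")
  m <- as.matrix(dist(xy))
  dimnames(m) <- list(coords$id, coords$id)
  pairwise_matrix(m, "geographic")
}

#' Environmental (Euclidean) distance matrix on standardized variables
#'
#' @param env matrix/data.frame of environmental values (rows = locations),
#'   expected standardized to zero mean unit variance per column
#' @param ids location IDs (defaults to rownames)
#' @param standardize re-standardize columns first (default TRUE)
#' @return [pairwise_matrix()] of kind "environmental"
#' @export
environmental_distance_matrix <- function(env, ids = NULL,
                                          standardize = TRUE) {
  env <- as.matrix(env)
  if (any(!is.finite(env))) stop("non-finite environmental values")
  if (standardize) env <- scale(env)
  env[is.nan(env)] <- 0  # constant columns carry no distance
  m <- as.matrix(dist(env))
  ids <- ids %||% rownames(env)
  dimnames(m) <- list(ids, ids)
  pairwise_matrix(m, "environmental")
}
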