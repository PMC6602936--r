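#' Build the conductance graph of a resistance raster
#'
#' Converts a resistance raster into the node/edge graph used by the
#' circuit-theory solver. Every non-nodata cell is a node; cells are
#' connected to their eight neighbours. Edge resistance between adjacent
#' cells a, b is `mean(R_a, R_b)` for orthogonal neighbours and
#' `mean(R_a, R_b) * sqrt(2)` for diagonal neighbours (average-resistance
#' mode, the conventional default for 8-neighbour raster circuits);
#' conductance is its reciprocal. With `edge_mode = "average_conductance"`
#' the edge conductance is instead `mean(1/R_a, 1/R_b)` (divided by
#' `sqrt(2)` on diagonals).
#'
#' Focal individuals are snapped to the cell containing their coordinates;
#' several individuals may share a cell. All focal cells must fall on
#' non-nodata cells and lie in one connected component.
#'
#' @param resistance a [raster_grid] with all non-nodata values >= 1.
#' @param focal_xy data.frame or matrix with columns `x`, `y` (metres), one
#'   row per focal individual; row names (or an `id` column) become labels.
#' @param edge_mode `"average_resistance"` (default) or
#'   `"average_conductance"`.
#' @return An object of class `conductance_graph`.
#' @export
build_graph <- function(resistance, focal_xy,
                        edge_mode = c("average_resistance",
                                      "average_conductance")) {
  stopifnot(inherits(resistance, "raster_grid"))
  edge_mode <- match.arg(edge_mode)
  R <- resistance$values
  if (any(R[!is.na(R)] <= 0))
    stop("resistance values must be positive")
  nr <- nrow(R); nc <- ncol(R)
  node_id <- matrix(NA_integer_, nr, nc)
  keep <- which(!is.na(R))
  node_id[keep] <- seq_along(keep)
  n_nodes <- length(keep)
  if (n_nodes == 0L) stop("raster has no usable cells")

  # enumerate 8-neighbour edges via 4 forward shifts (E, S, SE, SW)
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  ei <- integer(0); ej <- integer(0); diagonal <- logical(0)
  ra <- numeric(0); rb <- numeric(0)
  rows <- row(R); cols <- col(R)
  for (s in shifts) {
    r2 <- rows + s[1L]; c2 <- cols + s[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc & !is.na(R)
    idx2 <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- !is.na(R[idx2])
    from <- which(ok)[ok2]; to <- idx2[ok2]
    ei <- c(ei, node_id[from]); ej <- c(ej, node_id[to])
    diagonal <- c(diagonal, rep(all(s != 0L), sum(ok2)))
    ra <- c(ra, R[from]); rb <- c(rb, R[to])
  }
  if (edge_mode == "average_resistance") {
    res <- (ra + rb) / 2
    res[diagonal] <- res[diagonal] * sqrt(2)
    cond <- 1 / res
  } else {
    cond <- (1 / ra + 1 / rb) / 2
    cond[diagonal] <- cond[diagonal] / sqrt(2)
  }

  focal_xy <- as.data.frame(focal_xy)
  if (!all(c("x", "y") %in% names(focal_xy)))
    stop("focal_xy needs columns 'x' and 'y'")
  labels <- if (!is.null(focal_xy$id)) as.character(focal_xy$id)
            else if (!is.null(rownames(focal_xy)) &&
                     !identical(rownames(focal_xy),
                                as.character(seq_len(nrow(focal_xy)))))
              rownames(focal_xy)
            else sprintf("ind%03d", seq_len(nrow(focal_xy)))
  rc <- cell_of(resistance, focal_xy$x, focal_xy$y)
  if (anyNA(rc$row)) {
    i <- which(is.na(rc$row))[1L]
    stop(sprintf("focal point (%g, %g) falls outside the raster",
                 focal_xy$x[i], focal_xy$y[i]))
  }
  fnode <- node_id[cbind(rc$row, rc$col)]
  if (anyNA(fnode)) {
    i <- which(is.na(fnode))[1L]
    stop(sprintf("focal point (%g, %g) falls on a nodata cell",
                 focal_xy$x[i], focal_xy$y[i]))
  }

  g <- structure(
    list(n_nodes = n_nodes, edges_i = ei, edges_j = ej, cond = cond,
         node_id = node_id, focal_node = fnode, labels = labels,
         raster = resistance, edge_mode = edge_mode),
    class = "conductance_graph"
  )
  comp <- reachable_from(g, fnode[1L])
  if (!all(comp[fnode]))
    stop("focal nodes fall in different connected components")
  g
}

#' @export
print.conductance_graph <- function(x, ...) {
  cat(sprintf(
    "<conductance_graph> %d nodes, %d edges, %d focal individuals (%d cells)\n",
    x$n_nodes, length(x$cond), length(x$focal_node),
    length(unique(x$focal_node))))
  invisible(x)
}

# BFS over the sparse adjacency, returns logical reachability vector
reachable_from <- function(g, start) {
  A <- Matrix::sparseMatrix(i = c(g$edges_i, g$edges_j),
                            j = c(g$edges_j, g$edges_i),
                            x = 1, dims = c(g$n_nodes, g$n_nodes))
  seen <- logical(g$n_nodes)
  frontier <- logical(g$n_nodes)
  frontier[start] <- TRUE
  while (any(frontier)) {
    seen <- seen | frontier
    nxt <- as.logical(A %*% frontier > 0)
    frontier <- nxt & !seen
  }
  seen
}

graph_laplacian <- function(g) {
  W <- Matrix::sparseMatrix(i = c(g$edges_i, g$edges_j),
                            j = c(g$edges_j, g$edges_i),
                            x = c(g$cond, g$cond),
                            dims = c(g$n_nodes, g$n_nodes))
  Matrix::Diagonal(x = Matrix::rowSums(W)) - W
}

# Cholesky of the Laplacian with the last node grounded; shared by
# resistance_matrix() and current_map()
grounded_factor <- function(g) {
  L <- graph_laplacian(g)
  n <- g$n_nodes
  Lr <- L[-n, -n, drop = FALSE]
  list(ch = Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Lr), "CsparseMatrix")),
       ground = n)
}

#' Pairwise effective resistance between focal individuals
#'
#' Effective (circuit-theory) resistance between every pair of focal
#' individuals on the conductance graph, obtained from sparse Laplacian
#' solves: one node is grounded, the reduced system is factorized once
#' (sparse Cholesky) and solved against one unit injection per focal cell;
#' `R_eff(s, t) = G_ss + G_tt - 2 G_st` on the resulting Green matrix.
#' Individuals sharing a cell have effective resistance 0.
#'
#' @param graph a [conductance_graph].
#' @return A labelled symmetric matrix (class `matrix`) with zero diagonal.
#' @export
resistance_matrix <- function(graph) {
  stopifnot(inherits(graph, "conductance_graph"))
  fac <- grounded_factor(graph)
  n <- graph$n_nodes
  cells <- unique(graph$focal_node)
  k <- length(cells)
  red_idx <- match(cells, seq_len(n))  # position in full indexing
  # RHS: unit injection at each focal cell (zero column if cell == ground)
  nz <- which(cells != fac$ground)
  E <- Matrix::sparseMatrix(i = red_idx[nz], j = nz, x = 1,
                            dims = c(n - 1L, k))
  V <- as.matrix(Matrix::solve(fac$ch, E))
  # Green matrix over focal cells (potential at cell t when injecting at s)
  G <- matrix(0, k, k)
  in_red <- cells != fac$ground
  G[in_red, ] <- V[red_idx[in_red], , drop = FALSE]
  Rcell <- outer(diag(G), diag(G), "+") - G - t(G)
  Rcell <- (Rcell + t(Rcell)) / 2
  diag(Rcell) <- 0
  idx <- match(graph$focal_node, cells)
  out <- Rcell[idx, idx, drop = FALSE]
  dimnames(out) <- list(graph$labels, graph$labels)
  out
}

#' Cumulative current map over focal pairs
#'
#' For each focal pair, a unit current is injected at the source and
#' extracted at the target; the current through a cell is half the sum of
#' absolute currents on its incident edges, plus the injected unit at the
#' source and target. Per-cell currents are summed over all pairs
#' (`pairs = NULL`) or the supplied subset, yielding the corridor map:
#' high cumulative current marks cells likely to carry movement.
#'
#' @param graph a [conductance_graph].
#' @param pairs optional 2-column matrix of focal individual indices (or a
#'   data.frame with columns `from`, `to`); default all unordered pairs with
#'   distinct cells.
#' @return A [raster_grid] of cumulative current, georeferenced like the
#'   input resistance raster.
#' @export
current_map <- function(graph, pairs = NULL) {
  stopifnot(inherits(graph, "conductance_graph"))
  nf <- length(graph$focal_node)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nf, 2L))
  } else {
    pairs <- as.matrix(as.data.frame(pairs))
    if (ncol(pairs) != 2L) stop("pairs must have two columns")
    if (any(pairs < 1L | pairs > nf)) stop("pair indices out of range")
  }
  fac <- grounded_factor(graph)
  n <- graph$n_nodes
  acc <- numeric(n)
  # solve per unique source/target cell pair
  cp <- cbind(graph$focal_node[pairs[, 1L]], graph$focal_node[pairs[, 2L]])
  cp <- t(apply(cp, 1L, sort))
  cp <- unique(cp[cp[, 1L] != cp[, 2L], , drop = FALSE])
  mult <- rep(1, nrow(cp))  # each unique cell pair counted once per focal pair
  if (nrow(cp) > 0L) {
    all_cp <- cbind(graph$focal_node[pairs[, 1L]], graph$focal_node[pairs[, 2L]])
    all_cp <- t(apply(all_cp, 1L, sort))
    key <- paste(cp[, 1L], cp[, 2L])
    mult <- as.numeric(table(factor(paste(all_cp[, 1L], all_cp[, 2L]),
                                    levels = key)))
  }
  for (p in seq_len(nrow(cp))) {
    s <- cp[p, 1L]; t_ <- cp[p, 2L]
    b <- numeric(n - 1L)
    if (s != fac$ground) b[s] <- b[s] + 1
    if (t_ != fac$ground) b[t_] <- b[t_] - 1
    v <- numeric(n)
    v[-fac$ground] <- as.numeric(Matrix::solve(fac$ch, b))
    edge_cur <- graph$cond * abs(v[graph$edges_i] - v[graph$edges_j])
    node_cur <- numeric(n)
    tab_i <- tapply(edge_cur, graph$edges_i, sum)
    tab_j <- tapply(edge_cur, graph$edges_j, sum)
    node_cur[as.integer(names(tab_i))] <- tab_i
    node_cur[as.integer(names(tab_j))] <-
      node_cur[as.integer(names(tab_j))] + tab_j
    inj <- numeric(n); inj[s] <- 1; inj[t_] <- 1
    acc <- acc + mult[p] * (node_cur + inj) / 2
  }
  out <- matrix(NA_real_, nrow(graph$raster$values), ncol(graph$raster$values))
  out[!is.na(graph$node_id)] <- acc[graph$node_id[!is.na(graph$node_id)]]
  raster_grid(out, cell_size = graph$raster$cell_size,
              xll = graph$raster$xll, yll = graph$raster$yll,
              nodata = graph$raster$nodata)
}
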