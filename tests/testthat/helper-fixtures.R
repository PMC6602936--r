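# Shared fixtures, built in code at test time.

# small labelled distance matrix from random points
random_dist <- function(n, seed, labels = sprintf("i%02d", seq_len(n))) {
  set.seed(seed)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(n * 2), n)))
  dimnames(m) <- list(labels, labels)
  m
}

# genotype table built directly from an allele list:
# calls[[ind]][[locus]] = c(a, b) or NULL for missing
toy_genotypes <- function(calls, x = NULL, y = NULL, sex = NULL,
                          loci = NULL) {
  n <- length(calls)
  L <- max(vapply(calls, length, integer(1)))
  if (is.null(loci)) loci <- sprintf("loc%02d", seq_len(L))
  al <- array(NA_integer_, c(n, L, 2L))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    pr <- calls[[i]][[l]]
    if (!is.null(pr)) { al[i, l, 1L] <- pr[1L]; al[i, l, 2L] <- pr[2L] }
  }
  genotype_table(ids = sprintf("ind%02d", seq_len(n)),
                 x = if (is.null(x)) seq_len(n) * 1000 else x,
                 y = if (is.null(y)) rep(0, n) else y,
                 sex = if (is.null(sex)) rep("U", n) else sex,
                 loci = loci, alleles = al)
}

# dense-Laplacian pseudoinverse oracle for effective resistance
resistance_oracle <- function(graph) {
  n <- graph$n_nodes
  L <- matrix(0, n, n)
  for (e in seq_along(graph$cond)) {
    i <- graph$edges_i[e]; j <- graph$edges_j[e]; c <- graph$cond[e]
    L[i, j] <- L[i, j] - c; L[j, i] <- L[j, i] - c
    L[i, i] <- L[i, i] + c; L[j, j] <- L[j, j] + c
  }
  Lp <- MASS::ginv(L)
  f <- graph$focal_node
  k <- length(f)
  out <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (f[a] != f[b])
      out[a, b] <- Lp[f[a], f[a]] + Lp[f[b], f[b]] - 2 * Lp[f[a], f[b]]
  }
  dimnames(out) <- list(graph$labels, graph$labels)
  out
}

# uniform raster with focal points at given cell centres (cell_size 1)
uniform_graph <- function(nr, nc, focal_cells, R = 1) {
  r <- raster_grid(matrix(R, nr, nc), cell_size = 1)
  xy <- data.frame(x = focal_cells[, 2] - 0.5,
                   y = nr - focal_cells[, 1] + 0.5)
  build_graph(r, xy)
}
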