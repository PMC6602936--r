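#' Shared-allele genetic distance (Dps) between individuals
#'
#' For each pair of individuals, over the loci typed in both, the number of
#' shared alleles per locus is the size of the multiset intersection of the
#' two allele pairs (0, 1 or 2); `Dps = 1 - sum(shared) / (2 L_ij)` where
#' `L_ij` is the number of commonly typed loci. Loci missing in either
#' individual are dropped pairwise.
#'
#' @param g a [genotype_table].
#' @return Labelled symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
dps_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  n <- length(g$ids); L <- length(g$loci)
  lt <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  ii <- lt[, 1L]; jj <- lt[, 2L]   # ii > jj
  shared <- numeric(nrow(lt)); nloc <- integer(nrow(lt))
  for (l in seq_len(L)) {
    a <- g$alleles[, l, 1L]; b <- g$alleles[, l, 2L]  # sorted pairs
    ok <- !is.na(a[ii]) & !is.na(a[jj])
    ai <- a[ii][ok]; bi <- b[ii][ok]; aj <- a[jj][ok]; bj <- b[jj][ok]
    exact <- ai == aj & bi == bj
    any1 <- ai == aj | ai == bj | bi == aj | bi == bj
    shared[ok] <- shared[ok] + ifelse(exact, 2L, as.integer(any1))
    nloc[ok] <- nloc[ok] + 1L
  }
  if (any(nloc == 0L)) {
    bad <- which(nloc == 0L)[1L]
    stop(sprintf("individuals %s and %s share no typed locus",
                 g$ids[jj[bad]], g$ids[ii[bad]]))
  }
  d <- matrix(0, n, n, dimnames = list(g$ids, g$ids))
  v <- 1 - shared / (2 * nloc)
  d[cbind(ii, jj)] <- v
  d[cbind(jj, ii)] <- v
  d
}
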