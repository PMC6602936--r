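#' Individual microsatellite genotype table
#'
#' Container for diploid multilocus genotypes of georeferenced individuals:
#' for each individual an id, map coordinates (metres), sex, and per locus an
#' unordered pair of allele states (positive integers, repeat counts).
#' Missing calls are `NA` in both slots. Allele pairs are stored sorted so
#' that `{a, b}` and `{b, a}` are identical.
#'
#' @param ids character vector of unique individual ids.
#' @param x,y numeric coordinates (metres), finite.
#' @param sex character vector in `{"M", "F", "U"}` (`"U"` = unknown).
#' @param loci character vector of locus names.
#' @param alleles integer array `n x L x 2` of allele states; `NA` = missing.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, x, y, sex, loci, alleles) {
  n <- length(ids)
  stopifnot(length(x) == n, length(y) == n, length(sex) == n,
            all(is.finite(x)), all(is.finite(y)),
            !anyDuplicated(ids))
  sex <- toupper(as.character(sex))
  sex[!sex %in% c("M", "F")] <- "U"
  L <- length(loci)
  stopifnot(is.array(alleles), all(dim(alleles) == c(n, L, 2L)))
  if (any(alleles[!is.na(alleles)] <= 0))
    stop("allele states must be positive integers")
  # one NA in a pair makes the whole call missing
  miss <- is.na(alleles[, , 1L, drop = FALSE]) |
          is.na(alleles[, , 2L, drop = FALSE])
  alleles[, , 1L][miss[, , 1L]] <- NA_integer_
  alleles[, , 2L][miss[, , 1L]] <- NA_integer_
  # store pairs sorted
  a1 <- pmin(alleles[, , 1L], alleles[, , 2L])
  a2 <- pmax(alleles[, , 1L], alleles[, , 2L])
  alleles <- array(c(a1, a2), dim = c(n, L, 2L),
                   dimnames = list(ids, loci, c("a1", "a2")))
  # a locus must be typed for at least one individual
  typed_any <- apply(!is.na(alleles[, , 1L, drop = FALSE]), 2L, any)
  if (!all(typed_any))
    stop(sprintf("locus with no typed individuals: %s",
                 paste(loci[!typed_any], collapse = ", ")))
  structure(
    list(ids = as.character(ids), x = as.numeric(x), y = as.numeric(y),
         sex = sex, loci = as.character(loci),
         alleles = array(as.integer(alleles), dim = dim(alleles),
                         dimnames = dimnames(alleles))),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d loci (%d F / %d M / %d U)\n",
              length(x$ids), length(x$loci),
              sum(x$sex == "F"), sum(x$sex == "M"), sum(x$sex == "U")))
  miss <- mean(is.na(x$alleles[, , 1L]))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Subset individuals of a genotype table
#'
#' @param g a [genotype_table].
#' @param idx integer or logical index, or character ids.
#' @return A [genotype_table].
#' @export
subset_individuals <- function(g, idx) {
  if (is.character(idx)) idx <- match(idx, g$ids)
  genotype_table(g$ids[idx], g$x[idx], g$y[idx], g$sex[idx], g$loci,
                 g$alleles[idx, , , drop = FALSE])
}

#' Drop loci from a genotype table
#'
#' @param g a [genotype_table].
#' @param drop character vector of locus names to remove.
#' @return A [genotype_table].
#' @export
drop_loci <- function(g, drop) {
  keep <- !g$loci %in% drop
  if (!any(keep)) stop("cannot drop all loci")
  genotype_table(g$ids, g$x, g$y, g$sex, g$loci[keep],
                 g$alleles[, keep, , drop = FALSE])
}

#' Write / read a GenAlEx-style genotype CSV
#'
#' Plain-text exchange format: first line `n_loci,n_individuals`; second
#' line the column header (`id,pop`, two columns per locus, `x,y,sex`); one
#' row per individual. Missing alleles are written as 0.
#'
#' @param g a [genotype_table].
#' @param path file path.
#' @param pop population label written for every individual (single site by
#'   default).
#' @return `path` invisibly (write) or a [genotype_table] (read).
#' @export
write_genalex <- function(g, path, pop = "pop1") {
  L <- length(g$loci); n <- length(g$ids)
  A <- g$alleles
  A[is.na(A)] <- 0L
  cols <- as.vector(rbind(paste0(g$loci, ".1"), paste0(g$loci, ".2")))
  geno <- matrix(0L, n, 2L * L)
  geno[, seq(1L, 2L * L, 2L)] <- A[, , 1L]
  geno[, seq(2L, 2L * L, 2L)] <- A[, , 2L]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d,%d", L, n), con)
  writeLines(paste(c("id", "pop", cols, "x", "y", "sex"), collapse = ","), con)
  body <- cbind(g$ids, pop, geno, g$x, g$y, g$sex)
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_genalex
#' @export
read_genalex <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1L], ",")[[1L]])
  L <- hdr[1L]; n <- hdr[2L]
  cols <- strsplit(lines[2L], ",")[[1L]]
  loci <- unique(sub("\\.[12]$", "", cols[3:(2 + 2 * L)]))
  rows <- strsplit(lines[3:(2 + n)], ",")
  m <- do.call(rbind, rows)
  geno <- matrix(as.integer(m[, 3:(2 + 2 * L), drop = FALSE]), nrow = n)
  geno[geno == 0L] <- NA_integer_
  alleles <- array(NA_integer_, c(n, L, 2L))
  alleles[, , 1L] <- geno[, seq(1L, 2L * L, 2L)]
  alleles[, , 2L] <- geno[, seq(2L, 2L * L, 2L)]
  genotype_table(m[, 1L], as.numeric(m[, 2L + 2L * L + 1L]),
                 as.numeric(m[, 2L + 2L * L + 2L]),
                 m[, 2L + 2L * L + 3L], loci, alleles)
}

#' Pairwise Euclidean geographic distances
#'
#' @param g a [genotype_table].
#' @return Labelled symmetric matrix of straight-line distances (metres).
#' @export
geo_distance_matrix <- function(g) {
  d <- as.matrix(stats::dist(cbind(g$x, g$y)))
  dimnames(d) <- list(g$ids, g$ids)
  d
}
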