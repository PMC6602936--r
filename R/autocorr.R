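#' Multivariate spatial genetic autocorrelation correlogram
#'
#' Smouse-Peakall multivariate autocorrelation of multilocus genotypes over
#' distance classes. The squared genetic distance matrix is double-centered
#' into a covariance matrix
#' `c_ij = -1/2 (d2_ij - rowmean_i - colmean_j + grandmean)`; for a distance
#' class h the autocorrelation is
#' `r_h = sum(c_ij over ordered pairs with d_geo in h) /
#'        sum(c_ii over individuals involved in h)`.
#'
#' The null envelope comes from shuffling coordinates among individuals
#' (`n_perm` permutations, 2.5/97.5 percentiles per class); the one-tailed
#' upper P per class is the proportion of permuted `r >= r_obs`. The
#' bootstrap CI resamples pairs within the class with replacement
#' (`n_boot` draws).
#'
#' @param g a [genotype_table].
#' @param class_width_m distance class width in metres (contiguous classes
#'   `[0, w), [w, 2w), ...`).
#' @param max_dist_m upper bound for the last class; default spans the data.
#' @param n_perm,n_boot permutation / bootstrap counts.
#' @param sex_filter optional `"M"` or `"F"` to restrict to one sex.
#' @param seed optional integer seed.
#' @param genetic_d optional precomputed genetic distance matrix (defaults
#'   to [dps_matrix()]).
#' @return A data.frame of class `correlogram`: `class_lo`, `class_hi`,
#'   `n_pairs`, `r`, `p`, `perm_lo`, `perm_hi`, `boot_lo`, `boot_hi`.
#' @export
spatial_autocorrelogram <- function(g, class_width_m, max_dist_m = NULL,
                                    n_perm = 999, n_boot = 999,
                                    sex_filter = NULL, seed = NULL,
                                    genetic_d = NULL) {
  stopifnot(inherits(g, "genotype_table"))
  if (!is.null(sex_filter)) {
    keep <- g$sex == sex_filter
    g <- subset_individuals(g, keep)
    if (!is.null(genetic_d)) genetic_d <- genetic_d[keep, keep, drop = FALSE]
  }
  n <- length(g$ids)
  if (n < 10L) stop("need at least 10 individuals after filtering")
  if (!is.null(seed)) set.seed(seed)
  D <- if (is.null(genetic_d)) dps_matrix(g) else genetic_d
  C <- double_center(D^2)
  geo <- geo_distance_matrix(g)
  if (is.null(max_dist_m)) max_dist_m <- max(geo) + class_width_m / 100
  edges <- seq(0, max_dist_m + class_width_m, by = class_width_m)
  nb <- length(edges) - 1L

  lt <- which(lower.tri(geo), arr.ind = TRUE)
  bin_of <- function(gd) {
    b <- findInterval(gd[lt], edges, rightmost.closed = FALSE)
    b[b > nb] <- NA_integer_
    b
  }
  r_of <- function(C, bins) {
    vapply(seq_len(nb), function(h) {
      sel <- which(!is.na(bins) & bins == h)
      if (length(sel) == 0L) return(NA_real_)
      num <- 2 * sum(C[lt[sel, , drop = FALSE]])
      inv <- unique(c(lt[sel, 1L], lt[sel, 2L]))
      num / sum(diag(C)[inv])
    }, numeric(1))
  }

  bins <- bin_of(geo)
  r_obs <- r_of(C, bins)
  n_pairs <- vapply(seq_len(nb), function(h)
    sum(!is.na(bins) & bins == h), integer(1))
  if (any(n_pairs == 0L & seq_len(nb) <= max(which(n_pairs > 0L))))
    warning("empty distance class: r reported as missing")

  # null: shuffle coordinates among individuals (genotypes fixed)
  perm_r <- matrix(NA_real_, n_perm, nb)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n)
    perm_r[p, ] <- r_of(C, bin_of(geo[idx, idx]))
  }
  p_val <- vapply(seq_len(nb), function(h) {
    if (is.na(r_obs[h])) return(NA_real_)
    (1 + sum(perm_r[, h] >= r_obs[h], na.rm = TRUE)) / (1 + n_perm)
  }, numeric(1))
  perm_lo <- apply(perm_r, 2L, stats::quantile, probs = 0.025, na.rm = TRUE)
  perm_hi <- apply(perm_r, 2L, stats::quantile, probs = 0.975, na.rm = TRUE)

  # bootstrap over pairs within class
  boot_lo <- boot_hi <- rep(NA_real_, nb)
  dC <- diag(C)
  for (h in seq_len(nb)) {
    sel <- which(!is.na(bins) & bins == h)
    if (length(sel) < 2L) next
    bs <- vapply(seq_len(n_boot), function(b) {
      take <- sample(sel, length(sel), replace = TRUE)
      num <- 2 * sum(C[lt[take, , drop = FALSE]])
      inv <- unique(c(lt[take, 1L], lt[take, 2L]))
      num / sum(dC[inv])
    }, numeric(1))
    boot_lo[h] <- stats::quantile(bs, 0.025, na.rm = TRUE)
    boot_hi[h] <- stats::quantile(bs, 0.975, na.rm = TRUE)
  }

  out <- data.frame(class_lo = edges[seq_len(nb)],
                    class_hi = edges[-1L],
                    n_pairs = n_pairs, r = r_obs, p = p_val,
                    perm_lo = perm_lo, perm_hi = perm_hi,
                    boot_lo = boot_lo, boot_hi = boot_hi)
  # trim trailing empty classes
  last <- max(which(n_pairs > 0L), 1L)
  out <- out[seq_len(last), , drop = FALSE]
  class(out) <- c("correlogram", "data.frame")
  out
}

#' Double-center a squared-distance matrix
#'
#' Gower centering: `c_ij = -1/2 (d2_ij - rowmean_i - colmean_j +
#' grandmean)`. All row sums of the result are zero.
#'
#' @param d2 symmetric matrix of squared distances.
#' @return Centered covariance matrix.
#' @export
double_center <- function(d2) {
  rm_ <- rowMeans(d2); cm <- colMeans(d2); gm <- mean(d2)
  -0.5 * (d2 - outer(rm_, rep(1, ncol(d2))) -
            outer(rep(1, nrow(d2)), cm) + gm)
}
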