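#' Per-locus diversity, Hardy-Weinberg and null-allele screen
#'
#' Computes, for every locus: observed heterozygosity `Ho` (fraction of
#' typed individuals with two distinct alleles), unbiased expected
#' heterozygosity `He = (2n/(2n-1)) (1 - sum p_i^2)`, the inbreeding
#' coefficient `F_IS = 1 - Ho/He` (undefined when `He = 0`), a permutation
#' Hardy-Weinberg test, and the homozygote-excess null-allele frequency
#' estimator `(He - Ho) / (1 + He)`.
#'
#' The HWE test shuffles the pooled alleles among individuals within the
#' locus (`n_perm` shuffles) and uses `Ho` as the statistic; the reported P
#' is two-sided (doubled smaller tail), so both heterozygote deficits
#' (null alleles) and excesses (negative `F_IS`) register. P-values are
#' adjusted across loci by sequential (Holm) Bonferroni. A locus is flagged
#' `excluded` when its estimated null-allele frequency exceeds
#' `null_threshold` *and* its Holm-adjusted HWE P is at or below `alpha`.
#'
#' @param g a [genotype_table].
#' @param n_perm permutation count for the HWE test.
#' @param alpha significance level applied to Holm-adjusted HWE P-values.
#' @param null_threshold exclusion threshold on the null-allele frequency.
#' @param seed optional integer seed for the permutations.
#' @return A data.frame with one row per locus: `locus`, `n_typed`, `ho`,
#'   `he`, `f_is`, `hwe_p`, `hwe_p_holm`, `null_freq`, `excluded`.
#' @export
locus_screen <- function(g, n_perm = 999, alpha = 0.05,
                         null_threshold = 0.05, seed = NULL) {
  stopifnot(inherits(g, "genotype_table"))
  if (!is.null(seed)) set.seed(seed)
  L <- length(g$loci)
  out <- data.frame(locus = g$loci, n_typed = NA_integer_,
                    ho = NA_real_, he = NA_real_, f_is = NA_real_,
                    hwe_p = NA_real_, hwe_p_holm = NA_real_,
                    null_freq = NA_real_, excluded = FALSE,
                    stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    a1 <- g$alleles[, l, 1L]; a2 <- g$alleles[, l, 2L]
    typed <- !is.na(a1)
    nt <- sum(typed)
    if (nt < 2L) stop(sprintf("locus %s has fewer than 2 typed individuals",
                              g$loci[l]))
    a1 <- a1[typed]; a2 <- a2[typed]
    ho <- mean(a1 != a2)
    pool <- c(a1, a2)
    p <- table(pool) / length(pool)
    he <- (2 * nt / (2 * nt - 1)) * (1 - sum(p^2))
    fis <- if (he > 0) 1 - ho / he else NA_real_
    nullf <- if (he > 0 || ho > 0) (he - ho) / (1 + he) else 0
    hwe <- NA_real_
    if (he > 0) {
      perm_ho <- replicate(n_perm, {
        s <- sample(pool)
        mean(s[seq_len(nt)] != s[nt + seq_len(nt)])
      })
      p_up <- (1 + sum(perm_ho >= ho)) / (1 + n_perm)
      p_lo <- (1 + sum(perm_ho <= ho)) / (1 + n_perm)
      hwe <- min(1, 2 * min(p_up, p_lo))
    }
    out$n_typed[l] <- nt; out$ho[l] <- ho; out$he[l] <- he
    out$f_is[l] <- fis; out$hwe_p[l] <- hwe; out$null_freq[l] <- nullf
  }
  has_p <- !is.na(out$hwe_p)
  out$hwe_p_holm[has_p] <- holm_adjust(out$hwe_p[has_p])
  out$excluded <- !is.na(out$null_freq) & out$null_freq > null_threshold &
    !is.na(out$hwe_p_holm) & out$hwe_p_holm <= alpha
  out
}
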