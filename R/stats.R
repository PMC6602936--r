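# Distance-matrix statistics: Mantel, partial Mantel, MRM, AICc, Holm.

check_dist_matrix <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("%s must be a square matrix", name))
  if (max(abs(m - t(m))) > 1e-12)
    stop(sprintf("%s is not symmetric", name))
  m
}

# align matrices on common labels (order of the first); unlabelled matrices
# must already agree in size
align_matrices <- function(...) {
  ms <- list(...)
  labs <- lapply(ms, rownames)
  if (any(vapply(labs, is.null, logical(1)))) {
    n <- unique(vapply(ms, nrow, integer(1)))
    if (length(n) != 1L) stop("unlabelled matrices of different sizes")
    return(ms)
  }
  common <- Reduce(intersect, labs)
  if (length(common) < 3L) stop("fewer than 3 common labels")
  lapply(ms, function(m) m[common, common, drop = FALSE])
}

lower_vec <- function(m) m[lower.tri(m)]

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle vectors with permutation
#' inference: rows and columns of `a` are permuted jointly `n_perm` times
#' and `P = (1 + #{r_perm >= r_obs}) / (1 + n_perm)` (one-tailed upper by
#' default; `tail = "two"` uses `|r_perm| >= |r_obs|`). With
#' `exact = TRUE` (n <= 7) all `n!` permutations are enumerated instead.
#'
#' @param a,b symmetric distance matrices with matching labels.
#' @param n_perm number of random permutations.
#' @param seed optional integer seed.
#' @param tail `"upper"` or `"two"`.
#' @param exact enumerate all permutations (small n only).
#' @return List of class `mantel_result`: `r`, `p`, `n`, `n_perm`, `tail`.
#' @export
mantel_test <- function(a, b, n_perm = 9999, seed = NULL,
                        tail = c("upper", "two"), exact = FALSE) {
  tail <- match.arg(tail)
  m <- align_matrices(check_dist_matrix(a, "a"), check_dist_matrix(b, "b"))
  a <- m[[1L]]; b <- m[[2L]]
  n <- nrow(a)
  if (n < 4L) stop("need at least 4 individuals")
  va <- lower_vec(a); vb <- lower_vec(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant matrix: zero variance in lower triangle")
  r_obs <- stats::cor(va, vb)
  stat <- function(idx) stats::cor(lower_vec(a[idx, idx]), vb)
  if (exact) {
    if (n > 7L) stop("exact enumeration limited to n <= 7")
    perms <- all_permutations(n)
    r_perm <- vapply(perms, stat, numeric(1))
    p <- exceed_p(r_perm, r_obs, tail, exact = TRUE)
    n_perm <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(k) stat(sample.int(n)),
                     numeric(1))
    p <- exceed_p(r_perm, r_obs, tail, exact = FALSE)
  }
  structure(list(r = r_obs, p = p, n = n, n_perm = n_perm, tail = tail,
                 method = "mantel"),
            class = "mantel_result")
}

exceed_p <- function(r_perm, r_obs, tail, exact) {
  cmp <- if (tail == "two") abs(r_perm) >= abs(r_obs) - 1e-12
         else r_perm >= r_obs - 1e-12
  if (exact) mean(cmp) else (1 + sum(cmp)) / (1 + length(r_perm))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos - 1L)
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s: r = %.4f, P = %.4g (%s-tailed, %d permutations, n = %d)\n",
              x$method, x$r, x$p, x$tail, x$n_perm, x$n))
  invisible(x)
}

#' Partial Mantel test
#'
#' Correlation between distance matrices `a` and `b` after removing the
#' (linear) effect of `c` from both: lower-triangle vectors of `a` and `b`
#' are each regressed on that of `c` and the residuals correlated.
#' Inference uses the residual-permutation method: the residuals of
#' `a ~ c` are folded back into a symmetric matrix whose rows/columns are
#' permuted jointly; each permuted matrix is correlated with the fixed
#' residuals of `b ~ c`.
#'
#' @param a,b,c symmetric distance matrices with matching labels
#'   (`c` is partialled out).
#' @inheritParams mantel_test
#' @return List of class `mantel_result`.
#' @export
partial_mantel <- function(a, b, c, n_perm = 9999, seed = NULL,
                           tail = c("upper", "two")) {
  tail <- match.arg(tail)
  m <- align_matrices(check_dist_matrix(a, "a"), check_dist_matrix(b, "b"),
                      check_dist_matrix(c, "c"))
  a <- m[[1L]]; b <- m[[2L]]; c <- m[[3L]]
  n <- nrow(a)
  if (n < 4L) stop("need at least 4 individuals")
  va <- lower_vec(a); vb <- lower_vec(b); vc <- lower_vec(c)
  res_b <- residualize(vb, vc)
  if (stats::sd(res_b) < 1e-14)
    stop("c is collinear with b: residuals have no variance")
  res_a <- residualize(va, vc)
  if (stats::sd(res_a) < 1e-14)
    stop("c is collinear with a: residuals have no variance")
  r_obs <- stats::cor(res_a, res_b)
  # residuals of a ~ c as a symmetric matrix for permutation
  RA <- matrix(0, n, n)
  RA[lower.tri(RA)] <- res_a
  RA <- RA + t(RA)
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    stats::cor(lower_vec(RA[idx, idx]), res_b)
  }, numeric(1))
  p <- exceed_p(r_perm, r_obs, tail, exact = FALSE)
  structure(list(r = r_obs, p = p, n = n, n_perm = n_perm, tail = tail,
                 method = "partial mantel (residual permutation)"),
            class = "mantel_result")
}

residualize <- function(y, x) {
  # a constant conditioning vector carries no information: centre only
  if (stats::sd(x) < 1e-14) return(y - mean(y))
  X <- cbind(1, x)
  as.numeric(y - X %*% qr.coef(qr(X), y))
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the response distance matrix on one or more
#' predictor distance matrices, all vectorized to their lower triangles.
#' Permutation inference jointly permutes rows/columns of the response:
#' coefficient P-values compare `|b_perm| >= |b_obs|`, the overall P
#' compares permuted R-squared. Standardized coefficients (beta) come from
#' refitting on z-scored vectors. `VIF_j = 1/(1 - R2_j)` from regressing
#' predictor j on the remaining predictors (1 for a single predictor).
#' AICc treats the `n(n-1)/2` pairs as the effective sample size with
#' `k = #predictors + 2` (see Details).
#'
#' @details Distance pairs are not independent, so the AICc here is the
#' conventional heuristic used for MRM model ranking, not a likelihood-based
#' criterion with guaranteed frequentist properties; compare models with
#' identical responses only.
#'
#' @param gd response distance matrix.
#' @param predictors named list of predictor distance matrices.
#' @param n_perm permutations of the response.
#' @param seed optional integer seed.
#' @return List of class `mrm_result`: `coefficients` (data.frame with
#'   `term`, `estimate`, `beta`, `p`), `r_squared`, `p_overall`, `aicc`,
#'   `vif`, `n_pairs`.
#' @export
mrm <- function(gd, predictors, n_perm = 999, seed = NULL) {
  stopifnot(length(predictors) >= 1L)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    names(predictors) <- paste0("X", seq_along(predictors))
  ms <- do.call(align_matrices, c(list(check_dist_matrix(gd, "gd")),
                                  lapply(predictors, check_dist_matrix)))
  gd <- ms[[1L]]; predictors <- ms[-1L]
  y <- lower_vec(gd)
  X <- vapply(predictors, lower_vec, numeric(length(y)))
  X <- matrix(X, ncol = length(predictors),
              dimnames = list(NULL, names(predictors)))
  p_n <- ncol(X)
  # collinearity guard
  if (p_n > 1L) {
    cc <- stats::cor(X)
    diag(cc) <- 0
    if (any(abs(cc) > 1 - 1e-10)) {
      w <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1L, ]
      stop(sprintf("perfectly collinear predictors: %s and %s",
                   colnames(X)[w[1L]], colnames(X)[w[2L]]))
    }
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  coefs <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  # standardized beta
  beta <- c(NA_real_,
            stats::lm.fit(cbind(1, scale(X)), as.numeric(scale(y)))$
              coefficients[-1L])
  n <- nrow(gd)
  if (!is.null(seed)) set.seed(seed)
  b_perm <- matrix(NA_real_, n_perm, p_n + 1L)
  r2_perm <- numeric(n_perm)
  Xi <- cbind(1, X)
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    yp <- lower_vec(gd[idx, idx])
    fp <- stats::lm.fit(Xi, yp)
    b_perm[k, ] <- fp$coefficients
    r2_perm[k] <- 1 - sum(fp$residuals^2) / sum((yp - mean(yp))^2)
  }
  p_coef <- vapply(seq_len(p_n + 1L), function(j)
    (1 + sum(abs(b_perm[, j]) >= abs(coefs[j]) - 1e-12)) / (1 + n_perm),
    numeric(1))
  p_overall <- (1 + sum(r2_perm >= r2 - 1e-12)) / (1 + n_perm)
  vif <- rep(1, p_n)
  if (p_n > 1L) {
    vif <- vapply(seq_len(p_n), function(j) {
      fj <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      r2j <- 1 - sum(fj$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
      1 / (1 - r2j)
    }, numeric(1))
  }
  names(vif) <- colnames(X)
  n_eff <- length(y)
  k_par <- p_n + 2L
  aicc <- n_eff * log(rss / n_eff) + 2 * k_par +
    2 * k_par * (k_par + 1) / (n_eff - k_par - 1)
  structure(list(
    coefficients = data.frame(term = c("(Intercept)", colnames(X)),
                              estimate = unname(coefs), beta = unname(beta),
                              p = p_coef, stringsAsFactors = FALSE),
    r_squared = r2, p_overall = p_overall, aicc = aicc, vif = vif,
    n_pairs = n_eff, n = n, n_perm = n_perm),
    class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("MRM on %d pairs: R2 = %.4f (P = %.4g), AICc = %.2f\n",
              x$n_pairs, x$r_squared, x$p_overall, x$aicc))
  print(x$coefficients, row.names = FALSE)
  if (length(x$vif)) {
    cat("VIF:\n"); print(round(x$vif, 2))
  }
  invisible(x)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc numeric vector of AICc values for a model set.
#' @return data.frame with `aicc`, `delta`, `weight` (weights sum to 1).
#' @export
akaike_weights <- function(aicc) {
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  data.frame(aicc = aicc, delta = delta, weight = w / sum(w))
}

#' Sequential (Holm) Bonferroni adjustment
#'
#' Step-down Holm correction of a vector of P-values; monotone in the raw-P
#' ranks and capped at 1.
#'
#' @param pvals numeric vector of raw P-values in `(0, 1]`.
#' @return Adjusted P-values, same order as the input.
#' @export
holm_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "holm")
}
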