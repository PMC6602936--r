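# Causal-modelling engine: relative support, the IBR two-step test,
# univariate transformation optimization and coordinate-wise multivariate
# optimization of resistance surfaces.

#' Relative support between two competing resistance models
#'
#' `RS_{1|2} = A - B`, where `A` is the partial Mantel correlation of
#' genetic distance with model 1 partialling out model 2, and `B` the
#' partial Mantel correlation of genetic distance with model 2 partialling
#' out model 1. Positive RS favours model 1; RS is antisymmetric in the two
#' arguments.
#'
#' @param r_1given2 partial Mantel r of GD ~ model1 | model2 (the `A` term).
#' @param r_2given1 partial Mantel r of GD ~ model2 | model1 (the `B` term).
#' @return The RS value.
#' @export
relative_support <- function(r_1given2, r_2given1) {
  stopifnot(is.numeric(r_1given2), is.numeric(r_2given1),
            abs(r_1given2) <= 1, abs(r_2given1) <= 1)
  r_1given2 - r_2given1
}

#' Two-step causal-modelling test against the IBR null
#'
#' A resistance hypothesis is supported independently of the
#' isolation-by-resistance null when (1) the partial Mantel test of genetic
#' distance against the hypothesis, partialling out IBR, is significant,
#' and (2) the partial Mantel test of genetic distance against IBR,
#' partialling out the hypothesis, is not.
#'
#' @param gd genetic distance matrix.
#' @param lv_matrix resistance distances under the landscape hypothesis.
#' @param ibr_matrix resistance distances on the uniform (IBR) surface.
#' @param n_perm permutations per partial Mantel test.
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @return List of class `causal_report`: `r1`, `p1` (GD ~ LV | IBR),
#'   `r2`, `p2` (GD ~ IBR | LV), `rs` (= r1 - r2), `supported`.
#' @export
causal_ibr_test <- function(gd, lv_matrix, ibr_matrix, n_perm = 999,
                            alpha = 0.05, seed = NULL) {
  if (identical(dim(lv_matrix), dim(ibr_matrix)) &&
      max(abs(lv_matrix - ibr_matrix)) < 1e-12)
    stop("degenerate candidate: hypothesis matrix is identical to IBR")
  t1 <- partial_mantel(gd, lv_matrix, ibr_matrix, n_perm = n_perm,
                       seed = seed)
  t2 <- partial_mantel(gd, ibr_matrix, lv_matrix, n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else seed + 1L)
  structure(list(r1 = t1$r, p1 = t1$p, r2 = t2$r, p2 = t2$p,
                 rs = relative_support(t1$r, t2$r),
                 supported = t1$p <= alpha && t2$p > alpha,
                 alpha = alpha, n_perm = n_perm),
            class = "causal_report")
}

#' @export
print.causal_report <- function(x, ...) {
  cat(sprintf("GD ~ LV | IBR: r = %.3f, P = %.4g\n", x$r1, x$p1))
  cat(sprintf("GD ~ IBR | LV: r = %.3f, P = %.4g\n", x$r2, x$p2))
  cat(sprintf("RS vs IBR = %.3f; %s\n", x$rs,
              if (x$supported) "SUPPORTED" else "not supported"))
  invisible(x)
}

#' Default transformation parameter grid
#'
#' `R_max` in {2, 10, 100, 1000}; for the continuous (power-deviation)
#' family also `x` in {0.5, 1, 2, 5, 10} with the optimum held fixed.
#'
#' @param family `"classified"` or `"power_deviation"`.
#' @param optimum optimum value (power_deviation only).
#' @return data.frame of parameter combinations (`r_max`, and for
#'   power_deviation `x`, `optimum`).
#' @export
default_param_grid <- function(family = c("classified", "power_deviation"),
                               optimum = NULL) {
  family <- match.arg(family)
  r_max <- c(2, 10, 100, 1000)
  if (family == "classified") return(data.frame(r_max = r_max))
  stopifnot(!is.null(optimum))
  expand.grid(r_max = r_max, x = c(0.5, 1, 2, 5, 10), optimum = optimum,
              KEEP.OUT.ATTRS = FALSE)
}

spec_from_row <- function(variable, family, row) {
  if (family == "classified") {
    transform_spec(variable, "classified", r_max = row$r_max)
  } else {
    transform_spec(variable, "power_deviation", r_max = row$r_max,
                   x = row$x, optimum = row$optimum)
  }
}

# resistance distances for a composed set of specs on their source rasters
specs_to_matrix <- function(specs, rasters, focal_xy, edge_mode) {
  surfaces <- lapply(specs, function(s)
    transform_raster(rasters[[s$variable]], s))
  surf <- compose_surfaces(surfaces)
  resistance_matrix(build_graph(surf, focal_xy, edge_mode = edge_mode))
}

#' Univariate resistance-surface optimization for one landscape variable
#'
#' Evaluates every parameterization in `param_grid`: the variable raster is
#' transformed, resistance distances between focal individuals are computed
#' on the resulting surface, and the partial Mantel correlation of genetic
#' distance with those distances (partialling out the IBR distances) is the
#' objective. The best model is the highest-r parameterization whose P is
#' at or below `alpha`; when none is significant the top-r model is
#' returned with `supported = FALSE`. The full ranking is retained.
#'
#' @param gd genetic distance matrix (labels = focal individual ids).
#' @param variable_raster [raster_grid] of the raw landscape variable.
#' @param family transformation family for this variable.
#' @param param_grid data.frame of parameterizations (see
#'   [default_param_grid()]).
#' @param focal_xy data.frame with `id`, `x`, `y` for the focal individuals.
#' @param ibr_matrix IBR resistance distance matrix.
#' @param n_perm,alpha,seed inference settings.
#' @param variable variable name recorded in the specs.
#' @param edge_mode passed to [build_graph()].
#' @return List of class `candidate_model`: `variable`, `spec` (best),
#'   `r`, `p`, `supported`, `ranking` (data.frame with params, r, p).
#' @export
optimize_univariate <- function(gd, variable_raster, family, param_grid,
                                focal_xy, ibr_matrix, n_perm = 199,
                                alpha = 0.05, seed = NULL,
                                variable = "variable",
                                edge_mode = "average_resistance") {
  stopifnot(nrow(param_grid) >= 1L)
  rasters <- stats::setNames(list(variable_raster), variable)
  rank_df <- param_grid
  rank_df$r <- NA_real_; rank_df$p <- NA_real_
  for (k in seq_len(nrow(param_grid))) {
    spec <- spec_from_row(variable, family, param_grid[k, , drop = FALSE])
    lv <- specs_to_matrix(list(spec), rasters, focal_xy, edge_mode)
    pm <- partial_mantel(gd, lv, ibr_matrix, n_perm = n_perm,
                         seed = if (is.null(seed)) NULL else seed + k)
    rank_df$r[k] <- pm$r; rank_df$p[k] <- pm$p
  }
  ord <- order(-rank_df$r)
  rank_df <- rank_df[ord, , drop = FALSE]
  sig <- which(rank_df$p <= alpha)
  best_row <- if (length(sig)) rank_df[sig[1L], , drop = FALSE]
              else rank_df[1L, , drop = FALSE]
  best_spec <- spec_from_row(variable, family, best_row)
  structure(list(variable = variable, family = family, spec = best_spec,
                 r = best_row$r, p = best_row$p,
                 supported = length(sig) > 0L,
                 ranking = rank_df, alpha = alpha, n_perm = n_perm),
            class = "candidate_model")
}

#' @export
print.candidate_model <- function(x, ...) {
  cat(sprintf("<candidate_model> %s: best r = %.3f (P = %.4g), %s\n",
              x$variable, x$r, x$p,
              if (x$supported) "supported" else "not supported"))
  print(x$spec)
  invisible(x)
}

#' Coordinate-wise multivariate resistance-surface optimization
#'
#' Builds a multivariate model from ranked univariate winners. Variables
#' are appended in rank order; after each addition the parameters of every
#' included variable are re-optimized one variable at a time (grid search
#' with the others fixed), the objective being the partial Mantel r of
#' genetic distance against the composed surface's resistance distances,
#' partialling out IBR. An appended variable stays only if the full model
#' passes the reduced-model test: GD ~ full | reduced significant and
#' GD ~ reduced | full not significant. Rounds repeat until no parameter
#' changes or `max_rounds` is reached.
#'
#' @param gd genetic distance matrix.
#' @param winners list of supported [optimize_univariate()] results, each
#'   carrying `variable`, `family`, `spec`, `ranking`, and with an
#'   attached grid (the `ranking` parameter columns are reused).
#' @param rasters named list of raw variable rasters (names = variables).
#' @param focal_xy focal individuals (`id`, `x`, `y`).
#' @param ibr_matrix IBR resistance distances.
#' @param n_perm,alpha,seed inference settings.
#' @param max_rounds maximum full optimization rounds per model size.
#' @param edge_mode passed to [build_graph()].
#' @return List of class `multivariate_model`: `specs` (named list of the
#'   included variables' specs), `r`, `p`, `included`, `rejected`,
#'   `reduced_tests` (per appended variable), `rs_vs_reduced`, `converged`.
#' @export
optimize_multivariate <- function(gd, winners, rasters, focal_xy,
                                  ibr_matrix, n_perm = 199, alpha = 0.05,
                                  seed = NULL, max_rounds = 4,
                                  edge_mode = "average_resistance") {
  stopifnot(length(winners) >= 1L)
  ord <- order(-vapply(winners, function(w) w$r, numeric(1)))
  winners <- winners[ord]
  seed_k <- if (is.null(seed)) NULL else seed
  next_seed <- function() {
    if (is.null(seed_k)) return(NULL)
    seed_k <<- seed_k + 1L
    seed_k
  }
  param_cols <- function(w) setdiff(names(w$ranking), c("r", "p"))
  obj <- function(specs) {
    lv <- specs_to_matrix(specs, rasters, focal_xy, edge_mode)
    pm <- partial_mantel(gd, lv, ibr_matrix, n_perm = n_perm,
                         seed = next_seed())
    list(r = pm$r, p = pm$p, lv = lv)
  }

  if (length(winners) == 1L) {
    w <- winners[[1L]]
    ev <- obj(stats::setNames(list(w$spec), w$variable))
    return(structure(list(specs = stats::setNames(list(w$spec), w$variable),
                          r = ev$r, p = ev$p, included = w$variable,
                          rejected = character(0),
                          reduced_tests = list(), rs_vs_reduced = numeric(0),
                          converged = TRUE),
                     class = "multivariate_model"))
  }

  specs <- stats::setNames(list(winners[[1L]]$spec), winners[[1L]]$variable)
  best <- obj(specs)
  included <- winners[[1L]]$variable
  rejected <- character(0)
  reduced_tests <- list()
  rs_vs_reduced <- numeric(0)
  converged <- TRUE

  # re-optimize each included variable's parameters, holding others fixed
  refine <- function(specs, best) {
    for (round in seq_len(max_rounds)) {
      changed <- FALSE
      for (v in names(specs)) {
        w <- winners[[which(vapply(winners, function(z) z$variable,
                                   character(1)) == v)]]
        grid <- unique(w$ranking[param_cols(w)])
        for (k in seq_len(nrow(grid))) {
          cand_spec <- spec_from_row(v, w$family, grid[k, , drop = FALSE])
          if (isTRUE(all.equal(cand_spec[c("r_max", "x", "optimum")],
                               specs[[v]][c("r_max", "x", "optimum")])))
            next
          cand <- specs; cand[[v]] <- cand_spec
          ev <- obj(cand)
          if (ev$r > best$r + 1e-12) {     # accept only improvements
            specs <- cand; best <- ev; changed <- TRUE
          }
        }
      }
      if (!changed) return(list(specs = specs, best = best,
                                converged = TRUE))
    }
    list(specs = specs, best = best, converged = FALSE)
  }

  for (w in winners[-1L]) {
    reduced_lv <- best$lv
    # append the variable and re-optimize: for the first pair both
    # variables are optimized coordinate-wise (second free with first
    # fixed, then first free with second fixed, until stable); later
    # variables are optimized alone with the accepted set held constant.
    # The reduced-model test then decides whether the addition stays.
    cand_specs <- c(specs, stats::setNames(list(w$spec), w$variable))
    cand <- obj(cand_specs)
    if (length(specs) == 1L) {
      # first pair: exhaustive scan of the joint parameter grid (the
      # coordinate-wise search can stall on a ridge where both variables
      # must strengthen together), before the pair is judged
      v1 <- names(specs)[1L]
      w1 <- winners[[which(vapply(winners, function(z) z$variable,
                                  character(1)) == v1)]]
      g1 <- unique(w1$ranking[param_cols(w1)])
      g2 <- unique(w$ranking[param_cols(w)])
      for (k1 in seq_len(nrow(g1))) for (k2 in seq_len(nrow(g2))) {
        trial <- list(spec_from_row(v1, w1$family, g1[k1, , drop = FALSE]),
                      spec_from_row(w$variable, w$family,
                                    g2[k2, , drop = FALSE]))
        names(trial) <- c(v1, w$variable)
        ev <- obj(trial)
        if (ev$r > cand$r + 1e-12) { cand_specs <- trial; cand <- ev }
      }
    }
    # later variables enter at their univariate-best parameters: judging
    # them after tuning on the same objective would bias the reduced-model
    # test towards acceptance
    # reduced-model test (tests 3 and 4)
    t3 <- partial_mantel(gd, cand$lv, reduced_lv, n_perm = n_perm,
                         seed = next_seed())
    t4 <- partial_mantel(gd, reduced_lv, cand$lv, n_perm = n_perm,
                         seed = next_seed())
    reduced_tests[[w$variable]] <-
      list(r3 = t3$r, p3 = t3$p, r4 = t4$r, p4 = t4$p)
    rs_vs_reduced[w$variable] <- relative_support(t3$r, t4$r)
    if (t3$p <= alpha && t4$p > alpha) {
      specs <- cand_specs; best <- cand
      included <- c(included, w$variable)
      ref2 <- refine(specs, best)   # settle parameters after acceptance
      specs <- ref2$specs; best <- ref2$best
      converged <- converged && ref2$converged
    } else {
      rejected <- c(rejected, w$variable)
    }
  }

  structure(list(specs = specs, r = best$r, p = best$p,
                 included = included, rejected = rejected,
                 reduced_tests = reduced_tests,
                 rs_vs_reduced = rs_vs_reduced, converged = converged),
            class = "multivariate_model")
}

#' @export
print.multivariate_model <- function(x, ...) {
  cat(sprintf("<multivariate_model> %s: r = %.3f (P = %.4g)%s\n",
              paste(x$included, collapse = " + "), x$r, x$p,
              if (x$converged) "" else " [not converged]"))
  if (length(x$rejected))
    cat("  rejected:", paste(x$rejected, collapse = ", "), "\n")
  invisible(x)
}
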