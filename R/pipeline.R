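# End-to-end orchestration: locus screen -> Dps -> IBD -> autocorrelogram ->
# univariate optimization -> causal modelling -> multivariate optimization ->
# MRM with VIF-driven exclusion -> current map, with every table written out.

#' Run the full landscape-genetics pipeline
#'
#' Executes the whole inference chain on a genotype table plus a set of
#' landscape rasters and writes the report tables (CSV) and the cumulative
#' current map (ASCII grid) of the best-supported model to `out_dir`.
#' Every output file carries a comment header with the package version,
#' master seed and a hash of the configuration, and a rerun with the same
#' configuration and seed is byte-identical.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{genotypes}{path to a GenAlEx-style CSV, or a
#'       [genotype_table].}
#'     \item{rasters}{named list of Arc/Info ASCII grid paths or
#'       [raster_grid] objects (raw landscape variables).}
#'     \item{variables}{named list: per variable a list with `family`
#'       (`"classified"` or `"power_deviation"`) and, for the latter,
#'       `optimum`; optional `grid` data.frame overrides
#'       [default_param_grid()].}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{master integer seed (default 1).}
#'     \item{alpha}{significance level (default 0.05).}
#'     \item{n_perm}{optional list overriding permutation counts:
#'       `ibd` (10000), `partial` (999), `hwe` (999), `autocorr` (199),
#'       `mrm` (499).}
#'     \item{class_width_m}{autocorrelogram class width (default 5000).}
#'     \item{edge_mode}{circuit edge mode (default "average_resistance").}
#'     \item{write_current_map}{logical (default TRUE).}
#'   }
#' @return List of class `report_bundle` with all stage results and the
#'   paths of the written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (req in c("genotypes", "rasters", "variables", "out_dir"))
    if (is.null(config[[req]]))
      stop(sprintf("config is missing '%s'", req))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  np <- utils::modifyList(list(ibd = 10000, partial = 999, hwe = 999,
                               autocorr = 199, mrm = 499),
                          if (is.null(config$n_perm)) list()
                          else config$n_perm)
  class_width <- if (is.null(config$class_width_m)) 5000
                 else config$class_width_m
  edge_mode <- if (is.null(config$edge_mode)) "average_resistance"
               else config$edge_mode
  cfg_hash <- config_hash(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  stamp <- sprintf("# resistkit %s; seed=%d; config=%s",
                   as.character(utils::packageVersion("resistkit")),
                   seed, cfg_hash)
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    con <- file(p, "w"); on.exit(close(con))
    writeLines(stamp, con)
    utils::write.csv(format(df, digits = 10), con, row.names = FALSE)
    paths[name] <<- p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  g <- stage("load genotypes",
             if (inherits(config$genotypes, "genotype_table"))
               config$genotypes
             else read_genalex(config$genotypes))
  rasters <- stage("load rasters", lapply(config$rasters, function(r) {
    if (inherits(r, "raster_grid")) r
    else if (is.character(r) && file.exists(r)) read_ascii_grid(r)
    else stop(sprintf("raster path not found: %s", r))
  }))

  screen <- stage("locus screen",
                  locus_screen(g, n_perm = np$hwe, alpha = alpha,
                               seed = seed))
  emit(screen, "locus_screen")
  dropped <- screen$locus[screen$excluded]
  if (length(dropped) && length(dropped) < length(g$loci))
    g <- drop_loci(g, dropped)

  gd <- stage("Dps", dps_matrix(g))
  geo <- geo_distance_matrix(g)
  ibd <- stage("IBD", mantel_test(gd, geo, n_perm = np$ibd,
                                  seed = seed + 1L))
  emit(data.frame(test = "IBD (GD ~ geographic distance)", r = ibd$r,
                  p = ibd$p, n_perm = ibd$n_perm), "ibd")

  autoc <- stage("autocorrelogram", {
    res <- spatial_autocorrelogram(g, class_width_m = class_width,
                                   n_perm = np$autocorr,
                                   n_boot = np$autocorr,
                                   seed = seed + 2L)
    res$subset <- "all"
    for (s in c("F", "M")) {
      if (sum(g$sex == s) >= 10L) {
        rs <- spatial_autocorrelogram(g, class_width_m = class_width,
                                      n_perm = np$autocorr,
                                      n_boot = np$autocorr,
                                      sex_filter = s, seed = seed + 2L)
        rs$subset <- s
        res <- rbind(res, rs)
      }
    }
    res
  })
  emit(autoc, "autocorrelogram")

  template <- rasters[[1L]]
  ibr <- ibr_surface(template)
  focal <- data.frame(id = g$ids, x = g$x, y = g$y)
  ibr_mat <- stage("IBR distances",
                   resistance_matrix(build_graph(ibr, focal,
                                                 edge_mode = edge_mode)))

  uni <- list()
  uni_rows <- list()
  causal_rows <- list()
  vi <- 0L
  for (v in names(config$variables)) {
    vi <- vi + 1L
    vc <- config$variables[[v]]
    grid <- if (!is.null(vc$grid)) as.data.frame(vc$grid)
            else default_param_grid(vc$family, optimum = vc$optimum)
    cm <- stage(paste("univariate", v),
                optimize_univariate(gd, rasters[[v]], vc$family, grid,
                                    focal, ibr_mat, n_perm = np$partial,
                                    alpha = alpha, seed = seed + 10L * vi,
                                    variable = v, edge_mode = edge_mode))
    uni[[v]] <- cm
    uni_rows[[v]] <- data.frame(variable = v, params = spec_label(cm$spec),
                                r = cm$r, p = cm$p, supported = cm$supported)
    ct <- stage(paste("causal", v), {
      lv <- specs_to_matrix(list(cm$spec),
                            stats::setNames(rasters[v], v), focal,
                            edge_mode)
      causal_ibr_test(gd, lv, ibr_mat, n_perm = np$partial, alpha = alpha,
                      seed = seed + 10L * vi + 5L)
    })
    causal_rows[[v]] <- data.frame(variable = v,
                                   params = spec_label(cm$spec),
                                   rs_ibr = ct$rs, r1 = ct$r1, p1 = ct$p1,
                                   r2 = ct$r2, p2 = ct$p2,
                                   supported = ct$supported)
  }
  emit(do.call(rbind, uni_rows), "univariate")
  causal_tab <- do.call(rbind, causal_rows)
  emit(causal_tab, "causal")

  supported <- names(uni)[vapply(causal_rows, function(r) r$supported,
                                 logical(1))]
  multi <- NULL
  if (length(supported) >= 2L) {
    multi <- stage("multivariate",
                   optimize_multivariate(gd, uni[supported], rasters, focal,
                                         ibr_mat, n_perm = np$partial,
                                         alpha = alpha, seed = seed + 100L,
                                         edge_mode = edge_mode))
    mt <- data.frame(
      model = paste(multi$included, collapse = " + "),
      params = paste(vapply(multi$specs, spec_label, character(1)),
                     collapse = "; "),
      r = multi$r, p = multi$p,
      rejected = paste(multi$rejected, collapse = " + "),
      converged = multi$converged)
    emit(mt, "multivariate")
  } else {
    emit(data.frame(model = if (length(supported) == 1L) supported
                    else "IBD only",
                    params = "", r = NA_real_, p = NA_real_,
                    rejected = "", converged = TRUE), "multivariate")
  }

  mrm_res <- stage("MRM", {
    preds <- list(IBR = ibr_mat)
    for (v in supported)
      preds[[v]] <- specs_to_matrix(list(uni[[v]]$spec),
                                    stats::setNames(rasters[v], v),
                                    focal, edge_mode)
    mrm_model_select(gd, preds, n_perm = np$mrm, seed = seed + 200L)
  })
  emit(mrm_res$table, "mrm")

  cm_path <- NULL
  if (!identical(config$write_current_map, FALSE)) {
    cm_path <- stage("current map", {
      best_specs <- if (!is.null(multi)) multi$specs
                    else if (length(supported) >= 1L)
                      stats::setNames(
                        lapply(supported[1L], function(v) uni[[v]]$spec),
                        supported[1L])
                    else NULL
      surf <- if (is.null(best_specs)) ibr
              else compose_surfaces(lapply(names(best_specs), function(v)
                transform_raster(rasters[[v]], best_specs[[v]])))
      gr <- build_graph(surf, focal, edge_mode = edge_mode)
      cmap <- current_map(gr)
      p <- file.path(out_dir, "current_map.asc")
      write_ascii_grid(cmap, p)
      p
    })
    paths["current_map"] <- cm_path
  }

  structure(list(genotypes = g, locus_screen = screen, dps = gd,
                 ibd = ibd, autocorrelogram = autoc,
                 univariate = uni, causal = causal_tab,
                 multivariate = multi, mrm = mrm_res,
                 supported = supported, paths = paths, seed = seed,
                 config_hash = cfg_hash),
            class = "report_bundle")
}

spec_label <- function(spec) {
  if (spec$family == "classified")
    sprintf("classified; R_max=%g", spec$r_max)
  else
    sprintf("optimum=%g; x=%g; R_max=%g", spec$optimum, spec$x, spec$r_max)
}

# deterministic hash of the configuration (paths and parameters)
config_hash <- function(config) {
  config$out_dir <- NULL
  norm <- config[order(names(config))]
  norm <- rapply(norm, function(x)
    if (inherits(x, "genotype_table") || inherits(x, "raster_grid"))
      "<object>" else x, how = "replace")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(norm), collapse = ""), tf)
  unname(substr(tools::md5sum(tf), 1L, 12L))
}

#' MRM model selection with collinearity handling
#'
#' Fits the full MRM of the genetic distances on all predictor matrices;
#' when any predictor has VIF > 10, the most strongly correlated predictor
#' pair is identified and the model is refitted dropping each member in
#' turn. The resulting model set is ranked by AICc with Akaike weights.
#'
#' @param gd response distance matrix.
#' @param predictors named list of predictor distance matrices.
#' @param n_perm,seed permutation settings per fit.
#' @param vif_threshold collinearity threshold (default 10).
#' @return List: `models` (named list of [mrm()] fits), `table`
#'   (per-model AICc ranking with weights), `best` (name of the
#'   AICc-best model).
#' @export
mrm_model_select <- function(gd, predictors, n_perm = 499, seed = NULL,
                             vif_threshold = 10) {
  full <- mrm(gd, predictors, n_perm = n_perm, seed = seed)
  models <- list(full = full)
  if (length(predictors) > 2L && max(full$vif) > vif_threshold) {
    X <- vapply(predictors, lower_vec, numeric(nrow(gd) * (nrow(gd) - 1) / 2))
    cc <- abs(stats::cor(X)); diag(cc) <- 0
    w <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    pair <- names(predictors)[w]
    for (drop in pair) {
      nm <- paste0("drop_", drop)
      models[[nm]] <- mrm(gd, predictors[setdiff(names(predictors), drop)],
                          n_perm = n_perm, seed = seed)
    }
  }
  aicc <- vapply(models, function(m) m$aicc, numeric(1))
  wtab <- akaike_weights(aicc)
  tab <- data.frame(model = names(models),
                    predictors = vapply(models, function(m)
                      paste(m$coefficients$term[-1L], collapse = " + "),
                      character(1)),
                    r_squared = vapply(models, function(m) m$r_squared,
                                       numeric(1)),
                    p_overall = vapply(models, function(m) m$p_overall,
                                       numeric(1)),
                    max_vif = vapply(models, function(m) max(m$vif),
                                     numeric(1)),
                    aicc = wtab$aicc, delta_aicc = wtab$delta,
                    weight = wtab$weight)
    tab <- tab[order(tab$aicc), , drop = FALSE]
  list(models = models, table = tab, best = tab$model[1L])
}
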