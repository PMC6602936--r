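# Synthetic landscapes and genotypes: every downstream stage of the
# pipeline is testable by parameter recovery on data simulated with a known
# resistance structure.

#' Generate a synthetic landscape scenario
#'
#' Builds a named set of co-registered rasters: a smooth, spatially
#' correlated elevation field (moving-average filtered Gaussian noise),
#' slope and aspect derived from it by central finite differences, vertical
#' river lines every `river_spacing` columns, horizontal road lines every
#' `road_spacing` rows, and a binary forest layer (elevation above its
#' median). Aspect is the downslope direction in degrees `[0, 360)`
#' clockwise from north; flat cells get aspect 0 and slope 0.
#'
#' @param shape `c(rows, cols)`, both at least 8.
#' @param seed integer seed; layers are identical across calls with the
#'   same arguments.
#' @param river_spacing column spacing of the vertical river lines.
#' @param road_spacing row spacing of the horizontal road lines.
#' @param cell_size cell edge (metres); 1 km by default.
#' @param relief standard deviation (metres) of the elevation field.
#' @param smooth_passes number of 3x3 moving-average passes applied to the
#'   elevation noise.
#' @return List of class `landscape_scenario`: `layers` (named
#'   [raster_grid]s: elevation, slope, aspect, rivers, roads, forest),
#'   `shape`, `cell_size`, `seed`.
#' @export
make_landscape <- function(shape, seed = 1, river_spacing = 3,
                           road_spacing = 4, cell_size = 1000,
                           relief = 500, smooth_passes = 4) {
  if (length(shape) != 2L || any(shape < 8L))
    stop("shape must be at least (8, 8)")
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  set.seed(seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (k in seq_len(smooth_passes)) z <- smooth3x3(z)
  z <- (z - mean(z)) / stats::sd(z)
  elev <- 500 + relief * z

  d <- finite_differences(elev, cell_size)
  slope <- atan(sqrt(d$dzdx^2 + d$dzdy^2)) * 180 / pi
  aspect <- (atan2(d$dzdx, -d$dzdy) * 180 / pi) %% 360
  aspect[slope == 0] <- 0

  rivers <- matrix(0, nr, nc)
  rcols <- seq(river_spacing, nc, by = river_spacing)
  rivers[, rcols] <- 1
  roads <- matrix(0, nr, nc)
  rrows <- seq(road_spacing, nr, by = road_spacing)
  roads[rrows, ] <- 1
  forest <- (elev > stats::median(elev)) * 1

  as_layer <- function(v) raster_grid(v, cell_size = cell_size)
  structure(list(
    layers = list(elevation = as_layer(elev), slope = as_layer(slope),
                  aspect = as_layer(aspect), rivers = as_layer(rivers),
                  roads = as_layer(roads), forest = as_layer(forest)),
    shape = c(nr, nc), cell_size = cell_size, seed = seed),
    class = "landscape_scenario")
}

smooth3x3 <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  # pad by edge replication, then average the 3x3 neighbourhood
  zp <- z[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + zp[dr + seq_len(nr), dc + seq_len(nc)]
  acc / 9
}

finite_differences <- function(z, cs) {
  nr <- nrow(z); nc <- ncol(z)
  east <- z[, c(2:nc, nc)]; west <- z[, c(1L, 1:(nc - 1L))]
  south <- z[c(2:nr, nr), ]; north <- z[c(1L, 1:(nr - 1L)), ]
  span_x <- matrix(2, nr, nc); span_x[, c(1L, nc)] <- 1
  span_y <- matrix(2, nr, nc); span_y[c(1L, nr), ] <- 1
  list(dzdx = (east - west) / (span_x * cs),
       dzdy = (north - south) / (span_y * cs))  # y increases northwards
}

#' @export
print.landscape_scenario <- function(x, ...) {
  cat(sprintf("<landscape_scenario> %d x %d cells (%g m), seed %d; layers: %s\n",
              x$shape[1L], x$shape[2L], x$cell_size, x$seed,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Write all scenario layers as Arc/Info ASCII grids
#'
#' @param scenario a [make_landscape()] scenario.
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_landscape <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(scenario$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(scenario$layers[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Stepping-stone deme model on a resistance surface
#'
#' One deme per non-nodata cell of `surface`, each of constant size `n_e`.
#' Migration follows the 8-neighbour conductance graph of the surface: the
#' per-edge rate is `m_max * (edge conductance / max edge conductance)`, so
#' a deme's total emigration is at most `(4 + 4/sqrt(2)) * m_max` (interior
#' deme on a uniform surface) and migration is exactly proportional to edge
#' conductance. Reproduction is Wright-Fisher within deme
#' (each offspring draws two parents, implemented as backward migration:
#' each parent comes from a neighbouring deme with the corresponding edge
#' probability). Mutation is stepwise: each allele copies with probability
#' `1 - mu`, otherwise gains or loses one repeat unit.
#'
#' @param surface [raster_grid] true resistance surface (>= 1 everywhere).
#' @param n_e diploid individuals per deme.
#' @param n_loci number of microsatellite loci.
#' @param mu per-locus per-generation stepwise mutation rate.
#' @param generations number of non-overlapping generations to simulate.
#' @param m_max migration rate on the most conductive edge; per-deme total
#'   emigration must stay at or below 1, which bounds `m_max` by about
#'   0.146 on a uniform surface.
#' @param edge_mode passed to [build_graph()].
#' @return List of class `deme_model`.
#' @export
deme_model <- function(surface, n_e = 50, n_loci = 13, mu = 5e-4,
                       generations = 100, m_max = 0.1,
                       edge_mode = "average_resistance") {
  stopifnot(inherits(surface, "raster_grid"), n_e >= 1, n_loci >= 1,
            mu >= 0, generations >= 0, m_max >= 0, m_max <= 1)
  ok <- which(!is.na(surface$values))
  n_demes <- length(ok)
  # deme adjacency + conductances from the circuit graph (cell centres)
  ctr <- cell_centres(surface)
  rows <- row(surface$values)[ok]; cols <- col(surface$values)[ok]
  xy <- data.frame(id = sprintf("deme%04d", seq_len(n_demes)),
                   x = ctr$x[cols], y = ctr$y[rows])
  mig_i <- integer(0); mig_j <- integer(0); mig_rate <- numeric(0)
  if (n_demes > 1L) {
    gr <- build_graph(surface, xy, edge_mode = edge_mode)
    if (length(gr$cond) > 0L) {
      rate <- m_max * gr$cond / max(gr$cond)
      mig_i <- c(gr$edges_i, gr$edges_j)
      mig_j <- c(gr$edges_j, gr$edges_i)
      mig_rate <- c(rate, rate)
      tot <- tapply(mig_rate, mig_i, sum)
      if (any(mig_rate < 0) || any(tot > 1))
        stop(paste("migration rates inconsistent with the deme grid:",
                   "per-deme emigration exceeds 1; lower m_max"))
    }
  }
  structure(list(surface = surface, n_demes = n_demes, n_e = n_e,
                 n_loci = n_loci, mu = mu, generations = generations,
                 m_max = m_max,
                 deme_x = xy$x, deme_y = xy$y,
                 mig_i = mig_i, mig_j = mig_j, mig_rate = mig_rate),
            class = "deme_model")
}

#' @export
print.deme_model <- function(x, ...) {
  cat(sprintf(
    "<deme_model> %d demes x %d individuals, %d loci, mu = %g, G = %d, m_max = %g\n",
    x$n_demes, x$n_e, x$n_loci, x$mu, x$generations, x$m_max))
  invisible(x)
}

#' Simulate microsatellite genotypes on a deme model
#'
#' Forward Wright-Fisher simulation on the stepping-stone grid: founders
#' draw each allele uniformly from 8-20 repeat units; each generation every
#' deme produces exactly `n_e` offspring (2 `n_e` gametes) whose parents
#' come from the deme itself or, with the per-edge migration probabilities,
#' from a neighbouring deme; alleles then mutate stepwise with probability
#' `mu`. With `mu = 0` and `generations = 0` the founder pool is returned
#' unchanged. Finally `n_samples` individuals are drawn without
#' replacement; sampled coordinates are the deme (cell) centre plus a
#' uniform jitter smaller than half a cell, and sex is assigned 50/50.
#'
#' @param model a [deme_model].
#' @param n_samples individuals to sample (at most the population of the
#'   sampled demes).
#' @param seed integer seed; the run is reproducible per seed.
#' @param sample_from `"all"` demes, or `"habitat"` to sample only demes
#'   below the geometric midpoint of the surface's resistance range
#'   (individuals are not collected on the barrier features themselves).
#' @return A [genotype_table]; the sampled individuals' deme indices are
#'   attached as attribute `"deme"`.
#' @export
simulate_genotypes <- function(model, n_samples = 150, seed = 1,
                               sample_from = c("all", "habitat")) {
  stopifnot(inherits(model, "deme_model"))
  sample_from <- match.arg(sample_from)
  n_tot <- model$n_demes * model$n_e
  set.seed(seed)
  L <- model$n_loci; N <- model$n_e; K <- model$n_demes
  deme_of <- rep(seq_len(K), each = N)
  A1 <- matrix(sample(8:20, n_tot * L, replace = TRUE), n_tot, L)
  A2 <- matrix(sample(8:20, n_tot * L, replace = TRUE), n_tot, L)

  # per-deme source distribution for a parent (stay prob + neighbour probs)
  src <- vector("list", K)
  for (d in seq_len(K)) {
    sel <- model$mig_i == d
    nb <- model$mig_j[sel]; pr <- model$mig_rate[sel]
    src[[d]] <- list(demes = c(d, nb), prob = c(1 - sum(pr), pr))
  }

  for (gen in seq_len(model$generations)) {
    # draw two parent demes for every offspring
    p1_deme <- integer(n_tot); p2_deme <- integer(n_tot)
    for (d in seq_len(K)) {
      off <- which(deme_of == d)
      s <- src[[d]]
      p1_deme[off] <- s$demes[sample.int(length(s$demes), length(off),
                                         replace = TRUE, prob = s$prob)]
      p2_deme[off] <- s$demes[sample.int(length(s$demes), length(off),
                                         replace = TRUE, prob = s$prob)]
    }
    p1 <- (p1_deme - 1L) * N + sample.int(N, n_tot, replace = TRUE)
    p2 <- (p2_deme - 1L) * N + sample.int(N, n_tot, replace = TRUE)
    pick1 <- matrix(stats::runif(n_tot * L) < 0.5, n_tot, L)
    pick2 <- matrix(stats::runif(n_tot * L) < 0.5, n_tot, L)
    B1 <- ifelse(pick1, A1[p1, , drop = FALSE], A2[p1, , drop = FALSE])
    B2 <- ifelse(pick2, A1[p2, , drop = FALSE], A2[p2, , drop = FALSE])
    if (model$mu > 0) {
      B1 <- mutate_stepwise(B1, model$mu)
      B2 <- mutate_stepwise(B2, model$mu)
    }
    A1 <- B1; A2 <- B2
  }

  pool <- seq_len(n_tot)
  if (sample_from == "habitat") {
    # habitat = cells below the geometric midpoint of the resistance range,
    # i.e. off the high-resistance barrier features
    rvals <- model$surface$values[!is.na(model$surface$values)]
    habitat <- which(rvals <= sqrt(min(rvals) * max(rvals)) + 1e-9)
    pool <- which(deme_of %in% habitat)
  }
  if (n_samples > length(pool))
    stop(sprintf("n_samples (%d) exceeds sampleable individuals (%d)",
                 n_samples, length(pool)))
  take <- sort(sample(pool, n_samples))
  d <- deme_of[take]
  cs <- model$surface$cell_size
  jit <- function(n) stats::runif(n, -0.499, 0.499) * cs
  alleles <- array(NA_integer_, c(n_samples, L, 2L))
  alleles[, , 1L] <- A1[take, , drop = FALSE]
  alleles[, , 2L] <- A2[take, , drop = FALSE]
  g <- genotype_table(
    ids = sprintf("ind%04d", seq_len(n_samples)),
    x = model$deme_x[d] + jit(n_samples),
    y = model$deme_y[d] + jit(n_samples),
    sex = sample(rep_len(c("F", "M"), n_samples)),
    loci = sprintf("loc%02d", seq_len(L)),
    alleles = alleles)
  attr(g, "deme") <- d
  g
}

mutate_stepwise <- function(A, mu) {
  hit <- stats::runif(length(A)) < mu
  if (any(hit)) {
    step <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
    A[hit] <- pmax(1L, A[hit] + step)
  }
  A
}

#' Bundled simulation presets
#'
#' Three study conditions used throughout the test suites:
#'
#' * `"strong"` — rivers plus roads (both classified, `R_max = 100`) shape
#'   migration: strong, recoverable landscape structure with two
#'   geometrically independent barrier systems.
#' * `"weak"` — rivers only, `R_max = 2`: marginal structure.
#' * `"ibd"` — uniform surface: pure isolation by distance, no landscape
#'   signal.
#'
#' Defaults follow the package's reference condition: a 15 x 15 deme grid,
#' `n_e = 50`, 13 loci, `mu = 5e-4`, 100 generations, `m_max = 0.1`. This
#' keeps differentiation in the quasi-linear regime where shared-allele
#' distance still responds approximately linearly to effective resistance;
#' much stronger structure saturates and the causal-modelling partial
#' Mantel tests lose their intended behaviour (see the methods vignette).
#'
#' @param name preset name.
#' @param shape deme/raster grid shape.
#' @param seed landscape seed.
#' @param ... overrides passed to [deme_model()].
#' @return List: `scenario`, `true_specs` (list of [transform_spec]s, empty
#'   for `"ibd"`), `surface` (composed true surface), `model`.
#' @export
landscape_preset <- function(name = c("strong", "weak", "ibd"),
                             shape = c(15, 15), seed = 1, ...) {
  name <- match.arg(name)
  scenario <- make_landscape(shape, seed = seed)
  true_specs <- switch(name,
    strong = list(
      transform_spec("rivers", "classified", r_max = 100),
      transform_spec("roads", "classified", r_max = 100)),
    weak = list(transform_spec("rivers", "classified", r_max = 2)),
    ibd = list())
  surface <- if (length(true_specs)) {
    compose_surfaces(lapply(true_specs, function(s)
      transform_raster(scenario$layers[[s$variable]], s)))
  } else {
    ibr_surface(scenario$layers$elevation)
  }
  args <- utils::modifyList(list(surface = surface, generations = 100),
                            list(...))
  model <- do.call(deme_model, args)
  list(scenario = scenario, true_specs = true_specs, surface = surface,
       model = model, name = name)
}
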