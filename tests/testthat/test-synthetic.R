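test_that("landscapes are deterministic per seed and have valid layers", {
  a <- make_landscape(c(20, 20), seed = 1)
  b <- make_landscape(c(20, 20), seed = 1)
  for (nm in names(a$layers))
    expect_identical(a$layers[[nm]]$values, b$layers[[nm]]$values)
  c <- make_landscape(c(20, 20), seed = 2)
  expect_false(identical(a$layers$elevation$values,
                         c$layers$elevation$values))
  asp <- a$layers$aspect$values
  expect_true(all(asp >= 0 & asp < 360))
  expect_true(all(a$layers$rivers$values %in% c(0, 1)))
  expect_true(all(a$layers$roads$values %in% c(0, 1)))
  expect_error(make_landscape(c(5, 20)), "8")
})

test_that("river rasterization count follows the spacing rule", {
  sc <- make_landscape(c(20, 20), seed = 1, river_spacing = 5)
  # 4 vertical lines at columns 5, 10, 15, 20 -> 4 * 20 river cells
  expect_equal(sum(sc$layers$rivers$values), 4 * 20)
})

test_that("flat elevation yields zero slope", {
  d <- resistkit:::finite_differences(matrix(7, 6, 6), 1000)
  expect_true(all(d$dzdx == 0) && all(d$dzdy == 0))
  # and the slope layer of a nearly flat landscape is ~0 where gradient is 0
  sc <- make_landscape(c(8, 8), seed = 1, relief = 0)
  expect_true(all(sc$layers$slope$values == 0))
  expect_true(all(sc$layers$aspect$values == 0))
})

test_that("zero generations and zero mutation return the founder pool", {
  ps <- landscape_preset("ibd", shape = c(8, 8), seed = 1,
                         generations = 0, mu = 0, n_loci = 5)
  g1 <- simulate_genotypes(ps$model, n_samples = 20, seed = 3)
  g2 <- simulate_genotypes(ps$model, n_samples = 20, seed = 3)
  expect_identical(g1$alleles, g2$alleles)
  expect_true(all(g1$alleles >= 8 & g1$alleles <= 20))
  # coordinate jitter stays within half a cell of the deme centre
  cs <- ps$model$surface$cell_size
  d <- attr(g1, "deme")
  expect_true(all(abs(g1$x - ps$model$deme_x[d]) < cs / 2))
  expect_true(all(abs(g1$y - ps$model$deme_y[d]) < cs / 2))
})

test_that("simulation is reproducible per seed and respects deme sizes", {
  ps <- landscape_preset("weak", shape = c(8, 8), seed = 2,
                         generations = 5, n_loci = 4, n_e = 10)
  g1 <- simulate_genotypes(ps$model, n_samples = 30, seed = 11)
  g2 <- simulate_genotypes(ps$model, n_samples = 30, seed = 11)
  expect_identical(g1$alleles, g2$alleles)
  expect_identical(g1$x, g2$x)
  g3 <- simulate_genotypes(ps$model, n_samples = 30, seed = 12)
  expect_false(identical(g1$alleles, g3$alleles))
  expect_error(simulate_genotypes(ps$model, n_samples = 1e6, seed = 1),
               "exceeds")
})

test_that("alleles in the next generation come from the parent pool when mu = 0", {
  ps <- landscape_preset("ibd", shape = c(8, 8), seed = 4,
                         generations = 3, mu = 0, n_loci = 6, n_e = 20)
  g <- simulate_genotypes(ps$model, n_samples = 50, seed = 5)
  expect_true(all(g$alleles >= 8 & g$alleles <= 20))
})

test_that("migration feasibility is validated", {
  surf <- raster_grid(matrix(1, 8, 8), cell_size = 1000)
  expect_error(deme_model(surf, m_max = 0.9), "emigration")
  m <- deme_model(surf, m_max = 0.1)
  # per-deme emigration totals stay below 1 and rates are conductance-scaled
  tot <- tapply(m$mig_rate, m$mig_i, sum)
  expect_true(all(tot <= 1))
  expect_equal(max(m$mig_rate), 0.1)
})

test_that("heterozygosity decays at the Wright-Fisher drift rate", {
  # single closed deme, N_e = 50, G = 100, mu = 0: expect
  # H_G = H_0 (1 - 1/(2 N_e))^G on average over replicates
  n_rep <- 20
  surf <- raster_grid(matrix(1, 1, 1), cell_size = 1000)
  model <- deme_model(surf, n_e = 50, n_loci = 13, mu = 0,
                      generations = 100, m_max = 0)
  gene_div <- function(g) {
    mean(vapply(seq_along(g$loci), function(l) {
      a <- c(g$alleles[, l, 1], g$alleles[, l, 2])
      p <- table(a) / length(a)
      (length(a) / (length(a) - 1)) * (1 - sum(p^2))
    }, numeric(1)))
  }
  h0 <- numeric(n_rep); hG <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    f <- deme_model(surf, n_e = 50, n_loci = 13, mu = 0, generations = 0,
                    m_max = 0)
    hG[k] <- gene_div(simulate_genotypes(model, 50, seed = 1000 + k))
    h0[k] <- gene_div(simulate_genotypes(f, 50, seed = 1000 + k))
  }
  ratio <- mean(hG) / mean(h0)
  expected <- (1 - 1 / 100)^100
  se <- sd(hG / mean(h0)) / sqrt(n_rep)
  expect_lt(abs(ratio - expected), max(3 * se, 0.03))
})

test_that("two isolated demes drift to high Dps after many generations", {
  # m = 0, G >> N_e: demes fix independently; between-deme Dps approaches 1
  surf <- raster_grid(matrix(1, 1, 2), cell_size = 1000)
  between <- numeric(10)
  for (k in 1:10) {
    model <- deme_model(surf, n_e = 10, n_loci = 13, mu = 0,
                        generations = 150, m_max = 0)
    g <- simulate_genotypes(model, 20, seed = 300 + k)
    d <- attr(g, "deme")
    dps <- dps_matrix(g)
    between[k] <- mean(dps[d == 1, d == 2])
  }
  # expected ~ 1 - P(two demes fix the same allele) = roughly 1 - 1/13
  expect_gt(mean(between), 0.8)
})

test_that("panmixia yields no isolation by distance", {
  # emulate panmixia by a tiny 2x2 grid with near-maximal mixing (per-deme
  # emigration close to 1): genotypes become exchangeable across demes
  surf <- raster_grid(matrix(1, 2, 2), cell_size = 1000)
  sig <- 0L
  n_rep <- 20
  for (k in seq_len(n_rep)) {
    model <- deme_model(surf, n_e = 50, n_loci = 10, mu = 0,
                        generations = 30, m_max = 0.35)
    g <- simulate_genotypes(model, 40, seed = 400 + k)
    m <- mantel_test(dps_matrix(g), geo_distance_matrix(g),
                     n_perm = 99, seed = k)
    sig <- sig + (m$p <= 0.05)
  }
  expect_lte(sig, 0.10 * n_rep)  # >= 90% non-significant
})

test_that("habitat sampling avoids barrier cells", {
  ps <- landscape_preset("strong", shape = c(12, 12), seed = 5,
                         generations = 2)
  g <- simulate_genotypes(ps$model, 40, seed = 6, sample_from = "habitat")
  d <- attr(g, "deme")
  vals <- ps$surface$values[!is.na(ps$surface$values)]
  expect_true(all(vals[d] <= sqrt(min(vals) * max(vals)) + 1e-9))
})
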