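test_that("locus summaries match closed-form diversity values", {
  # 10 individuals all heterozygous A/B at one locus: Ho = 1,
  # unbiased He = (2n/(2n-1)) * (1 - 0.5) = 10/19, F_IS < 0
  calls <- rep(list(list(c(100, 102), c(8, 8))), 10)
  g <- toy_genotypes(calls)
  s <- locus_screen(g, n_perm = 199, seed = 1)
  expect_equal(s$ho[1], 1)
  expect_equal(s$he[1], 10 / 19)
  expect_lt(s$f_is[1], 0)
  # monomorphic second locus: Ho = He = 0, F_IS and HWE P missing
  expect_equal(s$ho[2], 0)
  expect_equal(s$he[2], 0)
  expect_true(is.na(s$f_is[2]))
  expect_true(is.na(s$hwe_p[2]))
  expect_equal(s$null_freq[2], 0)
})

test_that("null-allele estimator is zero when Ho equals He", {
  he <- 0.6; ho <- 0.6
  expect_equal((he - ho) / (1 + he), 0)
  # homozygote excess gives a positive estimate via locus_screen
  calls <- c(rep(list(list(c(100, 100))), 8), rep(list(list(c(102, 102))), 8))
  g <- toy_genotypes(calls)
  s <- locus_screen(g, n_perm = 199, seed = 1)
  expect_gt(s$null_freq[1], 0)
  expect_equal(s$ho[1], 0)
})

test_that("Dps handles shared-allele counting by multiset intersection", {
  g <- toy_genotypes(list(
    list(c(100, 102)),    # ind 1
    list(c(100, 104)),    # ind 2: shares one allele -> Dps = 0.5
    list(c(100, 102)),    # ind 3: identical to ind 1 -> 0
    list(c(106, 108))     # ind 4: nothing shared -> 1
  ))
  d <- dps_matrix(g)
  expect_equal(d["ind01", "ind02"], 0.5)
  expect_equal(d["ind01", "ind03"], 0)
  expect_equal(d["ind01", "ind04"], 1)
  # homozygote vs heterozygote sharing: {a,a} vs {a,b} shares one
  g2 <- toy_genotypes(list(list(c(5, 5)), list(c(5, 7))))
  expect_equal(dps_matrix(g2)[1, 2], 0.5)
})

test_that("Dps is symmetric, bounded, and invariant to relabeling and locus order", {
  set.seed(42)
  n <- 20; L <- 5
  al <- array(sample(8:12, n * L * 2, TRUE), c(n, L, 2))
  al[1, 2, ] <- NA   # some missing calls
  g <- genotype_table(sprintf("i%02d", 1:n), runif(n), runif(n),
                      rep("U", n), sprintf("L%d", 1:L), al)
  d <- dps_matrix(g)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  # allele relabeling (add 100 to every allele) leaves Dps unchanged
  g2 <- genotype_table(g$ids, g$x, g$y, g$sex, g$loci, al + 100L)
  expect_equal(dps_matrix(g2), d)
  # locus order permutation leaves Dps unchanged
  perm <- sample(L)
  g3 <- genotype_table(g$ids, g$x, g$y, g$sex, g$loci[perm],
                       al[, perm, , drop = FALSE])
  expect_equal(dps_matrix(g3), d)
})

test_that("pairs with no commonly typed locus are an error naming the pair", {
  g <- toy_genotypes(list(
    list(c(1, 2), NULL),
    list(NULL, c(3, 4))
  ))
  expect_error(dps_matrix(g), "ind01.*ind02|ind02.*ind01")
})

test_that("GenAlEx round trip preserves genotypes, coordinates and sex", {
  set.seed(9)
  ps <- landscape_preset("ibd", shape = c(8, 8), seed = 1,
                         generations = 0, n_loci = 4)
  g <- simulate_genotypes(ps$model, n_samples = 25, seed = 2)
  p <- tempfile(fileext = ".csv")
  write_genalex(g, p)
  g2 <- read_genalex(p)
  expect_equal(g2$alleles, g$alleles)
  expect_equal(g2$x, g$x)
  expect_equal(g2$sex, g$sex)
  expect_equal(g2$loci, g$loci)
})

test_that("double-centered covariance has zero row sums", {
  set.seed(3)
  d <- random_dist(15, 3)
  C <- double_center(d^2)
  expect_lt(max(abs(rowSums(C))), 1e-10)
})

test_that("autocorrelation r matches a direct double-loop oracle", {
  # all individuals at one location -> a single distance class; r must equal
  # sum of off-diagonal c over sum of diagonal c, computed by brute force
  set.seed(11)
  n <- 12
  al <- array(sample(8:14, n * 4 * 2, TRUE), c(n, 4, 2))
  g <- genotype_table(sprintf("i%02d", 1:n), rep(1, n), rep(1, n),
                      rep("U", n), sprintf("L%d", 1:4), al)
  res <- spatial_autocorrelogram(g, class_width_m = 10, max_dist_m = 10,
                                 n_perm = 19, n_boot = 19, seed = 1)
  D <- dps_matrix(g)
  C <- matrix(NA_real_, n, n)
  d2 <- D^2
  for (i in 1:n) for (j in 1:n)
    C[i, j] <- -0.5 * (d2[i, j] - mean(d2[i, ]) - mean(d2[, j]) + mean(d2))
  r_oracle <- sum(C[row(C) != col(C)]) / sum(diag(C))
  expect_equal(res$r[1], r_oracle, tolerance = 1e-10)
})

test_that("autocorrelation is inside the null envelope for shuffled coordinates", {
  # genotypes with spatial structure destroyed by permuting coordinates:
  # observed r should sit inside the permutation envelope in most runs
  set.seed(21)
  ps <- landscape_preset("ibd", shape = c(8, 8), seed = 3,
                         generations = 10, n_loci = 8)
  inside <- 0L; total <- 0L
  for (k in 1:10) {
    g <- simulate_genotypes(ps$model, n_samples = 30, seed = 100 + k)
    idx <- sample(length(g$ids))
    gp <- genotype_table(g$ids, g$x[idx], g$y[idx], g$sex, g$loci, g$alleles)
    res <- spatial_autocorrelogram(gp, class_width_m = 3000,
                                   n_perm = 99, n_boot = 19,
                                   seed = 200 + k)
    ok <- !is.na(res$r)
    inside <- inside + sum(res$r[ok] >= res$perm_lo[ok] &
                           res$r[ok] <= res$perm_hi[ok])
    total <- total + sum(ok)
  }
  expect_gte(inside / total, 0.9)
})
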