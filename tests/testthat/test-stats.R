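test_that("mantel r is the lower-triangle correlation; identical matrices give 1", {
  a <- random_dist(10, 1)
  m <- mantel_test(a, a, n_perm = 99, seed = 1)
  expect_equal(m$r, 1)
  b <- random_dist(10, 2)
  m2 <- mantel_test(a, b, n_perm = 99, seed = 1)
  expect_equal(m2$r, cor(a[lower.tri(a)], b[lower.tri(b)]))
  # r is symmetric in the arguments
  expect_equal(mantel_test(b, a, n_perm = 99, seed = 1)$r, m2$r)
  # cross-check against the community implementation
  skip_if_not_installed("vegan")
  expect_equal(m2$r, unname(vegan::mantel(a, b, permutations = 9)$statistic),
               tolerance = 1e-12)
})

test_that("exact enumeration at n = 4 equals the rank of the observed statistic", {
  a <- random_dist(4, 5)
  b <- random_dist(4, 6)
  m <- mantel_test(a, b, exact = TRUE)
  expect_equal(m$n_perm, 24L)
  # oracle: recompute all 24 permutation statistics by explicit loops
  perms <- list()
  for (i in 1:4) for (j in setdiff(1:4, i)) for (k in setdiff(1:4, c(i, j)))
    perms[[length(perms) + 1]] <- c(i, j, k, setdiff(1:4, c(i, j, k)))
  vb <- b[lower.tri(b)]
  r_all <- vapply(perms, function(p) {
    ap <- a[p, p]
    cor(ap[lower.tri(ap)], vb)
  }, numeric(1))
  r_obs <- cor(a[lower.tri(a)], vb)
  expect_equal(m$p, mean(r_all >= r_obs - 1e-12))
})

test_that("constant matrices are rejected", {
  a <- matrix(1, 5, 5); diag(a) <- 0
  dimnames(a) <- list(letters[1:5], letters[1:5])
  expect_error(mantel_test(a, random_dist(5, 1, letters[1:5]), n_perm = 9),
               "constant")
})

test_that("partial mantel r agrees with the analytic partial correlation", {
  for (seed in c(5, 17, 23)) {
    a <- random_dist(10, seed)
    b <- random_dist(10, seed + 100)
    c <- random_dist(10, seed + 200)
    pm <- partial_mantel(a, b, c, n_perm = 9, seed = 1)
    va <- a[lower.tri(a)]; vb <- b[lower.tri(b)]; vc <- c[lower.tri(c)]
    rab <- cor(va, vb); rac <- cor(va, vc); rbc <- cor(vb, vc)
    expect_equal(pm$r, (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2)),
                 tolerance = 1e-10)
  }
})

test_that("partial mantel degenerates gracefully", {
  a <- random_dist(8, 1)
  b <- random_dist(8, 2)
  # constant C: partialling it out leaves the simple mantel r
  c0 <- matrix(1, 8, 8, dimnames = dimnames(a))
  diag(c0) <- 0
  pm <- partial_mantel(a, b, c0, n_perm = 9, seed = 1)
  expect_equal(pm$r, cor(a[lower.tri(a)], b[lower.tri(b)]),
               tolerance = 1e-12)
  # A = B: partial r = 1 whatever C
  c <- random_dist(8, 4)
  expect_equal(partial_mantel(a, a, c, n_perm = 9, seed = 1)$r, 1)
  # C collinear with B is an error
  expect_error(partial_mantel(a, b, 2 * b, n_perm = 9), "collinear")
})

test_that("mantel permutation P is invariant to joint relabeling", {
  a <- random_dist(9, 31)
  b <- random_dist(9, 32)
  m1 <- mantel_test(a, b, n_perm = 199, seed = 7)
  idx <- sample(9)
  a2 <- a[idx, idx]; b2 <- b[idx, idx]
  m2 <- mantel_test(a2, b2, n_perm = 199, seed = 7)
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
})

test_that("MRM reproduces mantel r^2 with one predictor and flags collinearity", {
  gd <- random_dist(12, 41)
  x1 <- random_dist(12, 42)
  fit <- mrm(gd, list(x1 = x1), n_perm = 99, seed = 1)
  r_mantel <- mantel_test(gd, x1, n_perm = 9, seed = 1)$r
  expect_lt(abs(fit$r_squared - r_mantel^2), 1e-10)
  expect_equal(fit$vif, c(x1 = 1))
  # identical response: R2 = 1, beta = 1
  fit2 <- mrm(gd, list(x = gd), n_perm = 9, seed = 1)
  expect_equal(fit2$r_squared, 1)
  expect_equal(fit2$coefficients$beta[2], 1, tolerance = 1e-10)
  # perfectly collinear predictors error naming the pair
  expect_error(mrm(gd, list(a = x1, b = 2 * x1), n_perm = 9),
               "collinear.*\\ba\\b|collinear.*\\bb\\b")
})

test_that("orthogonalized predictors give unit VIF", {
  set.seed(50)
  n <- 10
  # build two predictor matrices whose lower triangles are orthogonal
  v1 <- rnorm(n * (n - 1) / 2)
  v2 <- residuals(lm(rnorm(length(v1)) ~ v1))
  mk <- function(v) {
    m <- matrix(0, n, n); m[lower.tri(m)] <- v; m <- m + t(m)
    dimnames(m) <- list(letters[1:n], letters[1:n]); m
  }
  gd <- random_dist(n, 51, letters[1:n])
  fit <- mrm(gd, list(p1 = mk(v1), p2 = mk(v2)), n_perm = 9, seed = 1)
  expect_equal(unname(fit$vif), c(1, 1), tolerance = 1e-10)
})

test_that("Akaike weights follow the closed form", {
  w <- akaike_weights(c(100, 102))
  expect_equal(w$delta, c(0, 2))
  expect_equal(w$weight, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(sum(w$weight), 1)
  # invariant to a constant shift
  w2 <- akaike_weights(c(0, 2))
  expect_equal(w2$weight, w$weight)
})

test_that("Holm adjustment matches hand computations and is monotone", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.05, 0.05, 0.05)), c(0.15, 0.15, 0.15))
  expect_identical(holm_adjust(numeric(0)), numeric(0))
  set.seed(60)
  p <- runif(10)
  adj <- holm_adjust(p)
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
  expect_true(all(adj <= 1))
})
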