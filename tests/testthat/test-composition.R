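# Binned compositions, geometric means, ilr transform, paired Hotelling T2.

test_that("binned compositions close to 100 and handle concentration cases", {
  # uniform density over a 100-nt window -> every part 10
  dens <- density_from_counts(list(u = rep(2L, 100)))
  win <- windows_tbl("u", 100L, 0L, 100L)
  comp <- bin_composition(dens, win)
  expect_equal(comp$part, rep(10, 10))
  # 30-nt window with all density in the first 3 nt -> [100, 0, ..., 0]
  cts <- integer(30)
  cts[1:3] <- 5L
  comp2 <- bin_composition(density_from_counts(list(c = cts)),
                           windows_tbl("c", 30L, 0L, 30L))
  expect_equal(comp2$part, c(100, rep(0, 9)))
})

test_that("bin sums match a brute-force segmentation oracle", {
  set.seed(13)
  vals <- rpois(100, 4)
  dens <- density_from_counts(list(x = vals))
  comp <- bin_composition(dens, windows_tbl("x", 100L, 0L, 100L))
  oracle <- vapply(1:10, function(b) {
    100 * sum(vals[((b - 1) * 10 + 1):(b * 10)]) / sum(vals)
  }, numeric(1))
  expect_equal(comp$part, oracle)
  # 103-nt window: remainder goes to the three 3'-most bins (sizes 10x7, 11x3)
  vals2 <- rpois(103, 4)
  comp2 <- bin_composition(density_from_counts(list(y = vals2)),
                           windows_tbl("y", 103L, 0L, 103L))
  sizes <- c(rep(10, 7), rep(11, 3))
  ends <- cumsum(sizes)
  oracle2 <- vapply(1:10, function(b) {
    100 * sum(vals2[(ends[b] - sizes[b] + 1):ends[b]]) / sum(vals2)
  }, numeric(1))
  expect_equal(comp2$part, oracle2)
  expect_equal(sum(comp2$part), 100)
})

test_that("geometric mean profile is idempotent, symmetric and matches its closed form", {
  # identical compositions -> that composition
  m <- matrix(rep(c(30, 20, 10, 25, 15), 4), nrow = 4, byrow = TRUE)
  gm <- geometric_mean_profile(composition_from_matrix(m))
  expect_equal(gm$part, c(30, 20, 10, 25, 15))
  # two mirrored 2-part compositions -> [50, 50]
  m2 <- matrix(c(80, 20, 20, 80), nrow = 2, byrow = TRUE)
  gm2 <- geometric_mean_profile(composition_from_matrix(m2))
  expect_equal(gm2$part, c(50, 50))
  # random compositions: exp(mean(log)) re-closed, by direct oracle
  set.seed(101)
  m3 <- matrix(runif(50, 1, 10), nrow = 5)
  m3 <- 100 * m3 / rowSums(m3)
  gm3 <- geometric_mean_profile(composition_from_matrix(m3))
  oracle <- exp(colMeans(log(m3)))
  expect_equal(gm3$part, 100 * oracle / sum(oracle))
  expect_equal(sum(gm3$part), 100)
})

test_that("zero parts are replaced multiplicatively before log-ratio work", {
  m <- matrix(c(50, 0, 30, 20,
                25, 25, 25, 25), nrow = 2, byrow = TRUE)
  gm <- geometric_mean_profile(composition_from_matrix(m))
  expect_true(all(is.finite(gm$part)))
  expect_equal(sum(gm$part), 100)
  # the replaced zero is 65% of the smallest nonzero part of that row
  ilr <- ilr_transform(composition_from_matrix(m))
  expect_true(all(is.finite(ilr$value)))
})

test_that("ilr of the uniform composition is the zero vector", {
  m <- matrix(10, nrow = 3, ncol = 10)
  ilr <- ilr_transform(composition_from_matrix(m))
  expect_equal(ilr$value, rep(0, 27))
  expect_equal(attr(ilr, "basis_id"), "pivot-1")
})

test_that("ilr coordinates match an explicit contrast-matrix oracle", {
  x <- c(1 / 2, 1 / 4, 1 / 4)
  # independent oracle: build the pivot basis from its definition and apply
  # t(V) %*% clr(x)
  V <- matrix(0, 3, 2)
  V[, 1] <- c(sqrt(2 / 3), -1 / sqrt(6), -1 / sqrt(6))
  V[, 2] <- c(0, sqrt(1 / 2), -sqrt(1 / 2))
  clr <- log(x) - mean(log(x))
  oracle <- as.numeric(t(V) %*% clr)
  got <- ilr_transform(composition_from_matrix(matrix(100 * x, nrow = 1)))
  expect_equal(got$value, oracle)
  # first pivot coordinate closed form: sqrt(2/3) * log(x1 / gm(x2, x3))
  expect_equal(got$value[1], sqrt(2 / 3) * log((1 / 2) / sqrt(1 / 16)))
})

test_that("ilr is closure-invariant", {
  set.seed(7)
  x <- runif(10, 1, 5)
  a <- ilr_transform(composition_from_matrix(matrix(x, nrow = 1)))
  b <- ilr_transform(composition_from_matrix(matrix(7.3 * x, nrow = 1)))
  expect_equal(a$value, b$value)
})

test_that("ilr bases are orthonormal with zero column sums", {
  for (type in c("pivot", "helmert")) {
    V <- ilr_basis(10, type)
    expect_equal(t(V) %*% V, diag(9), ignore_attr = TRUE)
    expect_equal(colSums(V), rep(0, 9))
  }
})

test_that("identical paired samples give T2 = 0 and p = 1", {
  set.seed(19)
  m <- matrix(rnorm(60), nrow = 12)
  a <- ilr_from_matrix(m)
  ht <- paired_hotelling(a, a)
  expect_equal(ht$T2, 0)
  expect_equal(ht$p_value, 1)
  expect_equal(ht$n_pairs, 12L)
})

test_that("paired T2, F and p match the direct matrix-formula oracle (n=12, p=2)", {
  set.seed(33)
  A <- matrix(rnorm(24), nrow = 12)
  B <- matrix(rnorm(24, mean = 0.4), nrow = 12)
  ht <- paired_hotelling(ilr_from_matrix(A), ilr_from_matrix(B))
  # oracle: explicit dbar' S^-1 dbar
  D <- A - B
  n <- 12; p <- 2
  dbar <- colMeans(D)
  S <- cov(D)
  T2o <- n * as.numeric(t(dbar) %*% solve(S) %*% dbar)
  Fo <- T2o * (n - p) / (p * (n - 1))
  expect_equal(ht$T2, T2o)
  expect_equal(ht$F, Fo)
  expect_equal(ht$df1, 2L)
  expect_equal(ht$df2, 10L)
  expect_equal(ht$p_value, pf(Fo, p, n - p, lower.tail = FALSE))
  # F relation invariant holds
  expect_equal(ht$F, ht$T2 * (ht$n_pairs - ht$df1) /
                 (ht$df1 * (ht$n_pairs - 1)))
  # broom-style accessors
  expect_equal(glance(ht)$T2, T2o)
  expect_equal(nrow(tidy(ht)), 2L)
})

test_that("T2 is invariant across orthonormal ilr bases", {
  set.seed(47)
  mk <- function() {
    m <- matrix(runif(200, 1, 20), nrow = 20)
    composition_from_matrix(100 * m / rowSums(m))
  }
  ca <- mk(); cb <- mk()
  h_pivot <- paired_hotelling(ilr_transform(ca), ilr_transform(cb))
  Vh <- ilr_basis(10, "helmert")
  h_helm <- paired_hotelling(ilr_transform(ca, Vh), ilr_transform(cb, Vh))
  expect_lt(abs(h_pivot$T2 - h_helm$T2), 1e-8)
  expect_lt(abs(h_pivot$p_value - h_helm$p_value), 1e-8)
})

test_that("degenerate paired inputs are rejected", {
  set.seed(3)
  small <- matrix(rnorm(45), nrow = 5, ncol = 9)
  expect_error(paired_hotelling(ilr_from_matrix(small),
                                ilr_from_matrix(small + 1)),
               "insufficient paired ORFs")
  # mismatched ORF sets
  a <- ilr_from_matrix(matrix(rnorm(20), nrow = 10,
                              dimnames = list(sprintf("x%d", 1:10), NULL)))
  b <- ilr_from_matrix(matrix(rnorm(20), nrow = 10,
                              dimnames = list(sprintf("y%d", 1:10), NULL)))
  expect_error(paired_hotelling(a, b), "different ORF sets")
  # collinear differences -> singular covariance
  base <- matrix(rnorm(12), nrow = 12, ncol = 1)
  A <- cbind(base, 2 * base)
  Bm <- matrix(0, nrow = 12, ncol = 2)
  expect_error(paired_hotelling(ilr_from_matrix(A), ilr_from_matrix(Bm)),
               "singular")
})

test_that("Mardia p-values are uniform under multivariate normality", {
  set.seed(59)
  reps <- 150
  pv <- replicate(reps, {
    X <- matrix(rnorm(400 * 3), ncol = 3)
    normality_check(X)$p_value[1]  # skewness component
  })
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Mardia's test rejects strongly lognormal samples with high power", {
  set.seed(67)
  hits <- replicate(30, {
    X <- exp(matrix(rnorm(200 * 3), ncol = 3))  # strongly skewed
    any(normality_check(X)$p_value < 0.05)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("normality check refuses n <= p", {
  X <- matrix(rnorm(45), nrow = 5, ncol = 9)
  expect_error(normality_check(X), "n > p")
})
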