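test_that("median-ratio size factors recover scalar column multiples", {
  m <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  expect_equal(unname(median_ratio_size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  expect_equal(unname(median_ratio_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)))
  # product constraint for scalars c and 1/c
  expect_equal(prod(median_ratio_size_factors(m2)), 1)
})

test_that("size factors match a brute-force per-row-ratio median", {
  set.seed(11)
  m <- matrix(rpois(15, 50) + 1, 5, 3)
  got <- median_ratio_size_factors(m)
  # independent oracle: literal definition, row by row
  geo <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  want <- apply(m, 2, function(col) median(col / geo))
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("size factors error without an all-positive reference row", {
  m <- cbind(c(0, 5), c(3, 0))
  expect_error(median_ratio_size_factors(m), "no reference rows")
})

test_that("NB test is centered under identity and recovers planted folds", {
  m <- matrix(50L, 20, 4, dimnames = list(paste0("r", 1:20), NULL))
  res <- nb_differential_test(m, c("a", "a", "b", "b"), c("a", "b"))
  expect_equal(res$log2fc, rep(0, 20))
  expect_true(all(res$p_value > 0.99))

  # power: 400 planted 4-fold among 2000 at the study thresholds
  set.seed(101)
  n <- 2000; planted <- 1601:2000
  mu <- matrix(100, n, 4)
  mu[planted, 3:4] <- 400
  cnt <- matrix(rnbinom(n * 4, mu = mu, size = 1 / 0.05), n, 4,
                dimnames = list(paste0("r", 1:n), NULL))
  res <- nb_differential_test(cnt, c("h", "h", "t", "t"), c("h", "t"))
  hit <- res$q_value < 0.01 & res$log2fc > 1
  expect_gte(mean(hit[planted]), 0.9)
  expect_lte(sum(hit[-planted]), 5)
})

test_that("NB test flags groups with zero total counts as degenerate", {
  m <- rbind(c(0L, 0L, 9L, 11L), c(5L, 6L, 5L, 6L))
  res <- nb_differential_test(m, c("a", "a", "b", "b"), c("a", "b"),
                              size_factors = rep(1, 4))
  expect_true(res$degenerate[1])
  expect_false(res$degenerate[2])
  expect_true(is.finite(res$log2fc[1]))
})

test_that("BH adjustment matches the step-up rule and handles NaN", {
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(5)
  p <- runif(100)
  got <- bh_adjust(p)
  # oracle: literal q_i = min over p_(j) >= p_i of m p_(j) / j
  m <- length(p)
  ord <- order(p)
  want <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(p[ord] >= p[i])
    want[i] <- min(1, min(m * p[ord][j] / j))
  }
  expect_equal(got, want, tolerance = 1e-12)
  # q nondecreasing along sorted p; same rejections as classical step-up
  expect_true(all(diff(got[ord]) >= -1e-12))
  alpha <- 0.1
  k <- max(c(0, which(p[ord] <= alpha * seq_len(m) / m)))
  classical <- if (k > 0) sort(ord[1:k]) else integer(0)
  expect_equal(sort(which(got < alpha | got == alpha)), classical)

  mixed <- c(0.01, NaN, 0.5)
  q <- bh_adjust(mixed)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(c(0.01, 0.5), "BH"))
})

test_that("Fisher exact test matches analytic cases and fisher.test", {
  r <- fisher_exact_2x2(matrix(5, 2, 2))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)

  r2 <- fisher_exact_2x2(rbind(c(10, 0), c(0, 10)))
  expect_equal(r2$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(r2$degenerate_or)

  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(3, 4))))

  set.seed(21)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 8), 2, 2)
    mine <- fisher_exact_2x2(tab)
    ref <- stats::fisher.test(tab)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    # invariance under simultaneous row and column swap
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact_2x2(swapped)$p_value, mine$p_value)
    expect_gt(mine$p_value, 0)
    expect_lte(mine$p_value, 1)
  }
})

test_that("signed-rank test: degenerate, all-positive and enumerated cases", {
  a <- c(1, 2, 3, 4, 5, 6, 7)
  r <- wilcoxon_signed_rank(a, a)
  expect_equal(r$p_value, 1)
  expect_true(r$all_zero)

  # 8 distinct positive differences: exact two-sided p = 2 / 2^8
  b <- a <- 1:8
  r2 <- wilcoxon_signed_rank(a + (1:8) / 10, b)
  expect_equal(r2$p_value, 2 / 2^8, tolerance = 1e-12)

  # n = 10 random pairs vs exhaustive sign-flip enumeration
  set.seed(33)
  x <- rnorm(10); y <- rnorm(10)
  r3 <- wilcoxon_signed_rank(x, y)
  d <- x - y
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 10))
  w_all <- as.matrix(signs) %*% rk
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  expect_equal(r3$p_value, min(1, 2 * min(p_le, p_ge)), tolerance = 1e-12)
})

test_that("signed-rank normal approximation agrees with wilcox.test", {
  set.seed(44)
  x <- rnorm(40); y <- rnorm(40, 0.3)
  r <- wilcoxon_signed_rank(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE, correct = FALSE))
  expect_equal(r$method, "normal")
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("z-score normalization gives population-sd rows and flags ties", {
  z <- zscore_normalize(rbind(c(1, 2, 3)))
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-6)

  z2 <- zscore_normalize(rbind(c(2, 2, 2), c(1, 2, 3)))
  expect_equal(as.numeric(z2[1, ]), c(0, 0, 0))
  expect_equal(attr(z2, "constant_rows"), 1L)

  set.seed(55)
  m <- matrix(rnorm(40), 10, 4)
  z3 <- zscore_normalize(m)
  expect_true(all(abs(rowMeans(z3)) < 1e-12))
  expect_true(all(abs(sqrt(rowMeans(z3^2)) - 1) < 1e-12))
})
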