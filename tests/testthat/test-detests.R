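test_that("Wilcoxon exact p-values match exhaustive enumeration", {
  # the textbook case: values 1..6, group 2 holds the top three ranks
  m <- matrix(1:6, nrow = 1)
  res <- wilcoxon_test(m, group = c(1, 1, 1, 2, 2, 2))
  expect_equal(res$p_raw, 2 / 20, tolerance = 1e-12)
  expect_equal(res$p_raw, oracle_wilcoxon_exact(1:6, c(1, 1, 1, 2, 2, 2)),
               tolerance = 1e-12)

  # every assignment of tie-free values for (3,3) and (4,4)
  for (n_per in c(3, 4)) {
    n <- 2 * n_per
    set.seed(n)
    values <- sort(rnorm(n))
    combs <- combn(n, n_per)
    for (b in seq_len(ncol(combs))) {
      grp <- rep(1, n)
      grp[combs[, b]] <- 2
      res <- wilcoxon_test(matrix(values, nrow = 1), group = grp)
      expect_equal(res$p_raw, oracle_wilcoxon_exact(values, grp),
                   tolerance = 1e-12)
    }
  }
})

test_that("Wilcoxon is symmetric in labels and rank-invariant", {
  sim <- tiny_sim(seed = 10)
  nm <- log2_cpm(sim$counts)
  grp <- sim$counts$group
  a <- wilcoxon_test(nm$values, grp)
  b <- wilcoxon_test(nm$values, 3L - grp)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)

  c_ <- wilcoxon_test(exp(nm$values), grp)
  expect_equal(a$p_raw, c_$p_raw, tolerance = 1e-12)
})

test_that("Wilcoxon approximation tracks the exact law for n = 4 vs 4", {
  # Enumerating all 70 assignments, the continuity-corrected normal
  # approximation deviates from the exact two-sided p by at most ~0.031
  # (the worst case sits at |W - EW| = 4); every configuration is checked
  # against that enumerated bound.
  values <- sort(rnorm(8))
  combs <- combn(8, 4)
  for (b in seq_len(ncol(combs))) {
    grp <- rep(1, 8)
    grp[combs[, b]] <- 2
    exact <- oracle_wilcoxon_exact(values, grp)
    approx <- wilcoxon_test(matrix(values, nrow = 1), grp,
                            exact_threshold = 0)$p_raw
    expect_lt(abs(approx - exact), 0.035)
  }
})

test_that("degenerate genes get p = 1", {
  m <- rbind(rep(3, 8), c(1, 2, 3, 4, 10, 11, 12, 13))
  res <- wilcoxon_test(m, rep(1:2, each = 4))
  expect_equal(res$p_raw[1], 1)
  sres <- score_test_asymptotic(m, rep(1:2, each = 4))
  expect_equal(sres$statistic[1], 0)
  expect_equal(sres$p_raw[1], 1)
  pres <- score_test_permutation(m, rep(1:2, each = 4), B = 50, seed = 1)
  expect_equal(pres$p_raw[1], 1)
})

test_that("the score statistic equals n * r^2 and its perfect-separation form", {
  set.seed(12)
  mat <- matrix(rnorm(50 * 20), nrow = 50)
  grp <- rep(1:2, each = 10)
  res <- score_test_asymptotic(mat, grp)
  expect_equal(res$statistic, oracle_score_stat(mat, grp), tolerance = 1e-10)

  # constant within groups, different between: r^2 = 1, stat = n
  m <- matrix(rep(c(0, 1), each = 5), nrow = 1)
  res2 <- score_test_asymptotic(m, rep(1:2, each = 5))
  expect_equal(res2$statistic, 10, tolerance = 1e-12)
  expect_equal(res2$p_raw, pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("the asymptotic score test holds its type-I error under the null", {
  set.seed(33)
  mat <- matrix(rnorm(2000 * 200), nrow = 2000)
  grp <- rep(1:2, each = 100)
  res <- score_test_asymptotic(mat, grp)
  frac <- mean(res$p_raw < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("weighted and unweighted score tests agree under homoskedastic data", {
  set.seed(14)
  mat <- matrix(rnorm(300 * 60), nrow = 300)
  grp <- rep(1:2, each = 30)
  plain <- score_test_asymptotic(mat, grp)
  weighted <- score_test_asymptotic(mat, grp, weights = TRUE)
  expect_gt(cor(plain$statistic, weighted$statistic), 0.98)
})

test_that("permutation p-values: floor, constancy and exhaustive equivalence", {
  set.seed(15)
  # a huge effect beats every random permutation: p at the floor 1/(B+1)
  m <- matrix(c(rnorm(5), rnorm(5, 20)), nrow = 1)
  res <- score_test_permutation(m, rep(1:2, each = 5), B = 99, seed = 3)
  expect_equal(res$p_raw, 1 / 100, tolerance = 1e-12)

  # exhaustive enumeration equals the brute-force oracle
  set.seed(16)
  mat <- matrix(rnorm(12 * 6), nrow = 12)
  mat[1, ] <- mat[1, ] + c(0, 0, 0, 3, 3, 3)
  grp <- rep(1:2, each = 3)
  ex <- score_test_permutation(mat, grp, exhaustive = TRUE)
  expect_identical(attr(ex, "n_permutations"), as.integer(choose(6, 3)))
  expect_equal(ex$p_raw, oracle_score_perm_exact(mat, grp), tolerance = 1e-10)
  expect_gte(min(ex$p_raw), 1 / (attr(ex, "n_permutations") + 1))
})

test_that("the permutation floor warning names the unreachable level", {
  set.seed(17)
  mat <- matrix(rnorm(5 * 8), nrow = 5)
  expect_warning(
    score_test_permutation(mat, rep(1:2, each = 4), B = 9, seed = 1,
                           min_level = 0.01),
    "floor"
  )
})

test_that("permutation and asymptotic p-values agree in rank at large n and B", {
  set.seed(18)
  n <- 200
  mat <- matrix(rnorm(250 * n), nrow = 250)
  shift <- seq(0, 0.3, length.out = 250)
  mat[, (n / 2 + 1):n] <- mat[, (n / 2 + 1):n] + shift
  grp <- rep(1:2, each = n / 2)
  pa <- score_test_asymptotic(mat, grp)
  pp <- score_test_permutation(mat, grp, B = 2000, seed = 4)
  expect_gt(cor(pa$p_raw, pp$p_raw, method = "spearman"), 0.99)
})

test_that("BH adjustment matches the hand-derived and classical step-up rules", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(19)
  for (i in 1:1000) {
    m <- sample(5:80, 1)
    p <- round(runif(m)^sample(1:3, 1), 4)
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    adj <- bh_adjust(p)
    expect_gte(min(adj - p), 0)
    expect_identical(adj <= q, oracle_bh_reject(p, q))
  }
})

test_that("de results carry coherent p-value bookkeeping", {
  sim <- tiny_sim(seed = 20)
  ds <- make_semisynthetic(
    sim$counts,
    build_plan(select_gold_standard(sim$truth, 0.5, seed = 1), 20, seed = 2),
    select_gold_standard(sim$truth, 0.5, seed = 1)
  )
  for (res in list(wilcoxon_test(ds), score_test_asymptotic(ds),
                   score_test_permutation(ds, B = 200, seed = 9))) {
    expect_true(all(res$p_raw > 0 & res$p_raw <= 1))
    expect_true(all(res$p_adjusted >= res$p_raw))
    expect_true(all(res$p_adjusted <= 1))
    if (attr(res, "n_permutations") > 0) {
      expect_gte(min(res$p_raw), 1 / (attr(res, "n_permutations") + 1))
    }
  }
})
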