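# Per-gene two-group tests. Each returns a `semibench_de` tibble:
# gene_id, statistic, p_raw, p_adjusted, with the method and its settings as
# attributes. All tests are two-sided.

new_de_result <- function(tbl, method, settings, n_permutations = 0L) {
  stopifnot(all(c("gene_id", "statistic", "p_raw") %in% names(tbl)))
  tbl$gene_id <- unname(tbl$gene_id)
  tbl$statistic <- unname(tbl$statistic)
  tbl$p_raw <- unname(tbl$p_raw)
  tbl$p_adjusted <- bh_adjust(tbl$p_raw)
  structure(
    tbl,
    class = c("semibench_de", class(tbl)),
    method = method,
    settings = settings,
    n_permutations = as.integer(n_permutations)
  )
}

#' @export
print.semibench_de <- function(x, ...) {
  cat(sprintf("<semibench_de> method: %s (%d genes)\n",
              attr(x, "method"), nrow(x)))
  NextMethod()
}

#' @method tidy semibench_de
#' @export
tidy.semibench_de <- function(x, ...) {
  tibble(
    gene_id = x$gene_id,
    method = attr(x, "method"),
    statistic = x$statistic,
    p_raw = x$p_raw,
    p_adjusted = x$p_adjusted
  )
}

#' @method glance semibench_de
#' @export
glance.semibench_de <- function(x, ...) {
  tibble(
    method = attr(x, "method"),
    n_genes = nrow(x),
    n_permutations = attr(x, "n_permutations"),
    min_p_raw = min(x$p_raw),
    n_adj_05 = sum(x$p_adjusted <= 0.05)
  )
}

resolve_matrix_group <- function(x, group) {
  if (inherits(x, "semisynthetic_dataset")) {
    list(mat = x$analysis, group = x$group)
  } else if (inherits(x, "count_matrix")) {
    list(mat = x$counts, group = group %||% x$group)
  } else {
    if (is.null(group)) abort("`group` is required when `x` is a plain matrix.")
    stopifnot(is.matrix(x), length(group) == ncol(x))
    if (is.null(rownames(x))) rownames(x) <- sprintf("gene_%05d", seq_len(nrow(x)))
    list(mat = x, group = as.integer(factor(as.character(group))))
  }
}

#' Per-gene Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test of each gene between the two groups, via
#' [stats::wilcox.test()]: exact null distribution when both group sizes are
#' at most `exact_threshold` and the gene has no ties, otherwise the normal
#' approximation with tie correction and continuity correction. The test is
#' invariant to any strictly monotone transform of the values. A gene whose
#' values are all identical gets p = 1 (degenerate ranks).
#'
#' @param x Genes x samples matrix, [count_matrix()] or
#'   `semisynthetic_dataset`.
#' @param group Per-sample labels (1/2); taken from `x` when it carries them.
#' @param exact_threshold Largest per-group size for which the exact
#'   distribution is used (default 10).
#' @return A `semibench_de` tibble with BH-adjusted p-values.
#' @export
wilcoxon_test <- function(x, group = NULL, exact_threshold = 10) {
  mg <- resolve_matrix_group(x, group)
  mat <- mg$mat
  grp <- mg$group
  i1 <- grp == 1L
  i2 <- grp == 2L
  n1 <- sum(i1)
  n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) abort("Both groups need at least 2 samples.")
  n_degenerate <- 0L
  res <- vapply(seq_len(nrow(mat)), function(g) {
    v <- mat[g, ]
    if (max(v) == min(v)) {
      n_degenerate <<- n_degenerate + 1L
      return(c(n1 * n2 / 2, 1))
    }
    use_exact <- n1 <= exact_threshold && n2 <= exact_threshold &&
      anyDuplicated(v) == 0L
    wt <- suppressWarnings(
      wilcox.test(v[i2], v[i1], exact = use_exact, correct = TRUE)
    )
    c(wt$statistic, wt$p.value)
  }, numeric(2))
  if (n_degenerate > 0) {
    log_info("wilcoxon_test: %d gene(s) with all-identical values set to p = 1",
             n_degenerate)
  }
  new_de_result(
    tibble(gene_id = rownames(mat), statistic = res[1, ], p_raw = res[2, ]),
    method = "wilcoxon",
    settings = list(exact_threshold = exact_threshold, two_sided = TRUE,
                    tie_policy = "normal approximation with tie correction")
  )
}

# Score statistic n * r^2 for every row of `mat` against each column of the
# 0/1 indicator matrix `gmat` (one column per labeling). Zero-variance rows
# get statistic 0.
score_stat_matrix <- function(mat, gmat) {
  n <- nrow(gmat)
  xc <- mat - rowMeans(mat)
  sxx <- rowSums(xc^2)
  gc <- gmat - matrix(colMeans(gmat), nrow = n, ncol = ncol(gmat), byrow = TRUE)
  sgg <- colSums(gc^2)
  num <- (xc %*% gc)^2
  stat <- n * sweep(sweep(num, 1, pmax(sxx, .Machine$double.xmin), "/"),
                    2, sgg, "/")
  stat[sxx == 0, ] <- 0
  stat
}

#' Asymptotic score test for a group effect
#'
#' Per gene, the score test of the group coefficient in a linear model of
#' expression on the group indicator, referred to its chi-square(1) limit.
#' With `weights = FALSE` (the default) the statistic is \eqn{n r^2}, where
#' `r` is the sample correlation between the gene's values and the centered
#' group indicator. With `weights = TRUE`, per-observation precision weights
#' are estimated by pooling squared OLS residuals across all genes, averaging
#' them within 20 quantile bins of the fitted values, flooring the bin means
#' at 1e-8 and inverting them; the statistic is then the weighted score test.
#' This weight estimator is a simple binned smoother, not the estimator of
#' any published heteroskedasticity-weighted method. Applying it to
#' non-normalized data is discouraged because raw values are not comparable
#' across samples.
#'
#' @inheritParams wilcoxon_test
#' @param weights Estimate precision weights (default FALSE).
#' @return A `semibench_de` tibble. Zero-variance genes get statistic 0 and
#'   p = 1.
#' @export
score_test_asymptotic <- function(x, group = NULL, weights = FALSE) {
  mg <- resolve_matrix_group(x, group)
  mat <- mg$mat
  grp <- mg$group
  n <- length(grp)
  if (sum(grp == 1L) < 2 || sum(grp == 2L) < 2 || n < 4) {
    abort("Both groups need at least 2 samples and n >= 4.")
  }
  g <- as.numeric(grp == 2L)
  if (!weights) {
    stat <- as.vector(score_stat_matrix(mat, matrix(g, ncol = 1)))
  } else {
    w <- precision_weights(mat, grp)
    stat <- weighted_score_stat(mat, g, w)
  }
  p <- pmax(pchisq(stat, df = 1, lower.tail = FALSE), 1e-300)
  new_de_result(
    tibble(gene_id = rownames(mat), statistic = stat, p_raw = p),
    method = "score_asymptotic",
    settings = list(weights = weights, two_sided = TRUE)
  )
}

# Binned variance smoother: pool (fitted, residual^2) pairs over all genes,
# average residual^2 in 20 quantile bins of the fitted values, floor at 1e-8.
precision_weights <- function(mat, grp, n_bins = 20, floor = 1e-8) {
  i1 <- grp == 1L
  i2 <- grp == 2L
  fitted <- matrix(0, nrow(mat), ncol(mat))
  fitted[, i1] <- rowMeans(mat[, i1, drop = FALSE])
  fitted[, i2] <- rowMeans(mat[, i2, drop = FALSE])
  resid2 <- (mat - fitted)^2
  fv <- as.vector(fitted)
  breaks <- unique(quantile(fv, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(fv, breaks = breaks, include.lowest = TRUE)
  bin_var <- tapply(as.vector(resid2), bin, mean)
  v <- pmax(bin_var[as.integer(bin)], floor)
  matrix(1 / v, nrow(mat), ncol(mat))
}

# Weighted score statistic U^2 / V per gene, reducing to n r^2 at w == 1.
weighted_score_stat <- function(mat, g, w) {
  n <- length(g)
  sw <- rowSums(w)
  ybar <- rowSums(w * mat) / sw
  gbar <- rowSums(w * matrix(g, nrow(mat), n, byrow = TRUE)) / sw
  gc <- matrix(g, nrow(mat), n, byrow = TRUE) - gbar
  yc <- mat - ybar
  u <- rowSums(w * yc * gc)
  s2 <- rowSums(w * yc^2) / n
  v <- s2 * rowSums(w * gc^2)
  stat <- ifelse(v > 0, u^2 / v, 0)
  stat
}

#' Permutation score test
#'
#' Recomputes the score statistic under `B` random permutations of the group
#' labels (the same label permutations are shared across all genes, drawn
#' from one seeded stream) and reports the add-one permutation p-value
#' \deqn{p = (1 + \#\{b : T_b \ge T_{obs}\}) / (B + 1),}
#' which is valid for any B and makes the attainable floor `1/(B+1)` explicit.
#' That floor matters after multiple-testing correction: when `1/(B+1)`
#' exceeds the smallest BH threshold in play, no gene can clear it, which is
#' why the permutation test loses power at stringent nominal FDR levels.
#'
#' With `exhaustive = TRUE` all distinct group assignments are enumerated and
#' the exact permutation p-value `#\{T_b >= T_obs\}/M` is returned (the
#' observed assignment is part of the enumeration).
#'
#' @inheritParams wilcoxon_test
#' @param B Number of random label permutations (default 1000).
#' @param seed Optional integer seed for the permutation stream.
#' @param exhaustive Enumerate all assignments instead of sampling.
#' @param min_level If supplied, warn when `1/(B+1)` exceeds it.
#' @return A `semibench_de` tibble.
#' @export
score_test_permutation <- function(x, group = NULL, B = 1000, seed = NULL,
                                   exhaustive = FALSE, min_level = NULL) {
  mg <- resolve_matrix_group(x, group)
  mat <- mg$mat
  grp <- mg$group
  n <- length(grp)
  if (sum(grp == 1L) < 2 || sum(grp == 2L) < 2 || n < 4) {
    abort("Both groups need at least 2 samples and n >= 4.")
  }
  if (!exhaustive && (!is.numeric(B) || B < 1)) abort("`B` must be >= 1.")
  g <- as.numeric(grp == 2L)
  obs <- as.vector(score_stat_matrix(mat, matrix(g, ncol = 1)))

  if (exhaustive) {
    pos2 <- combn(n, sum(g))
    gmat <- matrix(0, n, ncol(pos2))
    gmat[cbind(as.vector(pos2), rep(seq_len(ncol(pos2)), each = nrow(pos2)))] <- 1
    s <- score_stat_matrix(mat, gmat)
    m <- ncol(gmat)
    tol <- 1e-8 * pmax(1, obs)
    p <- rowSums(s >= obs - tol) / m
    n_perm <- m
  } else {
    if (!is.null(seed)) set.seed(seed)
    B <- as.integer(B)
    gmat <- vapply(seq_len(B), function(b) sample(g), numeric(n))
    s <- score_stat_matrix(mat, gmat)
    tol <- 1e-8 * pmax(1, obs)
    p <- (1 + rowSums(s >= obs - tol)) / (B + 1)
    n_perm <- B
    if (!is.null(min_level) && 1 / (B + 1) > min_level) {
      warn(sprintf(
        "Permutation floor 1/(B+1) = %.2g exceeds the smallest nominal level %.2g; p-values cannot resolve below the floor.",
        1 / (B + 1), min_level
      ))
    }
  }
  new_de_result(
    tibble(gene_id = rownames(mat), statistic = obs, p_raw = p),
    method = "score_permutation",
    settings = list(B = n_perm, seed = seed, exhaustive = exhaustive,
                    two_sided = TRUE),
    n_permutations = n_perm
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_(j >= i) min(1, p_(j) * m / j)`, returned in the original
#' order. Thresholding the adjusted values at `q` reproduces the classical
#' BH rejection rule (reject the `k` smallest p-values for the largest `k`
#' with `p_(k) <= k q / m`). Computed via [stats::p.adjust()].
#'
#' @param p_raw Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_raw) {
  if (!is.numeric(p_raw) || anyNA(p_raw) ||
      any(p_raw < 0) || any(p_raw > 1)) {
    abort("`p_raw` must be p-values in [0, 1] without NAs.")
  }
  p.adjust(p_raw, method = "BH")
}
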