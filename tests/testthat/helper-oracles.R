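# Independent brute-force oracles. These re-derive expected values from the
# definitions by direct enumeration or element-wise evaluation; they never
# call the package code paths they check.

# Element-wise log2-CPM from the definition.
oracle_log2cpm <- function(counts, lib, factors, pseudocount) {
  out <- matrix(NA_real_, nrow(counts), ncol(counts))
  for (g in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      out[g, j] <- log2(
        (counts[g, j] + pseudocount) /
          (lib[j] * factors[j] + 2 * pseudocount) * 1e6
      )
    }
  }
  out
}

# Low-count filter evaluated gene by gene from the stated rule.
oracle_filter <- function(counts, group, lib, min_count, min_total_count) {
  cutoff <- min_count / median(lib) * 1e6
  m <- min(sum(group == 1), sum(group == 2))
  keep <- logical(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    n_above <- 0
    for (j in seq_len(ncol(counts))) {
      if (counts[g, j] / lib[j] * 1e6 >= cutoff) n_above <- n_above + 1
    }
    keep[g] <- (n_above >= m) && (sum(counts[g, ]) >= min_total_count)
  }
  keep
}

# Exact two-sided Wilcoxon p-value by enumerating every group assignment.
# Uses tail counting |W - E(W)| >= |w_obs - E(W)|, which equals the doubled
# one-tail probability for the symmetric tie-free null.
oracle_wilcoxon_exact <- function(values, group) {
  n <- length(values)
  idx2 <- which(group == 2)
  n2 <- length(idx2)
  r <- rank(values)
  w_obs <- sum(r[idx2]) - n2 * (n2 + 1) / 2
  ew <- n2 * (n - n2) / 2
  combs <- combn(n, n2)
  ws <- apply(combs, 2, function(ii) sum(r[ii]) - n2 * (n2 + 1) / 2)
  min(1, mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-12))
}

# Classical BH step-up rejection set: largest k with p_(k) <= k q / m.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0, which(ps <= seq_len(m) * q / m)))
  rejected <- logical(m)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  rejected
}

# Score statistic n * r^2 computed gene by gene with stats::cor.
oracle_score_stat <- function(mat, group) {
  g <- as.numeric(group == 2)
  n <- length(g)
  vapply(seq_len(nrow(mat)), function(i) {
    r <- suppressWarnings(cor(mat[i, ], g))
    if (is.na(r)) 0 else n * r^2
  }, numeric(1))
}

# Exact permutation p-values for the score test by full enumeration.
oracle_score_perm_exact <- function(mat, group) {
  n <- length(group)
  n2 <- sum(group == 2)
  combs <- combn(n, n2)
  stats <- sapply(seq_len(ncol(combs)), function(b) {
    gb <- rep(1, n)
    gb[combs[, b]] <- 2
    oracle_score_stat(mat, gb)
  })
  if (is.null(dim(stats))) stats <- matrix(stats, nrow = nrow(mat))
  obs <- oracle_score_stat(mat, group)
  vapply(seq_len(nrow(mat)), function(i) {
    mean(stats[i, ] >= obs[i] - 1e-10)
  }, numeric(1))
}

# TMM factor for a 2-sample matrix by direct enumeration of the trimmed gene
# set (log-ratio trim 30%, intensity trim 5%, inverse-variance weights),
# followed by the geometric-mean-1 rescaling over both samples.
oracle_tmm_two_sample <- function(x, ref_col = 2) {
  lib <- colSums(x)
  obs_col <- setdiff(1:2, ref_col)
  pair_factor <- function(obs, ref, n_obs, n_ref) {
    p_obs <- obs / n_obs
    p_ref <- ref / n_ref
    ok <- p_obs > 0 & p_ref > 0
    m <- log2(p_obs[ok] / p_ref[ok])
    a <- (log2(p_obs[ok]) + log2(p_ref[ok])) / 2
    w <- 1 / ((n_obs - obs[ok]) / (n_obs * obs[ok]) +
                (n_ref - ref[ok]) / (n_ref * ref[ok]))
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * 0.3) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1
    hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    2^(sum((m * w)[keep]) / sum(w[keep]))
  }
  f <- c(1, 1)
  f[obs_col] <- pair_factor(x[, obs_col], x[, ref_col],
                            lib[obs_col], lib[ref_col])
  f / exp(mean(log(f)))
}
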