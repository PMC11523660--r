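#' Library-size confounding diagnostic
#'
#' Quantifies the mechanism by which permuting raw counts before
#' normalization breaks the null: a high count swapped from a deeply
#' sequenced donor into a sample with a much smaller library size creates an
#' artificially large normalized expression. For every null gene g the
#' diagnostic computes
#' \deqn{d_g = \overline{\log(L_{donor}/L_{recipient})}_{group 1} -
#'       \overline{\log(L_{donor}/L_{recipient})}_{group 2}}
#' using the dataset's donor map and original library sizes, and
#' \eqn{s_g}, the signed group difference of the analyzed values (group 1
#' minus group 2). It reports the Spearman rank correlation between
#' \eqn{d_g} and \eqn{s_g} across null genes with a permutation p-value.
#' A positive association means apparent "differential expression" of null
#' genes is tracking differences in library size, not biology. When all
#' library sizes are equal, every \eqn{d_g} is exactly 0 and the report is
#' flagged `no_imbalance`.
#'
#' @param dataset A `semisynthetic_dataset` carrying a donor map.
#' @param result Optional `semibench_de` result; when supplied, the
#'   diagnostic is restricted to the genes it analyzed.
#' @param n_perm Number of pairings permuted for the p-value (default 999).
#' @param seed Optional integer seed.
#' @return An object of class `confounding_report`: list with `per_gene`
#'   (tibble of `gene_id`, `d`, `s`), `rho`, `p_perm`, `n_null` and
#'   `no_imbalance`.
#' @export
confounding_diagnostic <- function(dataset, result = NULL, n_perm = 999,
                                   seed = NULL) {
  stopifnot(inherits(dataset, "semisynthetic_dataset"))
  kept_ids <- rownames(dataset$analysis)
  null_ids <- intersect(rownames(dataset$plan$permutations), kept_ids)
  if (!is.null(result)) null_ids <- intersect(null_ids, result$gene_id)
  if (length(null_ids) == 0L) abort("No null genes to diagnose.")
  if (length(null_ids) < 30L) {
    warn("Fewer than 30 null genes; the rank correlation will be unstable.")
  }
  dm <- dataset$donor_map[null_ids, , drop = FALSE]
  log_l <- log(dataset$library_sizes_original)
  n <- ncol(dm)
  imb <- matrix(log_l[as.vector(dm)], nrow = nrow(dm), ncol = n) -
    matrix(log_l, nrow = nrow(dm), ncol = n, byrow = TRUE)
  i1 <- dataset$group == 1L
  i2 <- dataset$group == 2L
  d <- rowMeans(imb[, i1, drop = FALSE]) - rowMeans(imb[, i2, drop = FALSE])
  a <- dataset$analysis[null_ids, , drop = FALSE]
  s <- rowMeans(a[, i1, drop = FALSE]) - rowMeans(a[, i2, drop = FALSE])

  if (all(abs(d) < 1e-12)) {
    out <- list(
      per_gene = tibble(gene_id = null_ids, d = d, s = s),
      rho = NA_real_, p_perm = NA_real_,
      n_null = length(null_ids), no_imbalance = TRUE
    )
    return(structure(out, class = "confounding_report"))
  }

  rd <- rank(d)
  rs <- rank(s)
  rho <- cor(rd, rs)
  if (!is.null(seed)) set.seed(seed)
  rho_perm <- vapply(seq_len(n_perm), function(b) cor(rd, sample(rs)),
                     numeric(1))
  p_perm <- (1 + sum(abs(rho_perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  structure(
    list(
      per_gene = tibble(gene_id = null_ids, d = d, s = s),
      rho = rho, p_perm = p_perm,
      n_null = length(null_ids), no_imbalance = FALSE
    ),
    class = "confounding_report"
  )
}

#' @export
print.confounding_report <- function(x, ...) {
  if (x$no_imbalance) {
    cat(sprintf("<confounding_report> no imbalance: all library sizes equal (%d null genes)\n",
                x$n_null))
  } else {
    cat(sprintf(
      "<confounding_report> Spearman rho(d, s) = %.3f over %d null genes (permutation p = %.4g)\n",
      x$rho, x$n_null, x$p_perm
    ))
  }
  invisible(x)
}

#' @method tidy confounding_report
#' @export
tidy.confounding_report <- function(x, ...) x$per_gene

#' @method glance confounding_report
#' @export
glance.confounding_report <- function(x, ...) {
  tibble(rho = x$rho, p_perm = x$p_perm, n_null = x$n_null,
         no_imbalance = x$no_imbalance)
}
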