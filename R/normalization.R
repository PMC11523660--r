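#' Filter genes with low counts
#'
#' Keeps a gene when (a) its counts-per-million exceed the CPM value that
#' `min_count` reads represent at the median library size, in at least `m`
#' samples where `m` is the smaller group size, and (b) its total count over
#' all samples is at least `min_total_count`. Both comparisons are inclusive
#' (`>=`). This is the filtering rule of the standard edgeR-style
#' preprocessing for two-group designs.
#'
#' @param counts A [count_matrix()].
#' @param min_count Reads a gene must reach at the median library size
#'   (default 10).
#' @param min_total_count Minimum total reads across all samples (default 15).
#' @return Named logical vector over genes (`TRUE` = keep).
#' @export
filter_low_counts <- function(counts, min_count = 10, min_total_count = 15) {
  stopifnot(inherits(counts, "count_matrix"))
  if (min_count <= 0 || min_total_count <= 0) {
    abort("`min_count` and `min_total_count` must be positive.")
  }
  lib <- counts$library_sizes
  cpm_cutoff <- min_count / median(lib) * 1e6
  cpm <- t(t(counts$counts) / lib) * 1e6
  m <- min(tabulate(counts$group, nbins = 2L))
  keep <- (rowSums(cpm >= cpm_cutoff) >= m) &
    (rowSums(counts$counts) >= min_total_count)
  if (!any(keep)) {
    abort("Empty matrix after filtering: no gene passes the low-count rule.")
  }
  setNames(keep, counts$gene_ids)
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values between-sample scaling factors: for each sample, a
#' precision-weighted mean of per-gene log2 ratios against a reference sample,
#' after trimming the 30% most extreme log-ratios and the 5% most extreme
#' average log-intensities. Factors are rescaled to have geometric mean 1. The
#' reference is the sample whose upper-quartile count fraction is closest to
#' the mean upper-quartile fraction.
#'
#' @param counts A [count_matrix()].
#' @param reference Optional integer index of the reference sample.
#' @param logratio_trim,sum_trim Trim fractions for log-ratios (default 0.30)
#'   and average intensities (default 0.05).
#' @param do_weighting Use inverse asymptotic-variance weights (default TRUE).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, reference = NULL,
                        logratio_trim = 0.30, sum_trim = 0.05,
                        do_weighting = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  x <- counts$counts
  lib <- counts$library_sizes
  if (ncol(x) < 2L) abort("TMM needs at least 2 samples.")
  if (is.null(reference)) {
    f75 <- apply(x, 2, quantile, probs = 0.75) / lib
    reference <- which.min(abs(f75 - mean(f75)))
  }
  f <- vapply(seq_len(ncol(x)), function(j) {
    tmm_pair(x[, j], x[, reference], lib[j], lib[reference],
             logratio_trim, sum_trim, do_weighting,
             sample_id = counts$sample_ids[j])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, counts$sample_ids)
}

# One sample against the reference; mirrors the standard TMM definition.
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim, sum_trim, do_weighting, sample_id = "?") {
  log_r <- log2((obs / n_obs) / (ref / n_ref))
  abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(log_r) & is.finite(abs_e) & (abs_e > -1e10)
  log_r <- log_r[fin]
  abs_e <- abs_e[fin]
  v <- v[fin]
  if (length(log_r) == 0L) {
    warn(sprintf("Sample %s shares no co-expressed genes with the reference; TMM factor set to 1.",
                 sample_id))
    return(1)
  }
  if (max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_l <- floor(n * logratio_trim) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * sum_trim) + 1
  hi_s <- n + 1 - lo_s
  keep <- (rank(log_r) >= lo_l & rank(log_r) <= hi_l) &
    (rank(abs_e) >= lo_s & rank(abs_e) <= hi_s)
  f <- if (do_weighting) {
    sum(log_r[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(log_r[keep], na.rm = TRUE)
  }
  if (is.na(f)) f <- 0
  2^f
}

#' Log2 counts-per-million transformation
#'
#' Applies the low-count filter and then the log2-CPM transform
#' \deqn{v_{gj} = \log_2\!\frac{(y_{gj} + c)\,10^6}{L_j f_j + 2c}}
#' where \eqn{c} is the pseudocount, \eqn{L_j} the library size per
#' `libsize_mode`, and \eqn{f_j} the TMM factor (1 when `tmm = FALSE`). The
#' `2c` in the denominator matches the voom-style convention; set
#' `pseudocount = 0` for the plain CPM form (zero counts then map to `-Inf`).
#'
#' @param counts A [count_matrix()].
#' @param pseudocount Nonnegative pseudocount added to counts (default 0.5).
#' @param tmm Apply TMM scaling factors (default FALSE).
#' @param libsize_mode `"recompute"` (column sums of `counts$counts`) or
#'   `"fixed"` (use `fixed_libsizes`, or the library sizes stored in
#'   `counts`). The fixed mode exists so that permutation-ordering experiments
#'   can hold the denominator constant.
#' @param fixed_libsizes Per-sample positive library sizes for
#'   `libsize_mode = "fixed"`.
#' @param filter Apply [filter_low_counts()] first (default TRUE).
#' @param min_count,min_total_count Passed to [filter_low_counts()].
#'
#' @return An object of class `normalized_matrix`: list with `values` (the
#'   log2-CPM matrix over kept genes), `kept_genes` (named logical over all
#'   input genes), `library_sizes_used`, `tmm_factors` and `provenance` (a
#'   record of every choice that produced `values`).
#' @export
log2_cpm <- function(counts, pseudocount = 0.5, tmm = FALSE,
                     libsize_mode = c("recompute", "fixed"),
                     fixed_libsizes = NULL, filter = TRUE,
                     min_count = 10, min_total_count = 15) {
  stopifnot(inherits(counts, "count_matrix"))
  libsize_mode <- match.arg(libsize_mode)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    abort("`pseudocount` must be a single nonnegative number.")
  }
  lib <- switch(libsize_mode,
    recompute = colSums(counts$counts),
    fixed = fixed_libsizes %||% counts$library_sizes
  )
  lib <- setNames(as.numeric(lib), counts$sample_ids)
  bad <- which(lib <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Zero or negative library size for sample(s): %s",
                  paste(counts$sample_ids[bad], collapse = ", ")))
  }
  keep <- if (filter) {
    # filter against the same library sizes the transform will use
    cm_f <- counts
    cm_f$library_sizes <- lib
    filter_low_counts(cm_f, min_count, min_total_count)
  } else {
    setNames(rep(TRUE, nrow(counts$counts)), counts$gene_ids)
  }
  f <- if (tmm) tmm_factors(counts) else setNames(rep(1, ncol(counts$counts)),
                                                  counts$sample_ids)
  y <- counts$counts[keep, , drop = FALSE]
  denom <- lib * f + 2 * pseudocount
  values <- log2(t((t(y) + pseudocount) / denom) * 1e6)
  structure(
    list(
      values = values,
      kept_genes = keep,
      library_sizes_used = lib,
      tmm_factors = f,
      provenance = list(
        filter = if (filter) list(min_count = min_count,
                                  min_total_count = min_total_count) else NULL,
        pseudocount = pseudocount,
        tmm = tmm,
        libsize_mode = libsize_mode
      )
    ),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf(
    "<normalized_matrix> %d/%d genes kept, %d samples; pseudocount %.3g, TMM %s, libsizes %s\n",
    nrow(x$values), length(x$kept_genes), ncol(x$values),
    x$provenance$pseudocount, ifelse(x$provenance$tmm, "on", "off"),
    x$provenance$libsize_mode
  ))
  invisible(x)
}
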