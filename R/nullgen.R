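#' Select gold-standard positive genes
#'
#' Samples a uniformly random subset of the truly DE genes to retain,
#' unpermuted, as gold-standard true positives; all remaining genes (including
#' the unselected DE genes) are treated as null and will have their values
#' permuted across samples. With `fraction = 0` every gene is permuted (the
#' complete-null benchmark).
#'
#' @param truth Truth tibble from [simulate_counts()] (columns `gene_id`,
#'   `is_de`, `lfc`, `gold_standard`), or an externally supplied table of the
#'   same shape for users with real data.
#' @param fraction Fraction in \[0, 1\] of DE genes retained; the subset size
#'   is `floor(fraction * #DE)`.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return `truth` with `gold_standard` set.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 100, n_per_group = c(5, 5), seed = 1))
#' tr <- select_gold_standard(sim$truth, fraction = 0.5, seed = 2)
#' sum(tr$gold_standard)
select_gold_standard <- function(truth, fraction = 0.5, seed = NULL) {
  check_truth(truth)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    abort("`fraction` must lie in [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)
  de_idx <- which(truth$is_de)
  n_gold <- floor(fraction * length(de_idx))
  gold_idx <- if (n_gold > 0) sample(de_idx, n_gold) else integer(0)
  truth$gold_standard <- FALSE
  truth$gold_standard[gold_idx] <- TRUE
  truth
}

check_truth <- function(truth) {
  needed <- c("gene_id", "is_de", "lfc", "gold_standard")
  if (!is.data.frame(truth) || !all(needed %in% names(truth))) {
    abort("`truth` must be a data frame with columns gene_id, is_de, lfc, gold_standard.")
  }
  if (any(truth$gold_standard & !truth$is_de)) {
    abort("`gold_standard` genes must be a subset of `is_de` genes.")
  }
  if (any(truth$lfc != 0 & !truth$is_de)) {
    abort("`lfc` must be 0 exactly for non-DE genes.")
  }
  invisible(truth)
}

#' Build a permutation plan
#'
#' Defines which genes are forced under the null and how their values are
#' swapped between samples. Every gene not in the gold standard is a null
#' gene; each null gene receives one uniformly random permutation of the
#' sample indices (or a single shared permutation when
#' `granularity = "shared"`). Per-gene independent permutations are the
#' default: they are what makes the donor/recipient library-size imbalance
#' vary from gene to gene.
#'
#' @param truth Truth tibble with `gold_standard` resolved
#'   (see [select_gold_standard()]).
#' @param n_samples Number of samples the permutations act on (>= 2).
#' @param scheme One of `"permute_then_normalize"` (permute raw counts, then
#'   filter and normalize the permuted matrix), `"raw_no_normalization"`
#'   (permute raw counts, analyze raw counts), `"normalize_then_permute"`
#'   (filter and normalize first, permute the normalized values).
#' @param granularity `"per_gene"` (default) or `"shared"`.
#' @param seed Optional integer seed.
#' @return An object of class `permutation_plan`.
#' @export
build_plan <- function(truth, n_samples,
                       scheme = c("normalize_then_permute",
                                  "permute_then_normalize",
                                  "raw_no_normalization"),
                       granularity = c("per_gene", "shared"),
                       seed = NULL) {
  check_truth(truth)
  scheme <- match.arg(scheme)
  granularity <- match.arg(granularity)
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2) {
    abort("`n_samples` must be at least 2.")
  }
  n_samples <- as.integer(n_samples)
  if (!is.null(seed)) set.seed(seed)
  null_genes <- setNames(!truth$gold_standard, truth$gene_id)
  n_null <- sum(null_genes)
  perms <- if (granularity == "shared") {
    matrix(rep(sample.int(n_samples), n_null), nrow = n_null, byrow = TRUE)
  } else {
    t(vapply(seq_len(n_null), function(i) sample.int(n_samples),
             integer(n_samples)))
  }
  rownames(perms) <- truth$gene_id[null_genes]
  structure(
    list(
      scheme = scheme,
      gene_ids = truth$gene_id,
      null_genes = null_genes,
      permutations = perms,
      granularity = granularity,
      seed = seed,
      n_samples = n_samples
    ),
    class = "permutation_plan"
  )
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat(sprintf(
    "<permutation_plan> scheme %s, %d null genes / %d genes, %d samples, %s permutations\n",
    x$scheme, sum(x$null_genes), length(x$null_genes), x$n_samples,
    x$granularity
  ))
  invisible(x)
}

# In-place row permutation: new[i, j] <- mat[i, perms[i, j]] for the rows
# named in rownames(perms) that appear in mat.
permute_rows <- function(mat, perms) {
  ids <- intersect(rownames(perms), rownames(mat))
  if (length(ids) == 0L) return(mat)
  rows <- match(ids, rownames(mat))
  p <- perms[ids, , drop = FALSE]
  n <- ncol(mat)
  row_idx <- matrix(rows, nrow = length(rows), ncol = n)
  mat[rows, ] <- matrix(mat[cbind(as.vector(row_idx), as.vector(p))],
                        nrow = length(rows), ncol = n)
  mat
}

#' Construct a semi-synthetic dataset under a permutation plan
#'
#' Applies the plan's permutations in the order its scheme dictates:
#' \describe{
#'   \item{permute_then_normalize}{Null-gene raw count rows are permuted
#'     first; the permuted matrix is then filtered and log2-CPM transformed.
#'     By default library sizes are recomputed from the permuted matrix (the
#'     behavior that generates the library-size artifact).}
#'   \item{raw_no_normalization}{Raw counts are permuted and analyzed as-is;
#'     only genes with zero counts in all samples are dropped.}
#'   \item{normalize_then_permute}{The original matrix is filtered and
#'     normalized first; permutations are then applied to the normalized rows
#'     of the null genes that survived filtering, so the group assignment is
#'     independent of the analyzed values by construction.}
#' }
#' A donor map records, for each analyzed gene and sample, the index of the
#' sample whose original value it now carries (identity for gold-standard
#' genes).
#'
#' @param counts A [count_matrix()].
#' @param plan A [build_plan()] result consistent with `counts`.
#' @param truth Truth tibble matching `plan`.
#' @param pseudocount,tmm,min_count,min_total_count Normalization parameters,
#'   see [log2_cpm()].
#' @param libsize_mode `"recompute"` (default) or `"fixed"`; in fixed mode the
#'   permute-then-normalize scheme keeps the library sizes supplied in
#'   `fixed_libsizes` (default: those stored in `counts`) instead of
#'   recomputing them from the permuted matrix.
#' @param fixed_libsizes Optional per-sample library sizes for fixed mode.
#' @return An object of class `semisynthetic_dataset`: list with `analysis`
#'   (the matrix handed to the tests), `group`, `truth`, `kept_genes`,
#'   `donor_map`, `plan`, `scheme`, `library_sizes_original`,
#'   `library_sizes_used` and `normalization` (provenance or NULL).
#' @export
make_semisynthetic <- function(counts, plan, truth,
                               pseudocount = 0.5, tmm = FALSE,
                               libsize_mode = c("recompute", "fixed"),
                               fixed_libsizes = NULL,
                               min_count = 10, min_total_count = 15) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(plan, "permutation_plan"))
  check_truth(truth)
  libsize_mode <- match.arg(libsize_mode)
  if (!identical(plan$gene_ids, counts$gene_ids)) {
    bad <- union(setdiff(plan$gene_ids, counts$gene_ids),
                 setdiff(counts$gene_ids, plan$gene_ids))
    abort(sprintf("Plan and counts disagree on the gene set (%d genes differ): %s%s",
                  length(bad), paste(head(bad, 5), collapse = ", "),
                  if (length(bad) > 5) ", ..." else ""))
  }
  if (!identical(truth$gene_id, counts$gene_ids)) {
    abort("`truth` and `counts` must cover the same genes in the same order.")
  }
  if (plan$n_samples != ncol(counts$counts)) {
    abort("`plan` was built for a different number of samples.")
  }
  n <- ncol(counts$counts)
  scheme <- plan$scheme

  if (scheme == "normalize_then_permute") {
    nm <- log2_cpm(counts, pseudocount = pseudocount, tmm = tmm,
                   libsize_mode = libsize_mode,
                   fixed_libsizes = fixed_libsizes,
                   min_count = min_count, min_total_count = min_total_count)
    analysis <- permute_rows(nm$values, plan$permutations)
    kept <- nm$kept_genes
    lib_used <- nm$library_sizes_used
    provenance <- nm$provenance
  } else {
    permuted <- permute_rows(counts$counts, plan$permutations)
    if (scheme == "raw_no_normalization") {
      kept <- setNames(rowSums(permuted) > 0, counts$gene_ids)
      analysis <- permuted[kept, , drop = FALSE]
      lib_used <- counts$library_sizes
      provenance <- NULL
    } else { # permute_then_normalize
      lib <- switch(libsize_mode,
        recompute = colSums(permuted),
        fixed = (fixed_libsizes %||% counts$library_sizes)
      )
      pm <- count_matrix(permuted, group = counts$group,
                         gene_ids = counts$gene_ids,
                         sample_ids = counts$sample_ids,
                         library_sizes = lib)
      nm <- log2_cpm(pm, pseudocount = pseudocount, tmm = tmm,
                     libsize_mode = "fixed", fixed_libsizes = lib,
                     min_count = min_count, min_total_count = min_total_count)
      analysis <- nm$values
      kept <- nm$kept_genes
      lib_used <- nm$library_sizes_used
      provenance <- nm$provenance
    }
  }

  kept_ids <- names(kept)[kept]
  donor_map <- matrix(rep(seq_len(n), each = length(kept_ids)),
                      nrow = length(kept_ids), ncol = n,
                      dimnames = list(kept_ids, counts$sample_ids))
  null_kept <- intersect(rownames(plan$permutations), kept_ids)
  if (length(null_kept) > 0) {
    donor_map[null_kept, ] <- plan$permutations[null_kept, , drop = FALSE]
  }

  structure(
    list(
      analysis = analysis,
      group = counts$group,
      truth = truth,
      kept_genes = kept,
      donor_map = donor_map,
      plan = plan,
      scheme = scheme,
      library_sizes_original = counts$library_sizes,
      library_sizes_used = lib_used,
      normalization = provenance
    ),
    class = "semisynthetic_dataset"
  )
}

#' @export
print.semisynthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<semisynthetic_dataset> scheme %s: %d analyzed genes x %d samples (%d gold-standard, %d null)\n",
    x$scheme, nrow(x$analysis), ncol(x$analysis),
    sum(x$truth$gold_standard[x$kept_genes[x$truth$gene_id]]),
    sum(x$plan$null_genes[names(x$kept_genes)[x$kept_genes]])
  ))
  invisible(x)
}
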