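#' Two-group RNA-seq count matrix
#'
#' Container for a genes x samples matrix of nonnegative integer counts with
#' per-sample group labels and library sizes. Library sizes default to the
#' column sums of the counts; they may be overridden (e.g. when a sub-matrix
#' should keep the sequencing depth of the full experiment).
#'
#' @param counts Numeric matrix of nonnegative integers, genes in rows and
#'   samples in columns. Row and column names are used as gene and sample
#'   identifiers when `gene_ids`/`sample_ids` are not supplied.
#' @param group Per-sample group labels, coercible to the integers 1 and 2.
#'   Both groups must be non-empty.
#' @param gene_ids,sample_ids Optional character identifiers; must be unique.
#' @param library_sizes Optional per-sample positive totals. Default: column
#'   sums of `counts`.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_ids`, `sample_ids`, `group` (integer 1/2) and `library_sizes`.
#' @export
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' cm <- count_matrix(m, group = c(1, 1, 2, 2))
#' cm
count_matrix <- function(counts, group, gene_ids = NULL, sample_ids = NULL,
                         library_sizes = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (genes x samples).")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("`counts` must contain finite nonnegative integers.")
  }
  gene_ids <- gene_ids %||% rownames(counts) %||%
    sprintf("gene_%05d", seq_len(nrow(counts)))
  sample_ids <- sample_ids %||% colnames(counts) %||%
    sprintf("sample_%04d", seq_len(ncol(counts)))
  if (length(gene_ids) != nrow(counts) || anyDuplicated(gene_ids)) {
    abort("`gene_ids` must be unique and match nrow(counts).")
  }
  if (length(sample_ids) != ncol(counts) || anyDuplicated(sample_ids)) {
    abort("`sample_ids` must be unique and match ncol(counts).")
  }
  if (length(group) != ncol(counts)) {
    abort("`group` must have one label per sample.")
  }
  group <- as.integer(factor(as.character(group)))
  if (anyNA(group) || !all(group %in% c(1L, 2L)) || length(unique(group)) != 2L) {
    abort("`group` must contain exactly two non-empty groups.")
  }
  library_sizes <- library_sizes %||% colSums(counts)
  if (length(library_sizes) != ncol(counts) || any(library_sizes <= 0)) {
    abort("`library_sizes` must be positive, one per sample.")
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(
    list(
      counts = counts,
      gene_ids = gene_ids,
      sample_ids = sample_ids,
      group = group,
      library_sizes = setNames(as.numeric(library_sizes), sample_ids)
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d genes x %d samples (group sizes %d/%d)\n",
    nrow(x$counts), ncol(x$counts), sum(x$group == 1L), sum(x$group == 2L)
  ))
  cat(sprintf(
    "  library sizes: median %.3g, range [%.3g, %.3g]\n",
    median(x$library_sizes), min(x$library_sizes), max(x$library_sizes)
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset the samples of a count matrix
#'
#' Keeps the stored library sizes of the retained samples (a library size is a
#' property of the sample, not of the gene subset under analysis).
#'
#' @param x A [count_matrix()].
#' @param samples Integer or logical index over samples.
#' @return A `count_matrix` over the selected samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts[, samples, drop = FALSE]
  count_matrix(
    counts,
    group = x$group[samples],
    gene_ids = x$gene_ids,
    sample_ids = colnames(counts),
    library_sizes = x$library_sizes[samples]
  )
}

#' @method as_tibble count_matrix
#' @export
as_tibble.count_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(x$gene_ids, times = ncol(x$counts)),
    sample_id = rep(x$sample_ids, each = nrow(x$counts)),
    group = rep(x$group, each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
}
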