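# Plain-text serialization: TSV/CSV matrices with JSON sidecars so every
# result records the provenance that produced it.

#' Write and read a count-matrix bundle
#'
#' A bundle directory holds `counts.tsv` (first column `gene_id`, one column
#' per sample), `groups.csv` (`sample_id`, `group`), `truth.csv`
#' (`gene_id`, `is_de`, `lfc`, `gold_standard`) and `meta.json`
#' (library sizes). With `mtx = TRUE` a MatrixMarket copy is written as
#' `counts.mtx` plus `genes.txt`/`samples.txt` sidecars.
#'
#' @param counts A [count_matrix()].
#' @param truth Optional truth tibble.
#' @param dir Output directory (created if needed).
#' @param mtx Also write MatrixMarket files (requires the Matrix package).
#' @return `dir`, invisibly.
#' @export
write_count_bundle <- function(counts, dir, truth = NULL, mtx = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- dplyr::bind_cols(
    tibble(gene_id = counts$gene_ids),
    as_tibble(as.data.frame(counts$counts))
  )
  readr::write_tsv(tsv, file.path(dir, "counts.tsv"))
  readr::write_csv(tibble(sample_id = counts$sample_ids, group = counts$group),
                   file.path(dir, "groups.csv"))
  if (!is.null(truth)) {
    check_truth(truth)
    readr::write_csv(truth, file.path(dir, "truth.csv"))
  }
  jsonlite::write_json(
    list(library_sizes = as.list(setNames(counts$library_sizes,
                                          counts$sample_ids))),
    file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (mtx) {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      abort("MatrixMarket output needs the Matrix package.")
    }
    Matrix::writeMM(Matrix::Matrix(counts$counts, sparse = TRUE),
                    file.path(dir, "counts.mtx"))
    writeLines(counts$gene_ids, file.path(dir, "genes.txt"))
    writeLines(counts$sample_ids, file.path(dir, "samples.txt"))
  }
  invisible(dir)
}

#' @rdname write_count_bundle
#' @return `read_count_bundle()`: list with `counts` and (if present) `truth`.
#' @export
read_count_bundle <- function(dir) {
  tsv <- readr::read_tsv(file.path(dir, "counts.tsv"),
                         show_col_types = FALSE)
  groups <- readr::read_csv(file.path(dir, "groups.csv"),
                            show_col_types = FALSE)
  m <- as.matrix(tsv[, -1])
  rownames(m) <- tsv$gene_id
  meta_path <- file.path(dir, "meta.json")
  lib <- if (file.exists(meta_path)) {
    unlist(jsonlite::read_json(meta_path)$library_sizes)
  } else {
    NULL
  }
  counts <- count_matrix(m, group = groups$group[match(colnames(m),
                                                       groups$sample_id)],
                         library_sizes = lib[colnames(m)])
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  } else {
    NULL
  }
  list(counts = counts, truth = truth)
}

#' Write and read a normalized matrix
#'
#' The values go to TSV; the provenance (filter rule, pseudocount, TMM
#' factors, library sizes used) goes to a JSON sidecar `<path>.json`.
#'
#' @param nm A `normalized_matrix` from [log2_cpm()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(nm, path) {
  stopifnot(inherits(nm, "normalized_matrix"))
  tsv <- dplyr::bind_cols(
    tibble(gene_id = rownames(nm$values)),
    as_tibble(as.data.frame(nm$values))
  )
  readr::write_tsv(tsv, path)
  jsonlite::write_json(
    list(
      provenance = nm$provenance,
      kept_genes = as.list(nm$kept_genes),
      library_sizes_used = as.list(nm$library_sizes_used),
      tmm_factors = as.list(nm$tmm_factors)
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_normalized
#' @export
read_normalized <- function(path) {
  tsv <- readr::read_tsv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"))
  values <- as.matrix(tsv[, -1])
  rownames(values) <- tsv$gene_id
  structure(
    list(
      values = values,
      kept_genes = unlist(side$kept_genes),
      library_sizes_used = unlist(side$library_sizes_used),
      tmm_factors = unlist(side$tmm_factors),
      provenance = side$provenance
    ),
    class = "normalized_matrix"
  )
}

#' Write and read a permutation plan
#'
#' Compact JSON: scheme, seed, granularity and the per-gene permutation
#' arrays.
#'
#' @param plan A [build_plan()] result.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "permutation_plan"))
  jsonlite::write_json(
    list(
      scheme = plan$scheme,
      granularity = plan$granularity,
      seed = plan$seed,
      n_samples = plan$n_samples,
      gene_ids = plan$gene_ids,
      null_genes = unname(plan$null_genes),
      permutations = lapply(seq_len(nrow(plan$permutations)),
                            function(i) unname(plan$permutations[i, ]))
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  null_genes <- setNames(as.logical(x$null_genes), x$gene_ids)
  perms <- if (is.list(x$permutations)) {
    do.call(rbind, x$permutations)
  } else {
    x$permutations
  }
  rownames(perms) <- x$gene_ids[null_genes]
  structure(
    list(
      scheme = x$scheme,
      gene_ids = x$gene_ids,
      null_genes = null_genes,
      permutations = perms,
      granularity = x$granularity,
      seed = x$seed,
      n_samples = as.integer(x$n_samples)
    ),
    class = "permutation_plan"
  )
}

#' Write a semi-synthetic dataset bundle
#'
#' Writes `analysis.tsv` (the matrix handed to the tests), `truth.csv`,
#' `plan.json` and `meta.json` (scheme, groups, library sizes) into `dir`.
#'
#' @param dataset A `semisynthetic_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(dataset, dir) {
  stopifnot(inherits(dataset, "semisynthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- dplyr::bind_cols(
    tibble(gene_id = rownames(dataset$analysis)),
    as_tibble(as.data.frame(dataset$analysis))
  )
  readr::write_tsv(tsv, file.path(dir, "analysis.tsv"))
  readr::write_csv(dataset$truth, file.path(dir, "truth.csv"))
  write_plan(dataset$plan, file.path(dir, "plan.json"))
  jsonlite::write_json(
    list(
      scheme = dataset$scheme,
      group = dataset$group,
      library_sizes_original = as.list(dataset$library_sizes_original),
      library_sizes_used = as.list(dataset$library_sizes_used),
      normalization = dataset$normalization
    ),
    file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Write a DE test result
#'
#' CSV with `gene_id`, `method`, `statistic`, `p_raw`, `p_adjusted`; the
#' settings go to a JSON sidecar `<path>.json`.
#'
#' @param result A `semibench_de`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(result, path) {
  stopifnot(inherits(result, "semibench_de"))
  readr::write_csv(tidy(result), path)
  jsonlite::write_json(
    list(method = attr(result, "method"),
         n_permutations = attr(result, "n_permutations"),
         settings = attr(result, "settings")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Write benchmark report CSVs
#'
#' `summary.csv` and `replicates.csv` plus a `config.json` sidecar.
#'
#' @param report A `semibench_eval`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "semibench_eval"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$summary, file.path(dir, "summary.csv"))
  readr::write_csv(report$replicates, file.path(dir, "replicates.csv"))
  jsonlite::write_json(
    list(mode = report$mode,
         sim_config = unclass(report$sim_config),
         eval_config = unclass(report$eval_config)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}
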