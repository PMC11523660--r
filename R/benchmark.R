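#' Evaluation configuration for replicate benchmarks
#'
#' @param nominal_levels Strictly increasing nominal FDR levels in (0, 1).
#'   Defaults include the 1%, 5% and 10% levels.
#' @param n_replicates Number of replicate semi-synthetic datasets
#'   (default 50).
#' @param sample_size_grid Optional integer vector of per-group sizes; for
#'   each replicate, columns are subsampled without replacement (balanced
#'   across groups) from the full simulated matrix, so all grid sizes share
#'   the same gene-level parameters. `NULL` uses the full simulated size.
#' @param schemes Subset of the three permutation orderings, see
#'   [build_plan()].
#' @param methods Subset of `"wilcoxon"`, `"score_asymptotic"`,
#'   `"score_permutation"`.
#' @param gold_fraction Fraction of DE genes kept as gold standard
#'   (default 0.5). With 0, the benchmark switches to complete-null
#'   evaluation (per-gene type-I error at the raw levels plus the
#'   any-discovery rate at the BH levels), because the false discovery
#'   proportion against an empty gold standard degenerates to 1\{R > 0\}.
#' @param n_permutations `B` for the permutation test (default 1000).
#' @param root_seed Integer seed from which every replicate's seeds are
#'   derived deterministically.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(nominal_levels = c(0.01, 0.05, 0.1),
                        n_replicates = 50L,
                        sample_size_grid = NULL,
                        schemes = c("permute_then_normalize",
                                    "raw_no_normalization",
                                    "normalize_then_permute"),
                        methods = c("wilcoxon", "score_asymptotic",
                                    "score_permutation"),
                        gold_fraction = 0.5,
                        n_permutations = 1000L,
                        root_seed = 1L) {
  if (!is.numeric(nominal_levels) || any(nominal_levels <= 0) ||
      any(nominal_levels >= 1) || is.unsorted(nominal_levels, strictly = TRUE)) {
    abort("`nominal_levels` must be strictly increasing and inside (0, 1).")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    abort("`n_replicates` must be a positive integer.")
  }
  if (!is.null(sample_size_grid) &&
      (any(sample_size_grid < 2) || any(sample_size_grid != round(sample_size_grid)))) {
    abort("`sample_size_grid` entries must be integers >= 2 (per group).")
  }
  schemes <- match.arg(schemes, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.numeric(gold_fraction) || gold_fraction < 0 || gold_fraction > 1) {
    abort("`gold_fraction` must lie in [0, 1].")
  }
  structure(
    list(
      nominal_levels = as.numeric(nominal_levels),
      n_replicates = as.integer(n_replicates),
      sample_size_grid = if (is.null(sample_size_grid)) NULL else as.integer(sample_size_grid),
      schemes = schemes,
      methods = methods,
      gold_fraction = gold_fraction,
      n_permutations = as.integer(n_permutations),
      root_seed = as.integer(root_seed)
    ),
    class = "eval_config"
  )
}

#' Score one replicate against the gold standard
#'
#' A discovery is a gene with BH-adjusted p at or below the nominal level; a
#' false discovery is a discovery outside the gold standard. The false
#' discovery proportion is `FP / max(R, 1)` (0 when nothing is discovered)
#' and power is `TP / #gold_standard` over all gold-standard genes in
#' `truth`, so gold genes lost to filtering count against power.
#'
#' @param result A `semibench_de` result.
#' @param truth Truth tibble covering (at least) the analyzed genes.
#' @param levels Nominal FDR levels.
#' @return Tibble with one row per level: `level`, `R`, `TP`, `FP`, `FDP`,
#'   `power`.
#' @export
evaluate_replicate <- function(result, truth, levels) {
  check_truth(truth)
  if (!all(result$gene_id %in% truth$gene_id)) {
    abort("`result` contains genes absent from `truth`.")
  }
  gold <- truth$gold_standard[match(result$gene_id, truth$gene_id)]
  n_gold <- sum(truth$gold_standard)
  purrr::map_dfr(levels, function(q) {
    disc <- result$p_adjusted <= q
    r <- sum(disc)
    tp <- sum(disc & gold)
    tibble(
      level = q, R = r, TP = tp, FP = r - tp,
      FDP = (r - tp) / max(r, 1),
      power = if (n_gold > 0) tp / n_gold else NA_real_
    )
  })
}

run_one_method <- function(method, ds, B, seed, min_level) {
  switch(method,
    wilcoxon = wilcoxon_test(ds),
    score_asymptotic = {
      if (ds$scheme == "raw_no_normalization") {
        log_info("score test on non-normalized values: heteroskedasticity across samples is not accounted for")
      }
      score_test_asymptotic(ds)
    },
    score_permutation = score_test_permutation(ds, B = B, seed = seed,
                                               min_level = min_level),
    abort(sprintf("Unknown method '%s'.", method))
  )
}

#' Run a replicate semi-synthetic benchmark
#'
#' For each replicate: simulate a count matrix, select the gold standard,
#' and for every per-group size in the grid and every scheme build one
#' permutation plan (the same permutations are reused across schemes, so
#' scheme contrasts are paired) and one semi-synthetic dataset, run every
#' method, and score it. All seeds derive deterministically from
#' `eval$root_seed`, so two runs with identical configs are identical.
#'
#' @param sim A [sim_config()]; its `n_per_group` must cover the largest grid
#'   entry.
#' @param eval An [eval_config()].
#' @param pseudocount,tmm,libsize_mode,min_count,min_total_count
#'   Normalization parameters passed to [make_semisynthetic()].
#' @return An object of class `semibench_eval`: list with `summary`
#'   (aggregated over replicates, with Monte-Carlo standard errors),
#'   `replicates` (the per-replicate table), `mode` (`"gold"` or
#'   `"complete_null"`), and the two configs.
#' @export
run_benchmark <- function(sim, eval,
                          pseudocount = 0.5, tmm = FALSE,
                          libsize_mode = "recompute",
                          min_count = 10, min_total_count = 15) {
  stopifnot(inherits(sim, "sim_config"), inherits(eval, "eval_config"))
  grid <- eval$sample_size_grid
  if (!is.null(grid) && max(grid) > min(sim$n_per_group)) {
    abort("`sample_size_grid` exceeds the simulated per-group size.")
  }
  complete_null <- eval$gold_fraction == 0
  set.seed(eval$root_seed)
  rep_seeds <- sample.int(2147483040L, eval$n_replicates)

  rows <- purrr::map_dfr(seq_len(eval$n_replicates), function(r) {
    set.seed(rep_seeds[r])
    sub <- sample.int(2147483040L, 4L)
    cfg_r <- sim
    cfg_r$seed <- sub[1]
    simres <- simulate_counts(cfg_r)
    truth_r <- select_gold_standard(simres$truth, eval$gold_fraction,
                                    seed = sub[2])
    ns <- grid %||% NA_integer_
    set.seed(sub[3])
    n_seeds <- matrix(sample.int(2147483040L, length(ns) * 2L), ncol = 2L)
    purrr::map_dfr(seq_along(ns), function(k) {
      n_k <- ns[k]
      counts_k <- if (is.na(n_k)) {
        simres$counts
      } else {
        set.seed(n_seeds[k, 1])
        keep <- c(sample(which(simres$counts$group == 1L), n_k),
                  sample(which(simres$counts$group == 2L), n_k))
        subset_samples(simres$counts, sort(keep))
      }
      n_samples <- ncol(counts_k$counts)
      purrr::map_dfr(eval$schemes, function(scheme) {
        plan <- build_plan(truth_r, n_samples = n_samples, scheme = scheme,
                           seed = n_seeds[k, 2])
        ds <- make_semisynthetic(counts_k, plan, truth_r,
                                 pseudocount = pseudocount, tmm = tmm,
                                 libsize_mode = libsize_mode,
                                 min_count = min_count,
                                 min_total_count = min_total_count)
        purrr::map_dfr(eval$methods, function(method) {
          res <- run_one_method(method, ds, B = eval$n_permutations,
                                seed = sub[4],
                                min_level = min(eval$nominal_levels))
          ev <- if (complete_null) {
            evaluate_complete_null(res, eval$nominal_levels)
          } else {
            evaluate_replicate(res, truth_r, eval$nominal_levels)
          }
          ev$replicate <- r
          ev$scheme <- scheme
          ev$method <- method
          ev$n1 <- sum(counts_k$group == 1L)
          ev$n2 <- sum(counts_k$group == 2L)
          if (!complete_null) {
            log_info("replicate %d scheme %s method %s n %d+%d: R=%s FP=%s",
                     r, scheme, method, ev$n1[1], ev$n2[1],
                     paste(ev$R, collapse = "/"),
                     paste(ev$FP, collapse = "/"))
          }
          ev
        })
      })
    })
  })

  rows <- dplyr::relocate(rows, "replicate", "scheme", "method", "n1", "n2")
  summary <- if (complete_null) {
    rows |>
      dplyr::group_by(.data$scheme, .data$method, .data$n1, .data$n2,
                      .data$level) |>
      dplyr::summarise(
        type1 = mean(.data$type1_raw),
        type1_se = sd(.data$type1_raw) / sqrt(dplyr::n()),
        any_discovery_rate = mean(.data$any_discovery),
        n_replicates = dplyr::n(),
        .groups = "drop"
      )
  } else {
    rows |>
      dplyr::group_by(.data$scheme, .data$method, .data$n1, .data$n2,
                      .data$level) |>
      dplyr::summarise(
        fdr = mean(.data$FDP),
        fdr_median = median(.data$FDP),
        fdr_se = sd(.data$FDP) / sqrt(dplyr::n()),
        power_se = sd(.data$power) / sqrt(dplyr::n()),
        power = mean(.data$power),
        mean_R = mean(.data$R),
        n_replicates = dplyr::n(),
        .groups = "drop"
      )
  }
  structure(
    list(
      summary = summary,
      replicates = rows,
      mode = if (complete_null) "complete_null" else "gold",
      sim_config = sim,
      eval_config = eval
    ),
    class = "semibench_eval"
  )
}

# Complete-null scoring: FDP against an empty gold standard is 1{R > 0}, so
# report the per-gene type-I error at each raw level alongside the BH
# any-discovery (family-wise) rate.
evaluate_complete_null <- function(result, levels) {
  purrr::map_dfr(levels, function(a) {
    tibble(
      level = a,
      type1_raw = mean(result$p_raw <= a),
      any_discovery = any(result$p_adjusted <= a),
      R = sum(result$p_adjusted <= a)
    )
  })
}

#' @export
print.semibench_eval <- function(x, ...) {
  cat(sprintf("<semibench_eval> mode %s: %d replicates, schemes [%s], methods [%s]\n",
              x$mode, x$eval_config$n_replicates,
              paste(x$eval_config$schemes, collapse = ", "),
              paste(x$eval_config$methods, collapse = ", ")))
  print(x$summary, n = 20)
  invisible(x)
}

#' @method tidy semibench_eval
#' @export
tidy.semibench_eval <- function(x, ...) x$summary

#' @method glance semibench_eval
#' @export
glance.semibench_eval <- function(x, ...) {
  tibble(
    mode = x$mode,
    n_replicates = x$eval_config$n_replicates,
    n_genes = x$sim_config$n_genes,
    n_schemes = length(x$eval_config$schemes),
    n_methods = length(x$eval_config$methods),
    n_levels = length(x$eval_config$nominal_levels),
    root_seed = x$eval_config$root_seed
  )
}

#' Power as a function of sample size
#'
#' Long-format table of empirical power per (scheme, method, per-group size,
#' level), ready for plotting.
#'
#' @param report A `semibench_eval` from [run_benchmark()].
#' @return Tibble with columns `scheme`, `method`, `n1`, `n2`, `n`, `level`,
#'   `power`, `power_se`.
#' @export
power_vs_n_curve <- function(report) {
  stopifnot(inherits(report, "semibench_eval"))
  if (report$mode != "gold") {
    abort("Power curves need a gold-standard benchmark (gold_fraction > 0).")
  }
  report$summary |>
    dplyr::mutate(n = .data$n1 + .data$n2) |>
    dplyr::select("scheme", "method", "n1", "n2", "n", "level",
                  "power", "power_se") |>
    dplyr::arrange(.data$scheme, .data$method, .data$level, .data$n)
}
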