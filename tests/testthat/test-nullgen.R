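test_that("gold-standard selection sizes and edge fractions are exact", {
  sim <- tiny_sim(n_genes = 400, de_fraction = 0.25, seed = 1)
  tr <- select_gold_standard(sim$truth, 0.5, seed = 3)
  expect_identical(sum(tr$gold_standard), as.integer(floor(0.5 * 100)))
  expect_true(all(tr$is_de[tr$gold_standard]))

  expect_identical(select_gold_standard(sim$truth, 1, seed = 3)$gold_standard,
                   sim$truth$is_de)
  expect_false(any(select_gold_standard(sim$truth, 0, seed = 3)$gold_standard))
  expect_error(select_gold_standard(sim$truth, 1.2), "\\[0, 1\\]")

  # the inferred GTEx-scale arithmetic: half of 5778 DE genes -> 2889
  truth <- tibble::tibble(
    gene_id = sprintf("g%05d", 1:14445),
    is_de = c(rep(TRUE, 5778), rep(FALSE, 14445 - 5778)),
    lfc = c(rep(1, 5778), rep(0, 14445 - 5778)),
    gold_standard = FALSE
  )
  tr2 <- select_gold_standard(truth, 0.5, seed = 9)
  expect_identical(sum(tr2$gold_standard), 2889L)
})

test_that("plans are seeded bijections with the requested granularity", {
  sim <- tiny_sim(n_genes = 100, seed = 2)
  tr <- select_gold_standard(sim$truth, 0.5, seed = 5)
  p1 <- build_plan(tr, 20, scheme = "normalize_then_permute", seed = 8)
  p2 <- build_plan(tr, 20, scheme = "normalize_then_permute", seed = 8)
  expect_identical(p1$permutations, p2$permutations)
  expect_identical(unname(p1$null_genes), !tr$gold_standard)
  expect_true(all(apply(p1$permutations, 1,
                        function(p) identical(sort(p), 1:20))))

  sh <- build_plan(tr, 20, granularity = "shared", seed = 8)
  expect_true(all(apply(sh$permutations, 1,
                        function(p) identical(p, sh$permutations[1, ]))))

  expect_error(build_plan(tr, 1), "at least 2")
})

test_that("uniform per-gene permutations hit the identity at rate 1/n!", {
  truth <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000),
    is_de = FALSE, lfc = 0, gold_standard = FALSE
  )
  plan <- build_plan(truth, 6, seed = 31)
  frac_identity <- mean(apply(plan$permutations, 1,
                              function(p) identical(p, 1:6)))
  p0 <- 1 / factorial(6)
  expect_lt(abs(frac_identity - p0), 3 * sqrt(p0 * (1 - p0) / 1000))
})

test_that("gold rows are untouched and null rows keep their multiset", {
  sim <- tiny_sim(n_genes = 150, n_per_group = c(10, 10), seed = 4)
  tr <- select_gold_standard(sim$truth, 0.5, seed = 6)
  gold_ids <- tr$gene_id[tr$gold_standard]

  for (scheme in c("permute_then_normalize", "raw_no_normalization",
                   "normalize_then_permute")) {
    plan <- build_plan(tr, 20, scheme = scheme, seed = 13)
    ds <- make_semisynthetic(sim$counts, plan, tr)
    if (scheme == "raw_no_normalization") {
      kept_gold <- intersect(gold_ids, rownames(ds$analysis))
      expect_identical(ds$analysis[kept_gold, ],
                       sim$counts$counts[kept_gold, ])
    } else if (scheme == "normalize_then_permute") {
      nm <- log2_cpm(sim$counts)
      kept_gold <- intersect(gold_ids, rownames(ds$analysis))
      expect_identical(ds$analysis[kept_gold, ], nm$values[kept_gold, ])
      # permutation preserves each null row's multiset of normalized values
      null_kept <- setdiff(rownames(ds$analysis), gold_ids)
      for (id in head(null_kept, 20)) {
        expect_identical(sort(unname(ds$analysis[id, ])),
                         sort(unname(nm$values[id, ])))
      }
    } else {
      # raw-domain permutation preserves the multiset of raw counts
      null_ids <- rownames(plan$permutations)
      permuted <- semibench:::permute_rows(sim$counts$counts,
                                           plan$permutations)
      for (id in head(null_ids, 20)) {
        expect_identical(sort(unname(permuted[id, ])),
                         sort(unname(sim$counts$counts[id, ])))
      }
      expect_identical(permuted[gold_ids, ], sim$counts$counts[gold_ids, ])
    }
    # donor map: identity for gold rows, the plan's permutation for null rows
    kept_gold <- intersect(gold_ids, rownames(ds$donor_map))
    expect_true(all(ds$donor_map[kept_gold, ] ==
                      rep(1:20, each = length(kept_gold))))
    null_kept <- intersect(rownames(plan$permutations), rownames(ds$donor_map))
    expect_identical(unname(ds$donor_map[null_kept, ]),
                     unname(plan$permutations[null_kept, ]))
  }
})

test_that("equal fixed library sizes make schemes A and C identical", {
  sim <- simulate_counts(sim_config(
    n_genes = 100, n_per_group = c(10, 10),
    libsize = list(median = 1, sdlog = 0), seed = 17
  ))
  tr <- select_gold_standard(sim$truth, 0.5, seed = 18)
  fixed <- rep(1e6, 20)
  planA <- build_plan(tr, 20, scheme = "permute_then_normalize", seed = 19)
  planC <- build_plan(tr, 20, scheme = "normalize_then_permute", seed = 19)
  expect_identical(planA$permutations, planC$permutations)
  dsA <- make_semisynthetic(sim$counts, planA, tr, libsize_mode = "fixed",
                            fixed_libsizes = fixed)
  dsC <- make_semisynthetic(sim$counts, planC, tr, libsize_mode = "fixed",
                            fixed_libsizes = fixed)
  expect_identical(dsA$analysis, dsC$analysis)
})

test_that("scheme C leaves null-gene group differences centered at zero", {
  sim <- tiny_sim(n_genes = 150, n_per_group = c(10, 10), seed = 23)
  tr <- select_gold_standard(sim$truth, 0, seed = 24)
  diffs <- vapply(1:40, function(b) {
    plan <- build_plan(tr, 20, scheme = "normalize_then_permute",
                       seed = 100 + b)
    ds <- make_semisynthetic(sim$counts, plan, tr)
    i1 <- ds$group == 1L
    mean(rowMeans(ds$analysis[, i1]) - rowMeans(ds$analysis[, !i1]))
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-3)
})

test_that("plan/counts mismatches are reported", {
  sim <- tiny_sim(n_genes = 50, seed = 3)
  tr <- select_gold_standard(sim$truth, 0.5, seed = 4)
  plan <- build_plan(tr, 20, seed = 5)
  other <- tiny_sim(n_genes = 40, seed = 3)
  expect_error(make_semisynthetic(other$counts, plan, tr), "gene set")
  short_plan <- build_plan(tr, 10, seed = 5)
  expect_error(make_semisynthetic(sim$counts, short_plan, tr),
               "different number of samples")
})
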