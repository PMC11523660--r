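#' Simulation configuration for two-group RNA-seq counts
#'
#' Describes a negative-binomial generator for a two-group experiment with
#' heterogeneous library sizes and a known subset of truly differentially
#' expressed (DE) genes. Counts for gene g in sample j are drawn as
#' \deqn{y_{gj} \sim NB(\mu = s_j\,\mu_g\,2^{\lambda_g 1[j \in \mathrm{group}\,2]},\ \phi_g)}
#' with the edgeR variance convention \eqn{Var = \mu + \phi\mu^2}.
#'
#' Defaults emulate filtered bulk RNA-seq from large human cohorts: gene
#' baseline means are heavy-tailed log-normal (spanning several orders of
#' magnitude), dispersions follow the classic `phi = phi0 + slope/mu` trend
#' with `phi0 = 0.16` (biological CV ~0.4, typical of human population
#' samples), and per-sample library-size factors are log-normal with log-sd
#' 0.7, i.e. a several-fold depth spread across samples.
#'
#' @param n_genes Positive integer, number of genes.
#' @param n_per_group Length-2 positive integer vector: samples per group.
#' @param de_fraction Proportion in \[0, 1\] of genes that are truly DE.
#' @param lfc List with `location`, `scale`, `min_abs`: DE genes get
#'   log2-fold-changes `sign * (min_abs + |N(location, scale)|)` with random
#'   sign, so every true effect has `|lfc| >= min_abs`.
#' @param baseline List with `meanlog`, `sdlog`: log-normal law of the
#'   per-gene baseline mean \eqn{\mu_g}.
#' @param dispersion List with `intercept`, `slope`, `floor`: the dispersion
#'   is `max(intercept + slope / mu, floor)`.
#' @param libsize List with `median`, `sdlog`: per-sample size factors
#'   \eqn{s_j} are log-normal with this median and log-sd. `sdlog = 0` gives
#'   equal size factors (useful for homogeneous-limit checks).
#' @param seed Integer root seed. One root seed spawns independent child
#'   streams for (means, lfc, library sizes, counts), so changing e.g. the
#'   library-size law does not perturb the gene means.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_counts()], [gtex_like_config()]
#' @export
sim_config <- function(n_genes = 2000,
                       n_per_group = c(100, 100),
                       de_fraction = 0.1,
                       lfc = list(location = 0, scale = 0.8, min_abs = 0.5),
                       baseline = list(meanlog = log(150), sdlog = 2.0),
                       dispersion = list(intercept = 0.16, slope = 2, floor = 0.01),
                       libsize = list(median = 1, sdlog = 0.7),
                       seed = 1L) {
  lfc <- modifyList(list(location = 0, scale = 0.8, min_abs = 0.5), lfc)
  baseline <- modifyList(list(meanlog = log(150), sdlog = 2.0), baseline)
  dispersion <- modifyList(list(intercept = 0.16, slope = 2, floor = 0.01), dispersion)
  libsize <- modifyList(list(median = 1, sdlog = 0.7), libsize)

  check_pos_int <- function(x, what, min = 1L) {
    if (length(x) == 0 || anyNA(x) || any(x != round(x)) || any(x < min)) {
      abort(sprintf("`%s` must be integer(s) >= %d.", what, min))
    }
  }
  check_pos_int(n_genes, "n_genes")
  if (length(n_per_group) != 2L) abort("`n_per_group` must have length 2.")
  check_pos_int(n_per_group, "n_per_group")
  if (!is.numeric(de_fraction) || is.na(de_fraction) ||
      de_fraction < 0 || de_fraction > 1) {
    abort("`de_fraction` must lie in [0, 1].")
  }
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num_ok(lfc$location) || !num_ok(lfc$scale) || lfc$scale < 0 ||
      !num_ok(lfc$min_abs) || lfc$min_abs < 0) {
    abort("`lfc` parameters must be finite; scale and min_abs nonnegative.")
  }
  if (!num_ok(baseline$meanlog) || !num_ok(baseline$sdlog) || baseline$sdlog < 0) {
    abort("`baseline` parameters must be finite with sdlog >= 0.")
  }
  if (!num_ok(dispersion$intercept) || dispersion$intercept < 0 ||
      !num_ok(dispersion$slope) || dispersion$slope < 0 ||
      !num_ok(dispersion$floor) || dispersion$floor <= 0) {
    abort("`dispersion` parameters must be finite and nonnegative; floor > 0.")
  }
  if (!num_ok(libsize$median) || libsize$median <= 0 ||
      !num_ok(libsize$sdlog) || libsize$sdlog < 0) {
    abort("`libsize` parameters must be finite; median > 0, sdlog >= 0.")
  }
  check_pos_int(seed, "seed", min = 0L)

  structure(
    list(
      n_genes = as.integer(n_genes),
      n_per_group = as.integer(n_per_group),
      de_fraction = de_fraction,
      lfc = lfc,
      baseline = baseline,
      dispersion = dispersion,
      libsize = libsize,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sim_config> %d genes, n = %d + %d, DE fraction %.3g\n",
      "  lfc: sign * (%.3g + |N(%.3g, %.3g)|); baseline logN(%.3g, %.3g)\n",
      "  dispersion: max(%.3g + %.3g/mu, %.3g); libsize logN(median %.3g, sd %.3g); seed %d\n"
    ),
    x$n_genes, x$n_per_group[1], x$n_per_group[2], x$de_fraction,
    x$lfc$min_abs, x$lfc$location, x$lfc$scale,
    x$baseline$meanlog, x$baseline$sdlog,
    x$dispersion$intercept, x$dispersion$slope, x$dispersion$floor,
    x$libsize$median, x$libsize$sdlog, x$seed
  ))
  invisible(x)
}

#' GTEx-like default configuration
#'
#' Configuration sized like the GTEx heart atrial appendage vs left ventricle
#' comparison commonly used for semi-synthetic benchmarks: 372 and 386 samples
#' per group, 14445 genes of which 40% (5778) are truly DE, so that retaining
#' half of the DE genes as gold-standard positives leaves 2889 unpermuted true
#' positives. Library-size factors have log-sd 0.7 (several-fold spread).
#'
#' @param scale Positive scale factor applied to both the gene count and the
#'   group sizes (rounded); proportions such as `de_fraction` are preserved.
#'   `scale = 0.1` gives group sizes (37, 39).
#' @param seed Integer seed stored in the config.
#' @return A [sim_config()].
#' @export
gtex_like_config <- function(scale = 1, seed = 1L) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    abort("`scale` must be a positive number.")
  }
  sim_config(
    n_genes = max(1L, round(14445 * scale)),
    n_per_group = pmax(1L, round(c(372, 386) * scale)),
    de_fraction = 0.4,
    libsize = list(median = 1, sdlog = 0.7),
    seed = seed
  )
}

#' Simulate a two-group count matrix with known DE truth
#'
#' Draws a dataset from a [sim_config()]. The generator is fully determined by
#' `config$seed`: identical configs reproduce identical datasets.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{counts}{A [count_matrix()].}
#'     \item{truth}{A tibble with `gene_id`, `is_de`, `lfc` (0 exactly for
#'       non-DE genes) and `gold_standard` (all `FALSE` until
#'       [select_gold_standard()] is applied).}
#'     \item{params}{List of the realized per-gene means `mu`, dispersions
#'       `phi` and per-sample size factors `size_factors`.}
#'   }
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, n_per_group = c(5, 5), seed = 7))
#' sim$counts
#' head(sim$truth)
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genes
  n <- sum(config$n_per_group)
  group <- rep(1:2, config$n_per_group)

  set.seed(config$seed)
  child <- sample.int(2147483040L, 4L)

  set.seed(child[1])
  mu <- rlnorm(g, config$baseline$meanlog, config$baseline$sdlog)
  phi <- pmax(config$dispersion$intercept + config$dispersion$slope / mu,
              config$dispersion$floor)

  n_de <- round(g * config$de_fraction)
  lfc <- numeric(g)
  is_de <- logical(g)
  set.seed(child[2])
  if (n_de > 0) {
    de_idx <- sample.int(g, n_de)
    is_de[de_idx] <- TRUE
    magnitude <- config$lfc$min_abs +
      abs(rnorm(n_de, config$lfc$location, config$lfc$scale))
    sign <- sample(c(-1, 1), n_de, replace = TRUE)
    lfc[de_idx] <- sign * magnitude
  }

  set.seed(child[3])
  s <- rlnorm(n, meanlog = log(config$libsize$median),
              sdlog = config$libsize$sdlog)

  mean_mat <- (mu * 2^(lfc %o% as.numeric(group == 2L))) *
    rep(s, each = g)

  set.seed(child[4])
  counts <- matrix(
    rnbinom(g * n, mu = mean_mat, size = 1 / phi),
    nrow = g, ncol = n
  )

  gene_ids <- sprintf("gene_%05d", seq_len(g))
  sample_ids <- sprintf("s%04d_g%d", seq_len(n), group)
  cm <- count_matrix(counts, group = group, gene_ids = gene_ids,
                     sample_ids = sample_ids)
  truth <- tibble(
    gene_id = gene_ids,
    is_de = is_de,
    lfc = lfc,
    gold_standard = FALSE
  )
  list(
    counts = cm,
    truth = truth,
    params = list(mu = setNames(mu, gene_ids),
                  phi = setNames(phi, gene_ids),
                  size_factors = setNames(s, sample_ids))
  )
}
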