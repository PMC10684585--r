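#' Classification accuracy in percent
#'
#' @param predictions,labels equal-length vectors.
#' @return `100 * mean(predictions == labels)`.
#' @export
accuracy <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  if (length(labels) == 0) stop("empty input")
  100 * mean(as.character(predictions) == as.character(labels))
}

#' Expected accuracy of a uniform-random classifier
#'
#' @param M number of balanced classes.
#' @return `100 / M` (percent).
#' @export
random_baseline_expected_accuracy <- function(M) {
  stopifnot(M >= 1)
  100 / M
}

#' Monte-Carlo check of the chance baseline
#'
#' Draws uniform predictions for a balanced test set of `n_test` samples,
#' `n_draws` times, and returns the mean accuracy. Agrees with
#' [random_baseline_expected_accuracy()] up to Monte-Carlo error.
#'
#' @param M class count.
#' @param n_test balanced test-set size (must be a multiple of M).
#' @param n_draws simulation repeats.
#' @param seed RNG seed.
#' @export
simulate_random_baseline <- function(M, n_test = 60L, n_draws = 1e5L,
                                     seed = 1L) {
  stopifnot(M >= 1, n_test %% M == 0)
  set.seed(seed)
  labels <- rep(seq_len(M), each = n_test / M)
  hits <- vapply(seq_len(n_draws), function(i) {
    sum(sample.int(M, n_test, replace = TRUE) == labels)
  }, 0)
  100 * mean(hits) / n_test
}

#' Best single-source baseline
#'
#' Fits a one-source ensemble per source on the few-shot set, evaluates each
#' on the test split, and returns the best (ties broken by the lowest source
#' index, i.e. bank order).
#'
#' @param banks named list of few-shot [feature_bank()]s.
#' @param few_shot a [few_shot_set()].
#' @param test_banks named list of test banks aligned with `test_labels`.
#' @param test_labels test labels.
#' @param config an [mstl_config()].
#' @return list with `source_id`, `accuracy`, and `per_source` (named
#'   accuracy vector).
#' @export
best_single_source <- function(banks, few_shot, test_banks, test_labels,
                               config = mstl_config()) {
  stopifnot(length(banks) >= 1)
  ids <- vapply(banks, function(b) b$source_id, "")
  acc <- vapply(seq_along(banks), function(i) {
    m <- fit_ensemble(banks[i], few_shot, config)
    accuracy(predict_batch(m, test_banks[i]), test_labels)
  }, 0)
  names(acc) <- ids
  best <- which.max(acc)
  list(source_id = unname(ids[best]), accuracy = unname(acc[best]),
       per_source = acc)
}

# per-run seeds derived from one base seed, kept below 2^31
derive_seeds <- function(seed, n, stream = 0L) {
  set.seed(seed + stream)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Accuracy sweep over shot counts
#'
#' For each k in `shots` and each of `n_seeds` replicate runs, draws an
#' independent few-shot set and test split from the scenario, fits the
#' ensemble, and records test accuracy.
#'
#' @param scenario a [make_scenario()] scenario.
#' @param shots positive ascending shot counts.
#' @param n_seeds replicate runs per shot count.
#' @param n_test_per_class test samples per class.
#' @param config an [mstl_config()].
#' @param seed base seed for the replicate streams.
#' @return data.frame with columns `k`, `mean_accuracy`, `sd_accuracy`,
#'   `n_seeds`.
#' @export
shot_sweep <- function(scenario, shots = c(1, 5, 10, 20), n_seeds = 20L,
                       n_test_per_class = 10L, config = mstl_config(),
                       seed = 1L) {
  stopifnot(all(shots >= 1), !is.unsorted(shots, strictly = TRUE))
  fs_seeds <- derive_seeds(seed, n_seeds, stream = 0L)
  te_seeds <- derive_seeds(seed, n_seeds, stream = 1L)
  rows <- lapply(shots, function(k) {
    acc <- vapply(seq_len(n_seeds), function(r) {
      train <- sample_few_shot(scenario, k, seed = fs_seeds[r])
      test <- sample_test(scenario, n_test_per_class, seed = te_seeds[r])
      model <- fit_ensemble(train$banks, train$few_shot, config)
      accuracy(predict_batch(model, test$banks), test$labels)
    }, 0)
    data.frame(k = k, mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
               n_seeds = n_seeds)
  })
  do.call(rbind, rows)
}

#' Stability of source weights over repeated few-shot draws
#'
#' Refits the ensemble on `n_runs` independent few-shot draws and summarizes
#' the distribution of each source's weight. The group mode yields one group
#' correlation per source and run; the per-dimension mode pools the
#' per-dimension correlations over dimensions and runs, the spread a
#' per-dimension weighting scheme exposes.
#'
#' @param scenario a [make_scenario()] scenario.
#' @param n_runs number of independent few-shot draws (>= 2).
#' @param k shots per class.
#' @param config an [mstl_config()] (its `mode` selects which weights are
#'   summarized).
#' @param seed base seed.
#' @return data.frame with one row per source: `source_id`, `median`, `iqr`,
#'   `mode`, `n_runs`.
#' @export
weight_stability <- function(scenario, n_runs = 20L, k = 20L,
                             config = mstl_config(), seed = 1L) {
  stopifnot(n_runs >= 2)
  run_seeds <- derive_seeds(seed, n_runs, stream = 2L)
  weights <- lapply(seq_len(n_runs), function(r) {
    train <- sample_few_shot(scenario, k, seed = run_seeds[r])
    model <- fit_ensemble(train$banks, train$few_shot, config)
    if (config$mode == "group") {
      lapply(model$sources, function(s) s$group_rho)
    } else {
      lapply(model$sources, function(s) s$per_dim_rho)
    }
  })
  ids <- scenario$source_ids
  rows <- lapply(ids, function(id) {
    v <- unlist(lapply(weights, `[[`, id))
    data.frame(source_id = id, median = stats::median(v),
               iqr = stats::IQR(v), mode = config$mode, n_runs = n_runs)
  })
  do.call(rbind, rows)
}

#' Results table for multi-method comparison
#'
#' @param x numeric matrix or data.frame: rows = experimental units
#'   (dataset/run), columns = methods, cells = accuracy in percent.
#' @return validated numeric matrix of class `results_table`.
#' @export
results_table <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("results table must be numeric")
  if (any(!is.finite(m))) stop("results table has missing cells")
  if (any(m < 0 | m > 100)) stop("accuracies must lie in [0, 100]")
  if (is.null(colnames(m))) colnames(m) <- paste0("method", seq_len(ncol(m)))
  structure(m, class = c("results_table", "matrix"))
}

#' Average (fractional) ranks of methods
#'
#' Ranks each row's accuracies (rank 1 = best accuracy; ties get the mean of
#' the tied ranks) and averages the ranks over rows. Per-row ranks always sum
#' to `k (k + 1) / 2`.
#'
#' @param results a [results_table()] (or coercible) with >= 2 methods.
#' @return named numeric vector of average ranks.
#' @export
average_ranks <- function(results) {
  m <- results_table(results)
  if (ncol(m) < 2) stop("need at least 2 methods")
  ranks <- t(apply(m, 1, function(row) rank(-row, ties.method = "average")))
  colMeans(ranks)
}

# Two-tailed critical values for average-rank post-hoc tests (Demsar 2006,
# "Statistical comparisons of classifiers over multiple data sets", Table 5):
# Nemenyi q_alpha = studentized range q / sqrt(2); Bonferroni-Dunn q_alpha
# for k - 1 comparisons against a control. Rows: k = 2..10.
demsar_q <- list(
  nemenyi = list(
    `0.05` = c(1.960, 2.343, 2.569, 2.728, 2.850, 2.949, 3.031, 3.102, 3.164),
    `0.1`  = c(1.645, 2.052, 2.291, 2.459, 2.589, 2.693, 2.780, 2.855, 2.920)
  ),
  bonferroni_dunn = list(
    `0.05` = c(1.960, 2.241, 2.394, 2.498, 2.576, 2.638, 2.690, 2.724, 2.773),
    `0.1`  = c(1.645, 1.960, 2.128, 2.241, 2.326, 2.394, 2.450, 2.498, 2.539)
  )
)

#' Critical difference for average-rank comparisons
#'
#' `CD = q_alpha * sqrt(k (k + 1) / (6 N))`: two methods differ significantly
#' when their average-rank gap is at least CD. The `q_alpha` constants are
#' the published two-tailed Nemenyi / Bonferroni-Dunn critical values for
#' k = 2..10 methods at alpha 0.05 or 0.1.
#'
#' @param k number of methods (2..10).
#' @param N number of experimental units.
#' @param alpha 0.05 or 0.1.
#' @param test `"nemenyi"` (all-pairs) or `"bonferroni_dunn"` (against a
#'   control).
#' @return the CD value.
#' @export
critical_difference <- function(k, N, alpha = 0.05,
                                test = c("nemenyi", "bonferroni_dunn")) {
  test <- match.arg(test)
  if (!alpha %in% c(0.05, 0.1)) stop("alpha must be 0.05 or 0.1")
  if (k < 2 || k > 10) stop("k must be between 2 and 10 (tabulated range)")
  if (N < 1) stop("N must be positive")
  q <- demsar_q[[test]][[as.character(alpha)]][k - 1]
  q * sqrt(k * (k + 1) / (6 * N))
}

#' Rank-based omnibus tests over a results table
#'
#' Runs the Friedman test (methods as repeated measures over the rows) and
#' the Kruskal-Wallis H-test (methods as independent groups) on a results
#' table. Identical method columns yield a Friedman statistic of 0 and
#' p close to 1.
#'
#' @param results a [results_table()] (or coercible).
#' @return list with `friedman` and `kruskal`, each holding `statistic` and
#'   `p_value`.
#' @export
rank_tests <- function(results) {
  m <- results_table(results)
  if (ncol(m) < 2 || nrow(m) < 2) stop("need >= 2 methods and >= 2 rows")
  fr <- stats::friedman.test(unclass(m))
  # fully tied rows (e.g. identical method columns) make the tie-corrected
  # statistic 0/0; the correct limit is no evidence against the null
  if (is.nan(fr$statistic)) {
    fr$statistic <- 0
    fr$p.value <- 1
  }
  values <- as.vector(m)
  groups <- factor(rep(colnames(m), each = nrow(m)))
  kw <- stats::kruskal.test(values, groups)
  list(friedman = list(statistic = unname(fr$statistic),
                       p_value = fr$p.value),
       kruskal = list(statistic = unname(kw$statistic),
                      p_value = kw$p.value))
}

#' Post-hoc comparison report
#'
#' Average ranks plus the critical difference and, for the Nemenyi test, the
#' pairs whose rank gap reaches significance.
#'
#' @param results a [results_table()].
#' @param alpha 0.05 or 0.1.
#' @param test passed to [critical_difference()].
#' @return list with `average_ranks`, `cd`, `alpha`, `test`,
#'   `significant_pairs` (data.frame).
#' @export
posthoc_report <- function(results, alpha = 0.05,
                           test = c("nemenyi", "bonferroni_dunn")) {
  test <- match.arg(test)
  m <- results_table(results)
  ar <- average_ranks(m)
  cd <- critical_difference(ncol(m), nrow(m), alpha, test)
  pairs <- utils::combn(names(ar), 2)
  gap <- abs(ar[pairs[1, ]] - ar[pairs[2, ]])
  sig <- data.frame(method_a = pairs[1, ], method_b = pairs[2, ],
                    rank_gap = unname(gap),
                    significant = unname(gap >= cd))
  list(average_ranks = ar, cd = cd, alpha = alpha, test = test,
       significant_pairs = sig)
}
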