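test_that("accuracy and the chance baseline are exact", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(accuracy(c(1, 2, 3), c(3, 1, 2)), 0)
  expect_equal(accuracy(c(1, rep(0, 59))[1:60], rep(1, 60)), 100 * 1 / 60)
  expect_error(accuracy(integer(), integer()), "empty")
  expect_equal(random_baseline_expected_accuracy(6), 100 / 6)
  expect_equal(round(random_baseline_expected_accuracy(6), 2), 16.67)
  expect_equal(random_baseline_expected_accuracy(1), 100)
  expect_equal(random_baseline_expected_accuracy(2), 50)
})

test_that("simulated chance agrees with the analytic value", {
  sim <- simulate_random_baseline(6, n_test = 60, n_draws = 2e4, seed = 1)
  expect_lt(abs(sim - 100 / 6), 0.5)
})

test_that("best_single_source picks the informative source and is self-consistent", {
  sc <- tiny_scenario()
  tr <- sample_few_shot(sc, 10, seed = 1)
  te <- sample_test(sc, 10, seed = 2)
  res <- best_single_source(tr$banks, tr$few_shot, te$banks, te$labels)
  expect_identical(res$source_id, "source01")  # separation 3 vs pure noise
  expect_equal(res$accuracy, unname(res$per_source[res$source_id]))
  # re-evaluating the returned source reproduces the returned accuracy
  m <- fit_ensemble(tr$banks[res$source_id], tr$few_shot)
  expect_equal(accuracy(predict_batch(m, te$banks[res$source_id]), te$labels),
               res$accuracy)
  # single source: trivially that source
  solo <- best_single_source(tr$banks[1], tr$few_shot, te$banks[1], te$labels)
  expect_identical(solo$source_id, "source01")
})

test_that("shot sweep is deterministic and monotone in the noiseless limit", {
  sc <- make_scenario(scenario_spec(2, 3, 8, c(4, 2), noise_sd = 1e-6,
                                    seed = 1))
  sw1 <- shot_sweep(sc, shots = c(1, 5), n_seeds = 3, seed = 7)
  sw2 <- shot_sweep(sc, shots = c(1, 5), n_seeds = 3, seed = 7)
  expect_identical(sw1, sw2)
  expect_equal(sw1$mean_accuracy, c(100, 100))  # separable at every k
  expect_error(shot_sweep(sc, shots = c(5, 1)), "unsorted|strictly")
})

test_that("weight stability reports one row per source with sensible spreads", {
  sc <- make_scenario(scenario_spec(2, 3, 8, c(3, 0), noise_sd = 1, seed = 2))
  ws <- weight_stability(sc, n_runs = 8, k = 20, seed = 3)
  expect_identical(ws$source_id, sc$source_ids)
  expect_true(all(ws$iqr >= 0))
  n <- 20 * 3
  expect_lte(ws$median[ws$source_id == "source02"], 3 / sqrt(n))
  # near-deterministic features: spread collapses
  scq <- make_scenario(scenario_spec(1, 3, 4, 2, noise_sd = 1e-9, seed = 4))
  wsq <- weight_stability(scq, n_runs = 4, k = 10, seed = 5)
  expect_lt(wsq$iqr[1], 1e-6)
})

test_that("average ranks are fractional and row-sums are exact", {
  # row ranks: (1,2,3) and (3,1,2) -> column means (2, 1.5, 2.5)
  m <- results_table(rbind(c(90, 80, 70), c(70, 90, 80)))
  expect_equal(unname(average_ranks(m)), c(2, 1.5, 2.5))
  two <- results_table(rbind(c(60, 50), c(70, 65), c(80, 20)))
  expect_equal(unname(average_ranks(two)), c(1, 2))
  tied <- results_table(rbind(c(50, 50, 50, 50)))
  expect_equal(unname(average_ranks(tied)), rep(2.5, 4))
  # per-row rank sums are k(k+1)/2 on random tables
  set.seed(9)
  for (i in 1:5) {
    k <- sample(3:7, 1)
    tab <- matrix(runif(4 * k, 0, 100), 4, k)
    ranks <- t(apply(tab, 1, function(r) rank(-r, ties.method = "average")))
    expect_equal(unname(rowSums(ranks)), rep(k * (k + 1) / 2, 4))
  }
  expect_error(results_table(rbind(c(101, 50))), "0, 100")
})

test_that("critical differences match an independent studentized-range computation", {
  # Nemenyi q_alpha = qtukey(1 - alpha, k, Inf) / sqrt(2)
  for (k in c(3, 6, 10)) {
    cd <- critical_difference(k, 20, alpha = 0.05, test = "nemenyi")
    q_oracle <- stats::qtukey(0.95, k, Inf) / sqrt(2)
    expect_equal(cd, q_oracle * sqrt(k * (k + 1) / (6 * 20)),
                 tolerance = 1e-3)
  }
  # Bonferroni-Dunn q_alpha is the two-sided normal quantile at alpha/(k-1)
  for (k in c(4, 6)) {
    cd <- critical_difference(k, 15, alpha = 0.1, test = "bonferroni_dunn")
    q_oracle <- stats::qnorm(1 - 0.1 / (k - 1) / 2)
    expect_equal(cd, q_oracle * sqrt(k * (k + 1) / (6 * 15)),
                 tolerance = 1e-3)
  }
  # scaling laws
  expect_equal(critical_difference(6, 40, 0.05) * sqrt(2),
               critical_difference(6, 20, 0.05), tolerance = 1e-12)
  expect_lt(critical_difference(6, 1e6, 0.05), 1e-2)
  expect_error(critical_difference(6, 20, alpha = 0.2), "alpha")
  expect_error(critical_difference(12, 20), "between 2 and 10")
})

test_that("rank tests flag dominance and ignore column order", {
  set.seed(10)
  # strongly ordered table: method1 always best, method3 always worst
  base <- matrix(runif(20, 40, 50), 20, 3)
  tab <- base + rep(c(20, 10, 0), each = 20)
  res <- rank_tests(tab)
  expect_lt(res$friedman$p_value, 0.05)
  expect_lt(res$kruskal$p_value, 0.05)
  # agreement with direct calls to the reference routines
  expect_equal(res$friedman$statistic,
               unname(stats::friedman.test(tab)$statistic))
  # permutation invariance of the statistics
  res_perm <- rank_tests(tab[, c(3, 1, 2)])
  expect_equal(res_perm$friedman$statistic, res$friedman$statistic)
  expect_equal(res_perm$kruskal$statistic, res$kruskal$statistic)
  # identical columns: Friedman statistic 0
  same <- matrix(rep(runif(10, 0, 100), 3), 10, 3)
  expect_equal(rank_tests(same)$friedman$statistic, 0)
})

test_that("posthoc report marks pairs beyond the critical difference", {
  set.seed(11)
  tab <- cbind(best = runif(20, 90, 95), mid = runif(20, 60, 92),
               worst = runif(20, 10, 15))
  rep_ <- posthoc_report(tab, alpha = 0.05, test = "nemenyi")
  sig <- rep_$significant_pairs
  bw <- sig$significant[sig$method_a == "best" & sig$method_b == "worst"]
  expect_true(bw)
  expect_equal(rep_$cd, critical_difference(3, 20, 0.05, "nemenyi"))
})
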