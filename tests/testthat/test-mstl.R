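test_that("class prior is the empirical label frequency", {
  fs <- few_shot_set(paste0("s", 1:120), rep(paste0("c", 1:6), each = 20))
  expect_equal(unname(estimate_class_prior(fs)), rep(1 / 6, 6))
  fs2 <- few_shot_set(paste0("s", 1:3), c("0", "0", "1"))
  expect_equal(unname(estimate_class_prior(fs2)), c(2 / 3, 1 / 3))
  set.seed(1)
  fs3 <- few_shot_set(paste0("s", 1:50),
                      sample(c("a", "b", "c"), 50, replace = TRUE))
  expect_equal(sum(estimate_class_prior(fs3)), 1)
})

test_that("worked single-dimension source model is recovered exactly", {
  scm <- fit_source_correlation(worked_bank(), worked_few_shot())
  expect_equal(unname(scm$g_table[1, ]), c(-1, 1), tolerance = 1e-10)
  expect_equal(unname(scm$per_dim_rho), 1, tolerance = 1e-10)
  expect_equal(scm$group_rho, 1, tolerance = 1e-10)
})

test_that("g rows are standardized under the class prior; rho bounded", {
  set.seed(21)
  n <- 90
  labels <- rep(c("a", "b", "c"), each = n / 3)
  bank <- feature_bank("s", paste0("x", 1:n), matrix(rnorm(n * 5), n, 5) +
                         outer(as.integer(factor(labels)), rep(0.5, 5)))
  fs <- few_shot_set(paste0("x", 1:n), labels)
  scm <- fit_source_correlation(bank, fs)
  prior <- estimate_class_prior(fs)
  for (j in 1:5) {
    expect_lt(abs(sum(prior * scm$g_table[j, ])), 1e-8)
    expect_equal(sum(prior * scm$g_table[j, ]^2), 1, tolerance = 1e-6)
  }
  expect_true(all(scm$per_dim_rho >= 0 & scm$per_dim_rho <= 1 + 1e-8))
  expect_true(scm$group_rho >= 0 && scm$group_rho <= 1 + 1e-8)
})

test_that("constant feature dimensions carry zero weight, with a warning when all do", {
  bank <- feature_bank("s", paste0("a", 1:4),
                       cbind(c(-1, -1, 1, 1), rep(2, 4)))
  scm <- fit_source_correlation(bank, worked_few_shot())
  expect_equal(unname(scm$per_dim_rho), c(1, 0))
  expect_true(scm$degenerate_mask[2])
  allconst <- feature_bank("s", paste0("a", 1:4), matrix(3, 4, 2))
  expect_warning(scm0 <- fit_source_correlation(allconst, worked_few_shot()),
                 "degenerate")
  expect_equal(scm0$group_rho, 0)
})

test_that("permuted labels give group_rho at the independence floor", {
  set.seed(31)
  n <- 600
  bank <- feature_bank("s", paste0("x", 1:n), matrix(rnorm(n * 32), n, 32))
  fs <- few_shot_set(paste0("x", 1:n),
                     sample(rep(paste0("c", 1:6), each = n / 6)))
  scm <- fit_source_correlation(bank, fs)
  expect_lte(scm$group_rho, 3 / sqrt(n))
})

test_that("fit_ensemble reduces to fit_source_correlation for one source and is symmetric", {
  bank <- worked_bank()
  fs <- worked_few_shot()
  em <- fit_ensemble(list(bank), fs)
  scm <- fit_source_correlation(bank, fs)
  expect_equal(em$sources$s1$g_table, scm$g_table, tolerance = 1e-12)
  expect_equal(em$sources$s1$group_rho, scm$group_rho, tolerance = 1e-12)
  expect_equal(em$rho_star, sum(source_weights(em)), tolerance = 1e-10)

  # two identical sources get identical models and weights
  bank2 <- feature_bank("s2", bank$sample_ids, bank$values)
  em2 <- fit_ensemble(list(bank, bank2), fs)
  w <- source_weights(em2)
  expect_equal(unname(w["s1"]), unname(w["s2"]))
  expect_equal(em2$sources$s1$g_table, em2$sources$s2$g_table,
               ignore_attr = TRUE)
})

test_that("fit_ensemble rejects misaligned banks, naming the offenders", {
  fs <- worked_few_shot()
  good <- worked_bank()
  bad <- feature_bank("s9", paste0("z", 1:4), matrix(rnorm(4), 4, 1))
  expect_error(fit_ensemble(list(good, bad), fs), "s9")
})

test_that("posterior scores follow the worked expansion and sum to 1", {
  em <- fit_ensemble(list(worked_bank()), worked_few_shot())
  s <- posterior_scores(em, list(s1 = 1))
  expect_equal(unname(s), c(0, 1), tolerance = 1e-10)
  expect_equal(predict(em, list(s1 = 1)), "1")
  expect_equal(predict(em, list(s1 = -1)), "0")

  # scores equal the prior when every correlation is zero
  allconst <- feature_bank("s1", paste0("a", 1:4), matrix(3, 4, 2))
  suppressWarnings(em0 <- fit_ensemble(list(allconst), worked_few_shot()))
  expect_equal(unname(posterior_scores(em0, list(s1 = c(9, 9)))),
               unname(em0$class_prior))
  # all-zero correlations + uniform prior: tie broken to the lowest class
  expect_equal(predict(em0, list(s1 = c(1, 2))), "0")

  # normalization identity on random inputs
  set.seed(41)
  sc <- tiny_scenario()
  tr <- sample_few_shot(sc, 5, seed = 42)
  m <- fit_ensemble(tr$banks, tr$few_shot)
  X <- lapply(sc$source_ids, function(i) matrix(rnorm(200 * 8), 200, 8))
  names(X) <- sc$source_ids
  expect_lt(max(abs(rowSums(score_batch(m, X)) - 1)), 1e-8)
})

test_that("group and per-dimension modes coincide for d = 1 sources", {
  set.seed(51)
  n <- 30
  labels <- rep(c("a", "b", "c"), each = 10)
  ids <- paste0("x", 1:n)
  banks <- list(feature_bank("u", ids, matrix(rnorm(n) + (labels == "a"))),
                feature_bank("v", ids, matrix(rnorm(n) + (labels == "b"))))
  fs <- few_shot_set(ids, labels)
  mg <- fit_ensemble(banks, fs, mstl_config(mode = "group"))
  mp <- fit_ensemble(banks, fs, mstl_config(mode = "per_dimension"))
  X <- list(u = matrix(rnorm(20)), v = matrix(rnorm(20)))
  expect_equal(score_batch(mg, X), score_batch(mp, X), tolerance = 1e-12)
})

test_that("deterministic label-coding features yield perfect prediction", {
  set.seed(61)
  # binary label, single deterministic feature: the rank-1 expansion is exact
  n <- 200
  labels2 <- rep(c("c1", "c2"), each = n / 2)
  code2 <- c(c1 = -1, c2 = 1)
  ids <- paste0("x", 1:n)
  m2 <- fit_ensemble(list(feature_bank("det", ids, matrix(code2[labels2]))),
                     few_shot_set(ids, labels2))
  test2 <- sample(c("c1", "c2"), 60, replace = TRUE)
  expect_equal(accuracy(predict_batch(m2, list(det = matrix(code2[test2]))),
                        test2), 100)

  # 3 classes need a multi-dimensional deterministic embedding (one-hot):
  # a single scalar code cannot be separated by the rank-1 score expansion
  labels3 <- rep(paste0("c", 1:3), each = 100)
  onehot <- function(l) diag(3)[match(l, paste0("c", 1:3)), , drop = FALSE]
  m3 <- fit_ensemble(list(feature_bank("oh", paste0("y", 1:300),
                                       onehot(labels3))),
                     few_shot_set(paste0("y", 1:300), labels3))
  test3 <- sample(paste0("c", 1:3), 60, replace = TRUE)
  expect_equal(accuracy(predict_batch(m3, list(oh = onehot(test3))), test3),
               100)
})

test_that("predict_batch equals elementwise single predictions", {
  sc <- tiny_scenario()
  tr <- sample_few_shot(sc, 4, seed = 70)
  te <- sample_test(sc, 3, seed = 71)
  m <- fit_ensemble(tr$banks, tr$few_shot)
  batch <- predict_batch(m, te$banks)
  single <- vapply(seq_along(te$labels), function(i) {
    predict(m, lapply(te$banks, function(b) b$values[i, ]))
  }, "")
  expect_identical(batch, single)
})

test_that("drop_source removes exactly one source and errors at the edges", {
  sc <- tiny_scenario()
  tr <- sample_few_shot(sc, 4, seed = 80)
  m <- fit_ensemble(tr$banks, tr$few_shot)
  prior <- m$class_prior
  m2 <- drop_source(m, "source02")
  expect_false("source02" %in% names(source_weights(m2)))
  expect_equal(m2$sources$source01, m$sources$source01)
  expect_equal(m2$class_prior, prior)
  expect_error(drop_source(m, "nope"), "unknown")
  expect_error(drop_source(m2, "source01"), "last source")
})

test_that("ensemble JSON persistence round-trips scores exactly", {
  sc <- tiny_scenario()
  tr <- sample_few_shot(sc, 4, seed = 90)
  m <- fit_ensemble(tr$banks, tr$few_shot)
  path <- withr::local_tempfile(fileext = ".json")
  save_ensemble(m, path)
  back <- load_ensemble(path)
  X <- lapply(sc$source_ids, function(i) matrix(rnorm(40), 5, 8))
  names(X) <- sc$source_ids
  expect_equal(score_batch(back, X), score_batch(m, X), tolerance = 1e-12)
  expect_equal(source_weights(back), source_weights(m), tolerance = 1e-12)
  expect_identical(back$mode, m$mode)
})

test_that("clip_probabilities affects probability output only", {
  em <- fit_ensemble(list(worked_bank()), worked_few_shot(),
                     mstl_config(clip_probabilities = TRUE))
  p <- posterior_probabilities(em, list(s1 = 2))  # raw scores (-0.5, 1.5)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1)
  s <- posterior_scores(em, list(s1 = 2))
  expect_lt(s[1], 0)  # ranking scores stay unclipped
})
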