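#' Configuration for ensemble fitting and prediction
#'
#' @param mode how source contributions are weighted in the posterior
#'   expansion: `"group"` uses one group correlation weight per source
#'   (the multivariate, group-correlation method); `"per_dimension"` weights
#'   every feature dimension by its own bivariate correlation (the
#'   per-dimension correlation-weighting comparison mode).
#' @param aggregate how per-dimension correlations aggregate into the group
#'   weight: `"mean"` keeps weights in `[0, 1]` and comparable across sources
#'   with different feature dimension; `"sum"` is the literal inner-product
#'   reading.
#' @param variance_floor degenerate-dimension threshold for feature
#'   standardization.
#' @param clip_probabilities if `TRUE`, probability output from
#'   [posterior_probabilities()] clips negative expansion values at 0 and
#'   renormalizes (ranking via [predict()] is never clipped).
#' @param tol,max_iter ACE convergence controls (used on iterative paths).
#' @return a list of class `mstl_config`.
#' @export
mstl_config <- function(mode = c("group", "per_dimension"),
                        aggregate = c("mean", "sum"),
                        variance_floor = 1e-8,
                        clip_probabilities = FALSE,
                        tol = 1e-6, max_iter = 100L) {
  structure(list(mode = match.arg(mode), aggregate = match.arg(aggregate),
                 variance_floor = variance_floor,
                 clip_probabilities = isTRUE(clip_probabilities),
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "mstl_config")
}

#' Empirical class prior of a few-shot set
#'
#' @param few_shot a [few_shot_set()].
#' @return named probability vector over the declared classes (uniform for a
#'   balanced k-shot set). Construction of the few-shot set already enforces
#'   that every class is present.
#' @export
estimate_class_prior <- function(few_shot) {
  stopifnot(inherits(few_shot, "few_shot_set"))
  counts <- table(factor(few_shot$labels, levels = few_shot$class_labels))
  prior <- as.numeric(counts) / length(few_shot$labels)
  stats::setNames(prior, few_shot$class_labels)
}

#' Fit one source's correlation functions and weights
#'
#' Standardizes the source's features on the few-shot set, then for every
#' feature dimension j sets the correlation function `g_j(y)` to the
#' class-conditional mean of the standardized feature, standardized to mean 0
#' and variance 1 under the empirical class prior. The per-dimension weight
#' is the empirical correlation `E[f_j g_j]`, which equals the correlation
#' ratio (between-class standard deviation of the standardized feature) and
#' lies in `[0, 1]`. The group weight aggregates the per-dimension weights
#' (mean by default).
#'
#' @param bank a [feature_bank()] whose rows align with `few_shot`.
#' @param few_shot a [few_shot_set()].
#' @param config an [mstl_config()].
#' @return an object of class `source_correlation_model`: `source_id`,
#'   `g_table` (d x M), `per_dim_rho`, `group_rho`, `degenerate_mask`,
#'   `standardizer`, `class_labels`.
#' @export
fit_source_correlation <- function(bank, few_shot, config = mstl_config()) {
  stopifnot(inherits(bank, "feature_bank"), inherits(few_shot, "few_shot_set"))
  if (!identical(bank$sample_ids, few_shot$sample_ids)) {
    stop(sprintf("bank '%s' sample ids do not align with the few-shot set",
                 bank$source_id))
  }
  std <- fit_standardizer(bank, config$variance_floor)
  z <- apply_standardizer(std, bank)$values
  yf <- factor(few_shot$labels, levels = few_shot$class_labels)
  prior <- estimate_class_prior(few_shot)
  fit <- fit_block_label_edge(z, as.integer(yf), few_shot$class_labels,
                              prior, config$variance_floor)
  group_rho <- switch(config$aggregate,
                      mean = mean(fit$per_dim_rho),
                      sum = sum(fit$per_dim_rho))
  if (all(fit$degenerate)) {
    warning(sprintf("source '%s': every feature dimension is degenerate on the few-shot set",
                    bank$source_id))
  }
  structure(list(source_id = bank$source_id,
                 g_table = fit$g,
                 per_dim_rho = fit$per_dim_rho,
                 group_rho = group_rho,
                 degenerate_mask = fit$degenerate,
                 standardizer = std,
                 class_labels = few_shot$class_labels),
            class = "source_correlation_model")
}

#' Fit the multi-source ensemble on a few-shot set
#'
#' Builds the star dependence graph (target label hub, one fixed feature
#' block per source), fits it with [ace_graph_fit()], and packages one
#' [fit_source_correlation()]-equivalent model per source plus the empirical
#' class prior. The aggregate maximal correlation attained (the fitting
#' objective) is the sum of the per-source edge correlations and is stored as
#' `rho_star`.
#'
#' @param banks named list of [feature_bank()]s, all aligned on the few-shot
#'   samples.
#' @param few_shot a [few_shot_set()].
#' @param config an [mstl_config()].
#' @return an object of class `ensemble_model`: `sources` (named list of
#'   `source_correlation_model`), `class_prior`, `class_labels`, `mode`,
#'   `config`, `rho_star`.
#' @export
fit_ensemble <- function(banks, few_shot, config = mstl_config()) {
  stopifnot(is.list(banks), length(banks) >= 1,
            inherits(few_shot, "few_shot_set"))
  ids <- vapply(banks, function(b) b$source_id, "")
  names(banks) <- ids
  if (anyDuplicated(ids)) stop("duplicate source ids among banks")
  misaligned <- ids[!vapply(banks, function(b)
    identical(b$sample_ids, few_shot$sample_ids), TRUE)]
  if (length(misaligned) > 0) {
    stop(sprintf("banks not aligned with the few-shot samples: %s",
                 paste(misaligned, collapse = ", ")))
  }

  stds <- lapply(banks, fit_standardizer,
                 variance_floor = config$variance_floor)
  blocks <- lapply(ids, function(id)
    apply_standardizer(stds[[id]], banks[[id]])$values)
  names(blocks) <- ids

  graph <- star_graph(ids)
  ace <- ace_graph_fit(blocks = blocks,
                       labels = list(label = few_shot$labels),
                       graph = graph,
                       tol = config$tol, max_iter = config$max_iter,
                       aggregate = config$aggregate,
                       variance_floor = config$variance_floor)

  prior <- estimate_class_prior(few_shot)
  sources <- lapply(ids, function(id) {
    gt <- ace$transforms$label[[id]]  # categories x dims
    g_tab <- t(`attributes<-`(gt, list(dim = dim(gt), dimnames = dimnames(gt))))
    structure(list(source_id = id,
                   g_table = g_tab,
                   per_dim_rho = attr(gt, "per_dim_rho"),
                   group_rho = unname(ace$edge_correlations[paste0(id, "~label")]),
                   degenerate_mask = attr(gt, "degenerate"),
                   standardizer = stds[[id]],
                   class_labels = few_shot$class_labels),
              class = "source_correlation_model")
  })
  names(sources) <- ids
  structure(list(sources = sources,
                 class_prior = prior,
                 class_labels = few_shot$class_labels,
                 mode = config$mode,
                 config = config,
                 rho_star = ace$aggregate),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: %d source(s), %d classes, mode '%s', rho* = %.4g\n",
              length(x$sources), length(x$class_labels), x$mode, x$rho_star))
  print(source_weights(x))
  invisible(x)
}

# Standardize per-source raw feature vectors/matrices with the stored
# few-shot statistics. `features`: named list of numeric vectors (one sample)
# or matrices (n samples).
standardize_for_model <- function(model, features) {
  ids <- names(model$sources)
  missing <- setdiff(ids, names(features))
  if (length(missing) > 0) {
    stop(sprintf("missing features for source(s): %s",
                 paste(missing, collapse = ", ")))
  }
  lapply(ids, function(id) {
    x <- features[[id]]
    if (inherits(x, "feature_bank")) x <- x$values
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    std <- model$sources[[id]]$standardizer
    if (ncol(x) != length(std$center)) {
      stop(sprintf("source '%s': %d feature dims, model expects %d",
                   id, ncol(x), length(std$center)))
    }
    z <- sweep(sweep(x, 2, std$center), 2, std$scale, `/`)
    z[, std$degenerate_mask] <- 0
    z
  }) |> stats::setNames(ids)
}

# Correlation-expansion scores for pre-standardized per-source matrices.
expansion_scores <- function(model, z_list) {
  n <- nrow(z_list[[1]])
  M <- length(model$class_labels)
  total <- matrix(0, n, M)
  for (id in names(model$sources)) {
    src <- model$sources[[id]]
    G <- src$g_table  # d x M
    contrib <- if (model$mode == "group") {
      src$group_rho * (z_list[[id]] %*% G)
    } else {
      z_list[[id]] %*% (src$per_dim_rho * G)
    }
    total <- total + contrib
  }
  scores <- sweep(1 + total, 2, model$class_prior, `*`)
  colnames(scores) <- model$class_labels
  scores
}

#' Posterior scores of the correlation expansion
#'
#' Evaluates `score(y) = P_Y(y) * (1 + sum_i w_i sum_j f_j^i(x) g_j^i(y))`
#' for one sample, where `f^i` are the source features standardized with the
#' few-shot statistics and the weights `w` are the group correlation (mode
#' `"group"`) or the per-dimension correlations (mode `"per_dimension"`).
#' The scores always sum to 1 (each `g` has mean 0 under the class prior) but
#' individual scores may be negative: the expansion is a truncated
#' reconstruction of the conditional, not a clipped probability.
#'
#' @param model an [fit_ensemble()] model.
#' @param features named list (by source id) of raw feature vectors for one
#'   sample.
#' @return named numeric vector of M scores.
#' @export
posterior_scores <- function(model, features) {
  stopifnot(inherits(model, "ensemble_model"))
  z <- standardize_for_model(model, features)
  drop(expansion_scores(model, z))
}

#' Posterior class probabilities
#'
#' Like [posterior_scores()] but, when the model config sets
#' `clip_probabilities`, negative scores are clipped at 0 and the vector
#' renormalized.
#'
#' @inheritParams posterior_scores
#' @export
posterior_probabilities <- function(model, features) {
  s <- posterior_scores(model, features)
  if (isTRUE(model$config$clip_probabilities)) {
    s <- pmax(s, 0)
    total <- sum(s)
    s <- if (total > 0) s / total else
      stats::setNames(rep(1 / length(s), length(s)), names(s))
  }
  s
}

#' Predict the target label
#'
#' Argmax of the posterior scores; ties are broken deterministically by the
#' lowest class index.
#'
#' @param object an `ensemble_model`.
#' @param features named list (by source id) of raw feature vectors for one
#'   sample.
#' @param ... unused.
#' @return the predicted class label (character).
#' @export
predict.ensemble_model <- function(object, features, ...) {
  s <- posterior_scores(object, features)
  object$class_labels[which.max(s)]
}

#' Predict labels for aligned feature banks
#'
#' @param model an `ensemble_model`.
#' @param banks named list of [feature_bank()]s (or raw matrices), one per
#'   source, rows aligned across sources.
#' @return character vector of predicted labels, one per row.
#' @export
predict_batch <- function(model, banks) {
  stopifnot(inherits(model, "ensemble_model"))
  z <- standardize_for_model(model, banks)
  ns <- vapply(z, nrow, 1L)
  if (length(unique(ns)) > 1) stop("banks disagree on the sample count")
  scores <- expansion_scores(model, z)
  model$class_labels[apply(scores, 1, which.max)]
}

#' Posterior score matrix for aligned feature banks
#'
#' @inheritParams predict_batch
#' @return n x M matrix of scores (rows sum to 1).
#' @export
score_batch <- function(model, banks) {
  stopifnot(inherits(model, "ensemble_model"))
  expansion_scores(model, standardize_for_model(model, banks))
}

#' Source weights of an ensemble
#'
#' @param model an `ensemble_model`.
#' @return named vector mapping source id to its group correlation weight.
#' @export
source_weights <- function(model) {
  stopifnot(inherits(model, "ensemble_model"))
  vapply(model$sources, function(s) s$group_rho, 0)
}

#' Remove a source from an ensemble
#'
#' Used for leave-one-source-out ablation: returns a model without the named
#' source; the remaining source models and the class prior are untouched.
#'
#' @param model an `ensemble_model` with at least 2 sources.
#' @param source_id id of the source to drop.
#' @return the reduced `ensemble_model`.
#' @export
drop_source <- function(model, source_id) {
  stopifnot(inherits(model, "ensemble_model"))
  if (!source_id %in% names(model$sources)) {
    stop(sprintf("unknown source id: %s", source_id))
  }
  if (length(model$sources) < 2) stop("cannot drop the last source")
  model$sources[[source_id]] <- NULL
  model$rho_star <- sum(source_weights(model))
  model
}

#' Save / load an ensemble model as JSON
#'
#' Persists priors, correlation-function tables, weights, standardizers, the
#' weighting mode and a config echo, under a format version.
#'
#' @param model an `ensemble_model`.
#' @param path JSON file path.
#' @return `load_ensemble()` returns the `ensemble_model`.
#' @export
save_ensemble <- function(model, path) {
  stopifnot(inherits(model, "ensemble_model"))
  obj <- list(
    format_version = 1L,
    mode = model$mode,
    class_labels = model$class_labels,
    class_prior = unname(model$class_prior),
    rho_star = model$rho_star,
    config = unclass(model$config),
    sources = lapply(model$sources, function(s) list(
      source_id = s$source_id,
      g_table = s$g_table,
      per_dim_rho = unname(s$per_dim_rho),
      group_rho = s$group_rho,
      degenerate_mask = unname(s$degenerate_mask),
      standardizer = list(center = unname(s$standardizer$center),
                          scale = unname(s$standardizer$scale),
                          degenerate_mask = unname(s$standardizer$degenerate_mask),
                          variance_floor = s$standardizer$variance_floor)
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported ensemble model format")
  }
  cfg <- do.call(mstl_config, obj$config[setdiff(names(obj$config), NULL)])
  class_labels <- as.character(obj$class_labels)
  sources <- lapply(obj$sources, function(s) {
    g <- as.matrix(s$g_table)
    dimnames(g) <- list(NULL, class_labels)
    structure(list(
      source_id = s$source_id,
      g_table = g,
      per_dim_rho = as.numeric(s$per_dim_rho),
      group_rho = s$group_rho,
      degenerate_mask = as.logical(s$degenerate_mask),
      standardizer = structure(
        list(center = as.numeric(s$standardizer$center),
             scale = as.numeric(s$standardizer$scale),
             degenerate_mask = as.logical(s$standardizer$degenerate_mask),
             variance_floor = s$standardizer$variance_floor),
        class = "standardizer"),
      class_labels = class_labels),
      class = "source_correlation_model")
  })
  names(sources) <- vapply(sources, function(s) s$source_id, "")
  structure(list(sources = sources,
                 class_prior = stats::setNames(as.numeric(obj$class_prior),
                                               class_labels),
                 class_labels = class_labels,
                 mode = obj$mode,
                 config = cfg,
                 rho_star = obj$rho_star),
            class = "ensemble_model")
}
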