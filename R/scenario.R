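#' Specification of a synthetic multi-source world
#'
#' Describes N source feature extractors of differing informativeness about M
#' balanced target classes. Source i produces d-dimensional features whose
#' class-conditional distribution is Gaussian with shared isotropic noise
#' `noise_sd` around class means separated by `separations[i]`; a separation
#' of 0 makes the source pure noise (a distractor carrying no label
#' information).
#'
#' @param n_sources number of sources N (>= 1).
#' @param n_classes number of target classes M (>= 2).
#' @param feature_dim feature dimension d per source (>= 1).
#' @param separations numeric vector of length N of class-mean separations
#'   (pairwise Euclidean distance between class means), all >= 0.
#' @param noise_sd within-class standard deviation sigma (> 0).
#' @param seed seed controlling the class-mean geometry.
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_sources, n_classes, feature_dim, separations,
                          noise_sd = 1, seed = 1L) {
  stopifnot(n_sources >= 1, n_classes >= 2, feature_dim >= 1,
            length(separations) == n_sources, all(separations >= 0),
            noise_sd > 0)
  structure(list(n_sources = as.integer(n_sources),
                 n_classes = as.integer(n_classes),
                 feature_dim = as.integer(feature_dim),
                 separations = as.numeric(separations),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Default synthetic study conditions
#'
#' Three informative sources of decreasing strength plus one pure-noise
#' distractor, six balanced classes, 64-dimensional features, unit noise:
#' the shape of a small multi-source emotion-recognition study (several
#' related source domains, one unrelated one, six expression classes).
#'
#' @param seed scenario seed.
#' @return a [scenario_spec()].
#' @export
default_scenario_spec <- function(seed = 1L) {
  scenario_spec(n_sources = 4L, n_classes = 6L, feature_dim = 64L,
                separations = c(2.0, 1.0, 0.5, 0.0), noise_sd = 1,
                seed = seed)
}

# Class means with all pairwise distances equal to delta.
# d >= M: centered orthonormal frame scaled by delta/sqrt(2).
# M == 2: antipodal pair +/- delta/2 along a random unit direction.
# otherwise: centered Gaussian rows rescaled so the mean pairwise distance
# is delta (exact equidistance is impossible when d < M - 1).
class_mean_matrix <- function(M, d, delta) {
  if (delta == 0) return(matrix(0, M, d))
  if (M == 2) {
    u <- stats::rnorm(d)
    u <- u / sqrt(sum(u^2))
    return(rbind(u, -u) * delta / 2)
  }
  if (d >= M) {
    Q <- qr.Q(qr(matrix(stats::rnorm(d * M), d, M)))  # d x M orthonormal cols
    U <- t(Q)                                         # M orthonormal rows
    U <- sweep(U, 2, colMeans(U))                     # center: preserves distances
    return(U * delta / sqrt(2))
  }
  U <- matrix(stats::rnorm(M * d), M, d)
  U <- sweep(U, 2, colMeans(U))
  dist_mean <- mean(stats::dist(U))
  U * delta / dist_mean
}

#' Materialize a synthetic scenario
#'
#' Deterministic in the spec's seed: regenerating from the same spec yields
#' identical class means. The ground-truth informativeness ranking orders the
#' sources by decreasing separation (ties broken by source index).
#'
#' @param spec a [scenario_spec()].
#' @return an object of class `scenario` with `spec`, `source_ids`, `means`
#'   (list of M x d matrices), `class_labels`, `ground_truth_ranking`.
#' @export
make_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  source_ids <- sprintf("source%02d", seq_len(spec$n_sources))
  class_labels <- sprintf("class%d", seq_len(spec$n_classes))
  means <- lapply(seq_len(spec$n_sources), function(i) {
    m <- class_mean_matrix(spec$n_classes, spec$feature_dim,
                           spec$separations[i])
    rownames(m) <- class_labels
    m
  })
  names(means) <- source_ids
  ranking <- source_ids[order(-spec$separations, seq_along(source_ids))]
  structure(list(spec = spec, source_ids = source_ids, means = means,
                 class_labels = class_labels,
                 ground_truth_ranking = ranking),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario: %d sources, %d classes, d = %d, sigma = %g\n",
              x$spec$n_sources, x$spec$n_classes, x$spec$feature_dim,
              x$spec$noise_sd))
  cat("  separations:", paste(x$spec$separations, collapse = ", "), "\n")
  invisible(x)
}

# Draw per-source feature banks for given labels (indices into class_labels).
draw_banks <- function(scenario, y_idx, sample_ids) {
  sigma <- scenario$spec$noise_sd
  d <- scenario$spec$feature_dim
  n <- length(y_idx)
  banks <- lapply(scenario$source_ids, function(id) {
    noise <- matrix(stats::rnorm(n * d, sd = sigma), n, d)
    feature_bank(id, sample_ids, scenario$means[[id]][y_idx, , drop = FALSE] + noise)
  })
  names(banks) <- scenario$source_ids
  banks
}

#' Draw a stratified few-shot training set from a scenario
#'
#' Draws k samples per class (balanced, stratified) and the corresponding
#' feature banks for every source: features are the source's class mean plus
#' isotropic Gaussian noise. Training and evaluation draws should use
#' independent seeds.
#'
#' @param scenario a [make_scenario()] scenario.
#' @param k shots per class (>= 1).
#' @param seed RNG seed for the draw.
#' @return list with `banks` (named list of [feature_bank()]) and `few_shot`
#'   (a [few_shot_set()]).
#' @export
sample_few_shot <- function(scenario, k, seed = 1L) {
  stopifnot(inherits(scenario, "scenario"), k >= 1)
  set.seed(seed)
  M <- scenario$spec$n_classes
  y_idx <- rep(seq_len(M), each = k)
  sample_ids <- sprintf("shot%04d", seq_along(y_idx))
  banks <- draw_banks(scenario, y_idx, sample_ids)
  fs <- few_shot_set(sample_ids, scenario$class_labels[y_idx],
                     scenario$class_labels)
  list(banks = banks, few_shot = fs)
}

#' Draw a balanced test split from a scenario
#'
#' @param scenario a [make_scenario()] scenario.
#' @param n_per_class test samples per class (default 10).
#' @param seed RNG seed (keep independent of the few-shot seed).
#' @return list with `banks` and `labels` (character vector).
#' @export
sample_test <- function(scenario, n_per_class = 10L, seed = 2L) {
  stopifnot(inherits(scenario, "scenario"), n_per_class >= 1)
  set.seed(seed)
  M <- scenario$spec$n_classes
  y_idx <- rep(seq_len(M), each = n_per_class)
  sample_ids <- sprintf("test%04d", seq_along(y_idx))
  banks <- draw_banks(scenario, y_idx, sample_ids)
  list(banks = banks, labels = scenario$class_labels[y_idx],
       sample_ids = sample_ids)
}

#' Procedural toy image classes
#'
#' Generates `n_per_class` grayscale images per class as oriented sinusoidal
#' gratings (class-specific orientation and frequency) plus pixel noise: a
#' cheap, fully synthetic stand-in for an image classification domain on
#' which stub source networks can be trained end to end.
#'
#' @param n_classes number of texture classes.
#' @param n_per_class images per class.
#' @param size image side length.
#' @param noise_sd pixel noise standard deviation.
#' @param seed RNG seed.
#' @return list with `images` (list of matrices), `labels`, `sample_ids`.
#' @export
toy_image_classes <- function(n_classes = 4L, n_per_class = 25L, size = 32L,
                              noise_sd = 0.3, seed = 1L) {
  set.seed(seed)
  angles <- pi * (seq_len(n_classes) - 1) / n_classes
  freqs <- 2 + 2 * ((seq_len(n_classes) - 1) %% 3)
  xs <- outer(rep(1, size), seq_len(size)) / size
  ys <- outer(seq_len(size), rep(1, size)) / size
  images <- list(); labels <- character()
  for (cl in seq_len(n_classes)) {
    base_dir <- c(cos(angles[cl]), sin(angles[cl]))
    for (i in seq_len(n_per_class)) {
      phase <- stats::runif(1, 0, 2 * pi)
      img <- sin(2 * pi * freqs[cl] * (xs * base_dir[1] + ys * base_dir[2]) + phase) +
        matrix(stats::rnorm(size^2, sd = noise_sd), size, size)
      images[[length(images) + 1L]] <- img
      labels <- c(labels, sprintf("tex%d", cl))
    }
  }
  ids <- sprintf("img%04d", seq_along(images))
  names(images) <- ids
  list(images = images, labels = labels, sample_ids = ids)
}

#' Seeded random-projection stub source
#'
#' A deterministic untrained source model: features are a fixed seeded
#' Gaussian random projection of the flattened image followed by tanh.
#'
#' @param id source id.
#' @param input_dim flattened input length.
#' @param feature_dim output feature dimension.
#' @param seed projection seed.
#' @return a [source_model()].
#' @export
stub_source <- function(id, input_dim, feature_dim = 16L, seed = 1L) {
  set.seed(seed)
  W <- matrix(stats::rnorm(feature_dim * input_dim, sd = 1 / sqrt(input_dim)),
              feature_dim, input_dim)
  source_model(id, feature_dim,
               feature_map = function(img) tanh(drop(W %*% as.numeric(img))),
               metadata = list(architecture = "random_projection", seed = seed))
}

#' Train tiny stub source networks on procedural image classes
#'
#' Trains, per requested source, a single-hidden-layer network on its own
#' toy texture domain and exposes the hidden-layer activations as the
#' penultimate features, satisfying the black-box [source_model()] contract.
#' If training fails to fit, the stub falls back to seeded random-projection
#' features with a warning.
#'
#' @param n_sources number of stub sources.
#' @param feature_dim hidden-layer width (= feature dimension).
#' @param n_classes,n_per_class,size toy domain shape per source.
#' @param seed base seed; source i uses `seed + i`.
#' @param maxit training iterations.
#' @return list of [source_model()]s with training accuracy in `metadata`.
#' @export
train_stub_sources <- function(n_sources = 2L, feature_dim = 16L,
                               n_classes = 4L, n_per_class = 25L,
                               size = 16L, seed = 1L, maxit = 100L) {
  lapply(seq_len(n_sources), function(i) {
    dom <- toy_image_classes(n_classes, n_per_class, size,
                             seed = seed + i)
    X <- t(vapply(dom$images, as.numeric, numeric(size^2)))
    yf <- factor(dom$labels)
    set.seed(seed + i)
    fit <- tryCatch(
      nnet::nnet(X, nnet::class.ind(yf), size = feature_dim,
                 softmax = TRUE, maxit = maxit, trace = FALSE,
                 MaxNWts = 100000),
      error = function(e) NULL)
    id <- sprintf("stub%02d", i)
    if (is.null(fit)) {
      warning(sprintf("stub source %s: training failed, falling back to random projection", id))
      return(stub_source(id, input_dim = size^2, feature_dim = feature_dim,
                         seed = seed + i))
    }
    train_acc <- mean(levels(yf)[max.col(stats::predict(fit, X))] == dom$labels)
    # penultimate features: hidden-layer activations
    w <- fit$wts
    n_in <- size^2
    n_hidden_wts <- (n_in + 1) * feature_dim
    Wh <- matrix(w[seq_len(n_hidden_wts)], n_in + 1, feature_dim)
    Wo <- matrix(w[-seq_len(n_hidden_wts)], feature_dim + 1, n_classes)
    feature_map <- function(img) {
      x <- c(1, as.numeric(img))
      if (length(x) != n_in + 1) {
        stop(sprintf("stub source %s expects %d pixels, got %d",
                     id, n_in, length(x) - 1))
      }
      1 / (1 + exp(-drop(x %*% Wh)))
    }
    head_fn <- function(feat) {
      z <- drop(c(1, feat) %*% Wo)
      exp(z - max(z)) / sum(exp(z - max(z)))
    }
    source_model(id, feature_dim, feature_map, head = head_fn,
                 metadata = list(architecture = "nnet_1hidden",
                                 train_accuracy = train_acc,
                                 n_source_classes = n_classes))
  })
}
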