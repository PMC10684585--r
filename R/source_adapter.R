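#' Black-box source model contract
#'
#' Wraps a pre-trained source classifier as an opaque feature extractor: the
#' only requirement downstream is `feature_map`, a function mapping one input
#' (e.g. a preprocessed image) to a numeric vector of length `feature_dim`
#' (by convention the penultimate-layer activations). The source's own
#' classification head may be stored but is never consulted: the target
#' classes may be disjoint from the source classes.
#'
#' @param id source identifier.
#' @param feature_dim output length of `feature_map`.
#' @param feature_map function: input -> numeric vector of length
#'   `feature_dim`.
#' @param head optional function: feature vector -> source-class scores.
#' @param metadata optional list (architecture tag, training notes).
#' @return an object of class `source_model`.
#' @export
source_model <- function(id, feature_dim, feature_map, head = NULL,
                         metadata = list()) {
  stopifnot(is.character(id), length(id) == 1,
            is.function(feature_map),
            feature_dim >= 1)
  structure(list(id = id, feature_dim = as.integer(feature_dim),
                 feature_map = feature_map, head = head,
                 metadata = metadata),
            class = "source_model")
}

#' Feature bank: one source's features on a set of target samples
#'
#' @param source_id id of the source model that produced the features.
#' @param sample_ids ordered character vector of sample identifiers.
#' @param values numeric n x d matrix, rows aligned with `sample_ids`.
#' @return an object of class `feature_bank`.
#' @export
feature_bank <- function(source_id, sample_ids, values) {
  values <- as.matrix(values)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(sample_ids)) {
    stop("row count must equal the number of sample ids")
  }
  if (length(values) > 0 && any(!is.finite(values))) {
    stop("feature bank values must all be finite")
  }
  rownames(values) <- sample_ids
  structure(list(source_id = as.character(source_id),
                 sample_ids = sample_ids, values = values),
            class = "feature_bank")
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("feature_bank '%s': %d samples x %d dims\n",
              x$source_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Extract features for an ordered collection of inputs
#'
#' Applies a source model's feature map to each input, preserving order.
#' Extraction is deterministic for a fixed model.
#'
#' @param model a [source_model()].
#' @param images list of preprocessed inputs (see [preprocess_image()]).
#' @param sample_ids optional ids; defaults to names of `images` or
#'   `s1, s2, ...`.
#' @return a [feature_bank()].
#' @export
extract_features <- function(model, images, sample_ids = NULL) {
  stopifnot(inherits(model, "source_model"))
  if (is.null(sample_ids)) {
    sample_ids <- names(images)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(images))
  }
  values <- matrix(0, length(images), model$feature_dim)
  for (i in seq_along(images)) {
    v <- model$feature_map(images[[i]])
    if (length(v) != model$feature_dim) {
      stop(sprintf("model '%s' returned %d features, expected %d",
                   model$id, length(v), model$feature_dim))
    }
    values[i, ] <- v
  }
  feature_bank(model$id, sample_ids, values)
}

# bilinear resize of a single-channel matrix to size x size
resize_bilinear <- function(m, size) {
  h <- nrow(m); w <- ncol(m)
  if (h == size && w == size) return(m)
  # map output pixel centers to input coordinates
  ry <- (seq_len(size) - 0.5) * h / size + 0.5
  rx <- (seq_len(size) - 0.5) * w / size + 0.5
  y0 <- pmin(pmax(floor(ry), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(rx), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  top <- m[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx) +
    m[y0, x1, drop = FALSE] * outer(1 - wy, wx)
  bot <- m[y1, x0, drop = FALSE] * outer(wy, 1 - wx) +
    m[y1, x1, drop = FALSE] * outer(wy, wx)
  top + bot
}

#' Preprocess a raw image for feature extraction
#'
#' Resizes to `size` x `size` (bilinear) and normalizes the pixel values of
#' each image to zero mean and unit variance. A variance floor protects
#' constant images, which map to all zeros.
#'
#' @param img numeric matrix (grayscale), numeric array with a channel
#'   dimension, or a path to a PNG file (requires the `png` package).
#' @param size output spatial size (default 32).
#' @param variance_floor variance below which the image is treated as
#'   constant.
#' @return numeric `size` x `size` matrix (multi-channel inputs are averaged
#'   to one channel before normalization).
#' @export
preprocess_image <- function(img, size = 32L, variance_floor = 1e-8) {
  if (is.character(img)) {
    if (!file.exists(img)) stop(sprintf("cannot read image: %s", img))
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading image files requires the 'png' package")
    }
    img <- tryCatch(png::readPNG(img),
                    error = function(e) stop(sprintf("undecodable image: %s", img)))
  }
  if (is.array(img) && length(dim(img)) == 3) {
    img <- apply(img, c(1, 2), mean)
  }
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("image must be a numeric matrix, array, or PNG path")
  }
  out <- resize_bilinear(img, as.integer(size))
  m <- mean(out)
  v <- mean((out - m)^2)
  if (v < variance_floor) {
    matrix(0, size, size)
  } else {
    (out - m) / sqrt(v)
  }
}

#' Load a class-per-directory image layout
#'
#' Reads `root/<class_name>/*.png`, preprocesses every image, and returns the
#' inputs together with their labels.
#'
#' @param root directory whose subdirectories name the classes.
#' @param size passed to [preprocess_image()].
#' @return list with `images` (named list), `labels` (character), and
#'   `sample_ids`.
#' @export
load_image_directory <- function(root, size = 32L) {
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop(sprintf("no class directories under %s", root))
  images <- list(); labels <- character(); ids <- character()
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl), pattern = "\\.png$",
                             full.names = TRUE))
    for (f in files) {
      id <- paste0(cl, "/", basename(f))
      images[[id]] <- preprocess_image(f, size = size)
      labels <- c(labels, cl)
      ids <- c(ids, id)
    }
  }
  list(images = images, labels = labels, sample_ids = ids)
}

#' Per-dimension standardizer fitted on a feature bank
#'
#' Computes per-dimension mean and scale (population variance, denominator
#' n) on a fitting bank so that applying the standardizer yields mean-0 /
#' variance-1 columns, matching the constraints the correlation transforms
#' must satisfy. Dimensions whose variance falls below `variance_floor` are
#' flagged degenerate and map to exactly 0; with k-shot fitting sets this is
#' common and must not produce infinities. Applying to new data reuses the
#' fitted statistics, so evaluation data never leaks into the normalization.
#'
#' @param bank a [feature_bank()] with at least 2 rows.
#' @param variance_floor degenerate-dimension threshold (default 1e-8).
#' @return an object of class `standardizer` with `center`, `scale`,
#'   `degenerate_mask`, `variance_floor`.
#' @export
fit_standardizer <- function(bank, variance_floor = 1e-8) {
  stopifnot(inherits(bank, "feature_bank"))
  n <- nrow(bank$values)
  if (n < 2) stop("standardizer fitting requires at least 2 samples")
  center <- colMeans(bank$values)
  v <- colMeans(sweep(bank$values, 2, center)^2)
  degenerate <- v < variance_floor
  scale <- sqrt(pmax(v, variance_floor))
  structure(list(center = center, scale = scale,
                 degenerate_mask = degenerate,
                 variance_floor = variance_floor),
            class = "standardizer")
}

#' @param std a `standardizer` from [fit_standardizer()].
#' @rdname fit_standardizer
#' @export
apply_standardizer <- function(std, bank) {
  stopifnot(inherits(std, "standardizer"), inherits(bank, "feature_bank"))
  if (ncol(bank$values) != length(std$center)) {
    stop("feature dimension does not match the standardizer")
  }
  z <- sweep(sweep(bank$values, 2, std$center), 2, std$scale, `/`)
  z[, std$degenerate_mask] <- 0
  feature_bank(bank$source_id, bank$sample_ids, z)
}

#' Few-shot labelled target set
#'
#' The handful of labelled target samples used for adaptation. Construction
#' enforces stratification: every declared class must appear at least once.
#'
#' @param sample_ids sample identifiers.
#' @param labels labels, one per sample.
#' @param class_labels declared class list; defaults to the sorted unique
#'   labels.
#' @return an object of class `few_shot_set` with an additional `k` field
#'   (shots per class) when the set is balanced.
#' @export
few_shot_set <- function(sample_ids, labels, class_labels = NULL) {
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  stopifnot(length(sample_ids) == length(labels), length(labels) > 0)
  if (is.null(class_labels)) class_labels <- sort(unique(labels))
  class_labels <- as.character(class_labels)
  unknown <- setdiff(labels, class_labels)
  if (length(unknown) > 0) {
    stop(sprintf("labels outside the declared class list: %s",
                 paste(unique(unknown), collapse = ", ")))
  }
  counts <- table(factor(labels, levels = class_labels))
  if (any(counts == 0)) {
    stop(sprintf("stratification violated; missing class(es): %s",
                 paste(class_labels[counts == 0], collapse = ", ")))
  }
  k <- if (length(unique(counts)) == 1) as.integer(counts[1]) else NA_integer_
  structure(list(sample_ids = sample_ids, labels = labels,
                 class_labels = class_labels, k = k),
            class = "few_shot_set")
}

#' Save / load a feature bank (TSV body + JSON sidecar)
#'
#' The TSV holds `sample_id` plus one column per feature dimension; the JSON
#' sidecar (`<path>.json`) records the source id, feature dimension, sample
#' count and an MD5 checksum of the TSV body. Loading verifies shape and
#' checksum, so silent corruption or a mismatched sidecar is rejected.
#'
#' @param bank a [feature_bank()].
#' @param path TSV file path.
#' @return `load_bank()` returns the [feature_bank()].
#' @export
save_bank <- function(bank, path) {
  stopifnot(inherits(bank, "feature_bank"))
  d <- ncol(bank$values)
  df <- data.frame(sample_id = bank$sample_ids, check.names = FALSE)
  if (d > 0) {
    vals <- as.data.frame(bank$values)
    names(vals) <- paste0("V", seq_len(d))
    df <- cbind(df, vals)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- list(source_id = bank$source_id,
                  feature_dim = d,
                  n_samples = nrow(bank$values),
                  checksum = unname(tools::md5sum(path)),
                  format_version = 1L)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_bank
#' @export
load_bank <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    stop(sprintf("missing bank file or sidecar for %s", path))
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  checksum <- unname(tools::md5sum(path))
  if (!identical(checksum, meta$checksum)) {
    stop(sprintf("checksum mismatch for %s", path))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(sample_id = "character"),
                          check.names = FALSE)
  values <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  if (nrow(df) == 0) values <- matrix(0, 0, meta$feature_dim)
  if (ncol(values) != meta$feature_dim || nrow(values) != meta$n_samples) {
    stop(sprintf("bank shape %dx%d does not match sidecar %dx%d for %s",
                 nrow(values), ncol(values), meta$n_samples,
                 meta$feature_dim, path))
  }
  feature_bank(meta$source_id, df$sample_id, values)
}
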