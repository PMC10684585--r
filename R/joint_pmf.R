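#' Discrete joint probability mass function
#'
#' Container for a finite joint distribution of two discrete variables.
#' All entries must be non-negative, the total mass must equal 1 (within
#' 1e-12), and every row and column marginal must be strictly positive:
#' categories that never occur carry no information about the association
#' and must be dropped by the caller before construction.
#'
#' @param probs numeric matrix of joint probabilities, rows indexing the
#'   categories of `X` and columns the categories of `Y`.
#' @param x_labels,y_labels optional category identifiers; defaults are taken
#'   from `dimnames(probs)` or generated as `x1, x2, ...` / `y1, y2, ...`.
#' @return an object of class `joint_pmf` with elements `probs`, `x_labels`,
#'   `y_labels`, `x_marginal`, `y_marginal`.
#' @examples
#' pmf <- joint_pmf(matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2))
#' pmf$x_marginal
#' @export
joint_pmf <- function(probs, x_labels = NULL, y_labels = NULL) {
  probs <- as.matrix(probs)
  if (!is.numeric(probs) || any(!is.finite(probs))) {
    stop("joint pmf entries must be finite numbers")
  }
  if (any(probs < 0)) stop("joint pmf entries must be non-negative")
  if (abs(sum(probs) - 1) > 1e-12) {
    stop(sprintf("joint pmf mass is %.15g, not 1", sum(probs)))
  }
  if (is.null(x_labels)) {
    x_labels <- rownames(probs)
    if (is.null(x_labels)) x_labels <- paste0("x", seq_len(nrow(probs)))
  }
  if (is.null(y_labels)) {
    y_labels <- colnames(probs)
    if (is.null(y_labels)) y_labels <- paste0("y", seq_len(ncol(probs)))
  }
  x_labels <- as.character(x_labels)
  y_labels <- as.character(y_labels)
  stopifnot(length(x_labels) == nrow(probs), length(y_labels) == ncol(probs))

  px <- rowSums(probs)
  py <- colSums(probs)
  if (any(px <= 0)) {
    stop(sprintf("degenerate x category with zero marginal: %s",
                 paste(x_labels[px <= 0], collapse = ", ")))
  }
  if (any(py <= 0)) {
    stop(sprintf("degenerate y category with zero marginal: %s",
                 paste(y_labels[py <= 0], collapse = ", ")))
  }
  dimnames(probs) <- list(x_labels, y_labels)
  structure(
    list(probs = probs, x_labels = x_labels, y_labels = y_labels,
         x_marginal = stats::setNames(px, x_labels),
         y_marginal = stats::setNames(py, y_labels)),
    class = "joint_pmf"
  )
}

#' Build a joint pmf from paired discrete samples
#'
#' Tabulates the empirical joint distribution of two equal-length discrete
#' sample vectors. Categories never observed are dropped (they would create
#' zero marginals).
#'
#' @param x,y discrete sample vectors of equal length.
#' @return a [joint_pmf()].
#' @export
empirical_joint_pmf <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  tab <- table(factor(x), factor(y))
  probs <- as.matrix(tab) / length(x)
  keep_x <- rowSums(probs) > 0
  keep_y <- colSums(probs) > 0
  joint_pmf(probs[keep_x, keep_y, drop = FALSE])
}

#' @export
print.joint_pmf <- function(x, ...) {
  cat(sprintf("joint_pmf: %d x %d categories\n",
              nrow(x$probs), ncol(x$probs)))
  print(x$probs, ...)
  invisible(x)
}

#' Scaled joint probability matrix
#'
#' Returns the matrix with entries `P(x, y) / sqrt(P_X(x) * P_Y(y))`. Its
#' largest singular value is always 1 (attained by the constant transforms),
#' and its second singular value is the maximal correlation of the pair.
#'
#' @param pmf a [joint_pmf()].
#' @return a numeric matrix with the same dimnames as `pmf$probs`.
#' @export
scaled_pmf_matrix <- function(pmf) {
  stopifnot(inherits(pmf, "joint_pmf"))
  pmf$probs / sqrt(outer(pmf$x_marginal, pmf$y_marginal))
}

#' Maximal correlation of a discrete pair via SVD
#'
#' Computes the Hirschfeld-Gebelein-Renyi maximal correlation of a discrete
#' joint distribution as the second largest singular value of the scaled
#' joint probability matrix, together with the full spectral decomposition.
#' The singular vectors divided elementwise by the square root of the
#' corresponding marginal give the optimal transforms: each non-trivial pair
#' `(f_i, g_i)` has mean 0 and variance 1 under its marginal, and the leading
#' pair is the constant function 1 with singular value 1.
#'
#' @param pmf a [joint_pmf()].
#' @return a list with `rho` (the maximal correlation, in `[0, 1]`) and
#'   `decomposition`, a `spectral_decomposition` object holding
#'   `singular_values` (descending), `f_functions` and `g_functions`
#'   (categories in rows, components in columns), and the two marginals.
#'   A 1xK or Kx1 pmf has no non-trivial component and returns `rho = 0`.
#' @examples
#' maximal_correlation_svd(joint_pmf(matrix(c(0.4, 0.1, 0.1, 0.4), 2)))$rho
#' @export
maximal_correlation_svd <- function(pmf) {
  stopifnot(inherits(pmf, "joint_pmf"))
  B <- scaled_pmf_matrix(pmf)
  sv <- svd(B)
  d <- sv$d
  # Convert singular vectors to transforms satisfying the mean-0/variance-1
  # constraints; fix signs so the largest-|entry| coordinate of f is positive.
  f <- sv$u / sqrt(pmf$x_marginal)
  g <- sv$v / sqrt(pmf$y_marginal)
  for (i in seq_along(d)) {
    pivot <- which.max(abs(f[, i]))
    if (f[pivot, i] < 0) {
      f[, i] <- -f[, i]
      g[, i] <- -g[, i]
    }
  }
  # The trivial component is constant 1 by construction; force exactness.
  f[, 1] <- 1
  g[, 1] <- 1
  d[1] <- 1
  rownames(f) <- pmf$x_labels
  rownames(g) <- pmf$y_labels
  colnames(f) <- colnames(g) <- paste0("c", seq_along(d))
  dec <- structure(
    list(singular_values = d, f_functions = f, g_functions = g,
         x_marginal = pmf$x_marginal, y_marginal = pmf$y_marginal),
    class = "spectral_decomposition"
  )
  rho <- if (length(d) >= 2) min(max(d[2], 0), 1) else 0
  list(rho = rho, decomposition = dec)
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat("spectral_decomposition\n  singular values:",
      paste(signif(x$singular_values, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct a conditional distribution from a spectral decomposition
#'
#' Builds `P(y | x) = P_Y(y) * (1 + sum_i rho_i f_i(x) g_i(y))`, summing over
#' the first `truncation` non-trivial correlation components. With all
#' components the reconstruction equals the exact Bayes conditional; at any
#' truncation the rows still sum to 1 because every non-trivial `g_i` has
#' mean 0 under `P_Y`.
#'
#' @param decomposition a `spectral_decomposition` from
#'   [maximal_correlation_svd()].
#' @param y_marginal marginal distribution of `Y` (must match the
#'   decomposition's categories).
#' @param truncation number of non-trivial components to keep, or `"all"`.
#' @return matrix of conditional probabilities, rows = x categories.
#' @export
conditional_from_decomposition <- function(decomposition, y_marginal,
                                           truncation = "all") {
  stopifnot(inherits(decomposition, "spectral_decomposition"))
  n_comp <- length(decomposition$singular_values) - 1L  # non-trivial count
  if (identical(truncation, "all")) truncation <- n_comp
  truncation <- as.integer(truncation)
  if (truncation < 0 || truncation > n_comp) {
    stop(sprintf("truncation %d outside available components [0, %d]",
                 truncation, n_comp))
  }
  if (length(y_marginal) != nrow(decomposition$g_functions)) {
    stop("y_marginal length does not match the decomposition")
  }
  f <- decomposition$f_functions
  g <- decomposition$g_functions
  rho <- decomposition$singular_values
  expansion <- matrix(1, nrow(f), nrow(g))
  if (truncation > 0) {
    idx <- seq(2L, 1L + truncation)
    expansion <- expansion +
      f[, idx, drop = FALSE] %*% (rho[idx] * t(g[, idx, drop = FALSE]))
  }
  cond <- sweep(expansion, 2, y_marginal, `*`)
  dimnames(cond) <- list(rownames(f), rownames(g))
  cond
}

#' Read / write a joint pmf as a CSV matrix
#'
#' The CSV carries y category labels in the header row and x category labels
#' in the first column.
#'
#' @param path file path.
#' @return [read_joint_pmf()] returns a [joint_pmf()].
#' @export
read_joint_pmf <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  joint_pmf(as.matrix(df))
}

#' @param pmf a [joint_pmf()].
#' @rdname read_joint_pmf
#' @export
write_joint_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "joint_pmf"))
  utils::write.csv(as.data.frame(pmf$probs), path, row.names = TRUE)
  invisible(path)
}
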