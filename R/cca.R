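#' Regularized canonical correlation analysis with permutation test
#'
#' Canonical correlations between two multivariate blocks via the standard
#' whitened cross-covariance SVD, with ridge regularization of both block
#' covariances (lambda = `ridge` times the covariance trace) for stability on
#' small samples. Significance per canonical pair is assessed by a
#' row-permutation null of the second block.
#'
#' @param x,y numeric matrices with one row per case (same case count).
#'   Columns are standardized internally.
#' @param n_permutations number of label permutations for p-values (0 skips
#'   the test).
#' @param seed integer seed for the permutation draw.
#' @param ridge ridge fraction of the covariance trace; 0 disables
#'   regularization (an error is raised if a block covariance is singular).
#' @return a `cca_result`: `canonical_correlations` (descending, in \[0,1\]),
#'   `x_loadings`, `y_loadings`, `p_values` (or `NULL`).
#' @export
cca <- function(x, y, n_permutations = 0, seed = 1, ridge = 1e-6) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("`x` and `y` must have the same case count", call. = FALSE)
  n <- nrow(x)
  if (n < ncol(x) + 2 || n < ncol(y) + 2)
    stop("need at least features + 2 cases per block", call. = FALSE)
  xs <- scale(x); ys <- scale(y)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  ys[, attr(ys, "scaled:scale") == 0] <- 0
  core <- function(xs, ys) {
    Cxx <- stats::cov(xs); Cyy <- stats::cov(ys)
    Cxy <- stats::cov(xs, ys)
    if (ridge > 0) {
      Cxx <- Cxx + ridge * sum(diag(Cxx)) * diag(ncol(xs))
      Cyy <- Cyy + ridge * sum(diag(Cyy)) * diag(ncol(ys))
    }
    isqrt <- function(C) {
      e <- eigen(C, symmetric = TRUE)
      if (min(e$values) < 1e-12 * max(e$values))
        stop("singular block covariance: increase `ridge` to regularize",
             call. = FALSE)
      e$vectors %*% diag(1 / sqrt(e$values), nrow = ncol(C)) %*% t(e$vectors)
    }
    Wx <- isqrt(Cxx); Wy <- isqrt(Cyy)
    sv <- svd(Wx %*% Cxy %*% Wy)
    k <- min(ncol(xs), ncol(ys))
    list(r = pmin(sv$d[seq_len(k)], 1),
         a = Wx %*% sv$u[, seq_len(k), drop = FALSE],
         b = Wy %*% sv$v[, seq_len(k), drop = FALSE])
  }
  obs <- core(xs, ys)
  p <- NULL
  if (n_permutations > 0) {
    exceed <- numeric(length(obs$r))
    with_seed(seed, {
      for (b in seq_len(n_permutations)) {
        rp <- core(xs, ys[sample.int(n), , drop = FALSE])$r
        exceed <- exceed + (rp >= obs$r)
      }
    })
    p <- (1 + exceed) / (n_permutations + 1)
  }
  structure(list(canonical_correlations = obs$r, x_loadings = obs$a,
                 y_loadings = obs$b, p_values = p,
                 n = n, n_permutations = n_permutations),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("cca_result: r =", paste(sprintf("%.3f", x$canonical_correlations),
                               collapse = ", "), "\n")
  if (!is.null(x$p_values))
    cat("  permutation p =", paste(sprintf("%.3g", x$p_values), collapse = ", "), "\n")
  invisible(x)
}
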