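# Canonical correlation analysis between the CSF block (X) and the selected
# peripheral block (Y), with the sequential Wilks/Rao test chain, loadings,
# cross-loadings and redundancy indices.

# Symmetric inverse square root of a correlation matrix; errors naming the
# collinear columns when rank-deficient (optional tiny ridge on request).
inv_sqrt_corr <- function(R, cols, ridge = 0, tol = 1e-10) {
  if (ridge > 0) {
    R <- R + diag(ridge, nrow(R))
    inform(sprintf("applied ridge %g to a correlation matrix", ridge))
  }
  e <- eigen(R, symmetric = TRUE)
  if (any(e$values < tol)) {
    small <- e$values < tol
    involved <- cols[apply(abs(e$vectors[, small, drop = FALSE]) > 0.1, 1, any)]
    abort(sprintf("block is rank deficient (collinear columns involve: %s); consider `ridge`",
                  paste(involved, collapse = ", ")))
  }
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Fit a canonical correlation analysis between two variable blocks
#'
#' Standardizes both blocks (mean 0, unit variance, n-1 denominator) and
#' extracts the canonical structure from the singular value decomposition of
#' the whitened cross-correlation matrix
#' `R_xx^{-1/2} R_xy R_yy^{-1/2}` -- numerically stable and equivalent to
#' the classical generalized eigenproblem. Coefficients are scaled so each
#' canonical variate has unit variance; within each canonical function the
#' coefficient pair is sign-flipped together (preserving
#' `cor(U_k, V_k) = +r_k`) so that the x-block variable with the
#' largest-magnitude loading loads positively.
#'
#' The maximum number of canonical functions is `s = min(p, q)`. The
#' sequential test of functions `k..s` uses Wilks' lambda
#' `Lambda_k = prod_{i>=k} (1 - r_i^2)` with Rao's F approximation
#' (see [rao_f()]).
#'
#' @param x Samples x p block (tibble with `sample_id`, data frame, or
#'   matrix) -- the CSF biomarkers in the motivating analysis.
#' @param y Samples x q block -- the selected peripheral variables.
#' @param ridge Optional ridge (e.g. `1e-8`) added to the within-block
#'   correlation matrices when a block is numerically collinear; default 0
#'   (rank deficiency is an error).
#' @return A `cca_fit` object: list with `correlations` (length s,
#'   descending), `eigenvalues` (`r^2/(1-r^2)`), `x_coefficients`,
#'   `y_coefficients` (standardized, columns = functions), `x_loadings`,
#'   `y_loadings`, `x_cross_loadings`, `y_cross_loadings`, `wilks` (tibble:
#'   `function_`, `correlation`, `eigenvalue`, `lambda`, `statistic`, `df1`,
#'   `df2`, `p.value`), `redundancy` (tibble per function and block),
#'   `scores` (list of U and V variate matrices), `n`, `p`, `q`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3)
#' y <- matrix(rnorm(80), 20, 4)
#' fit <- cca_fit(x, y)
#' tidy(fit)
#' @export
cca_fit <- function(x, y, ridge = 0) {
  xm <- as_block_matrix(x, "x")
  ym <- as_block_matrix(y, "y")
  if (nrow(xm) != nrow(ym)) abort("`x` and `y` must have the same samples")
  if (!is.null(rownames(xm)) && !is.null(rownames(ym)) &&
      !identical(rownames(xm), rownames(ym))) {
    abort("`x` and `y` sample orders differ")
  }
  n <- nrow(xm); p <- ncol(xm); q <- ncol(ym)
  if (n <= p + q) abort(sprintf("need n > p + q (n = %d, p = %d, q = %d)", n, p, q))
  if (any(apply(xm, 2, sd) == 0) || any(apply(ym, 2, sd) == 0)) {
    abort("constant columns are not allowed; drop them before fitting")
  }
  xs <- scale(xm); ys <- scale(ym)
  x_names <- colnames(xm) %||% paste0("X", seq_len(p))
  y_names <- colnames(ym) %||% paste0("Y", seq_len(q))
  Rxx <- crossprod(xs) / (n - 1)
  Ryy <- crossprod(ys) / (n - 1)
  Rxy <- crossprod(xs, ys) / (n - 1)
  Wx <- inv_sqrt_corr(Rxx, x_names, ridge)
  Wy <- inv_sqrt_corr(Ryy, y_names, ridge)
  sv <- svd(Wx %*% Rxy %*% Wy)
  s <- min(p, q)
  r <- pmin(pmax(sv$d[seq_len(s)], 0), 1)
  A <- Wx %*% sv$u[, seq_len(s), drop = FALSE]
  B <- Wy %*% sv$v[, seq_len(s), drop = FALSE]
  x_load <- Rxx %*% A
  # sign convention: flip each function so the x variable with the largest
  # |loading| has a positive loading; flip a and b together
  flip <- vapply(seq_len(s), function(k) {
    sign(x_load[which.max(abs(x_load[, k])), k])
  }, numeric(1))
  flip[flip == 0] <- 1
  A <- sweep(A, 2, flip, `*`)
  B <- sweep(B, 2, flip, `*`)
  x_load <- Rxx %*% A
  y_load <- Ryy %*% B
  x_cross <- sweep(x_load, 2, r, `*`)
  y_cross <- sweep(y_load, 2, r, `*`)
  fn <- paste0("F", seq_len(s))
  dimnames(A) <- list(x_names, fn); dimnames(B) <- list(y_names, fn)
  dimnames(x_load) <- dimnames(x_cross) <- list(x_names, fn)
  dimnames(y_load) <- dimnames(y_cross) <- list(y_names, fn)
  wilks <- purrr::map_dfr(seq_len(s), function(k) {
    lam <- wilks_lambda(r, k)
    dplyr::bind_cols(tibble(function_ = k, correlation = r[k],
                            eigenvalue = cca_eigenvalue(r[k]), lambda = lam),
                     rao_f(lam, p, q, n, k))
  })
  redundancy <- purrr::map_dfr(seq_len(s), function(k) {
    tibble(function_ = k,
           x_redundancy = r[k]^2 * mean(x_load[, k]^2),
           y_redundancy = r[k]^2 * mean(y_load[, k]^2))
  })
  scores <- list(U = xs %*% A, V = ys %*% B)
  structure(list(correlations = r, eigenvalues = cca_eigenvalue(r),
                 x_coefficients = A, y_coefficients = B,
                 x_loadings = x_load, y_loadings = y_load,
                 x_cross_loadings = x_cross, y_cross_loadings = y_cross,
                 wilks = wilks, redundancy = redundancy, scores = scores,
                 n = n, p = p, q = q),
            class = "cca_fit")
}

#' Wilks' lambda for canonical functions k..s
#'
#' `Lambda_k = prod_{i=k}^{s} (1 - r_i^2)`: the unexplained variance share
#' tested by the hypothesis that canonical functions k and beyond are null.
#'
#' @param correlations Vector of canonical correlations (descending).
#' @param k Index of the first function included, `1 <= k <= s`.
#' @return Wilks' lambda in (0, 1\].
#' @export
wilks_lambda <- function(correlations, k = 1) {
  s <- length(correlations)
  if (k < 1 || k > s) abort("`k` out of range")
  prod(1 - correlations[k:s]^2)
}

#' Canonical eigenvalue from a canonical correlation
#'
#' `lambda = r^2 / (1 - r^2)`, the eigenvalue of the canonical root.
#'
#' @param r Canonical correlation(s) in \[0, 1).
#' @return Eigenvalue(s); errors at `r = 1`.
#' @export
cca_eigenvalue <- function(r) {
  if (any(r < 0 | r > 1)) abort("`r` must lie in [0, 1)")
  if (any(r == 1)) abort("eigenvalue infinite at r = 1")
  r^2 / (1 - r^2)
}

#' Rao's F approximation for a sequential Wilks test
#'
#' For the test of canonical functions `k..s` with effective dimensions
#' `p_k = p - k + 1`, `q_k = q - k + 1`:
#' `t = sqrt((p_k^2 q_k^2 - 4) / (p_k^2 + q_k^2 - 5))` (t = 1 when the
#' denominator is <= 0 or `p_k q_k = 2`), `df1 = p_k q_k`,
#' `df2 = t * ((n-1) - (p_k + q_k + 1)/2) - df1/2 + 1`, and
#' `F = ((1 - Lambda^{1/t}) / Lambda^{1/t}) * (df2 / df1)`. For
#' `p = q = 1` this reduces exactly to the squared Pearson t statistic on
#' F(1, n-2).
#'
#' @param lambda Wilks' lambda in (0, 1\].
#' @param p,q Block dimensions.
#' @param n Sample count.
#' @param k Function index (sequential test starts at function k).
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p.value`.
#' @export
rao_f <- function(lambda, p, q, n, k = 1) {
  if (lambda <= 0 || lambda > 1) abort("`lambda` must be in (0, 1]")
  pk <- p - k + 1; qk <- q - k + 1
  if (pk < 1 || qk < 1) abort("`k` exceeds the number of canonical functions")
  den <- pk^2 + qk^2 - 5
  t_exp <- if (den <= 0 || pk * qk == 2) 1 else sqrt((pk^2 * qk^2 - 4) / den)
  df1 <- pk * qk
  df2 <- t_exp * ((n - 1) - (pk + qk + 1) / 2) - df1 / 2 + 1
  if (df2 <= 0) abort(sprintf("df2 = %.2f <= 0: n too small for this test", df2))
  lam_t <- lambda^(1 / t_exp)
  f_stat <- ((1 - lam_t) / lam_t) * (df2 / df1)
  tibble(statistic = f_stat, df1 = df1, df2 = df2,
         p.value = pf(f_stat, df1, df2, lower.tail = FALSE))
}

#' Canonical loadings of a fitted model
#'
#' Correlation of each original (standardized) variable with its own
#' block's canonical variates; equals `R_xx %*% A` by the standard identity.
#'
#' @param model A `cca_fit`.
#' @param block `"x"` or `"y"`.
#' @return Variables x functions matrix of loadings in \[-1, 1\].
#' @export
cca_loadings <- function(model, block = c("x", "y")) {
  block <- match.arg(block)
  model[[paste0(block, "_loadings")]]
}

#' Canonical cross-loadings of a fitted model
#'
#' Correlation of each original variable with the *opposite* block's
#' variates; identically `r_k` times the own-block loading.
#'
#' @inheritParams cca_loadings
#' @return Variables x functions matrix of cross-loadings.
#' @export
cca_cross_loadings <- function(model, block = c("x", "y")) {
  block <- match.arg(block)
  model[[paste0(block, "_cross_loadings")]]
}

#' Redundancy index per canonical function
#'
#' Share of a block's total variance explained by the opposite block's
#' variate: `RI_k = r_k^2 * mean(loading_k^2)`, equivalently the mean
#' squared cross-loading.
#'
#' @inheritParams cca_loadings
#' @param k Optional function index; all functions when `NULL`.
#' @return Numeric vector of redundancy indices in \[0, 1\].
#' @export
cca_redundancy <- function(model, block = c("x", "y"), k = NULL) {
  block <- match.arg(block)
  ri <- model$redundancy[[paste0(block, "_redundancy")]]
  if (is.null(k)) ri else ri[k]
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("<cca_fit> n = %d, p = %d, q = %d\n", x$n, x$p, x$q))
  print(as.data.frame(x$wilks), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-function summary of a canonical correlation fit
#'
#' One row per canonical function: correlation, eigenvalue, Wilks' lambda,
#' Rao's F with degrees of freedom and p-value, and both redundancy indices.
#'
#' @param x A `cca_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cca_fit <- function(x, ...) {
  dplyr::left_join(x$wilks, x$redundancy, by = "function_")
}

#' @export
glance.cca_fit <- function(x, ...) {
  tibble(n = x$n, p = x$p, q = x$q,
         first_correlation = x$correlations[1],
         first_p.value = x$wilks$p.value[1],
         n_significant = sum(x$wilks$p.value < 0.05))
}

#' Bar chart of canonical correlations
#'
#' @param object A `cca_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cca_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$function_),
                                  y = .data$correlation,
                                  fill = .data$p.value < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
                               name = "p < 0.05") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Canonical function", y = "Canonical correlation")
}
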