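# Single-marker ROC analysis and logistic combination of markers.

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Probability that a randomly chosen case scores above a randomly chosen
#' control, with ties credited one half -- computed from the rank-sum form
#' of the Mann-Whitney U statistic.
#'
#' @param scores Numeric vector of marker values (higher = more case-like
#'   as given; see `orientation` of [roc_curve()]).
#' @param labels Binary labels (case = 1, control = 0), tibble
#'   (`sample_id`, `diagnosis`) or vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)) # 0.75
#' @export
roc_auc <- function(scores, labels) {
  lab <- as_label_vector(labels)
  if (length(scores) != length(lab)) abort("`scores` and `labels` lengths differ")
  if (anyNA(scores)) abort("missing scores not allowed")
  n1 <- as.numeric(sum(lab == 1)); n0 <- as.numeric(sum(lab == 0))
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  rk <- rank(scores)
  (sum(rk[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve by threshold sweep
#'
#' Sweeps thresholds over the unique score values (predict case when
#' `score >= t`), yielding a staircase from (0, 0) to (1, 1) whose
#' trapezoidal area equals the Mann-Whitney AUC to machine precision (tied
#' scores produce single diagonal segments).
#'
#' @inheritParams roc_auc
#' @return A `roc_result`: list with `curve` (tibble `threshold`, `fpr`,
#'   `tpr`), `auc`, `auc_oriented` (`max(auc, 1 - auc)`, the
#'   direction-corrected value) and `orientation` (`"as_given"`).
#' @export
roc_curve <- function(scores, labels) {
  lab <- as_label_vector(labels)
  a <- roc_auc(scores, lab)
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & lab == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & lab == 0) / n0, numeric(1))
  curve <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(curve = curve, auc = a, auc_oriented = max(a, 1 - a),
                 orientation = "as_given",
                 n_case = n1, n_control = n0),
            class = "roc_result")
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (oriented %.3f), %d case / %d control\n",
              x$auc, x$auc_oriented, x$n_case, x$n_control))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, auc_oriented = x$auc_oriented,
         n_case = x$n_case, n_control = x$n_control)
}

#' ROC curve plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc))
}

#' Logistic regression of diagnosis on marker features
#'
#' Maximum-likelihood binomial fit (iteratively reweighted least squares via
#' [stats::glm()], convergence tolerance 1e-8, at most 100 iterations), with
#' per-coefficient Wald z statistics and two-sided p-values. Perfect
#' separation (vanishing residual deviance / diverging coefficients) and
#' non-convergence are errors; aliased collinear features are kept with a
#' zero coefficient and a warning.
#'
#' @param features Samples x markers block: tibble (optionally with
#'   `sample_id`), data frame, or matrix; `n > m + 1`.
#' @param labels Binary labels (case = 1, control = 0).
#' @param tol IRLS convergence tolerance on the deviance.
#' @param max_iter Maximum IRLS iterations.
#' @return A `marker_logit`: list with `coefficients` (tibble `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`), `fitted`
#'   (case probabilities), `converged`, `iterations`, `deviance`, `fit`
#'   (the underlying `glm` object).
#' @export
logistic_fit <- function(features, labels, tol = 1e-8, max_iter = 100) {
  fm <- as_block_matrix(features, "features")
  lab <- as_label_vector(labels)
  if (nrow(fm) != length(lab)) abort("`features` and `labels` sizes differ")
  if (nrow(fm) <= ncol(fm) + 1) abort("need n > m + 1 samples")
  if (is.null(colnames(fm))) colnames(fm) <- paste0("marker", seq_len(ncol(fm)))
  df <- data.frame(.y = lab, fm, check.names = FALSE)
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial(),
        control = glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  fv <- fitted(fit)
  separated <- fit$deviance < 1e-6 ||
    (max(fv[lab == 0]) < 1e-8 && min(fv[lab == 1]) > 1 - 1e-8)
  if (separated) {
    abort(paste0("perfect separation detected: a linear combination of the ",
                 "markers splits cases from controls exactly, so maximum-",
                 "likelihood coefficients diverge"))
  }
  if (!fit$converged) abort("logistic regression did not converge")
  cf <- coef(fit)
  if (anyNA(cf)) {
    warn(sprintf("collinear marker(s) aliased (coefficient set to 0): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  coefs <- tibble(
    term = names(cf),
    estimate = unname(ifelse(is.na(cf), 0, cf)),
    std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
  )
  idx <- match(rownames(sm), coefs$term)
  coefs$std.error[idx] <- sm[, "Std. Error"]
  coefs$statistic[idx] <- sm[, "z value"]
  coefs$p.value[idx] <- sm[, "Pr(>|z|)"]
  structure(list(coefficients = coefs, fitted = as.numeric(fv),
                 converged = fit$converged, iterations = fit$iter,
                 deviance = fit$deviance, null_deviance = fit$null.deviance,
                 aic = fit$aic, fit = fit),
            class = "marker_logit")
}

#' @export
print.marker_logit <- function(x, ...) {
  cat(sprintf("<marker_logit> %d coefficient(s), deviance %.3f, %d IRLS iteration(s)\n",
              nrow(x$coefficients), x$deviance, x$iterations))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.marker_logit <- function(x, ...) x$coefficients

#' @export
glance.marker_logit <- function(x, ...) {
  tibble(deviance = x$deviance, null.deviance = x$null_deviance,
         AIC = x$aic, iterations = x$iterations, converged = x$converged)
}

#' Combined-marker diagnosis: logistic score plus its ROC curve
#'
#' Fits a logistic regression on all supplied markers, checks that every
#' marker coefficient meets the Wald significance threshold (warning
#' listing the violators -- the inclusion rule of the motivating analysis,
#' p < 0.1), and evaluates the ROC of the fitted case probabilities.
#'
#' @inheritParams logistic_fit
#' @param p_threshold Wald p-value each marker coefficient must beat;
#'   default 0.1.
#' @return A `combined_roc`: list with `model` (`marker_logit`), `roc`
#'   (`roc_result` on the fitted probabilities) and `p_threshold`.
#' @export
combined_roc <- function(features, labels, p_threshold = 0.1) {
  model <- logistic_fit(features, labels)
  cf <- model$coefficients[model$coefficients$term != "(Intercept)", ]
  bad <- cf$term[is.na(cf$p.value) | cf$p.value >= p_threshold]
  if (length(bad)) {
    warn(sprintf("marker coefficient(s) not significant at p < %g: %s",
                 p_threshold, paste(bad, collapse = ", ")))
  }
  roc <- roc_curve(model$fitted, labels)
  structure(list(model = model, roc = roc, p_threshold = p_threshold),
            class = "combined_roc")
}

#' @export
print.combined_roc <- function(x, ...) {
  cat(sprintf("<combined_roc> combined AUC = %.3f (coefficient rule p < %g)\n",
              x$roc$auc, x$p_threshold))
  print(x$model)
  invisible(x)
}

#' @export
tidy.combined_roc <- function(x, ...) tidy(x$model)

#' @export
glance.combined_roc <- function(x, ...) {
  dplyr::bind_cols(glance(x$roc), glance(x$model)[, c("deviance", "converged")])
}
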