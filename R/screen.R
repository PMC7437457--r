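# Pearson screening of peripheral variables against CSF biomarkers.

#' Sample Pearson correlation with validity checks
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; neither constant.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need n >= 3 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) abort("Pearson correlation undefined for a constant vector")
  cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact small-sample t transform: `t = r * sqrt((n-2)/(1-r^2))`
#' referred to a t distribution with `n - 2` degrees of freedom,
#' `p = 2 P(T > |t|)`. With CSF/peripheral screening at n = 36 this
#' reproduces, e.g., p = 0.014 for r = -0.408.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\] (vectorized).
#' @param n Sample size, `n >= 3`.
#' @return Two-sided p-value(s); exactly 0 when `|r| = 1`.
#' @export
pearson_p <- function(r, n) {
  if (any(abs(r) > 1)) abort("|r| cannot exceed 1")
  if (n < 3) abort("need n >= 3")
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t_stat <- abs(r[ok]) * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(t_stat, df = n - 2, lower.tail = FALSE)
  p
}

#' Screen peripheral variables against CSF biomarkers
#'
#' Computes the full Pearson r and p matrix between every peripheral
#' variable and every CSF variable, and selects the peripheral variables
#' with at least one correlation significant at `alpha`. No multiple-testing
#' correction is applied by default (each pair is judged at raw alpha, as in
#' the motivating analysis); `adjust = "BH"` switches selection to
#' Benjamini-Hochberg adjusted p-values across all pairs.
#'
#' Constant variables, for which the correlation is undefined, get `NA`
#' rows/columns and are excluded from selection with a warning.
#'
#' @param peripheral Samples x variables block: tibble with `sample_id` (as
#'   in a `csf_cohort`), plain data frame, or numeric matrix. The ES rows of
#'   an [score_cohort()] abundance matrix can be supplied via
#'   [assemble_peripheral()].
#' @param csf CSF block in the same sample order.
#' @param alpha Per-pair significance level in (0, 1); default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `marker_screen` object with elements `r` and `p`
#'   (peripheral x CSF matrices), `p_adjusted` (when adjusting), `selected`
#'   (character vector), `alpha`, `n`.
#' @export
screen_markers <- function(peripheral, csf, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  pm <- as_block_matrix(peripheral, "peripheral")
  cm <- as_block_matrix(csf, "csf")
  if (nrow(pm) != nrow(cm)) abort("peripheral and CSF blocks must share samples")
  if (!is.null(rownames(pm)) && !is.null(rownames(cm)) &&
      !identical(rownames(pm), rownames(cm))) {
    abort("peripheral and CSF blocks are not aligned on the same sample order")
  }
  n <- nrow(pm)
  if (n < 3) abort("need n >= 3 samples")
  const_p <- apply(pm, 2, sd) == 0
  const_c <- apply(cm, 2, sd) == 0
  if (any(const_p) || any(const_c)) {
    warn(sprintf("constant variable(s) excluded from selection: %s",
                 paste(c(colnames(pm)[const_p], colnames(cm)[const_c]),
                       collapse = ", ")))
  }
  r <- suppressWarnings(cor(pm, cm))
  r[const_p, ] <- NA_real_
  r[, const_c] <- NA_real_
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  p[!is.na(r)] <- pearson_p(r[!is.na(r)], n)
  p_adj <- NULL
  p_sel <- p
  if (adjust == "BH") {
    p_adj <- p
    p_adj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
    p_sel <- p_adj
  }
  hit <- !is.na(p_sel) & p_sel < alpha
  selected <- rownames(r)[rowSums(hit) > 0]
  structure(list(r = r, p = p, p_adjusted = p_adj, selected = selected,
                 alpha = alpha, adjust = adjust, n = n),
            class = "marker_screen")
}

#' @export
print.marker_screen <- function(x, ...) {
  cat(sprintf("<marker_screen> %d peripheral x %d CSF variables, n = %d, alpha = %g%s\n",
              nrow(x$r), ncol(x$r), x$n, x$alpha,
              if (x$adjust == "BH") " (BH-adjusted)" else ""))
  cat(sprintf("  selected (%d): %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Tidy a marker screen into one row per variable pair
#'
#' @param x A `marker_screen`.
#' @param ... Unused.
#' @return Tibble with `peripheral`, `csf`, `estimate`, `p.value`
#'   (plus `p.adjusted` if computed) and `significant`.
#' @export
tidy.marker_screen <- function(x, ...) {
  out <- tibble(
    peripheral = rep(rownames(x$r), times = ncol(x$r)),
    csf = rep(colnames(x$r), each = nrow(x$r)),
    estimate = as.vector(x$r),
    p.value = as.vector(x$p)
  )
  p_sel <- if (!is.null(x$p_adjusted)) x$p_adjusted else x$p
  if (!is.null(x$p_adjusted)) out$p.adjusted <- as.vector(x$p_adjusted)
  out$significant <- !is.na(as.vector(p_sel)) & as.vector(p_sel) < x$alpha
  out
}

#' @export
glance.marker_screen <- function(x, ...) {
  tibble(n = x$n, n_peripheral = nrow(x$r), n_csf = ncol(x$r),
         alpha = x$alpha, adjust = x$adjust, n_selected = length(x$selected))
}

#' Heatmap of the screening correlation matrix
#'
#' Tiles of Pearson r with significant pairs starred.
#'
#' @param object A `marker_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.marker_screen <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$csf, y = .data$peripheral,
                                  fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$significant, "*", "")),
                       size = 5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Pearson r") +
    ggplot2::labs(x = "CSF biomarker", y = "Peripheral variable")
}

#' Assemble the full peripheral block (immune-cell ES + plasma markers)
#'
#' Binds the transposed abundance matrix (samples x cell types) to the
#' plasma biomarker columns of a cohort, giving the samples x variables
#' peripheral block used for screening and canonical correlation.
#'
#' @param abundance An `abundance_matrix` from [score_cohort()].
#' @param peripheral Plasma biomarker tibble with `sample_id` (e.g.
#'   `cohort$peripheral`); optional.
#' @return Tibble with `sample_id` followed by one column per cell type and
#'   per plasma marker.
#' @export
assemble_peripheral <- function(abundance, peripheral = NULL) {
  es_t <- t(unclass(abundance))
  out <- tibble(sample_id = rownames(es_t))
  out <- dplyr::bind_cols(out, as_tibble(es_t))
  if (!is.null(peripheral)) {
    if (!identical(out$sample_id, peripheral$sample_id)) {
      abort("abundance samples and peripheral samples are not aligned")
    }
    out <- dplyr::bind_cols(out, peripheral[setdiff(names(peripheral), "sample_id")])
  }
  out
}
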