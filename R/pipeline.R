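# End-to-end orchestration: abundance scoring -> Pearson screening ->
# canonical correlation -> ROC / logistic combination, with optional
# plain-text artifact export.

#' Run the full peripheral-to-CSF association pipeline
#'
#' Stages, in order: (1) per-sample ES abundance scoring of the immune-cell
#' signatures; (2) assembly of the peripheral block (cell-type ES plus
#' plasma markers) and Pearson screening against the CSF block at
#' `screen_alpha`; (3) canonical correlation analysis of the CSF block
#' against the selected peripheral variables, with the sequential
#' Wilks/Rao tests, loadings, cross-loadings and redundancy indices;
#' (4) single-marker ROC for every peripheral variable whose absolute
#' loading on the first or second peripheral variate reaches
#' `loading_threshold`, plus the logistic-combined ROC of those markers.
#'
#' @param cohort A `csf_cohort` (e.g. from [harmonize_cohort()] or
#'   [simulate_cohort()]).
#' @param gene_sets Named list of signature gene sets (see [read_gmt()]).
#' @param gsea_weight ES exponent for [score_cohort()]; default 0.25.
#' @param screen_alpha Significance level of the Pearson screen.
#' @param loading_threshold Minimum `|loading|` on V1 or V2 for a
#'   peripheral variable to enter the ROC stage; default 0.29.
#' @param roc_markers Optional explicit character vector of ROC markers,
#'   overriding the loading rule.
#' @param p_threshold Wald inclusion threshold for the combined logistic
#'   model; default 0.1.
#' @param outdir Optional directory: when given, each stage's tables are
#'   written as TSV plus a JSON summary.
#' @return A `csf_pipeline_report`: list with `abundance`, `screen`, `cca`,
#'   `roc` (tibble of per-marker AUCs), `combined` (`combined_roc` or NULL),
#'   `roc_markers`, `config`.
#' @export
run_pipeline <- function(cohort, gene_sets, gsea_weight = 0.25,
                         screen_alpha = 0.05, loading_threshold = 0.29,
                         roc_markers = NULL, p_threshold = 0.1,
                         outdir = NULL) {
  stopifnot(inherits(cohort, "csf_cohort"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  abundance <- stage("score", score_cohort(cohort, gene_sets, weight = gsea_weight))
  peripheral <- assemble_peripheral(abundance, cohort$peripheral)
  screen <- stage("screen",
                  screen_markers(peripheral, cohort$csf, alpha = screen_alpha))
  if (!length(screen$selected)) {
    abort("pipeline stage 'screen': no peripheral variable passed the screen")
  }
  y_block <- peripheral[c("sample_id", screen$selected)]
  cca <- stage("cca", cca_fit(cohort$csf, y_block))
  if (is.null(roc_markers)) {
    yl <- cca$y_loadings
    top <- seq_len(min(2, ncol(yl)))
    roc_markers <- rownames(yl)[apply(abs(yl[, top, drop = FALSE]) >=
                                        loading_threshold, 1, any)]
  }
  if (!length(roc_markers)) {
    warn("no marker reached the loading threshold; skipping the ROC stage")
    roc_tab <- tibble(marker = character(), auc = numeric(),
                      auc_oriented = numeric())
    combined <- NULL
  } else {
    roc_tab <- purrr::map_dfr(roc_markers, function(m) {
      rr <- roc_curve(peripheral[[m]], cohort$labels)
      tibble(marker = m, auc = rr$auc, auc_oriented = rr$auc_oriented)
    })
    combined <- if (length(roc_markers) >= 2) {
      stage("roc", combined_roc(peripheral[c("sample_id", roc_markers)],
                                cohort$labels, p_threshold = p_threshold))
    } else NULL
  }
  report <- structure(
    list(abundance = abundance, screen = screen, cca = cca,
         roc = roc_tab, combined = combined, roc_markers = roc_markers,
         config = list(gsea_weight = gsea_weight, screen_alpha = screen_alpha,
                       loading_threshold = loading_threshold,
                       p_threshold = p_threshold,
                       version = as.character(utils::packageVersion("csflink")))),
    class = "csf_pipeline_report")
  if (!is.null(outdir)) write_pipeline_artifacts(report, outdir)
  report
}

write_tsv_file <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

write_pipeline_artifacts <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(tidy(report$abundance), file.path(outdir, "abundance.tsv"))
  write_tsv_file(tidy(report$screen), file.path(outdir, "screen.tsv"))
  write_tsv_file(tidy(report$cca), file.path(outdir, "cca_summary.tsv"))
  for (nm in c("x_coefficients", "y_coefficients", "x_loadings", "y_loadings",
               "x_cross_loadings", "y_cross_loadings")) {
    m <- report$cca[[nm]]
    write_tsv_file(data.frame(variable = rownames(m), m, check.names = FALSE),
                   file.path(outdir, paste0("cca_", nm, ".tsv")))
  }
  write_tsv_file(report$roc, file.path(outdir, "roc_auc.tsv"))
  if (!is.null(report$combined)) {
    write_tsv_file(tidy(report$combined$roc), file.path(outdir, "roc_combined_curve.tsv"))
    write_tsv_file(tidy(report$combined$model), file.path(outdir, "logistic_coefficients.tsv"))
  }
  jsonlite::write_json(
    list(config = report$config,
         selected = report$screen$selected,
         roc_markers = report$roc_markers,
         canonical_correlations = report$cca$correlations,
         combined_auc = if (!is.null(report$combined)) report$combined$roc$auc),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.csf_pipeline_report <- function(x, ...) {
  cat("<csf_pipeline_report>\n")
  cat(sprintf("  abundance: %d cell type(s) scored (ES weight = %g)\n",
              nrow(x$abundance), x$config$gsea_weight))
  cat(sprintf("  screen: %d variable(s) selected at alpha = %g: %s\n",
              length(x$screen$selected), x$config$screen_alpha,
              paste(x$screen$selected, collapse = ", ")))
  cat(sprintf("  cca: canonical correlations %s\n",
              paste(sprintf("%.3f", x$cca$correlations), collapse = ", ")))
  if (nrow(x$roc)) {
    cat(sprintf("  roc: %s\n",
                paste(sprintf("%s = %.3f", x$roc$marker, x$roc$auc),
                      collapse = ", ")))
  }
  if (!is.null(x$combined)) {
    cat(sprintf("  combined AUC = %.3f\n", x$combined$roc$auc))
  }
  invisible(x)
}

#' Export ranked gene lists for downstream differential-expression tools
#'
#' Writes the full two-class (case vs control) signal-to-noise ranking, one
#' gene per line with its statistic, plus the subset overlapping any
#' supplied signature -- inputs for external DEG / network / enrichment
#' tools, which this package deliberately does not reimplement.
#'
#' @param cohort A `csf_cohort`.
#' @param dir Output directory.
#' @param gene_sets Optional named list of signatures for the overlap file.
#' @return Named character vector of written file paths, invisibly.
#' @export
export_gene_lists <- function(cohort, dir, gene_sets = NULL) {
  stopifnot(inherits(cohort, "csf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ranked <- rank_two_class(cohort$expression, cohort$labels)
  paths <- c(ranked = file.path(dir, "ranked_genes.tsv"))
  write_tsv_file(ranked, paths[["ranked"]])
  if (!is.null(gene_sets)) {
    sig_genes <- unique(unlist(gene_sets))
    overlap <- ranked[ranked$gene_id %in% sig_genes, ]
    if (!nrow(overlap)) {
      warn("no expression gene overlaps the supplied signatures")
    }
    paths[["overlap"]] <- file.path(dir, "signature_overlap.tsv")
    write_tsv_file(overlap, paths[["overlap"]])
  }
  invisible(paths)
}
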