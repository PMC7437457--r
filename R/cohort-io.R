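#' Read a genes-by-samples expression matrix from TSV
#'
#' Reads a tab-separated expression table with genes in rows (first column =
#' gene identifiers, remaining columns = one sample each; the header row
#' carries a corner label followed by the sample identifiers). Values are
#' assumed to be already normalized on a log scale upstream -- the reader
#' does no transformation.
#'
#' Duplicate gene identifiers (e.g. multiple probes mapping to one gene) are
#' collapsed by their mean, with a message reporting how many were merged.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes x samples) with gene IDs as rownames and
#'   sample IDs as colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tS1\tS2", "G1\t1.5\t2.0", "G2\t0.3\t0.1"), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, fill = FALSE,
                   colClasses = "character", comment.char = "")
  if (ncol(df) < 2) abort("expression file needs a gene column plus >= 1 sample column")
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("duplicate sample IDs in header: %s",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  vals <- matrix(NA_real_, nrow(df), length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1]]) & df[[j + 1]] != "NA")
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at data line %d, sample %s",
                    df[[j + 1]][bad[1]], bad[1], sample_ids[j]))
    }
    vals[, j] <- v
  }
  check_finite_matrix(vals, "expression matrix")
  if (anyDuplicated(gene_ids)) {
    n_dup <- sum(duplicated(gene_ids))
    collapsed <- rowsum(vals, group = gene_ids, reorder = FALSE)
    counts <- as.vector(table(factor(gene_ids, levels = rownames(collapsed))))
    vals <- collapsed / counts
    inform(sprintf("collapsed %d duplicate gene ID(s) by mean", n_dup))
  } else {
    rownames(vals) <- gene_ids
  }
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: genes in rows, a `gene_id` corner label,
#' full-precision values, UTF-8, LF line endings.
#'
#' @param expression Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expression)), collapse = "\t"),
             con, sep = "\n")
  body <- apply(expression, 1, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(expression), body, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read gene-set signatures from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene1 TAB ...`.
#' Genes repeated within a line are kept once. Lines with fewer than three
#' fields, duplicate set names, and effectively empty sets are rejected.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (set name -> gene IDs),
#'   preserving file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("GMT file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("GMT parse error: line %d has %d field(s), need >= 3",
                  which(nf < 3)[1], nf[which(nf < 3)[1]]))
  }
  set_names <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(set_names)) {
    abort(sprintf("duplicate gene-set name(s): %s",
                  paste(unique(set_names[duplicated(set_names)]), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    abort(sprintf("GMT set '%s' (line %d) has no genes",
                  set_names[which(empty)[1]], which(empty)[1]))
  }
  setNames(sets, set_names)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional vector of per-set descriptions (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  description <- rep_len(description, length(gene_sets))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(gene_sets)) {
    writeLines(paste(c(names(gene_sets)[i], description[i], gene_sets[[i]]),
                     collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a biomarker table from CSV
#'
#' Expects a `sample_id` column plus one numeric column per biomarker
#' variable. Missing cells are allowed here; they are removed later by
#' listwise deletion in [harmonize_cohort()].
#'
#' @param path Path to a CSV file.
#' @return A tibble with a `sample_id` character column first.
#' @export
read_biomarkers <- function(path) {
  if (!file.exists(path)) abort(sprintf("biomarker file not found: %s", path))
  df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                   fill = FALSE, quote = "\"", comment.char = "")
  if (!"sample_id" %in% names(df)) abort("biomarker CSV must have a `sample_id` column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) abort("duplicate sample IDs in biomarker CSV")
  vars <- setdiff(names(df), "sample_id")
  if (anyDuplicated(vars)) abort("duplicate variable names in biomarker CSV")
  for (v in vars) {
    if (!is.numeric(df[[v]])) {
      abort(sprintf("biomarker column `%s` is not numeric", v))
    }
  }
  as_tibble(df[c("sample_id", vars)])
}

#' Write a biomarker tibble to CSV
#'
#' @param block Tibble with `sample_id` plus numeric columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biomarkers <- function(block, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(block, con, sep = ",", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Harmonize expression, CSF, peripheral and label tables into one cohort
#'
#' Restricts all four sources to the samples present in every one of them,
#' drops any sample with a missing biomarker cell (listwise deletion -- no
#' imputation), and reorders everything to a single canonical sample order
#' (lexicographic sort of sample IDs). Counts of dropped samples are
#' reported via a message.
#'
#' @param expression Genes x samples numeric matrix (see [read_expression()]).
#' @param csf Tibble of CSF biomarkers with `sample_id` (ABETA, TAU, PTAU in
#'   the motivating study).
#' @param peripheral Tibble of peripheral/plasma biomarkers with `sample_id`.
#' @param labels Tibble (`sample_id`, `diagnosis`) or named 0/1 vector;
#'   case = 1, control = 0.
#' @return A `csf_cohort` object: list with `expression`, `csf`,
#'   `peripheral`, `labels` (tibble), all in identical sample order.
#' @export
harmonize_cohort <- function(expression, csf, peripheral, labels) {
  stopifnot(is.matrix(expression))
  lab <- as_label_vector(labels)
  if (is.null(names(lab))) abort("labels must carry sample IDs")
  ids <- list(colnames(expression), csf$sample_id, peripheral$sample_id, names(lab))
  if (any(lengths(ids) == 0)) abort("all inputs must be nonempty")
  common <- Reduce(intersect, ids)
  if (!length(common)) abort("no common samples across expression, CSF, peripheral and labels")
  csf_m <- as_block_matrix(csf, "csf")[common, , drop = FALSE]
  per_m <- as_block_matrix(peripheral, "peripheral")[common, , drop = FALSE]
  complete <- !(rowSums(is.na(csf_m)) > 0 | rowSums(is.na(per_m)) > 0)
  kept <- sort(common[complete])
  if (!length(kept)) abort("no common samples remain after removing missing data")
  n_total <- length(unique(unlist(ids)))
  inform(sprintf(
    "harmonized cohort: %d sample(s) kept; %d dropped outside the three-way intersection; %d dropped for missing biomarker data",
    length(kept), n_total - length(common), sum(!complete)))
  new_cohort(
    expression = expression[, kept, drop = FALSE],
    csf = csf[match(kept, csf$sample_id), , drop = FALSE],
    peripheral = peripheral[match(kept, peripheral$sample_id), , drop = FALSE],
    labels = tibble(sample_id = kept, diagnosis = as.numeric(lab[kept]))
  )
}

new_cohort <- function(expression, csf, peripheral, labels,
                       class = character()) {
  out <- structure(
    list(expression = expression, csf = as_tibble(csf),
         peripheral = as_tibble(peripheral), labels = as_tibble(labels)),
    class = c(class, "csf_cohort"))
  validate_cohort(out)
}

validate_cohort <- function(x) {
  ids <- colnames(x$expression)
  if (!identical(ids, x$csf$sample_id) ||
      !identical(ids, x$peripheral$sample_id) ||
      !identical(ids, x$labels$sample_id)) {
    abort("cohort components disagree on sample IDs/order")
  }
  check_finite_matrix(x$expression, "cohort expression")
  if (anyNA(as_block_matrix(x$csf, "csf")) ||
      anyNA(as_block_matrix(x$peripheral, "peripheral"))) {
    abort("cohort biomarker blocks must have no missing values")
  }
  x
}

#' @export
print.csf_cohort <- function(x, ...) {
  lab <- x$labels$diagnosis
  cat(sprintf("<csf_cohort> %d samples (%d case / %d control)\n",
              length(lab), sum(lab == 1), sum(lab == 0)))
  cat(sprintf("  expression: %d genes\n", nrow(x$expression)))
  cat(sprintf("  CSF block: %s\n",
              paste(setdiff(names(x$csf), "sample_id"), collapse = ", ")))
  cat(sprintf("  peripheral block: %s\n",
              paste(setdiff(names(x$peripheral), "sample_id"), collapse = ", ")))
  invisible(x)
}

#' Write a full cohort input bundle to a directory
#'
#' Writes `expression.tsv`, `csf.csv`, `peripheral.csv`, `labels.csv` and,
#' when available (synthetic cohorts), `signatures.gmt` and `truth.json`,
#' so the whole pipeline can be re-run from plain-text files.
#'
#' @param cohort A `csf_cohort`.
#' @param dir Output directory (created if needed).
#' @param gene_sets Optional named list of signatures to write as GMT.
#' @return The directory path, invisibly.
#' @export
write_cohort_bundle <- function(cohort, dir, gene_sets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_biomarkers(cohort$csf, file.path(dir, "csf.csv"))
  write_biomarkers(cohort$peripheral, file.path(dir, "peripheral.csv"))
  write_biomarkers(cohort$labels, file.path(dir, "labels.csv"))
  if (is.null(gene_sets) && !is.null(cohort$truth)) {
    gene_sets <- cohort$truth$signatures
  }
  if (!is.null(gene_sets)) write_gmt(gene_sets, file.path(dir, "signatures.gmt"))
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(rho = tr$rho, delta = tr$delta, cell_delta = tr$cell_delta,
           shifted_marker = tr$shifted_marker, shifted_cell = tr$shifted_cell),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
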