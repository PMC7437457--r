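# Internal helpers shared across modules.

# Run `code` under a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so no global random state leaks out of the package.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Coerce a samples-x-variables block (tibble with sample_id, data.frame or
# matrix) to a numeric matrix with sample IDs as rownames.
as_block_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (!is.numeric(x)) abort(sprintf("`%s` must be a numeric matrix", arg))
    return(x)
  }
  if (is.data.frame(x)) {
    x <- as.data.frame(x)
    if ("sample_id" %in% names(x)) {
      rn <- as.character(x$sample_id)
      x <- x[setdiff(names(x), "sample_id")]
      m <- as.matrix(x)
      rownames(m) <- rn
    } else {
      m <- as.matrix(x)
    }
    if (!is.numeric(m)) {
      bad <- names(x)[!vapply(x, is.numeric, logical(1))]
      abort(sprintf("`%s` has non-numeric variable(s): %s",
                    arg, paste(bad, collapse = ", ")))
    }
    return(m)
  }
  abort(sprintf("`%s` must be a matrix or data frame", arg))
}

# Named vector of 0/1 diagnosis labels from a tibble (sample_id, diagnosis),
# a named vector, or a bare vector.
as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "diagnosis") %in% names(labels))) {
      abort("label table must have columns `sample_id` and `diagnosis`")
    }
    out <- setNames(as.numeric(labels$diagnosis), as.character(labels$sample_id))
  } else {
    out <- as.numeric(labels)
    names(out) <- names(labels)
  }
  if (anyNA(out) || !all(out %in% c(0, 1))) {
    abort("diagnosis labels must be binary (case = 1, control = 0)")
  }
  out
}

check_finite_matrix <- function(m, what) {
  if (!all(is.finite(m))) {
    abort(sprintf("%s contains non-finite values", what))
  }
  invisible(m)
}
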