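# Classed conditions so callers (and the shell wrapper) can map failures to
# exit codes: validation problems vs I/O problems.
stop_validation <- function(msg, class = NULL) {
  abort(msg, class = c(class, "microlens_validation_error", "microlens_error"))
}

stop_io <- function(msg) {
  abort(msg, class = c("microlens_io_error", "microlens_error"))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_validation(sprintf("`%s` must be a single integer >= %d, got %s.",
                            name, min, deparse(x)))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_validation(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    stop_validation(sprintf("`%s` = %g violates the required range %s%g, %g%s.",
                            name, x,
                            if (strict_min) "(" else "[", min, max,
                            if (strict_max) ")" else "]"))
  }
  as.numeric(x)
}

# Expression tibble contract: first column `gene` (unique character symbols),
# remaining columns numeric, non-negative sample values.
check_expression_tbl <- function(data, arg = "data", allow_one_sample = TRUE) {
  if (!is.data.frame(data) || ncol(data) < 2L) {
    stop_validation(sprintf(
      "`%s` must be a data frame with a `gene` column and >=1 sample column.", arg))
  }
  if (names(data)[1] != "gene") {
    stop_validation(sprintf("first column of `%s` must be named `gene`.", arg))
  }
  genes <- data[["gene"]]
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop_validation(sprintf("duplicate gene symbols in `%s`: %s.",
                            arg, paste(utils::head(dup, 5), collapse = ", ")))
  }
  vals <- data[-1]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    stop_validation(sprintf("all sample columns of `%s` must be numeric.", arg))
  }
  if (any(vapply(vals, function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    stop_validation(sprintf("`%s` contains negative expression values.", arg))
  }
  invisible(data)
}

expr_to_matrix <- function(data) {
  m <- as.matrix(data[-1])
  rownames(m) <- data[["gene"]]
  storage.mode(m) <- "double"
  m
}

matrix_to_expr <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene = rownames(m)), out)
}

sample_names <- function(data) names(data)[-1]

# Deterministic order statistic used everywhere a top-k cut is taken:
# decreasing value, ties broken by lexicographic gene symbol.
top_k_genes <- function(values, genes, k) {
  ord <- order(-values, genes, method = "radix")
  genes[ord[seq_len(k)]]
}
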