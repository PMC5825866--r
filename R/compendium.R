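#' Normalise a count matrix to reads per million
#'
#' Scales each sample column by `10^6 / column total`, so every column sums to
#' one million. This library-size normalisation makes expression levels
#' comparable across samples sequenced to different depths.
#'
#' @param data Expression tibble (`gene` column plus numeric sample columns)
#'   of raw read counts.
#' @return Expression tibble of RPM values; every sample column sums to 1e6.
#' @export
#' @examples
#' counts <- tibble::tibble(gene = c("a", "b", "c"), s1 = c(1, 1, 2))
#' normalise_rpm(counts)
normalise_rpm <- function(data) {
  check_expression_tbl(data)
  totals <- colSums(expr_to_matrix(data))
  if (any(totals == 0)) {
    stop_validation(sprintf("sample(s) with zero total counts: %s.",
                            paste(names(totals)[totals == 0], collapse = ", ")),
                    class = "microlens_degenerate_sample_error")
  }
  out <- data
  for (s in sample_names(data)) out[[s]] <- data[[s]] * 1e6 / totals[[s]]
  attr(out, "unit") <- "rpm"
  out
}

#' Average replicate samples into per-group profiles
#'
#' Collapses replicate columns to one column per group by the arithmetic mean
#' of each gene's values, as done when a compendium tissue has more than one
#' replicate library.
#'
#' @param data Expression tibble.
#' @param groups Named character vector mapping every sample label to its
#'   group label.
#' @return Expression tibble with one column per group, in first-appearance
#'   order of the groups.
#' @export
#' @examples
#' x <- tibble::tibble(gene = c("a", "b"), r1 = c(0, 2), r2 = c(10, 4))
#' average_replicates(x, c(r1 = "t1", r2 = "t1"))
average_replicates <- function(data, groups) {
  check_expression_tbl(data)
  samples <- sample_names(data)
  missing <- setdiff(samples, names(groups))
  if (length(missing) > 0) {
    stop_validation(sprintf("sample(s) not assigned to any group: %s.",
                            paste(missing, collapse = ", ")),
                    class = "microlens_mapping_error")
  }
  grp <- groups[samples]
  out <- tibble(gene = data$gene)
  for (g in unique(grp)) {
    members <- samples[grp == g]
    out[[g]] <- rowMeans(data[members])
  }
  out
}

#' Restrict a set of expression matrices to their common gene universe
#'
#' Keeps only gene symbols present in every matrix and returns all matrices
#' with rows in canonical (lexicographic) gene order, so downstream top-k
#' ranking and tie-breaking are well defined across datasets.
#'
#' @param matrices List of expression tibbles.
#' @return List of expression tibbles sharing an identical, lexicographically
#'   ordered `gene` column.
#' @export
harmonise_universe <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1L) {
    stop_validation("`matrices` must be a non-empty list of expression tibbles.")
  }
  purrr::walk(matrices, check_expression_tbl)
  common <- Reduce(intersect, lapply(matrices, function(m) m$gene))
  if (length(common) == 0) {
    stop_validation("gene universes have an empty intersection.",
                    class = "microlens_incompatibility_error")
  }
  common <- sort(common, method = "radix")
  lapply(matrices, function(m) {
    m[match(common, m$gene), , drop = FALSE]
  })
}

#' Discretise expression profiles to top-k binary indicators
#'
#' For each sample, sets the k most highly expressed genes to 1 and all others
#' to 0. This batch-robust binarisation discards between-dataset scale
#' differences while keeping each profile's high-expression identity. Ties at
#' the k-th value are broken by lexicographic gene symbol so the result is
#' deterministic.
#'
#' @param data Expression tibble.
#' @param k Number of genes set to 1 per sample (default 1000).
#' @return Binary expression tibble (`gene` plus 0/1 integer sample columns);
#'   every sample column sums exactly to `k`.
#' @export
#' @examples
#' x <- tibble::tibble(gene = c("a", "b", "c", "d"), s = c(5, 3, 1, 0))
#' discretise_top_k(x, 2)
discretise_top_k <- function(data, k = 1000) {
  check_expression_tbl(data)
  k <- check_count(k, "k")
  if (k > nrow(data)) {
    stop_validation(sprintf("k = %d exceeds the number of genes (%d).", k, nrow(data)),
                    class = "microlens_parameter_error")
  }
  out <- tibble(gene = data$gene)
  for (s in sample_names(data)) {
    top <- top_k_genes(data[[s]], data$gene, k)
    out[[s]] <- as.integer(data$gene %in% top)
  }
  out
}

check_binary_tbl <- function(bits, arg = "bits") {
  check_expression_tbl(bits, arg)
  vals <- as.matrix(bits[-1])
  if (!all(vals %in% c(0, 1))) {
    stop_validation(sprintf("`%s` must contain only 0/1 values.", arg))
  }
  invisible(bits)
}

#' Remove ubiquitously expressed genes from binary profiles
#'
#' Returns the genes whose expression indicator is 1 in at most
#' `max_frac` of the samples; genes on in strictly more than that fraction
#' (default: more than 20% of the datasets) are dropped before dissimilarity
#' computation, since ubiquitous genes carry no identity information.
#'
#' @param bits Binary expression tibble from [discretise_top_k()].
#' @param max_frac Maximum tolerated fraction of samples expressing the gene;
#'   removal is strict (`> max_frac`), so a gene at exactly the boundary is
#'   retained.
#' @return Character vector of retained gene symbols, in the input row order.
#' @export
ubiquity_filter <- function(bits, max_frac = 0.20) {
  check_binary_tbl(bits)
  check_number(max_frac, "max_frac", min = 0, max = 1)
  m <- as.matrix(bits[-1])
  frac <- rowSums(m) / ncol(m)
  bits$gene[frac <= max_frac]
}

#' Build a compendium of tissue-specific marker gene sets
#'
#' For each tissue, takes its `top_m` most highly expressed genes and keeps
#' only those that are highly expressed (i.e. in the top-`top_m` list) in at
#' most a fraction `spec_frac` of all tissues. The default parameters — top
#' 3000 genes, specific to 5% or fewer tissues — yield per-tissue marker sets
#' that are both highly expressed and rare among other tissues' high
#' expressors.
#'
#' @param data Expression tibble of replicate-averaged per-tissue profiles
#'   (>= 2 tissues).
#' @param top_m Number of top-expressed genes considered per tissue.
#' @param spec_frac Maximum fraction of tissues allowed to have a marker in
#'   their top-`top_m` list (inclusive boundary: "5% or fewer").
#' @return An object of class `marker_compendium`: list with `tissues`,
#'   `marker_sets` (named list of character vectors, sorted), `gene_universe`,
#'   `gene_top_counts` (how many tissues' top lists each gene is in), `top_m`
#'   and `spec_frac`.
#' @seealso [query_marker_set()], [fisher_enrichment()]
#' @export
build_marker_sets <- function(data, top_m = 3000, spec_frac = 0.05) {
  check_expression_tbl(data)
  top_m <- check_count(top_m, "top_m")
  check_number(spec_frac, "spec_frac", min = 0, max = 1)
  tissues <- sample_names(data)
  if (length(tissues) < 2L) {
    stop_validation("marker specificity is undefined for a single tissue.",
                    class = "microlens_specificity_error")
  }
  if (top_m > nrow(data)) {
    stop_validation(sprintf("top_m = %d exceeds the number of genes (%d).",
                            top_m, nrow(data)),
                    class = "microlens_parameter_error")
  }
  top_lists <- lapply(tissues, function(t) top_k_genes(data[[t]], data$gene, top_m))
  names(top_lists) <- tissues
  counts <- table(unlist(top_lists, use.names = FALSE))
  gene_top_counts <- setNames(rep(0L, nrow(data)), data$gene)
  gene_top_counts[names(counts)] <- as.integer(counts)
  specific <- names(gene_top_counts)[gene_top_counts / length(tissues) <= spec_frac]
  marker_sets <- lapply(top_lists, function(g) sort(intersect(g, specific), method = "radix"))

  structure(
    list(
      tissues = tissues,
      marker_sets = marker_sets,
      gene_universe = sort(data$gene, method = "radix"),
      gene_top_counts = gene_top_counts,
      top_m = top_m,
      spec_frac = spec_frac
    ),
    class = "marker_compendium"
  )
}

#' @export
print.marker_compendium <- function(x, ...) {
  cat(sprintf("<marker_compendium> %d tissues, %d-gene universe (top_m = %d, spec_frac = %g)\n",
              length(x$tissues), length(x$gene_universe), x$top_m, x$spec_frac))
  sizes <- lengths(x$marker_sets)
  cat(sprintf("  marker set sizes: min %d, median %g, max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}
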