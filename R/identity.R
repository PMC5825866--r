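#' Asymmetric binary dissimilarity between two 0/1 profiles
#'
#' Computes `(b + c) / (a + b + c)` where `a` counts positions on in both
#' profiles and `b`, `c` count positions on in only one: the fraction of
#' mismatches among positions where at least one profile is 1. Joint absences
#' are ignored — after top-k discretisation a 0 only means "not among the
#' highest expressed", which is uninformative. This matches the "binary"
#' distance convention of [stats::dist()].
#'
#' @param x,y Equal-length vectors of 0/1 values.
#' @return Dissimilarity in \[0, 1\].
#' @export
#' @examples
#' binary_dissimilarity(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 2/3
binary_dissimilarity <- function(x, y) {
  if (length(x) != length(y)) {
    stop_validation("`x` and `y` must have equal length.")
  }
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop_validation("`x` and `y` must be 0/1 vectors.")
  }
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1)
  if (a + b + c_ == 0) {
    stop_validation("binary dissimilarity is undefined for two all-zero profiles.",
                    class = "microlens_undefined_distance_error")
  }
  (b + c_) / (a + b + c_)
}

#' Pairwise binary dissimilarity matrix over retained genes
#'
#' Applies the asymmetric binary dissimilarity to every pair of discretised
#' profiles, restricted to a retained gene set (typically the output of
#' [ubiquity_filter()]).
#'
#' @param bits Binary expression tibble from [discretise_top_k()].
#' @param retained_genes Genes to use; default all genes in `bits`.
#' @return A [stats::dist] object labelled by sample; symmetric with zero
#'   diagonal and entries in \[0, 1\].
#' @export
dissimilarity_matrix <- function(bits, retained_genes = NULL) {
  check_binary_tbl(bits)
  if (is.null(retained_genes)) retained_genes <- bits$gene
  unknown <- setdiff(retained_genes, bits$gene)
  if (length(unknown) > 0) {
    stop_validation(sprintf("retained_genes not present in `bits`: %s.",
                            paste(utils::head(unknown, 5), collapse = ", ")))
  }
  m <- t(as.matrix(bits[bits$gene %in% retained_genes, -1, drop = FALSE]))
  if (sum(rowSums(m) == 0) >= 2L) {
    stop_validation("binary dissimilarity undefined: at least two profiles are all-zero over the retained genes.",
                    class = "microlens_undefined_distance_error")
  }
  dist(m, method = "binary")
}

#' Classical principal coordinates analysis
#'
#' Embeds a dissimilarity matrix in Euclidean space by Gower double-centring:
#' `B = -1/2 * J %*% D^2 %*% J` with centring projector
#' `J = I - 11'/n`, eigendecomposition of `B`, and coordinates equal to the
#' eigenvectors scaled by the square roots of the positive eigenvalues, sorted
#' by decreasing eigenvalue. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as the binary distance) are reported in `eig` but
#' excluded from the coordinates; no Cailliez/Lingoes correction is applied.
#'
#' @param d A [stats::dist] object or symmetric matrix of dissimilarities with
#'   zero diagonal and non-negative entries.
#' @param n_components Number of coordinate axes to return; default all axes
#'   with positive eigenvalue.
#' @return An object of class `lens_pcoa`: list with `labels`, `points`
#'   (matrix, columns `PC1`, `PC2`, ...), and `eig` (all eigenvalues,
#'   non-increasing). Supports [tidy()], [glance()] and [autoplot()].
#' @export
pcoa <- function(d, n_components = NULL) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8)) {
    stop_validation("`d` must be a symmetric dissimilarity matrix.")
  }
  if (any(m < 0)) stop_validation("`d` has negative entries.")
  if (any(abs(diag(m)) > 1e-12)) stop_validation("`d` must have a zero diagonal.")
  n <- nrow(m)
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (!is.null(n_components)) {
    n_components <- check_count(n_components, "n_components", min = 1L)
    if (n_components > n - 1L) {
      stop_validation(sprintf("n_components = %d exceeds n - 1 = %d.", n_components, n - 1L))
    }
  }

  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (m * m) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  eig <- e$values
  pos <- which(eig > max(abs(eig[1]), 1) * 1e-9 & eig > 0)
  keep <- if (is.null(n_components)) pos else utils::head(pos, n_components)
  pts <- if (length(keep) > 0) {
    sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(eig[keep]), `*`)
  } else {
    matrix(0, n, 0)
  }
  dimnames(pts) <- list(labels,
                        if (ncol(pts) > 0) paste0("PC", seq_len(ncol(pts))) else NULL)

  structure(list(labels = labels, points = pts, eig = eig),
            class = "lens_pcoa")
}

#' @export
print.lens_pcoa <- function(x, ...) {
  cat(sprintf("<lens_pcoa> %d samples, %d positive components\n",
              length(x$labels), ncol(x$points)))
  rel <- if (sum(x$eig[x$eig > 0]) > 0) x$eig / sum(x$eig[x$eig > 0]) else x$eig
  cat(sprintf("  leading eigenvalue fractions: %s\n",
              paste(sprintf("%.3f", utils::head(rel[rel > 0], 3)), collapse = ", ")))
  invisible(x)
}

#' Rank tissues by ordination-space proximity to a query
#'
#' Orders the remaining samples by ascending Euclidean distance to the query
#' in the retained (positive-eigenvalue) coordinate space; ties are broken
#' lexicographically by label.
#'
#' @param ordination A `lens_pcoa` object.
#' @param query_label Label of the query sample within the ordination.
#' @return Tibble with columns `tissue`, `distance`, `rank`.
#' @export
rank_by_proximity <- function(ordination, query_label) {
  if (!inherits(ordination, "lens_pcoa")) {
    stop_validation("`ordination` must be a `lens_pcoa` object.")
  }
  if (!query_label %in% ordination$labels) {
    stop_validation(sprintf("query label `%s` not found in the ordination.", query_label),
                    class = "microlens_lookup_error")
  }
  pts <- ordination$points
  q <- pts[query_label, , drop = FALSE]
  others <- setdiff(ordination$labels, query_label)
  dd <- if (ncol(pts) > 0) {
    sqrt(rowSums(sweep(pts[others, , drop = FALSE], 2, as.numeric(q))^2))
  } else {
    setNames(rep(0, length(others)), others)
  }
  ord <- order(dd, others, method = "radix")
  tibble(tissue = others[ord], distance = as.numeric(dd[ord]),
         rank = seq_along(others))
}

#' Tissue-specific marker set of a query profile
#'
#' Applies the compendium's own marker rule to a query sample: the query's
#' top-`top_m` genes intersected with the genes highly expressed in at most a
#' fraction `spec_frac` of the compendium tissues. The query's gene universe
#' must equal the compendium's.
#'
#' @param query Expression tibble with exactly one sample column (or the
#'   column to use named via `sample`).
#' @param compendium A `marker_compendium` from [build_marker_sets()].
#' @param sample Optional sample column name when `query` has several.
#' @return Sorted character vector of query marker genes.
#' @export
query_marker_set <- function(query, compendium, sample = NULL) {
  check_expression_tbl(query, "query")
  if (!inherits(compendium, "marker_compendium")) {
    stop_validation("`compendium` must be a `marker_compendium` object.")
  }
  if (is.null(sample)) {
    if (ncol(query) != 2L) {
      stop_validation("`query` has several sample columns; name one via `sample`.")
    }
    sample <- sample_names(query)[1]
  }
  if (!sample %in% sample_names(query)) {
    stop_validation(sprintf("sample `%s` not found in `query`.", sample),
                    class = "microlens_lookup_error")
  }
  if (!setequal(query$gene, compendium$gene_universe)) {
    stop_validation("query gene universe differs from the compendium's; harmonise first.",
                    class = "microlens_incompatibility_error")
  }
  top <- top_k_genes(query[[sample]], query$gene, compendium$top_m)
  n_tissues <- length(compendium$tissues)
  specific <- names(compendium$gene_top_counts)[
    compendium$gene_top_counts / n_tissues <= compendium$spec_frac]
  sort(intersect(top, specific), method = "radix")
}

#' One-sided Fisher exact p for a 2x2 overlap table
#'
#' Probability of an overlap at least as large as observed under the
#' hypergeometric null with the table's margins fixed: the enrichment-sided
#' Fisher exact test. Arguments are vectorised.
#'
#' @param a Overlap count (query and tissue markers).
#' @param b Query-only count.
#' @param c Tissue-only count.
#' @param d Remainder of the gene universe.
#' @return One-sided p-value(s).
#' @export
#' @examples
#' fisher_enrichment_p(5, 0, 0, 5)  # 1/252
#' fisher_enrichment_p(2, 0, 1, 7)  # 1/15
fisher_enrichment_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop_validation("table counts must be non-negative.")
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Marker-set enrichment of a query against a tissue compendium
#'
#' For each compendium tissue, tests over-representation of the tissue's
#' marker genes within the query's marker set by a one-sided Fisher exact
#' test on the 2x2 table (`a` = shared markers, `b` = query-only, `c` =
#' tissue-only, `d` = rest of the gene universe), then applies
#' Benjamini-Hochberg correction across tissues. The tissue with the smallest
#' FDR is the query's best identity call.
#'
#' @param query_markers Character vector of query marker genes (subset of the
#'   compendium's gene universe), e.g. from [query_marker_set()].
#' @param compendium A `marker_compendium`.
#' @return Tibble of class `lens_enrichment`, one row per tissue, ranked by
#'   ascending FDR then p then tissue label: columns `tissue`, `a`, `b`, `c`,
#'   `d`, `p_value`, `fdr`, `rank`.
#' @export
fisher_enrichment <- function(query_markers, compendium) {
  if (!inherits(compendium, "marker_compendium")) {
    stop_validation("`compendium` must be a `marker_compendium` object.")
  }
  if (length(query_markers) == 0) {
    stop_validation("the query marker set is empty.",
                    class = "microlens_degenerate_input_error")
  }
  universe <- compendium$gene_universe
  bad <- setdiff(query_markers, universe)
  if (length(bad) > 0) {
    stop_validation(sprintf("query markers outside the gene universe: %s.",
                            paste(utils::head(bad, 5), collapse = ", ")),
                    class = "microlens_incompatibility_error")
  }
  n_univ <- length(universe)
  q <- unique(query_markers)
  rows <- purrr::map_dfr(compendium$tissues, function(t) {
    mset <- compendium$marker_sets[[t]]
    a <- length(intersect(q, mset))
    b <- length(q) - a
    c_ <- length(mset) - a
    d <- n_univ - a - b - c_
    tibble(tissue = t, a = a, b = b, c = c_, d = d,
           p_value = fisher_enrichment_p(a, b, c_, d))
  })
  rows$fdr <- bh_adjust(rows$p_value)
  rows <- dplyr::arrange(rows, .data$fdr, .data$p_value, .data$tissue)
  rows$rank <- seq_len(nrow(rows))
  class(rows) <- c("lens_enrichment", class(rows))
  rows
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' Classic BH false-discovery-rate adjustment: sort the p-values ascending,
#' set `q_(i) = min over j >= i of min(1, p_(j) * m / j)`, and return the
#' adjusted values in the original order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in \[0, 1\], same length and order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03))  # 0.015 0.015 0.030
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0) || any(p_values > 1)) {
    stop_validation("`p_values` must be numeric in [0, 1] with no NA.")
  }
  p.adjust(p_values, method = "BH")
}

#' Pearson correlation between two replicate expression profiles
#'
#' Measures library-to-library reproducibility as the Pearson correlation of
#' (by default) `log2(x + 1)`-transformed expression values over the shared
#' gene universe.
#'
#' @param data Expression tibble holding both replicate columns.
#' @param sample_a,sample_b Names of the two sample columns.
#' @param log_transform Apply `log2(x + 1)` before correlating (default TRUE).
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(data, sample_a, sample_b, log_transform = TRUE) {
  check_expression_tbl(data)
  for (s in c(sample_a, sample_b)) {
    if (!s %in% sample_names(data)) {
      stop_validation(sprintf("sample `%s` not found.", s),
                      class = "microlens_lookup_error")
    }
  }
  x <- data[[sample_a]]
  y <- data[[sample_b]]
  if (log_transform) {
    x <- log2(x + 1)
    y <- log2(y + 1)
  }
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
    stop_validation("correlation undefined: fewer than 3 genes or zero variance.",
                    class = "microlens_undefined_correlation_error")
  }
  cor(x, y)
}
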