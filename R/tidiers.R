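#' Tidy a principal coordinates result
#'
#' @param x A `lens_pcoa` object.
#' @param ... Unused.
#' @return Tibble with `label` and one column per retained coordinate axis.
#' @method tidy lens_pcoa
#' @export
tidy.lens_pcoa <- function(x, ...) {
  dplyr::bind_cols(tibble(label = x$labels),
                   as_tibble(x$points, .name_repair = "minimal"))
}

#' Summarise a principal coordinates result
#'
#' @param x A `lens_pcoa` object.
#' @param ... Unused.
#' @return One-row tibble: sample count, retained components, fraction of
#'   positive-eigenvalue variance on the first two axes, and the count of
#'   negative eigenvalues (non-Euclidean signal).
#' @method glance lens_pcoa
#' @export
glance.lens_pcoa <- function(x, ...) {
  pos_total <- sum(x$eig[x$eig > 0])
  frac <- function(i) {
    if (length(x$eig) >= i && pos_total > 0 && x$eig[i] > 0) x$eig[i] / pos_total else 0
  }
  tibble(
    n_samples = length(x$labels),
    n_components = ncol(x$points),
    prop_pc1 = frac(1),
    prop_pc2 = frac(2),
    n_negative_eig = sum(x$eig < 0)
  )
}

#' Tidy a marker compendium into tissue-gene pairs
#'
#' @param x A `marker_compendium`.
#' @param ... Unused.
#' @return Tibble with columns `tissue` and `gene`, one row per marker.
#' @method tidy marker_compendium
#' @export
tidy.marker_compendium <- function(x, ...) {
  purrr::map_dfr(x$tissues, function(t) {
    tibble(tissue = t, gene = x$marker_sets[[t]])
  })
}

#' Summarise a marker compendium
#'
#' @param x A `marker_compendium`.
#' @param ... Unused.
#' @return One-row tibble with tissue count, universe size, construction
#'   parameters and marker-set size summaries.
#' @method glance marker_compendium
#' @export
glance.marker_compendium <- function(x, ...) {
  sizes <- lengths(x$marker_sets)
  tibble(
    n_tissues = length(x$tissues),
    n_genes = length(x$gene_universe),
    top_m = x$top_m,
    spec_frac = x$spec_frac,
    min_set_size = min(sizes),
    median_set_size = stats::median(sizes),
    max_set_size = max(sizes)
  )
}

#' Tidy an identity score into its ranked enrichment table
#'
#' @param x An `identity_score` object.
#' @param ... Unused.
#' @return The enrichment tibble (tissue, 2x2 counts, p, FDR, rank).
#' @method tidy identity_score
#' @export
tidy.identity_score <- function(x, ...) {
  as_tibble(x$enrichment)
}

#' Summarise an identity score
#'
#' @param x An `identity_score` object.
#' @param ... Unused.
#' @return One-row tibble with the top call by enrichment and by ordination
#'   proximity, its FDR and distance, and whether the two calls agree.
#' @method glance identity_score
#' @export
glance.identity_score <- function(x, ...) {
  tibble(
    top_enrichment = x$enrichment$tissue[1],
    top_fdr = x$enrichment$fdr[1],
    top_proximity = x$proximity$tissue[1],
    top_distance = x$proximity$distance[1],
    calls_agree = x$enrichment$tissue[1] == x$proximity$tissue[1],
    n_query_markers = length(x$query_markers)
  )
}
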