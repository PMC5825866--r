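#' Score the cell identity of a query transcriptome against a compendium
#'
#' End-to-end identity scoring: harmonises gene universes, averages query
#' replicates into a single profile, discretises every profile to its top-k
#' genes, removes ubiquitously expressed genes, embeds the profiles by binary
#' dissimilarity and principal coordinates, ranks tissues by proximity to the
#' query, and scores marker-set over-representation per tissue with one-sided
#' Fisher exact tests and Benjamini-Hochberg correction.
#'
#' @param compendium_data Expression tibble, one column per tissue
#'   (replicate-averaged).
#' @param query_data Expression tibble of one or more query replicate
#'   columns.
#' @param k Top-k discretisation cut (default 1000).
#' @param max_ubiquity Maximum fraction of profiles a gene may be "on" in
#'   before removal (default 0.20; removal is strict `>`).
#' @param top_m Marker candidate cut (default 3000).
#' @param spec_frac Marker specificity bound (default 0.05, inclusive).
#' @param query_label Label given to the averaged query profile.
#' @return An object of class `identity_score`: list with `enrichment`
#'   (ranked [fisher_enrichment()] tibble), `proximity` (ranked
#'   [rank_by_proximity()] tibble), `ordination` (`lens_pcoa`), `compendium`
#'   (`marker_compendium`), `query_markers`, `retained_genes` and `params`.
#' @export
#' @examples
#' sim <- simulate_compendium(n_tissues = 6, n_genes = 600,
#'                            markers_per_tissue = 20, seed = 1)
#' q <- simulate_query(sim, "tissue03", seed = 2)
#' res <- score_identity(sim$expression, q, k = 100, top_m = 200,
#'                       spec_frac = 1 / 6)
#' res$enrichment$tissue[1]
score_identity <- function(compendium_data, query_data,
                           k = 1000, max_ubiquity = 0.20,
                           top_m = 3000, spec_frac = 0.05,
                           query_label = "query") {
  check_expression_tbl(compendium_data, "compendium_data")
  check_expression_tbl(query_data, "query_data")
  if (query_label %in% sample_names(compendium_data)) {
    stop_validation(sprintf("`query_label` (%s) collides with a tissue label.", query_label))
  }
  h <- harmonise_universe(list(compendium_data, query_data))
  compendium_data <- h[[1]]
  query_data <- h[[2]]
  query_avg <- average_replicates(
    query_data,
    setNames(rep(query_label, length(sample_names(query_data))),
             sample_names(query_data))
  )

  combined <- dplyr::bind_cols(compendium_data, query_avg[query_label])
  bits <- discretise_top_k(combined, k)
  retained <- ubiquity_filter(bits, max_ubiquity)
  d <- dissimilarity_matrix(bits, retained)
  ordination <- pcoa(d)
  proximity <- rank_by_proximity(ordination, query_label)

  compendium <- build_marker_sets(compendium_data, top_m = top_m,
                                  spec_frac = spec_frac)
  query_markers <- query_marker_set(query_avg, compendium, sample = query_label)
  enrichment <- fisher_enrichment(query_markers, compendium)

  structure(
    list(
      enrichment = enrichment,
      proximity = proximity,
      ordination = ordination,
      compendium = compendium,
      query_markers = query_markers,
      retained_genes = retained,
      params = list(k = k, max_ubiquity = max_ubiquity, top_m = top_m,
                    spec_frac = spec_frac, query_label = query_label)
    ),
    class = "identity_score"
  )
}

#' @export
print.identity_score <- function(x, ...) {
  top_e <- x$enrichment[1, ]
  top_p <- x$proximity[1, ]
  cat(sprintf("<identity_score> query `%s` vs %d tissues\n",
              x$params$query_label, length(x$compendium$tissues)))
  cat(sprintf("  top by enrichment: %s (FDR = %.3g, overlap %d markers)\n",
              top_e$tissue, top_e$fdr, top_e$a))
  cat(sprintf("  top by ordination proximity: %s (distance = %.3g)\n",
              top_p$tissue, top_p$distance))
  invisible(x)
}

default_run_config <- function() {
  list(
    seed = 1L,
    stages = c("identity", "optics"),
    compendium = list(
      n_tissues = 20L, n_genes = 5000L, markers_per_tissue = 50L,
      marker_elevation = 10, baseline_log_mean = log(100),
      baseline_log_sd = 1.5, noise_sd = 0.1
    ),
    query = list(tissue = NULL, noise_sd = 0.1, n_replicates = 2L),
    identity = list(k = 1000L, max_ubiquity = 0.20, top_m = 3000L,
                    spec_frac = 0.05),
    optics = list(
      transmittance_by_dose = c("0" = 0.95, "200" = 0.95, "2000" = 0.85),
      n_per_group = 15L, between_lens_sd = 0.02,
      image_size = 64L, background_grey = 200, lens_diameter = 40L,
      noise_sd = 2, control = "0"
    )
  )
}

read_run_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_io("YAML configs need the `yaml` package; use JSON instead.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

merge_config <- function(user) {
  cfg <- default_run_config()
  for (section in names(user)) {
    if (is.list(cfg[[section]]) && is.list(user[[section]])) {
      cfg[[section]] <- modifyList(cfg[[section]], user[[section]])
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  cfg
}

#' Run the full synthetic-data pipeline and write its artifacts
#'
#' Composes the stages end to end: simulate a compendium with planted tissue
#' identities, simulate query replicates, score the query's identity
#' ([score_identity()]), and/or simulate a dose-response micro-lens experiment
#' and summarise it. All randomness flows from `config$seed`, so identical
#' config and seed give byte-identical output files.
#'
#' @param config A configuration list (see `microlens:::default_run_config()`
#'   for the shape and defaults), or a path to a JSON/YAML file with the same
#'   structure; omitted entries keep their defaults.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a list with the in-memory results (`identity`,
#'   `optics`) and the paths written.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(config)
  seed <- check_count(cfg$seed, "seed", min = 0L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  results <- list()
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths <<- c(paths, p)
    message(sprintf("[microlens] wrote %s", p))
  }

  if ("identity" %in% cfg$stages) {
    cc <- cfg$compendium
    sim <- simulate_compendium(
      n_tissues = cc$n_tissues, n_genes = cc$n_genes,
      markers_per_tissue = cc$markers_per_tissue,
      marker_elevation = cc$marker_elevation,
      baseline_log_mean = cc$baseline_log_mean,
      baseline_log_sd = cc$baseline_log_sd,
      noise_sd = cc$noise_sd, seed = seed
    )
    qc <- cfg$query
    tissue <- if (is.null(qc$tissue)) sample_names(sim$truth)[1] else qc$tissue
    query <- simulate_query(sim, tissue, noise_sd = qc$noise_sd,
                            n_replicates = qc$n_replicates, seed = seed + 1L)
    idp <- cfg$identity
    scored <- score_identity(sim$expression, query,
                             k = idp$k, max_ubiquity = idp$max_ubiquity,
                             top_m = idp$top_m, spec_frac = idp$spec_frac)
    results$identity <- scored
    results$planted_tissue <- tissue
    emit("expression.tsv", function(p) write_expression_tsv(sim$expression, p))
    emit("query.tsv", function(p) write_expression_tsv(query, p))
    emit("planted_markers.gmt",
         function(p) write_gmt(sim$markers, p, "planted"))
    emit("marker_sets.gmt",
         function(p) write_gmt(scored$compendium$marker_sets, p, "compendium"))
    emit("enrichment.tsv",
         function(p) readr::write_tsv(as_tibble(scored$enrichment), p))
    emit("proximity.tsv", function(p) readr::write_tsv(scored$proximity, p))
    emit("ordination.tsv",
         function(p) readr::write_tsv(tidy(scored$ordination), p))
    emit("eigenvalues.tsv",
         function(p) readr::write_tsv(
           tibble(component = seq_along(scored$ordination$eig),
                  eigenvalue = scored$ordination$eig), p))
  }

  if ("optics" %in% cfg$stages) {
    oc <- cfg$optics
    tr <- oc$transmittance_by_dose
    if (is.list(tr)) tr <- unlist(tr)
    meas <- simulate_treatment_groups(
      transmittance_by_dose = tr, n_per_group = oc$n_per_group,
      between_lens_sd = oc$between_lens_sd, image_size = oc$image_size,
      background_grey = oc$background_grey, lens_diameter = oc$lens_diameter,
      noise_sd = oc$noise_sd, seed = seed + 2L
    )
    dr_t <- dose_response_summary(meas, "transmittance_ratio", "dose",
                                  control = oc$control)
    dr_f <- dose_response_summary(meas, "focus_ratio", "dose",
                                  control = oc$control)
    results$optics <- list(measurements = meas, transmittance = dr_t,
                           focus = dr_f)
    emit("optics_measurements.tsv", function(p) readr::write_tsv(meas, p))
    emit("dose_response_transmittance.tsv",
         function(p) readr::write_tsv(dr_t, p))
    emit("dose_response_focus.tsv", function(p) readr::write_tsv(dr_f, p))
  }

  resolved <- cfg
  resolved$package_version <- as.character(packageVersion("microlens"))
  emit("run_config.json", function(p) {
    jsonlite::write_json(resolved, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  })

  invisible(c(results, list(paths = paths, config = resolved)))
}
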