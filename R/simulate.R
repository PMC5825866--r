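#' Simulate an expression compendium with planted tissue identities
#'
#' Generates a gene-by-tissue expression matrix that mimics a compendium of
#' tissue transcriptomes: every gene has a lognormal baseline shared across
#' tissues (real transcriptomes span several logs of dynamic range), and each
#' tissue carries a disjoint set of planted marker genes whose expression is
#' elevated `marker_elevation`-fold above their baseline. Multiplicative
#' lognormal noise is applied per entry.
#'
#' The returned truth matrix (noise-free expected values) is the reference
#' profile set for [simulate_query()]. With `baseline_log_sd = 0` and
#' `noise_sd = 0` the planted markers are exactly the top
#' `markers_per_tissue` genes of their tissue, so marker recovery by
#' [build_marker_sets()] is decidable.
#'
#' @param n_tissues Number of tissues (columns).
#' @param n_genes Number of genes (rows).
#' @param markers_per_tissue Planted marker genes per tissue; marker sets are
#'   disjoint across tissues unless `marker_overlap > 0`.
#' @param marker_elevation Fold-elevation of a marker above its gene baseline
#'   (> 1).
#' @param baseline_log_mean,baseline_log_sd Mean and standard deviation (natural
#'   log scale) of the per-gene baseline expression, drawn once and shared
#'   across tissues. `baseline_log_sd = 0` gives the flat-baseline limit.
#' @param noise_sd Standard deviation (log scale) of the multiplicative
#'   lognormal noise applied to every entry; 0 disables noise.
#' @param n_query_replicates Default replicate count recorded for
#'   [simulate_query()].
#' @param marker_overlap Fraction of each tissue's markers drawn from a block
#'   shared by all tissues (default 0: fully disjoint sets).
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output. `NULL` uses the current random state.
#'
#' @return An object of class `compendium_sim`: a list with elements
#'   `expression` (noisy tibble, `gene` column plus one column per tissue),
#'   `truth` (expected values, same shape), `markers` (named list of planted
#'   marker gene sets), and `params`.
#' @seealso [simulate_query()], [build_marker_sets()]
#' @export
#' @examples
#' sim <- simulate_compendium(n_tissues = 4, n_genes = 200,
#'                            markers_per_tissue = 10, seed = 1)
#' dim(sim$expression)
simulate_compendium <- function(n_tissues = 20,
                                n_genes = 5000,
                                markers_per_tissue = 50,
                                marker_elevation = 10,
                                baseline_log_mean = log(100),
                                baseline_log_sd = 1.5,
                                noise_sd = 0.1,
                                n_query_replicates = 2,
                                marker_overlap = 0,
                                seed = NULL) {
  n_tissues <- check_count(n_tissues, "n_tissues", min = 2L)
  n_genes <- check_count(n_genes, "n_genes")
  markers_per_tissue <- check_count(markers_per_tissue, "markers_per_tissue")
  check_number(marker_elevation, "marker_elevation", min = 1, strict_min = TRUE)
  check_number(baseline_log_sd, "baseline_log_sd", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(marker_overlap, "marker_overlap", min = 0, max = 1)
  n_shared <- as.integer(round(marker_overlap * markers_per_tissue))
  n_own <- markers_per_tissue - n_shared
  needed <- n_shared + n_tissues * n_own
  if (needed > n_genes) {
    stop_validation(sprintf(
      "planted marker sets need %d distinct genes but n_genes = %d (violates n_tissues * markers_per_tissue <= n_genes).",
      needed, n_genes))
  }

  genes <- paste0("gene", formatC(seq_len(n_genes), width = nchar(n_genes), flag = "0"))
  tissues <- paste0("tissue", formatC(seq_len(n_tissues), width = max(2L, nchar(n_tissues)), flag = "0"))

  shared <- if (n_shared > 0) genes[seq_len(n_shared)] else character(0)
  markers <- lapply(seq_len(n_tissues), function(t) {
    own <- genes[n_shared + (t - 1L) * n_own + seq_len(n_own)]
    c(shared, own)
  })
  names(markers) <- tissues

  build <- function() {
    baseline <- exp(rnorm(n_genes, baseline_log_mean, baseline_log_sd))
    truth <- matrix(baseline, n_genes, n_tissues,
                    dimnames = list(genes, tissues))
    for (t in tissues) {
      idx <- match(markers[[t]], genes)
      truth[idx, t] <- truth[idx, t] * marker_elevation
    }
    noisy <- if (noise_sd > 0) {
      truth * exp(matrix(rnorm(n_genes * n_tissues, 0, noise_sd), n_genes, n_tissues))
    } else {
      truth
    }
    list(truth = truth, noisy = noisy)
  }
  mats <- if (is.null(seed)) build() else withr::with_seed(seed, build())

  structure(
    list(
      expression = matrix_to_expr(mats$noisy),
      truth = matrix_to_expr(mats$truth),
      markers = markers,
      params = list(
        n_tissues = n_tissues, n_genes = n_genes,
        markers_per_tissue = markers_per_tissue,
        marker_elevation = marker_elevation,
        baseline_log_mean = baseline_log_mean,
        baseline_log_sd = baseline_log_sd,
        noise_sd = noise_sd, n_query_replicates = n_query_replicates,
        marker_overlap = marker_overlap, seed = seed
      )
    ),
    class = "compendium_sim"
  )
}

#' Simulate replicated query samples from a reference tissue profile
#'
#' Draws `n_replicates` query columns from one tissue's noise-free expected
#' profile, each perturbed by multiplicative lognormal noise, emulating
#' independent RNA-seq libraries prepared from the same purified cell
#' population.
#'
#' @param truth A `compendium_sim` object or an expression tibble of expected
#'   profiles (e.g. the `truth` element of [simulate_compendium()]).
#' @param tissue Column label of the tissue to replicate.
#' @param noise_sd Log-scale standard deviation of the replicate noise; 0
#'   yields exact copies of the tissue profile.
#' @param n_replicates Number of replicate columns.
#' @param seed Integer seed for reproducibility.
#' @param prefix Prefix for the replicate column labels
#'   (`<prefix>_rep1`, ...).
#'
#' @return Expression tibble with `gene` plus `n_replicates` columns.
#' @export
#' @examples
#' sim <- simulate_compendium(n_tissues = 4, n_genes = 200,
#'                            markers_per_tissue = 10, seed = 1)
#' q <- simulate_query(sim, "tissue01", noise_sd = 0.1, seed = 2)
simulate_query <- function(truth, tissue, noise_sd = 0.1, n_replicates = 2,
                           seed = NULL, prefix = "query") {
  if (inherits(truth, "compendium_sim")) truth <- truth$truth
  check_expression_tbl(truth, "truth")
  check_number(noise_sd, "noise_sd", min = 0)
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (!tissue %in% sample_names(truth)) {
    stop_validation(sprintf("tissue `%s` is not a column of the truth matrix.", tissue),
                    class = "microlens_lookup_error")
  }
  profile <- truth[[tissue]]
  n <- length(profile)
  draw <- function() {
    reps <- vapply(seq_len(n_replicates), function(i) {
      if (noise_sd > 0) profile * exp(rnorm(n, 0, noise_sd)) else profile
    }, numeric(n))
    colnames(reps) <- paste0(prefix, "_rep", seq_len(n_replicates))
    reps
  }
  reps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  dplyr::bind_cols(tibble(gene = truth$gene), as_tibble(reps))
}

#' Paraxial effective focal length of a ball lens
#'
#' Closed-form thick-lens focal length of a homogeneous sphere, measured from
#' the lens centre: `f = n * D / (4 * (n - 1))`. Used to pick a plausible
#' focal distance for simulated micro-lens stacks.
#'
#' @param refractive_index Refractive index of the sphere (> 1).
#' @param diameter Sphere diameter in micrometres (> 0).
#' @return Effective focal length in micrometres.
#' @export
#' @examples
#' ball_lens_focal_length(1.5, 100)  # 75
#' ball_lens_focal_length(2, 100)    # 50: focal point at the back surface
ball_lens_focal_length <- function(refractive_index, diameter) {
  check_number(refractive_index, "refractive_index", min = 1, strict_min = TRUE)
  check_number(diameter, "diameter", min = 0, strict_min = TRUE)
  refractive_index * diameter / (4 * (refractive_index - 1))
}

#' Simulate a five-plane micro-lens focal stack
#'
#' Generates grey-scale planes at axial offsets z in `{0, f/2, f, 3f/2, 2f}`
#' below the lens plane (f = `focal_distance`), mimicking the imaging protocol
#' in which the in-focus lens is photographed, the objective lowered to the
#' focal point and beyond, and intermediate planes captured. At z = 0 the lens
#' disc transmits `transmittance` of the background grey; at z > 0 a Gaussian
#' focal spot of width `spot_sigma` is added to the background with amplitude
#' `background_grey * focus_gain * exp(-(z - f)^2 / (2 * (f/2)^2))`, peaking at
#' the focal plane. Per-pixel Gaussian noise is added and values are clipped to
#' the 8-bit range and rounded.
#'
#' @param image_size Side length of the square image in pixels.
#' @param background_grey Grey level of the surrounding medium (0-255).
#' @param lens_diameter Lens disc diameter in pixels (the disc must fit inside
#'   the image with room for the background annulus).
#' @param lens_center `c(x, y)` pixel coordinates of the lens centre; default
#'   the image centre.
#' @param transmittance Fraction of background light transmitted through the
#'   lens at the lens plane, in \[0, 1\].
#' @param focus_gain Peak focal-spot amplitude relative to the background
#'   (>= 0); 0 means no focusing.
#' @param focal_distance Focal distance f in micrometres; default the paraxial
#'   ball-lens focal length at refractive index 1.42.
#' @param spot_sigma Gaussian focal-spot width in pixels; default
#'   `lens_diameter / 16`.
#' @param noise_sd Additive Gaussian pixel noise standard deviation in grey
#'   levels.
#' @param pixel_scale Micrometres per pixel.
#' @param seed Integer seed for the pixel noise.
#'
#' @return A `focal_stack` object: list with `planes` (five matrices, grey
#'   levels 0-255), `z_offsets` (micrometres), `lens_center`, `lens_diameter`,
#'   `background_region` (annulus outside the lens), `pixel_scale`, and the
#'   generating `truth` parameters.
#' @seealso [measure_stack()], [central_roi()]
#' @export
#' @examples
#' st <- simulate_focal_stack(transmittance = 0.8, noise_sd = 0, seed = 1)
#' measure_stack(st)
simulate_focal_stack <- function(image_size = 128,
                                 background_grey = 200,
                                 lens_diameter = 80,
                                 lens_center = NULL,
                                 transmittance = 1,
                                 focus_gain = 1,
                                 focal_distance = NULL,
                                 spot_sigma = NULL,
                                 noise_sd = 2,
                                 pixel_scale = 1,
                                 seed = NULL) {
  image_size <- check_count(image_size, "image_size", min = 8L)
  check_number(background_grey, "background_grey", min = 0, max = 255)
  check_number(lens_diameter, "lens_diameter", min = 0, strict_min = TRUE)
  check_number(transmittance, "transmittance", min = 0, max = 1)
  check_number(focus_gain, "focus_gain", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(pixel_scale, "pixel_scale", min = 0, strict_min = TRUE)
  if (is.null(lens_center)) lens_center <- rep((image_size + 1) / 2, 2)
  if (length(lens_center) != 2L || !is.numeric(lens_center)) {
    stop_validation("`lens_center` must be a numeric vector c(x, y).")
  }
  r <- lens_diameter / 2
  if (any(lens_center - r < 1) || any(lens_center + r > image_size)) {
    stop_validation("lens disc does not fit inside the image.",
                    class = "microlens_geometry_error")
  }
  if (is.null(focal_distance)) {
    focal_distance <- ball_lens_focal_length(1.42, lens_diameter * pixel_scale)
  }
  check_number(focal_distance, "focal_distance", min = 0, strict_min = TRUE)
  if (is.null(spot_sigma)) spot_sigma <- lens_diameter / 16
  check_number(spot_sigma, "spot_sigma", min = 0, strict_min = TRUE)

  bg_region <- default_background_region(lens_center, lens_diameter, image_size)

  z <- focal_distance * c(0, 0.5, 1, 1.5, 2)
  cols <- matrix(seq_len(image_size), image_size, image_size, byrow = TRUE)
  rows <- matrix(seq_len(image_size), image_size, image_size)
  r2 <- (cols - lens_center[1])^2 + (rows - lens_center[2])^2
  disc <- r2 <= r^2
  spot <- exp(-r2 / (2 * spot_sigma^2))

  draw <- function() {
    lapply(seq_along(z), function(i) {
      plane <- matrix(background_grey, image_size, image_size)
      if (i == 1L) {
        plane[disc] <- transmittance * background_grey
      } else {
        amp <- background_grey * focus_gain *
          exp(-(z[i] - focal_distance)^2 / (2 * (focal_distance / 2)^2))
        plane <- plane + amp * spot
      }
      if (noise_sd > 0) {
        plane <- plane + matrix(rnorm(image_size^2, 0, noise_sd),
                                image_size, image_size)
      }
      round(pmin(pmax(plane, 0), 255))
    })
  }
  planes <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  new_focal_stack(
    planes = planes, z_offsets = z, lens_center = lens_center,
    lens_diameter = lens_diameter, background_region = bg_region,
    pixel_scale = pixel_scale,
    truth = list(transmittance = transmittance, focus_gain = focus_gain,
                 focal_distance = focal_distance, spot_sigma = spot_sigma,
                 background_grey = background_grey, noise_sd = noise_sd,
                 seed = seed)
  )
}

#' Simulate measured treatment groups of micro-lenses
#'
#' Emulates a dose-response experiment: for each dose, `n_per_group` lenses
#' are simulated with per-lens planted transmittance drawn from a normal
#' distribution around the dose's mean (between-lens biological variability),
#' imaged as focal stacks, and measured with [measure_stack()].
#'
#' @param transmittance_by_dose Named numeric vector: mean planted
#'   transmittance per dose; names are dose labels (kept as given).
#' @param n_per_group Lenses per dose group.
#' @param between_lens_sd Between-lens standard deviation of planted
#'   transmittance.
#' @param focus_gain_by_dose Optional named numeric vector of per-dose focus
#'   gains; default 1 for every dose.
#' @param image_size,background_grey,lens_diameter,noise_sd Passed to
#'   [simulate_focal_stack()].
#' @param seed Integer seed covering all draws.
#'
#' @return Tibble with one row per lens: `dose`, `lens`, planted
#'   `true_transmittance`, and the [measure_stack()] measurement columns.
#' @seealso [dose_response_summary()]
#' @export
simulate_treatment_groups <- function(transmittance_by_dose = c("0" = 0.95, "200" = 0.95, "2000" = 0.85),
                                      n_per_group = 15,
                                      between_lens_sd = 0.02,
                                      focus_gain_by_dose = NULL,
                                      image_size = 64,
                                      background_grey = 200,
                                      lens_diameter = 40,
                                      noise_sd = 2,
                                      seed = NULL) {
  if (is.null(names(transmittance_by_dose)) || anyDuplicated(names(transmittance_by_dose))) {
    stop_validation("`transmittance_by_dose` must have unique dose names.")
  }
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2L)
  check_number(between_lens_sd, "between_lens_sd", min = 0)
  doses <- names(transmittance_by_dose)
  if (is.null(focus_gain_by_dose)) {
    focus_gain_by_dose <- setNames(rep(1, length(doses)), doses)
  }
  run <- function() {
    purrr::map_dfr(doses, function(d) {
      purrr::map_dfr(seq_len(n_per_group), function(i) {
        tr <- min(max(rnorm(1, transmittance_by_dose[[d]], between_lens_sd), 0), 1)
        st <- simulate_focal_stack(
          image_size = image_size, background_grey = background_grey,
          lens_diameter = lens_diameter, transmittance = tr,
          focus_gain = focus_gain_by_dose[[d]], noise_sd = noise_sd,
          seed = NULL
        )
        dplyr::bind_cols(
          tibble(dose = d, lens = i, true_transmittance = tr),
          measure_stack(st)
        )
      })
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
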