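#' Pixel regions: discs and annuli
#'
#' A `pixel_region` describes a set of pixels by geometry: a disc
#' (`center`, `radius`) or an annulus (`center`, `inner_radius`,
#' `outer_radius`). Membership of a pixel (integer coordinates, `x` = column,
#' `y` = row) is decided by the Euclidean distance of its centre from the
#' region centre.
#'
#' @param center Numeric `c(x, y)` pixel coordinates.
#' @param radius Disc radius in pixels.
#' @param inner_radius,outer_radius Annulus radii in pixels
#'   (`inner_radius < outer_radius`).
#' @return A `pixel_region` object.
#' @export
disc_region <- function(center, radius) {
  if (length(center) != 2L || !is.numeric(center)) {
    stop_validation("`center` must be numeric c(x, y).")
  }
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  structure(list(shape = "disc", center = as.numeric(center), radius = radius),
            class = "pixel_region")
}

#' @rdname disc_region
#' @export
annulus_region <- function(center, inner_radius, outer_radius) {
  if (length(center) != 2L || !is.numeric(center)) {
    stop_validation("`center` must be numeric c(x, y).")
  }
  check_number(inner_radius, "inner_radius", min = 0)
  check_number(outer_radius, "outer_radius", min = inner_radius, strict_min = TRUE)
  structure(list(shape = "annulus", center = as.numeric(center),
                 inner_radius = inner_radius, outer_radius = outer_radius),
            class = "pixel_region")
}

# Logical membership mask for a region over an nrow x ncol image.
region_mask <- function(region, dim) {
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  d2 <- (cols - region$center[1])^2 + (rows - region$center[2])^2
  if (region$shape == "disc") {
    d2 <= region$radius^2
  } else {
    d2 >= region$inner_radius^2 & d2 <= region$outer_radius^2
  }
}

#' Central measurement region of a lens
#'
#' The grey-level quantification region: a circular region concentric with the
#' lens whose diameter is one quarter of the lens diameter ("central quarter
#' diameter").
#'
#' @param lens_center `c(x, y)` pixel coordinates of the lens centre.
#' @param lens_diameter Lens diameter in pixels (>= 8, so the region contains
#'   at least one pixel).
#' @return A disc `pixel_region` with radius `lens_diameter / 8`.
#' @export
#' @examples
#' central_roi(c(64, 64), 80)  # disc of diameter 20
central_roi <- function(lens_center, lens_diameter) {
  check_number(lens_diameter, "lens_diameter", min = 8)
  disc_region(lens_center, lens_diameter / 8)
}

#' Mean grey level within a pixel region
#'
#' @param image Numeric matrix of grey levels.
#' @param region A `pixel_region`.
#' @return Arithmetic mean of the pixel values inside the region.
#' @export
roi_mean_grey <- function(image, region) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_validation("`image` must be a numeric matrix.")
  }
  if (!inherits(region, "pixel_region")) {
    stop_validation("`region` must be a `pixel_region`.")
  }
  mask <- region_mask(region, dim(image))
  if (!any(mask)) {
    stop_validation("the region contains no pixels.",
                    class = "microlens_empty_region_error")
  }
  mean(image[mask])
}

# Background annulus just outside the lens disc, clipped to stay inside the
# image; this is the "surrounding medium" reference used for normalisation.
default_background_region <- function(lens_center, lens_diameter, image_size) {
  r <- lens_diameter / 2
  edge <- min(lens_center[1] - 1, lens_center[2] - 1,
              image_size - lens_center[1], image_size - lens_center[2])
  inner <- 1.25 * r
  outer <- min(1.75 * r, edge)
  if (outer <= inner) {
    stop_validation("no room for a background annulus between the lens and the image edge.",
                    class = "microlens_geometry_error")
  }
  annulus_region(lens_center, inner, outer)
}

#' Construct a five-plane focal stack
#'
#' Container for a registered focal series: five grey-scale planes of equal
#' size taken at strictly increasing axial offsets starting at the lens plane
#' (z = 0), with the lens geometry and a background region outside the lens.
#'
#' @param planes List of five numeric matrices (grey levels), equal
#'   dimensions.
#' @param z_offsets Numeric vector of five axial offsets in micrometres,
#'   strictly increasing, first element 0.
#' @param lens_center `c(x, y)` pixel coordinates.
#' @param lens_diameter Lens diameter in pixels.
#' @param background_region A `pixel_region` outside the lens disc; default
#'   an annulus between 1.25 and 1.75 lens radii.
#' @param pixel_scale Micrometres per pixel.
#' @param truth Optional list of generating parameters (kept by the
#'   simulator).
#' @return A `focal_stack` object.
#' @export
new_focal_stack <- function(planes, z_offsets, lens_center, lens_diameter,
                            background_region = NULL, pixel_scale = 1,
                            truth = NULL) {
  if (!is.list(planes) || length(planes) != 5L ||
      !all(vapply(planes, is.matrix, logical(1)))) {
    stop_validation("`planes` must be a list of exactly five image matrices.")
  }
  dims <- vapply(planes, dim, integer(2))
  if (any(dims != dims[, 1])) {
    stop_validation("all planes must have identical dimensions.")
  }
  if (length(z_offsets) != 5L || z_offsets[1] != 0 || any(diff(z_offsets) <= 0)) {
    stop_validation("`z_offsets` must be five strictly increasing values starting at 0.")
  }
  if (is.null(background_region)) {
    background_region <- default_background_region(lens_center, lens_diameter,
                                                   min(dims[, 1]))
  }
  structure(
    list(planes = planes, z_offsets = as.numeric(z_offsets),
         lens_center = as.numeric(lens_center),
         lens_diameter = as.numeric(lens_diameter),
         background_region = background_region,
         pixel_scale = as.numeric(pixel_scale),
         truth = truth),
    class = "focal_stack"
  )
}

#' @export
print.focal_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<focal_stack> 5 planes of %dx%d px, z = %s um, lens diameter %g px\n",
              d[1], d[2], paste(signif(x$z_offsets, 4), collapse = "/"),
              x$lens_diameter))
  invisible(x)
}

#' Measure transmittance and focusing ability of a focal stack
#'
#' Computes the mean grey level of the central quarter-diameter region on each
#' of the five planes and the background (surrounding medium) mean from the
#' lens-plane image, then derives:
#' \describe{
#'   \item{transmittance_ratio}{lens-plane central mean / background mean —
#'     how much light passes through the lens relative to the medium.}
#'   \item{focus_ratio}{maximal below-lens central mean / background mean —
#'     the brightening at the best focal plane.}
#'   \item{focal_plane_index}{which below-lens plane (2-5) attains the
#'     maximum; ties resolved to the smallest offset.}
#' }
#'
#' @param stack A `focal_stack`.
#' @return One-row tibble: `transmittance_ratio`, `focus_ratio`,
#'   `focal_plane_index`, `focal_z`, `background_mean`, and `roi_mean_z1` ...
#'   `roi_mean_z5`.
#' @export
measure_stack <- function(stack) {
  if (!inherits(stack, "focal_stack")) {
    stop_validation("`stack` must be a `focal_stack` object.")
  }
  roi <- central_roi(stack$lens_center, stack$lens_diameter)
  roi_means <- vapply(stack$planes, roi_mean_grey, numeric(1), region = roi)
  background <- roi_mean_grey(stack$planes[[1]], stack$background_region)
  if (background == 0) {
    stop_validation("background mean grey is zero; ratios undefined.",
                    class = "microlens_normalisation_error")
  }
  below <- roi_means[-1]
  idx <- which.max(below)  # which.max takes the first maximum: smallest z on ties
  out <- tibble(
    transmittance_ratio = roi_means[1] / background,
    focus_ratio = max(below) / background,
    focal_plane_index = as.integer(idx + 1L),
    focal_z = stack$z_offsets[idx + 1L],
    background_mean = background
  )
  for (i in seq_along(roi_means)) out[[paste0("roi_mean_z", i)]] <- roi_means[i]
  out
}

#' Compare an optical metric between two groups by Student's t-test
#'
#' Two-sample pooled-variance (equal-variance) Student's t-test, two-sided,
#' with degrees of freedom `n_a + n_b - 2`; Welch's correction is available
#' via `var_equal = FALSE`. If both groups are degenerate (zero variance) and
#' their means are equal, the comparison is reported as `t = 0`, `p = 1`.
#'
#' @param data Tibble of per-lens measurements.
#' @param metric Name of the numeric metric column (e.g.
#'   `"transmittance_ratio"`).
#' @param group Name of the grouping column; it must take exactly two values.
#' @param var_equal Pooled-variance test when TRUE (default), Welch otherwise.
#' @return One-row tibble: group labels, sizes, means, standard errors of the
#'   mean, `t`, `df`, `p_value`.
#' @export
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' compare_groups(d, "y", "g")
compare_groups <- function(data, metric, group, var_equal = TRUE) {
  if (!is.data.frame(data)) stop_validation("`data` must be a data frame.")
  for (col in c(metric, group)) {
    if (!col %in% names(data)) {
      stop_validation(sprintf("column `%s` not found.", col),
                      class = "microlens_lookup_error")
    }
  }
  g <- as.character(data[[group]])
  levels <- unique(g)
  if (length(levels) != 2L) {
    stop_validation("`group` must take exactly two values.")
  }
  x <- data[[metric]][g == levels[1]]
  y <- data[[metric]][g == levels[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stop_validation("each group needs at least two measurements.")
  }
  sem <- function(v) sd(v) / sqrt(length(v))
  degenerate <- sd(x) == 0 && sd(y) == 0
  if (degenerate) {
    tstat <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    p <- if (mean(x) == mean(y)) 1 else 0
    df <- length(x) + length(y) - 2
  } else {
    tt <- t.test(x, y, var.equal = var_equal)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
    df <- unname(tt$parameter)
  }
  tibble(
    metric = metric,
    group_a = levels[1], group_b = levels[2],
    n_a = length(x), n_b = length(y),
    mean_a = mean(x), mean_b = mean(y),
    sem_a = sem(x), sem_b = sem(y),
    t = tstat, df = df, p_value = p
  )
}

#' Dose-response summary against a control group
#'
#' Summarises an optical metric per dose (mean +/- s.e.m.) and tests each dose
#' against the control group with [compare_groups()]. Doses are ordered
#' ascending by their numeric value when the labels are numeric, otherwise by
#' label.
#'
#' @param data Tibble of per-lens measurements with a dose column.
#' @param metric Metric column name.
#' @param dose Dose column name.
#' @param control Dose value identifying the control group.
#' @param var_equal Passed to [compare_groups()].
#' @return Tibble, one row per dose (control first among equals): `dose`, `n`,
#'   `mean`, `sem`, `t`, `df`, `p_value` (vs control; the control row compares
#'   the control with itself, yielding `p = 1`).
#' @export
dose_response_summary <- function(data, metric, dose, control, var_equal = TRUE) {
  if (!is.data.frame(data)) stop_validation("`data` must be a data frame.")
  for (col in c(metric, dose)) {
    if (!col %in% names(data)) {
      stop_validation(sprintf("column `%s` not found.", col),
                      class = "microlens_lookup_error")
    }
  }
  d <- as.character(data[[dose]])
  control <- as.character(control)
  if (!control %in% d) {
    stop_validation(sprintf("control dose `%s` not present.", control),
                    class = "microlens_lookup_error")
  }
  doses <- unique(d)
  num <- suppressWarnings(as.numeric(doses))
  doses <- if (!anyNA(num)) doses[order(num)] else sort(doses, method = "radix")
  ctrl_vals <- data[[metric]][d == control]
  purrr::map_dfr(doses, function(dd) {
    vals <- data[[metric]][d == dd]
    cmp <- if (dd == control) {
      # control vs itself: the no-effect reference row
      both <- tibble(g = rep(c("ctrl", "dose"), each = length(ctrl_vals)),
                     y = c(ctrl_vals, ctrl_vals))
      compare_groups(both, "y", "g", var_equal = var_equal)
    } else {
      both <- tibble(g = c(rep("ctrl", length(ctrl_vals)), rep("dose", length(vals))),
                     y = c(ctrl_vals, vals))
      compare_groups(both, "y", "g", var_equal = var_equal)
    }
    tibble(dose = dd, n = length(vals), mean = mean(vals),
           sem = sd(vals) / sqrt(length(vals)),
           t = cmp$t, df = cmp$df, p_value = cmp$p_value)
  })
}
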