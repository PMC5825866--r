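#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample labels and a first column of gene symbols.
#' Duplicate symbols, ragged rows and negative values are rejected with the
#' offending line numbers.
#'
#' @param path Path to the TSV file.
#' @param unit Optional unit tag to attach (`"counts"` or `"rpm"`).
#' @return Expression tibble (`gene` column plus numeric sample columns).
#' @export
read_expression_tsv <- function(path, unit = NULL) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  if (file.size(path) == 0) stop_io(sprintf("empty expression file: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2) stop_io(sprintf("no data rows in %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop_io(sprintf("ragged row in %s at line %d (%d fields, expected %d).",
                    path, bad, widths[bad], widths[1]))
  }
  header <- fields[[1]]
  genes <- vapply(fields[-1], `[[`, character(1), 1)
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1]
    stop_io(sprintf("duplicate gene symbol `%s` in %s at line %d.",
                    dup, path, which(genes == dup)[2] + 1L))
  }
  vals <- do.call(rbind, lapply(fields[-1], function(f) {
    suppressWarnings(as.numeric(f[-1]))
  }))
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1]
    stop_io(sprintf("non-numeric expression value in %s at line %d.", path, bad + 1L))
  }
  if (any(vals < 0)) {
    bad <- which(rowSums(vals < 0) > 0)[1]
    stop_io(sprintf("negative expression value in %s at line %d.", path, bad + 1L))
  }
  samples <- header[-1]
  colnames(vals) <- samples
  out <- dplyr::bind_cols(tibble(gene = genes), as_tibble(vals))
  check_expression_tbl(out)
  if (!is.null(unit)) attr(out, "unit") <- unit
  out
}

#' Write an expression tibble to TSV
#'
#' @param data Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(data, path) {
  check_expression_tbl(data)
  readr::write_tsv(data, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are collapsed with a warning;
#' duplicate set names are an error.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_io(sprintf("empty GMT file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0) {
    stop_io(sprintf("malformed GMT line %d in %s (need name, description, >=1 member).",
                    short[1], path))
  }
  nms <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nms)) {
    stop_io(sprintf("duplicate set name `%s` in %s.", nms[duplicated(nms)][1], path))
  }
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warn(sprintf("duplicate members collapsed in set `%s`.", f[1]))
      members <- unique(members)
    }
    members
  })
  setNames(sets, nms)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "") {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop_validation("`sets` must have unique names.")
  }
  lines <- vapply(names(sets), function(n) {
    paste(c(n, description, sets[[n]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a focal stack as TIFF planes plus a JSON sidecar
#'
#' Each plane is written as an 8-bit grey-scale TIFF
#' (`<prefix>_plane<i>.tif`); geometry and axial offsets go to
#' `<prefix>.json`.
#'
#' @param stack A `focal_stack`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Path of the JSON sidecar, invisibly.
#' @export
write_focal_stack <- function(stack, dir, prefix = "stack") {
  if (!inherits(stack, "focal_stack")) {
    stop_validation("`stack` must be a `focal_stack`.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(5)
  for (i in 1:5) {
    files[i] <- file.path(dir, sprintf("%s_plane%d.tif", prefix, i))
    tiff::writeTIFF(stack$planes[[i]] / 255, files[i], bits.per.sample = 8L)
  }
  bg <- stack$background_region
  sidecar <- list(
    planes = basename(files),
    z_offsets = stack$z_offsets,
    lens_center = stack$lens_center,
    lens_diameter = stack$lens_diameter,
    background_region = list(
      shape = bg$shape, center = bg$center,
      inner_radius = bg$inner_radius, outer_radius = bg$outer_radius,
      radius = bg$radius
    ),
    pixel_scale = stack$pixel_scale,
    truth = stack$truth
  )
  json_path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(json_path)
}

#' Read a focal stack from its JSON sidecar
#'
#' @param json_path Path to the sidecar written by [write_focal_stack()].
#' @return A `focal_stack` object with grey levels on the 0-255 scale.
#' @export
read_focal_stack <- function(json_path) {
  if (!file.exists(json_path)) stop_io(sprintf("file not found: %s", json_path))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  dir <- dirname(json_path)
  planes <- lapply(meta$planes, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop_io(sprintf("missing plane image: %s", p))
    round(tiff::readTIFF(p) * 255)
  })
  bg <- meta$background_region
  region <- if (identical(bg$shape, "disc")) {
    disc_region(bg$center, bg$radius)
  } else {
    annulus_region(bg$center, bg$inner_radius, bg$outer_radius)
  }
  new_focal_stack(
    planes = planes, z_offsets = meta$z_offsets,
    lens_center = meta$lens_center, lens_diameter = meta$lens_diameter,
    background_region = region, pixel_scale = meta$pixel_scale,
    truth = meta$truth
  )
}
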