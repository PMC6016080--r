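# Calibrated multi-channel fields, manual cilium paths, and result tables.
#
# Conventions (used throughout the package):
#  * coordinates are 0-based, row-major, with pixel centers at integer
#    positions;
#  * all physical distances are micrometres, derived via pixel_size_um;
#  * channel roles are assigned explicitly (sidecar JSON or role_map), never
#    guessed from file metadata, because staining defines the role.

RESERVED_ROLES <- c("axoneme", "membrane", "basal_body", "nucleus")

#' Construct a calibrated multi-channel field image
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions. Names are channel roles: `axoneme` (required for
#'   quantification), optionally `membrane`, `basal_body`, `nucleus`, and any
#'   number of marker channels under their own names (e.g. `"Kif7"`).
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @param field_id Identifier for the field.
#' @param metadata Free-form named list (bit depth, provenance, ...).
#' @return A `field_image` object.
#' @export
field_image <- function(channels, pixel_size_um, field_id = "field",
                        metadata = list()) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stopf("channels must be a named list of matrices")
  }
  if (anyDuplicated(names(channels))) {
    stopf("duplicated channel role: %s",
          paste(unique(names(channels)[duplicated(names(channels))]),
                collapse = ", "))
  }
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) stopf("all channels must share identical dimensions")
  if (!is_scalar_num(pixel_size_um) || pixel_size_um <= 0) {
    stopf("pixel_size_um must be a positive number")
  }
  for (nm in names(channels)) {
    if (any(channels[[nm]] < 0)) stopf("channel '%s' has negative intensities", nm)
    storage.mode(channels[[nm]]) <- "double"
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         field_id = as.character(field_id), metadata = metadata),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<field_image '%s'> %d x %d px (%.3g um/px), channels: %s\n",
              x$field_id, d[1L], d[2L], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

field_channel <- function(field, role) {
  ch <- field$channels[[role]]
  if (is.null(ch)) stopf("field '%s' has no '%s' channel", field$field_id, role,
                         class = "ciliametrics_missing_channel")
  ch
}

marker_names <- function(field) {
  setdiff(names(field$channels), RESERVED_ROLES)
}

#' Construct a cilium centerline trace
#'
#' @param points Numeric n x 2 matrix of ordered subpixel (row, col)
#'   coordinates (0-based), resampled to roughly 1-pixel arc spacing.
#' @param mask Integer m x 2 matrix of (row, col) pixel coordinates covering
#'   the cilium body; must contain the nearest-pixel rasterization of
#'   `points`. Defaults to exactly that rasterization.
#' @param field_id,cilium_id Identifiers.
#' @param oriented Whether the proximal (basal) end is known.
#' @param orientation_ambiguous Flag set when no basal-body evidence exists.
#' @return A `cilium_trace` object. After orientation the base is always the
#'   first point.
#' @export
cilium_trace <- function(points, mask = NULL, field_id = "field",
                         cilium_id = 1L, oriented = FALSE,
                         orientation_ambiguous = !oriented) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stopf("a trace needs at least 2 points")
  step <- sqrt(rowSums(diff(points)^2))
  if (any(step > sqrt(2) + 1e-6)) {
    points <- resample_polyline(points, spacing = 1.0)
  }
  rast <- unique(round(points))
  if (is.null(mask)) {
    mask <- rast
  } else {
    mask <- unique(as.matrix(mask))
    key <- function(m) paste(m[, 1L], m[, 2L])
    if (!all(key(rast) %in% key(mask))) {
      mask <- unique(rbind(mask, rast))
    }
  }
  storage.mode(mask) <- "integer"
  structure(
    list(points = unname(points), mask = unname(mask),
         field_id = as.character(field_id), cilium_id = cilium_id,
         oriented = isTRUE(oriented),
         orientation_ambiguous = isTRUE(orientation_ambiguous)),
    class = "cilium_trace"
  )
}

#' @export
print.cilium_trace <- function(x, ...) {
  cat(sprintf("<cilium_trace %s/%s> %d points, %.1f px, %s\n",
              x$field_id, x$cilium_id, nrow(x$points),
              polyline_length(x$points),
              if (x$oriented) "oriented" else "unoriented"))
  invisible(x)
}

# Logical mask matrix for a trace within a field of the given dimensions.
trace_mask_matrix <- function(trace, dims) {
  m <- matrix(FALSE, dims[1L], dims[2L])
  px <- trace$mask
  keep <- px[, 1L] >= 0L & px[, 1L] < dims[1L] & px[, 2L] >= 0L & px[, 2L] < dims[2L]
  m[px[keep, , drop = FALSE] + 1L] <- TRUE
  m
}

#' Read a calibrated field from TIFF plus channel roles
#'
#' If a JSON sidecar `<path without .tif>.json` written by [write_field()]
#' exists, roles and pixel size default to its contents; an explicit
#' `role_map` / `pixel_size_um` overrides it.
#'
#' @param path Multi-page TIFF path.
#' @param role_map Named character vector mapping 0-based page index to role,
#'   e.g. `c("0" = "axoneme", "1" = "membrane")`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param field_id Field identifier; defaults to the file stem.
#' @return A `field_image`.
#' @export
read_field <- function(path, role_map = NULL, pixel_size_um = NULL,
                       field_id = NULL) {
  sidecar <- sub("\\.tiff?$", ".json", path)
  meta <- if (file.exists(sidecar) && sidecar != path) {
    jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  } else NULL
  if (is.null(role_map) && !is.null(meta)) {
    role_map <- stats::setNames(meta$channels, seq_along(meta$channels) - 1L)
  }
  if (is.null(pixel_size_um) && !is.null(meta)) pixel_size_um <- meta$pixel_size_um
  if (is.null(field_id)) {
    field_id <- if (!is.null(meta$field_id)) meta$field_id
                else sub("\\.tiff?$", "", basename(path))
  }
  if (is.null(role_map)) stopf("role_map is required (no sidecar found)")
  if (is.null(pixel_size_um)) stopf("pixel_size_um is required (no sidecar found)")
  pages <- read_tiff(path)
  idx <- as.integer(names(role_map))
  if (any(is.na(idx)) || any(idx < 0L) || any(idx >= length(pages))) {
    stopf("role_map indices must be 0-based page indices (%d pages present)",
          length(pages))
  }
  if (!"axoneme" %in% role_map) {
    stopf("role_map must assign the 'axoneme' role",
          class = "ciliametrics_missing_channel")
  }
  channels <- stats::setNames(pages[idx + 1L], unname(role_map))
  field_image(channels, pixel_size_um, field_id = field_id,
              metadata = list(source = path,
                              bit_depth_hash = bit_depth_signature(pages)))
}

# Signature of sample value range used to warn when fields in one comparison
# were acquired at different depths ("equal settings" cannot be verified, only
# screened).
bit_depth_signature <- function(pages) {
  mx <- max(vapply(pages, max, 1.0))
  if (mx <= 255) "8bit-range" else if (mx <= 65535) "16bit-range" else "float-range"
}

#' Write a field as multi-page TIFF + JSON sidecar
#'
#' @param field A `field_image`.
#' @param dir Output directory (created if needed).
#' @param sample_type Passed to [write_tiff()]; default lossless float64.
#' @return Invisible list of written paths.
#' @export
write_field <- function(field, dir, sample_type = "float64") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(field$field_id, ".tif"))
  js <- file.path(dir, paste0(field$field_id, ".json"))
  write_tiff(unname(field$channels), tif, sample_type = sample_type)
  jsonlite::write_json(
    list(field_id = field$field_id, pixel_size_um = field$pixel_size_um,
         channels = names(field$channels), metadata = field$metadata),
    js, auto_unbox = TRUE, digits = NA)
  invisible(list(tiff = tif, sidecar = js))
}

#' Read user-clicked cilium paths (interactive-segmentation mode)
#'
#' Accepts the polyline vertices a user would click along each cilium, as in
#' interactive segmentation, and densifies them to <= 1-pixel arc spacing by
#' linear interpolation.
#'
#' @param path CSV with columns `field_id, cilium_id, vertex_order, row, col`
#'   (0-based pixel coordinates).
#' @return A list of `cilium_trace` objects.
#' @export
read_manual_paths <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("field_id", "cilium_id", "vertex_order", "row", "col")
  if (!all(need %in% names(df))) {
    stopf("manual path CSV must have columns: %s", paste(need, collapse = ", "))
  }
  keys <- unique(df[, c("field_id", "cilium_id")])
  traces <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$field_id == keys$field_id[i] & df$cilium_id == keys$cilium_id[i], ]
    if (nrow(sub) < 2L) {
      stopf("path %s/%s has fewer than 2 vertices", keys$field_id[i],
            keys$cilium_id[i])
    }
    if (any(diff(sub$vertex_order) <= 0)) {
      stopf("non-monotonic vertex_order in path %s/%s", keys$field_id[i],
            keys$cilium_id[i])
    }
    pts <- resample_polyline(cbind(sub$row, sub$col), spacing = 1.0)
    traces[[i]] <- cilium_trace(pts, field_id = keys$field_id[i],
                                cilium_id = keys$cilium_id[i])
  }
  traces
}

#' Write per-cilium and per-field results
#'
#' Writes `cilium_records.csv` (one row per cilium, stable column order) and
#' `field_summaries.json`.
#'
#' @param records Data frame of per-cilium records ([quantify_field()]).
#' @param summaries List of (or single) field summary objects.
#' @param out_dir Output directory.
#' @return Invisible list of written paths.
#' @export
write_results <- function(records, summaries, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "cilium_records.csv")
  js <- file.path(out_dir, "field_summaries.json")
  utils::write.csv(records, csv, row.names = FALSE)
  if (inherits(summaries, "field_summary")) summaries <- list(summaries)
  jsonlite::write_json(lapply(summaries, unclass), js, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(list(records = csv, summaries = js))
}
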