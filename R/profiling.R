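# Intensity profiling along traced cilia: transverse 3-pixel averaging at
# each path position, ten-bin arc-length normalization, mean-gray-value
# densitometry, and ciliary intensity normalized to surrounding fluorescence.

#' Profiling configuration
#'
#' @param n_bins Number of arc-length bins (ten is the convention: cilia of
#'   different lengths become comparable on a common axis).
#' @param transverse_px Odd number of transverse samples averaged per path
#'   position (3 = one above, one on, one below the path).
#' @param transverse_mode `"normal"` takes the offsets along the local path
#'   normal (rotation-invariant); `"literal_rows"` takes them along the
#'   image column direction (rows above/below), the literal reading of an
#'   improfile-style script, exact only for near-horizontal paths.
#' @param sample_spacing_px Arc spacing of path samples.
#' @param interp `"bilinear"` (default) or `"nearest"` intensity lookup;
#'   nearest reproduces pixel-exact improfile-style sampling and is what the
#'   brute-force test oracle uses.
#' @param background_mode `"annulus"` (per-cilium surrounding fluorescence)
#'   or `"field_robust"` (median of the whole channel).
#' @param annulus_inner_px,annulus_outer_px Dilation radii bounding the
#'   background annulus.
#' @return A `profile_config` object.
#' @export
profile_config <- function(n_bins = 10L, transverse_px = 3L,
                           transverse_mode = c("normal", "literal_rows"),
                           sample_spacing_px = 1.0,
                           interp = c("bilinear", "nearest"),
                           background_mode = c("annulus", "field_robust"),
                           annulus_inner_px = 2, annulus_outer_px = 5) {
  transverse_mode <- match.arg(transverse_mode)
  interp <- match.arg(interp)
  background_mode <- match.arg(background_mode)
  if (n_bins < 1L) stopf("n_bins must be >= 1")
  if (transverse_px < 1L || transverse_px %% 2L == 0L) {
    stopf("transverse_px must be an odd integer >= 1")
  }
  if (annulus_inner_px < 1 || annulus_outer_px <= annulus_inner_px) {
    stopf("need annulus_outer_px > annulus_inner_px >= 1")
  }
  structure(list(n_bins = as.integer(n_bins),
                 transverse_px = as.integer(transverse_px),
                 transverse_mode = transverse_mode,
                 sample_spacing_px = sample_spacing_px, interp = interp,
                 background_mode = background_mode,
                 annulus_inner_px = annulus_inner_px,
                 annulus_outer_px = annulus_outer_px),
            class = "profile_config")
}

#' Sample a marker's intensity along a trace
#'
#' At each path sample the reported intensity is the mean of
#' `transverse_px` lookups at unit-spaced offsets across the path
#' (above/on/below); offsets falling outside the image are dropped from the
#' mean.
#'
#' @param field A `field_image`.
#' @param trace A `cilium_trace` (base first if oriented).
#' @param marker Channel name to profile.
#' @param cfg A [profile_config()].
#' @return Data frame with `arc_px` (cumulative arc position), `s`
#'   (normalized arc in [0,1]) and `value`.
#' @export
sample_path_intensity <- function(field, trace, marker,
                                  cfg = profile_config()) {
  img <- field_channel(field, marker)
  pts <- resample_polyline(trace$points, spacing = cfg$sample_spacing_px)
  n <- nrow(pts)
  arc <- polyline_arc(pts)
  half <- (cfg$transverse_px - 1L) %/% 2L
  if (cfg$transverse_mode == "normal") {
    i_prev <- c(1L, seq_len(n - 1L)); i_next <- c(2:n, n)
    tang <- pts[i_next, , drop = FALSE] - pts[i_prev, , drop = FALSE]
    len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
    unit <- cbind(tang[, 2L], -tang[, 1L]) / len
  } else {
    unit <- cbind(rep(1, n), rep(0, n))  # image column direction: rows +/- 1
  }
  lookup <- if (cfg$interp == "bilinear") interp_bilinear else interp_nearest
  acc <- matrix(NA_real_, n, 2L * half + 1L)
  for (j in seq(-half, half)) {
    r <- pts[, 1L] + j * unit[, 1L]
    c_ <- pts[, 2L] + j * unit[, 2L]
    v <- lookup(img, r, c_)
    inside <- r >= 0 & r <= nrow(img) - 1 & c_ >= 0 & c_ <= ncol(img) - 1
    v[!inside] <- NA_real_
    acc[, j + half + 1L] <- v
  }
  value <- rowMeans(acc, na.rm = TRUE)
  data.frame(arc_px = arc, s = if (arc[n] > 0) arc / arc[n] else arc,
             value = value)
}

#' Reduce path samples to a fixed number of arc-length bins
#'
#' A sample at normalized arc position s is assigned to bin
#' `min(floor(s * n_bins), n_bins - 1) + 1` (half-open bins, last bin
#' closed); each bin's value is the arithmetic mean of its samples. A
#' profile with any empty bin is rejected (`too_short_to_bin` error), never
#' silently interpolated.
#'
#' @param samples Data frame from [sample_path_intensity()] (needs `s` and
#'   `value`).
#' @param cfg A [profile_config()].
#' @param marker Marker name carried on the result.
#' @param background Background estimate stored with the profile (subtracted
#'   by downstream tip calls, not here).
#' @param keep_samples Keep the raw samples on the object.
#' @return A `binned_profile`: `marker`, `bin_means` (proximal to distal),
#'   `n_samples`, `background`, optionally `raw_samples`.
#' @export
bin_profile <- function(samples, cfg = profile_config(), marker = "marker",
                        background = 0, keep_samples = FALSE) {
  nb <- cfg$n_bins
  if (nrow(samples) < nb) {
    stopf("profile too short to bin: %d samples for %d bins",
          nrow(samples), nb, class = "ciliametrics_too_short_to_bin")
  }
  bin <- pmin(floor(samples$s * nb), nb - 1L) + 1L
  counts <- tabulate(bin, nbins = nb)
  if (any(counts == 0L)) {
    stopf("profile too short to bin: empty bin(s) %s",
          paste(which(counts == 0L), collapse = ","),
          class = "ciliametrics_too_short_to_bin")
  }
  means <- as.numeric(tapply(samples$value, factor(bin, levels = seq_len(nb)),
                             mean))
  structure(list(marker = marker, bin_means = means,
                 n_samples = nrow(samples), background = background,
                 raw_samples = if (keep_samples) samples else NULL),
            class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat(sprintf("<binned_profile '%s'> %d bins from %d samples (background %.3g)\n",
              x$marker, length(x$bin_means), x$n_samples, x$background))
  print(round(x$bin_means, 3))
  invisible(x)
}

#' Mean gray value over a pixel selection
#'
#' Sum of the gray values of all pixels in the selection divided by the
#' number of pixels — the standard densitometry unit.
#'
#' @param img A numeric matrix (or a `field_image` plus `channel`).
#' @param mask Logical matrix, or m x 2 matrix of 0-based (row, col) pixels.
#' @param channel Channel role when `img` is a `field_image`.
#' @return The mean gray value.
#' @export
mean_gray_value <- function(img, mask, channel = NULL) {
  if (inherits(img, "field_image")) {
    if (is.null(channel)) stopf("channel required with a field_image")
    img <- field_channel(img, channel)
  }
  vals <- if (is.logical(mask)) {
    if (!any(mask)) stopf("empty selection")
    img[mask]
  } else {
    if (nrow(mask) == 0L) stopf("empty selection")
    img[cbind(mask[, 1L] + 1L, mask[, 2L] + 1L)]
  }
  sum(vals) / length(vals)
}

# Measurement band for densitometry: the nearest-pixel rasterization of the
# trace path widened to the transverse sampling width. This is the analog of
# the selection a user draws along the cilium, and stays inside the stained
# structure instead of following the threshold halo.
trace_band_matrix <- function(trace, dims, transverse_px = 3L) {
  band <- matrix(FALSE, dims[1L], dims[2L])
  pts <- trace$points
  n <- nrow(pts)
  half <- (transverse_px - 1L) %/% 2L
  i_prev <- c(1L, seq_len(n - 1L)); i_next <- c(2:n, n)
  tang <- pts[i_next, , drop = FALSE] - pts[i_prev, , drop = FALSE]
  len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
  nrm <- cbind(tang[, 2L], -tang[, 1L]) / len
  # widen transversely only: the selection follows the path, it does not
  # extend past the path ends
  px <- do.call(rbind, lapply(seq(-half, half), function(o) {
    round(pts + o * nrm)
  }))
  px <- unique(px)
  keep <- px[, 1L] >= 0 & px[, 1L] < dims[1L] & px[, 2L] >= 0 & px[, 2L] < dims[2L]
  band[px[keep, , drop = FALSE] + 1L] <- TRUE
  band
}

# Background annulus for a trace: dilation of the measurement band by the
# outer radius minus dilation by the inner radius, excluding other cilia
# bodies and nuclei.
annulus_mask <- function(field, trace, cfg, exclude_masks = list()) {
  dims <- dim(field$channels[[1L]])
  band <- trace_band_matrix(trace, dims, cfg$transverse_px)
  ann <- dilate_disk(band, cfg$annulus_outer_px) &
    !dilate_disk(band, cfg$annulus_inner_px)
  for (ex in exclude_masks) ann <- ann & !ex
  if ("nucleus" %in% names(field$channels)) {
    nuc <- field$channels$nucleus
    ann <- ann & !(nuc > max(otsu_threshold(nuc), robust_threshold(nuc, 5)))
  }
  ann
}

# Background level for profiles and tip calls, matching background_mode.
profile_background <- function(field, trace, marker, cfg,
                               exclude_masks = list()) {
  img <- field_channel(field, marker)
  if (cfg$background_mode == "field_robust") {
    return(robust_background(img)$level)
  }
  ann <- annulus_mask(field, trace, cfg, exclude_masks)
  if (!any(ann)) return(robust_background(img)$level)
  mean_gray_value(img, ann)
}

#' Ciliary intensity normalized to surrounding fluorescence
#'
#' Mean gray value of the marker over the cilium selection (the traced path
#' widened to the transverse sampling width) divided by its mean gray value
#' over a surrounding annulus (dilation of the selection by the outer radius
#' minus dilation by the inner radius, excluding other cilia and nuclei,
#' clipped at image borders).
#'
#' @param field A `field_image`.
#' @param trace The cilium's trace.
#' @param marker Channel to measure.
#' @param cfg A [profile_config()].
#' @param exclude_masks Optional list of logical matrices (other cilia) to
#'   exclude from the annulus.
#' @return The intensity ratio.
#' @export
normalized_cilium_intensity <- function(field, trace, marker,
                                        cfg = profile_config(),
                                        exclude_masks = list()) {
  img <- field_channel(field, marker)
  dims <- dim(img)
  body <- trace_band_matrix(trace, dims, cfg$transverse_px)
  ann <- annulus_mask(field, trace, cfg, exclude_masks)
  if (!any(ann)) {
    stopf("background annulus is empty (cilium fills the frame?)",
          class = "ciliametrics_empty_annulus")
  }
  mean_gray_value(img, body) / mean_gray_value(img, ann)
}

#' Stack oriented profiles into a cilia x bins matrix
#'
#' Rows with ambiguous orientation are excluded (and counted in a message)
#' because their proximal-to-distal bin order is unknown.
#'
#' @param profiles List of `binned_profile`s for one marker.
#' @param ambiguous Logical vector flagging orientation-ambiguous entries.
#' @param marker Marker name (checked against each profile).
#' @return Numeric matrix, one row per cilium, `n_bins` columns, input order.
#' @export
profile_group_matrix <- function(profiles, ambiguous = NULL, marker = NULL) {
  if (is.null(ambiguous)) ambiguous <- rep(FALSE, length(profiles))
  keep <- which(!ambiguous)
  if (length(keep) == 0L) {
    stopf("no valid (oriented) profiles", class = "ciliametrics_no_profiles")
  }
  if (length(keep) < length(profiles)) {
    message(sprintf("profile_group_matrix: excluded %d orientation-ambiguous profile(s)",
                    length(profiles) - length(keep)))
  }
  if (!is.null(marker)) {
    bad <- vapply(profiles[keep], function(p) !identical(p$marker, marker), TRUE)
    if (any(bad)) stopf("profiles for different markers mixed in one matrix")
  }
  do.call(rbind, lapply(profiles[keep], function(p) p$bin_means))
}
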