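# Automated cilium detection and tracing, trace orientation, and nucleus
# counting. Replaces interactive segmentation with a reproducible pipeline:
# robust background (median + k * MAD) -> optional ridge enhancement ->
# threshold -> connected components -> skeletonize -> prune to the longest
# geodesic path -> smooth + subpixel refine -> resample at ~1 px arc spacing.

#' Detection configuration
#'
#' @param detection_channel `"auto"` (membrane when present, else axoneme;
#'   the membrane sheath is continuous even over fragmented axonemes) or an
#'   explicit channel role.
#' @param threshold_k Robust-background sigma multiplier (threshold =
#'   median + k * MAD).
#' @param min_length_um Minimum geodesic length of a reported trace.
#' @param max_width_um Maximum mean body width of a reported trace.
#' @param ridge_enhance Apply difference-of-Gaussians ridge enhancement
#'   before thresholding.
#' @param smooth_sigma Gaussian pre-smoothing sigma (px) applied to the
#'   detection channel before background estimation and thresholding;
#'   suppresses pixel noise so faint cilia survive a k-sigma threshold.
#' @param nucleus_min_area_um2 Minimum nucleus component area.
#' @param cell_assign_radius_um Search radius for basal-body puncta and for
#'   assigning cilia to nuclei.
#' @return A `detection_config` object.
#' @export
detection_config <- function(detection_channel = "auto",
                             threshold_k = 5,
                             min_length_um = 1.0,
                             max_width_um = 1.0,
                             ridge_enhance = FALSE,
                             smooth_sigma = 1.0,
                             nucleus_min_area_um2 = 8,
                             cell_assign_radius_um = 20) {
  if (threshold_k <= 0 || min_length_um <= 0 || max_width_um <= 0) {
    stopf("thresholds must be positive")
  }
  structure(list(detection_channel = detection_channel,
                 threshold_k = threshold_k, min_length_um = min_length_um,
                 max_width_um = max_width_um,
                 ridge_enhance = isTRUE(ridge_enhance),
                 smooth_sigma = smooth_sigma,
                 nucleus_min_area_um2 = nucleus_min_area_um2,
                 cell_assign_radius_um = cell_assign_radius_um),
            class = "detection_config")
}

resolve_detection_channel <- function(field, cfg) {
  if (!identical(cfg$detection_channel, "auto")) return(cfg$detection_channel)
  if ("membrane" %in% names(field$channels)) "membrane" else "axoneme"
}

# Longest geodesic path through a skeleton (logical matrix). Ties between
# equally long paths are broken by total image intensity along the path.
# Returns an n x 2 matrix of 0-based (row, col) pixel coordinates.
skeleton_longest_path <- function(skel, intensity = NULL) {
  pix <- which(skel, arr.ind = TRUE)
  n <- nrow(pix)
  if (n == 0L) return(NULL)
  if (n == 1L) return(pix - 1L)
  vid <- matrix(0L, nrow(skel), ncol(skel))
  vid[pix] <- seq_len(n)
  from <- integer(); to <- integer(); w <- numeric()
  for (s in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nb <- cbind(pix[, 1L] + s[1L], pix[, 2L] + s[2L])
    okb <- nb[, 1L] >= 1L & nb[, 1L] <= nrow(skel) &
      nb[, 2L] >= 1L & nb[, 2L] <= ncol(skel)
    okb[okb] <- skel[nb[okb, , drop = FALSE]]
    if (!any(okb)) next
    from <- c(from, vid[pix[okb, , drop = FALSE]])
    to <- c(to, vid[nb[okb, , drop = FALSE]])
    w <- c(w, rep(sqrt(sum(s^2)), sum(okb)))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$weight <- w
  }
  deg <- igraph::degree(g)
  ends <- which(deg <= 1L)
  if (length(ends) == 0L) ends <- 1L  # cycle: arbitrary anchor
  d1 <- igraph::distances(g, v = ends[1L])[1L, ]
  u <- which.max(ifelse(is.finite(d1), d1, -Inf))
  du <- igraph::distances(g, v = u)[1L, ]
  cand_ends <- if (length(ends) > 1L) ends else seq_len(n)
  dmax <- max(du[cand_ends][is.finite(du[cand_ends])])
  vs <- cand_ends[is.finite(du[cand_ends]) & du[cand_ends] >= dmax - 1e-9]
  best <- NULL; best_int <- -Inf
  for (v in vs) {
    sp <- igraph::shortest_paths(g, from = u, to = v)$vpath[[1L]]
    ids <- as.integer(sp)
    tot <- if (is.null(intensity)) 0 else sum(intensity[pix[ids, , drop = FALSE]])
    if (is.null(best) || tot > best_int) { best <- ids; best_int <- tot }
  }
  pix[best, , drop = FALSE] - 1L
}

# Extend both path ends outward along the local tangent to the half-maximum
# point of the (smoothed) detection image: thinning retracts the skeleton
# about half a structure width inside each tip, and for a step edge blurred
# by a symmetric PSF the half-max crossing sits at the true edge.
extend_to_half_max <- function(pts, det, bg_level, max_ext_px = 10,
                               step_px = 0.25) {
  n <- nrow(pts)
  if (n < 3L) return(pts)
  interior <- pts[pmax(1L, pmin(n, round(seq(0.3, 0.7, length.out = 5L) * n))), ,
                  drop = FALSE]
  amp <- stats::median(interp_bilinear(det, interior[, 1L], interior[, 2L]))
  target <- bg_level + 0.5 * (amp - bg_level)
  if (amp <= bg_level) return(pts)
  extend_one <- function(end, dir) {
    dir <- dir / sqrt(sum(dir^2))
    s <- seq(step_px, max_ext_px, by = step_px)
    v <- interp_bilinear(det, end[1L] + s * dir[1L], end[2L] + s * dir[2L])
    below <- which(v < target)
    reach <- if (length(below)) s[below[1L]] - step_px / 2 else 0
    if (reach <= 0) NULL else end + reach * dir
  }
  tail_n <- min(4L, n - 1L)
  new_start <- extend_one(pts[1L, ], pts[1L, ] - pts[1L + tail_n, ])
  new_end <- extend_one(pts[n, ], pts[n, ] - pts[n - tail_n, ])
  out <- pts
  if (!is.null(new_start)) out <- rbind(new_start, out)
  if (!is.null(new_end)) out <- rbind(out, new_end)
  out
}

# Subpixel centerline refinement: shift each point to the intensity-weighted
# centroid along the local normal.
refine_subpixel <- function(pts, img, half_width = 2) {
  n <- nrow(pts)
  if (n < 3L) return(pts)
  off <- seq(-half_width, half_width, by = 0.5)
  i_prev <- c(1L, seq_len(n - 1L)); i_next <- c(2:n, n)
  tang <- pts[i_next, , drop = FALSE] - pts[i_prev, , drop = FALSE]
  len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
  nrm <- cbind(tang[, 2L], -tang[, 1L]) / len
  num <- numeric(n); den <- numeric(n)
  for (o in off) {
    v <- interp_bilinear(img, pts[, 1L] + o * nrm[, 1L],
                         pts[, 2L] + o * nrm[, 2L])
    num <- num + o * v
    den <- den + v
  }
  shift <- ifelse(den > 0, num / den, 0)
  shift <- pmin(pmax(shift, -1), 1)
  pts + shift * nrm
}

#' Detect and trace cilia in a field
#'
#' @param field A `field_image` with the detection channel present.
#' @param cfg A [detection_config()].
#' @return A list of `cilium_trace` objects (unoriented; see
#'   [orient_trace()]), with disjoint masks, geodesic length >=
#'   `min_length_um` and mean width <= `max_width_um`.
#' @export
detect_cilia <- function(field, cfg = detection_config()) {
  ch_name <- resolve_detection_channel(field, cfg)
  img <- field_channel(field, ch_name)
  px <- field$pixel_size_um
  bg <- robust_background(img)
  if (bg$spread == 0 && bg$level >= max(img)) {
    stopf("detection channel is saturated or constant; cannot threshold",
          class = "ciliametrics_saturated")
  }
  det <- if (cfg$smooth_sigma > 0) gaussian_blur(img, cfg$smooth_sigma) else img
  if (cfg$ridge_enhance) {
    det <- gaussian_blur(det, 1) - gaussian_blur(det, 3)
    det <- det - min(det)
  }
  thr <- robust_threshold(det, cfg$threshold_k)
  det_bg <- robust_background(det)$level
  mask <- det > thr
  lab <- label_components(mask)
  k <- max(lab)
  min_len_px <- cfg$min_length_um / px
  traces <- list()
  pixall <- which(lab > 0L, arr.ind = TRUE)
  laball <- lab[pixall]
  for (comp in seq_len(k)) {
    cp <- pixall[laball == comp, , drop = FALSE]
    area <- nrow(cp)
    if (area < max(3, min_len_px)) next
    # work in a padded bounding box for speed
    r0 <- max(1L, min(cp[, 1L]) - 2L); c0 <- max(1L, min(cp[, 2L]) - 2L)
    r1 <- min(nrow(img), max(cp[, 1L]) + 2L)
    c1 <- min(ncol(img), max(cp[, 2L]) + 2L)
    cm <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    cm[cbind(cp[, 1L] - r0 + 1L, cp[, 2L] - c0 + 1L)] <- TRUE
    skel <- skeletonize(cm)
    path <- skeleton_longest_path(skel, intensity = det[r0:r1, c0:c1])
    if (is.null(path) || nrow(path) < 2L) next
    path <- path + rep(c(r0 - 1L, c0 - 1L), each = nrow(path))
    geo_len <- polyline_length(path)
    if (geo_len < 1) next
    # body width = twice the median centerline-to-boundary distance (robust
    # for short cilia, where area / length is dominated by the end caps)
    nb_bg <- !cm
    boundary <- cm & (shift_mat(nb_bg, 1L, 0L, TRUE) | shift_mat(nb_bg, -1L, 0L, TRUE) |
                        shift_mat(nb_bg, 0L, 1L, TRUE) | shift_mat(nb_bg, 0L, -1L, TRUE))
    bp <- which(boundary, arr.ind = TRUE)
    d2b <- vapply(seq_len(nrow(path)), function(ii) {
      sqrt(min((bp[, 1L] - 1 - path[ii, 1L] + r0 - 1L)^2 +
                 (bp[, 2L] - 1 - path[ii, 2L] + c0 - 1L)^2))
    }, 1.0)
    width <- 2 * stats::median(d2b)
    if (width * px > cfg$max_width_um) next
    pts <- smooth_polyline(path, window = 5L)
    pts <- refine_subpixel(pts, det)
    pts <- extend_to_half_max(pts, det, det_bg)
    pts <- resample_polyline(pts, spacing = 1.0)
    if (polyline_length(pts) * px < cfg$min_length_um) next
    mask_px <- cp - 1L
    traces[[length(traces) + 1L]] <-
      cilium_trace(pts, mask = mask_px, field_id = field$field_id,
                   cilium_id = length(traces) + 1L)
  }
  traces
}

#' Orient a trace proximal-to-distal using the basal-body channel
#'
#' The trace end nearer its basal-body punctum becomes the base (first
#' point). Puncta are local maxima of the (smoothed) basal-body channel
#' above a k-sigma robust threshold; among those within
#' `cell_assign_radius_um` of either end the nearest one is taken as the
#' cilium's own basal body (brightness breaks ties between equidistant
#' puncta). Without a basal-body channel, or without a punctum in range, the
#' trace is flagged orientation-ambiguous. An exact distance tie between the
#' two ends is broken toward the end with the higher integrated
#' basal-channel intensity in a 3-px disk.
#'
#' @param trace A `cilium_trace`.
#' @param field The `field_image` it came from.
#' @param cfg A [detection_config()].
#' @return The trace, oriented (base first) or flagged ambiguous.
#' @export
orient_trace <- function(trace, field, cfg = detection_config()) {
  if (!"basal_body" %in% names(field$channels)) {
    trace$oriented <- FALSE
    trace$orientation_ambiguous <- TRUE
    return(trace)
  }
  bb <- field$channels$basal_body
  px <- field$pixel_size_um
  bbs <- if (cfg$smooth_sigma > 0) gaussian_blur(bb, cfg$smooth_sigma) else bb
  peaks <- local_maxima(bbs, robust_threshold(bbs, cfg$threshold_k))
  endA <- trace$points[1L, ]
  endB <- trace$points[nrow(trace$points), ]
  radius_px <- cfg$cell_assign_radius_um / px
  if (nrow(peaks) == 0L) {
    trace$oriented <- FALSE
    trace$orientation_ambiguous <- TRUE
    return(trace)
  }
  dA <- sqrt((peaks[, 1L] - endA[1L])^2 + (peaks[, 2L] - endA[2L])^2)
  dB <- sqrt((peaks[, 1L] - endB[1L])^2 + (peaks[, 2L] - endB[2L])^2)
  in_range <- pmin(dA, dB) <= radius_px
  if (!any(in_range)) {
    trace$oriented <- FALSE
    trace$orientation_ambiguous <- TRUE
    return(trace)
  }
  cand <- which(in_range)
  dmin <- pmin(dA, dB)[cand]
  near <- cand[dmin <= min(dmin) + 1e-9]
  best <- near[which.max(bbs[peaks[near, , drop = FALSE] + 1L])]
  disk_sum <- function(end) {
    idx <- disk_indices(dim(bb), end, 3)
    sum(bb[idx])
  }
  base_is_A <- if (abs(dA[best] - dB[best]) < 1e-9) {
    disk_sum(endA) >= disk_sum(endB)
  } else dA[best] < dB[best]
  if (!base_is_A) {
    trace$points <- trace$points[rev(seq_len(nrow(trace$points))), , drop = FALSE]
  }
  trace$oriented <- TRUE
  trace$orientation_ambiguous <- FALSE
  trace
}

#' Count nuclei in the DAPI channel
#'
#' Otsu threshold, hole filling, and connected components with an area
#' filter; centroids feed cilium-to-cell assignment for the ciliation
#' fraction.
#'
#' @param field A `field_image` with a `nucleus` channel.
#' @param cfg A [detection_config()].
#' @return List with `count` and `centroids` (n x 2, 0-based row/col).
#' @export
count_nuclei <- function(field, cfg = detection_config()) {
  img <- field_channel(field, "nucleus")
  px <- field$pixel_size_um
  sm <- gaussian_blur(img, 1)
  # Otsu separates nuclei from background when nuclei exist; the robust
  # k-sigma floor keeps an empty (pure-noise) field from being split in half
  thr <- max(otsu_threshold(sm), robust_threshold(sm, cfg$threshold_k))
  mask <- fill_holes(sm > thr)
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) return(list(count = 0L, centroids = matrix(numeric(), 0L, 2L)))
  min_px <- cfg$nucleus_min_area_um2 / px^2
  pix <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[pix]
  areas <- tabulate(labs, nbins = k)
  keep <- which(areas >= min_px)
  cent <- t(vapply(keep, function(comp) {
    colMeans(pix[labs == comp, , drop = FALSE]) - 1
  }, numeric(2L)))
  list(count = length(keep), centroids = cent)
}
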