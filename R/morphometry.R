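# Per-cilium morphometry: arc length, distal fragment counting, per-field
# ciliation fractions, and tip-positivity calls on binned profiles.

#' Arc length of a trace in micrometres
#'
#' Sum of Euclidean distances between consecutive subpixel trace points,
#' scaled by the pixel size.
#'
#' @param trace A `cilium_trace`.
#' @param pixel_size_um Micrometres per pixel.
#' @return Length in micrometres.
#' @export
trace_length <- function(trace, pixel_size_um) {
  polyline_length(trace$points) * pixel_size_um
}

#' Count detached distal fragments near a cilium tip
#'
#' A fragment is a connected component that is above threshold in the
#' axoneme channel, above threshold in the membrane channel when
#' `require_membrane` (membrane-bounded fragments), disjoint from the main
#' trace mask, within `search_radius_um` of the distal tip, and at least
#' 2 px in area.
#'
#' @param field A `field_image` with an axoneme channel.
#' @param trace The main cilium trace (oriented if possible; for unoriented
#'   traces both ends are treated as candidate tips).
#' @param cfg A [detection_config()] (supplies `threshold_k`).
#' @param require_membrane Require fragments to be membrane-positive
#'   (default). Errors if no membrane channel is present; pass `FALSE` for
#'   axoneme-only stainings.
#' @param search_radius_um Distal search radius.
#' @param exclude_traces Other traces in the field whose bodies must not be
#'   mistaken for fragments.
#' @param max_area_um2 Upper area bound for a fragment component; components
#'   larger than this are treated as other structures, not fragments.
#' @return Integer fragment count.
#' @export
count_fragments <- function(field, trace, cfg = detection_config(),
                            require_membrane = TRUE, search_radius_um = 5,
                            exclude_traces = list(), max_area_um2 = 1.5) {
  cand <- fragment_candidates(field, cfg, c(list(trace), exclude_traces),
                              require_membrane)
  count_fragments_from(cand, trace, field$pixel_size_um, search_radius_um,
                       max_area_um2)
}

# Field-level preprocessing for fragment counting: threshold the (smoothed)
# axoneme channel, remove all cilium bodies, and label the remaining
# candidate components with their membrane status. Shared by every trace of
# a field.
fragment_candidates <- function(field, cfg, traces, require_membrane) {
  ax <- field_channel(field, "axoneme")
  if (require_membrane && !"membrane" %in% names(field$channels)) {
    stopf(paste("membrane channel required to confirm membrane-bounded",
                "fragments; pass require_membrane = FALSE for axoneme-only",
                "stainings"), class = "ciliametrics_missing_channel")
  }
  if (cfg$smooth_sigma > 0) ax <- gaussian_blur(ax, cfg$smooth_sigma)
  mask <- ax > robust_threshold(ax, cfg$threshold_k)
  main <- matrix(FALSE, nrow(ax), ncol(ax))
  for (tr in traces) main <- main | trace_mask_matrix(tr, dim(ax))
  # keep cilium bodies out of the component search; the margin covers the
  # threshold halo (pre-smoothing widens it) so body edges are never
  # mistaken for fragments, even when the trace mask is a thin manual path
  cand <- mask & !dilate_disk(main, 1.5 + 2 * cfg$smooth_sigma)
  lab <- label_components(cand)
  k <- max(lab)
  pix <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[pix]
  mem_ok <- rep(TRUE, k)
  if (require_membrane && k > 0L) {
    mem <- field$channels$membrane
    if (cfg$smooth_sigma > 0) mem <- gaussian_blur(mem, cfg$smooth_sigma)
    mem_thr <- robust_threshold(mem, cfg$threshold_k)
    mem_ok <- vapply(seq_len(k), function(comp) {
      mean(mem[pix[labs == comp, , drop = FALSE]]) > mem_thr
    }, TRUE)
  }
  list(pix = pix, labs = labs, k = k, mem_ok = mem_ok)
}

count_fragments_from <- function(cand, trace, px, search_radius_um,
                                 max_area_um2) {
  if (cand$k == 0L) return(0L)
  tips <- if (trace$oriented) {
    trace$points[nrow(trace$points), , drop = FALSE]
  } else {
    trace$points[c(1L, nrow(trace$points)), , drop = FALSE]
  }
  radius_px <- search_radius_um / px
  max_px <- max_area_um2 / px^2
  n_frag <- 0L
  for (comp in seq_len(cand$k)) {
    cp <- cand$pix[cand$labs == comp, , drop = FALSE]
    if (nrow(cp) < 2L || nrow(cp) > max_px) next
    d <- apply(tips, 1L, function(tp) {
      min(sqrt((cp[, 1L] - 1 - tp[1L])^2 + (cp[, 2L] - 1 - tp[2L])^2))
    })
    if (min(d) > radius_px) next
    if (!cand$mem_ok[comp]) next
    n_frag <- n_frag + 1L
  }
  n_frag
}

#' Per-field ciliation summary
#'
#' A nucleus is ciliated when at least one trace is assigned to it
#' (assignment: nearest nucleus centroid within `cell_assign_radius_um` of
#' either trace end); a nucleus with several assigned cilia is counted once.
#'
#' @param traces List of `cilium_trace`s for the field.
#' @param nuclei Result of [count_nuclei()] (or `NULL` when no nucleus
#'   channel exists: counts are still reported, the fraction is flagged
#'   undefined).
#' @param pixel_size_um Micrometres per pixel.
#' @param cfg A [detection_config()].
#' @param field_id Field identifier.
#' @return A `field_summary`: `n_nuclei`, `n_ciliated`, `ciliation_fraction`
#'   (NA when undefined), `n_traces`, `fraction_defined`.
#' @export
summarize_field <- function(traces, nuclei, pixel_size_um,
                            cfg = detection_config(), field_id = "field") {
  n_traces <- length(traces)
  if (is.null(nuclei) || nuclei$count == 0L) {
    return(structure(list(field_id = field_id, n_nuclei = if (is.null(nuclei)) NA_integer_ else 0L,
                          n_ciliated = NA_integer_, ciliation_fraction = NA_real_,
                          fraction_defined = FALSE, n_traces = n_traces),
                     class = "field_summary"))
  }
  cent <- nuclei$centroids
  radius_px <- cfg$cell_assign_radius_um / pixel_size_um
  assigned <- integer()
  for (tr in traces) {
    ends <- tr$points[c(1L, nrow(tr$points)), , drop = FALSE]
    d <- vapply(seq_len(nrow(cent)), function(i) {
      min(sqrt((ends[, 1L] - cent[i, 1L])^2 + (ends[, 2L] - cent[i, 2L])^2))
    }, 1.0)
    i <- which.min(d)
    if (d[i] <= radius_px) assigned <- c(assigned, i)
  }
  n_cil <- length(unique(assigned))
  structure(list(field_id = field_id, n_nuclei = nuclei$count,
                 n_ciliated = n_cil,
                 ciliation_fraction = n_cil / nuclei$count,
                 fraction_defined = TRUE, n_traces = n_traces),
            class = "field_summary")
}

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf("<field_summary '%s'> %s nuclei, %s ciliated (fraction %s), %d traces\n",
              x$field_id, x$n_nuclei, x$n_ciliated,
              if (x$fraction_defined) sprintf("%.3f", x$ciliation_fraction)
              else "undefined", x$n_traces))
  invisible(x)
}

#' Call a marker tip-positive from its binned profile
#'
#' TRUE when the mean background-subtracted intensity of the distal bin(s)
#' is at least `fold_threshold` times the mean of bins 1..(n_bins - 2)
#' (bins 1-8 of a ten-bin profile). For orientation-ambiguous profiles the
#' call is made in both orientations and reported positive only if both
#' agree; otherwise the call is NA (flagged).
#'
#' @param profile A `binned_profile` (see [bin_profile()]); its `background`
#'   field is subtracted.
#' @param fold_threshold Distal-over-shaft fold threshold.
#' @param distal_bins How many distal bins form the tip compartment.
#' @param orientation_ambiguous Whether the underlying trace orientation is
#'   unknown.
#' @return TRUE/FALSE, or NA when ambiguous orientations disagree.
#' @export
call_tip_positive <- function(profile, fold_threshold = 2.0, distal_bins = 1L,
                              orientation_ambiguous = FALSE) {
  b <- profile$bin_means - profile$background
  nb <- length(b)
  call_one <- function(v) {
    distal <- mean(v[(nb - distal_bins + 1L):nb])
    shaft <- mean(v[1L:(nb - 2L)])
    if (shaft <= 0) return(distal > 0)
    distal >= fold_threshold * shaft
  }
  fwd <- call_one(b)
  if (!orientation_ambiguous) return(fwd)
  rev_ <- call_one(rev(b))
  if (fwd == rev_) fwd else NA
}
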