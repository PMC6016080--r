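# End-to-end per-field quantification: detection, orientation, morphometry,
# profiling, and the per-field summary, assembled into the tables the
# comparison functions consume.

#' Quantify every cilium in a field
#'
#' Runs the full pipeline: detect and orient traces, measure lengths, count
#' distal fragments, compute background-normalized marker intensities,
#' binned profiles (raw and background-subtracted columns) and tip calls,
#' count nuclei, and summarize the ciliation fraction.
#'
#' @param field A `field_image`.
#' @param cfg A [detection_config()].
#' @param profile_cfg A [profile_config()].
#' @param markers Channels to profile; defaults to all marker channels.
#' @param require_membrane Passed to [count_fragments()]; defaults to TRUE
#'   when a membrane channel is present.
#' @param traces Optional pre-computed traces (e.g. from
#'   [read_manual_paths()]) to use instead of automated detection.
#' @return List with `records` (data frame, one row per cilium; stable
#'   column order), `profiles` (per-marker list of `binned_profile`s),
#'   `traces`, `summary` (a `field_summary`), and `nuclei`.
#' @export
quantify_field <- function(field, cfg = detection_config(),
                           profile_cfg = profile_config(),
                           markers = NULL,
                           require_membrane = "membrane" %in% names(field$channels),
                           traces = NULL) {
  field_channel(field, "axoneme")  # quantification requires the axoneme role
  if (is.null(traces)) traces <- detect_cilia(field, cfg)
  traces <- lapply(traces, orient_trace, field = field, cfg = cfg)
  if (is.null(markers)) markers <- marker_names(field)
  px <- field$pixel_size_um
  dims <- dim(field$channels[[1L]])
  all_masks <- lapply(traces, trace_mask_matrix, dims = dims)
  nuclei <- if ("nucleus" %in% names(field$channels)) {
    count_nuclei(field, cfg)
  } else NULL
  nb <- profile_cfg$n_bins
  frag_cand <- if (length(traces)) {
    fragment_candidates(field, cfg, traces, require_membrane)
  } else NULL
  nuc_excl <- if ("nucleus" %in% names(field$channels)) {
    nucch <- field$channels$nucleus
    nucch > max(otsu_threshold(nucch), robust_threshold(nucch, 5))
  } else NULL
  profiles <- stats::setNames(
    lapply(markers, function(m) vector("list", length(traces))), markers)
  rows <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    tr$cilium_id <- i
    frag <- count_fragments_from(frag_cand, tr, px, search_radius_um = 5,
                                 max_area_um2 = 1.5)
    row <- data.frame(field_id = field$field_id, cilium_id = i,
                      length_um = trace_length(tr, px),
                      fragment_count = frag, fragmented = frag > 0L,
                      orientation_ambiguous = tr$orientation_ambiguous)
    # measurement band and background annulus are marker-independent
    band <- trace_band_matrix(tr, dims, profile_cfg$transverse_px)
    ann <- dilate_disk(band, profile_cfg$annulus_outer_px) &
      !dilate_disk(band, profile_cfg$annulus_inner_px)
    for (ex in all_masks[-i]) ann <- ann & !ex
    if (!is.null(nuc_excl)) ann <- ann & !nuc_excl
    for (m in markers) {
      img <- field$channels[[m]]
      bgm <- if (profile_cfg$background_mode == "annulus" && any(ann)) {
        mean_gray_value(img, ann)
      } else robust_background(img)$level
      norm <- if (any(ann)) mean_gray_value(img, band) / bgm else NA_real_
      prof <- tryCatch({
        smp <- sample_path_intensity(field, tr, m, profile_cfg)
        bin_profile(smp, profile_cfg, marker = m, background = bgm)
      }, ciliametrics_too_short_to_bin = function(e) NULL)
      profiles[[m]][[i]] <- prof
      row[[paste0("norm_intensity_", m)]] <- norm
      tip <- if (is.null(prof)) NA else {
        call_tip_positive(prof,
                          orientation_ambiguous = tr$orientation_ambiguous)
      }
      row[[paste0("tip_positive_", m)]] <- tip
      bins <- if (is.null(prof)) rep(NA_real_, nb) else prof$bin_means
      for (b in seq_len(nb)) {
        row[[sprintf("%s_bin%02d", m, b)]] <- bins[b]
      }
      for (b in seq_len(nb)) {
        row[[sprintf("%s_bgsub_bin%02d", m, b)]] <- bins[b] - bgm
      }
    }
    rows[[i]] <- row
    traces[[i]] <- tr
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field_id = character(), cilium_id = integer(),
               length_um = numeric(), fragment_count = integer(),
               fragmented = logical(), orientation_ambiguous = logical())
  summary <- summarize_field(traces, nuclei, px, cfg,
                             field_id = field$field_id)
  list(records = records, profiles = profiles, traces = traces,
       summary = summary, nuclei = nuclei)
}

#' Warn when fields in one comparison differ in recorded bit depth
#'
#' Densitometry comparisons assume equal acquisition settings; the reader
#' can only screen the recorded value range, not verify exposure.
#'
#' @param fields List of `field_image`s.
#' @return Invisibly TRUE if consistent, FALSE (with a warning) otherwise.
#' @export
check_equal_settings <- function(fields) {
  sig <- vapply(fields, function(f) {
    s <- f$metadata$bit_depth_hash
    if (is.null(s)) NA_character_ else s
  }, "")
  sig <- sig[!is.na(sig)]
  if (length(unique(sig)) > 1L) {
    warning("fields in this comparison differ in recorded bit depth; ",
            "densitometry assumes equal acquisition settings")
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
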