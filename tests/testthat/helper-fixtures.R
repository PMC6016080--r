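# Shared fixtures: small constructed fields, noise presets, brute-force
# oracles kept independent of the implementation paths they check, and a
# truth-matching helper for simulated fields.

noise_off <- list(poisson = FALSE, gain = 1, read_sd = 0)

snr_noise <- function(snr) noise_for_snr(sim_params(seed = 1), snr)

# A one-channel field with a single straight horizontal bar of the given
# half-width, crisp (no blur) unless sigma > 0.
bar_field <- function(nr = 64, nc = 64, row = 32, c0 = 12, c1 = 52,
                      half_width = 1, amp = 300, bg = 100, sigma = 0,
                      role = "axoneme", pixel_size_um = 0.1) {
  img <- matrix(bg, nr, nc)
  img[(row - half_width):(row + half_width) + 1L, (c0:c1) + 1L] <- bg + amp
  if (sigma > 0) img <- ciliametrics:::gaussian_blur(img, sigma)
  ch <- list(img)
  names(ch) <- role
  field_image(ch, pixel_size_um, field_id = "bar")
}

# Straight horizontal trace through pixel row `row`, columns c0..c1.
bar_trace <- function(row = 32, c0 = 12, c1 = 52) {
  cilium_trace(cbind(rep(row, c1 - c0 + 1L), c0:c1), field_id = "bar")
}

# Brute-force path-sampling oracle: nearest-pixel lookups at unit transverse
# offsets, off-image offsets dropped. Written directly from the sampling
# contract, sharing no code with sample_path_intensity().
oracle_sample_path <- function(img, pts, transverse_px = 3L,
                               mode = c("normal", "literal_rows")) {
  mode <- match.arg(mode)
  n <- nrow(pts)
  half <- (transverse_px - 1L) %/% 2L
  vals <- numeric(n)
  for (i in seq_len(n)) {
    if (mode == "normal") {
      a <- if (i == 1L) 1L else i - 1L
      b <- if (i == n) n else i + 1L
      tang <- pts[b, ] - pts[a, ]
      tang <- tang / sqrt(sum(tang^2))
      unit <- c(tang[2L], -tang[1L])
    } else {
      unit <- c(1, 0)
    }
    acc <- c()
    for (o in seq(-half, half)) {
      r <- round(pts[i, 1L] + o * unit[1L])
      c_ <- round(pts[i, 2L] + o * unit[2L])
      if (r >= 0 && r <= nrow(img) - 1 && c_ >= 0 && c_ <= ncol(img) - 1) {
        acc <- c(acc, img[r + 1L, c_ + 1L])
      }
    }
    vals[i] <- mean(acc)
  }
  vals
}

# Brute-force bin-assignment oracle: floor every sample's normalized arc
# position independently.
oracle_bin_means <- function(s, values, n_bins = 10L) {
  bin <- pmin(floor(s * n_bins), n_bins - 1L) + 1L
  vapply(seq_len(n_bins), function(b) mean(values[bin == b]), 1.0)
}

# Match detected traces to ground-truth cilia 1:1 by endpoint distance
# (mean base+tip distance under the better of the two orientations).
# Returns a data frame with one row per detected trace.
match_traces <- function(traces, truth, max_dist_px = 3) {
  used <- rep(FALSE, nrow(truth))
  out <- data.frame(trace = seq_along(traces),
                    truth_row = rep(NA_integer_, length(traces)),
                    matched = rep(FALSE, length(traces)))
  for (i in seq_along(traces)) {
    pts <- traces[[i]]$points
    ends <- pts[c(1L, nrow(pts)), , drop = FALSE]
    for (j in seq_len(nrow(truth))) {
      if (used[j]) next
      d1 <- sqrt((truth$base_r[j] - ends[1, 1])^2 + (truth$base_c[j] - ends[1, 2])^2) +
        sqrt((truth$tip_r[j] - ends[2, 1])^2 + (truth$tip_c[j] - ends[2, 2])^2)
      d2 <- sqrt((truth$base_r[j] - ends[2, 1])^2 + (truth$base_c[j] - ends[2, 2])^2) +
        sqrt((truth$tip_r[j] - ends[1, 1])^2 + (truth$tip_c[j] - ends[1, 2])^2)
      if (min(d1, d2) / 2 < max_dist_px) {
        used[j] <- TRUE
        out$truth_row[i] <- j
        out$matched[i] <- TRUE
        break
      }
    }
  }
  attr(out, "n_missed") <- sum(!used)
  out
}
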