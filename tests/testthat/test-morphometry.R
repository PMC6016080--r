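# Morphometry: arc length, fragment counting, ciliation summaries, tip calls.

test_that("trace length is the calibrated sum of segment lengths", {
  pts <- cbind(rep(0, 51), 0:50)  # 51 collinear points, 1 px apart
  tr <- cilium_trace(pts)
  expect_equal(trace_length(tr, 0.1), 5.0, tolerance = 1e-12)
  tr2 <- cilium_trace(rbind(c(0, 0), c(1, 1)))
  expect_equal(trace_length(tr2, 1), sqrt(2), tolerance = 1e-9)
})

test_that("a continuous cilium has zero fragments; rendered fragments count", {
  p0 <- sim_params(seed = 301, n_cells = 2, ciliation_prob = 1,
                   fragment_prob = 0, noise = noise_off)
  sim0 <- simulate_field(p0)
  tr0 <- detect_cilia(sim0$field)
  for (i in seq_along(tr0)) {
    expect_equal(count_fragments(sim0$field, tr0[[i]],
                                 exclude_traces = tr0[-i]), 0L)
  }
  # force exactly two fragments, zero noise
  p2 <- sim_params(seed = 302, n_cells = 2, ciliation_prob = 1,
                   fragment_prob = 1,
                   fragment_count_probs = c(`2` = 1), noise = noise_off)
  sim2 <- simulate_field(p2)
  tr2 <- detect_cilia(sim2$field)
  m <- match_traces(tr2, sim2$truth$cilia)
  expect_true(any(m$matched))
  for (i in which(m$matched)) {
    o <- orient_trace(tr2[[i]], sim2$field)
    expect_equal(count_fragments(sim2$field, o, exclude_traces = tr2[-i]), 2L)
  }
})

test_that("membrane confirmation is required unless explicitly disabled", {
  f <- bar_field(sigma = 1)  # axoneme only
  tr <- bar_trace()
  expect_error(count_fragments(f, tr),
               class = "ciliametrics_missing_channel")
  expect_equal(count_fragments(f, tr, require_membrane = FALSE), 0L)
})

test_that("axoneme-only debris is invisible when membrane is required", {
  p <- sim_params(seed = 303, n_cells = 2, ciliation_prob = 1,
                  fragment_prob = 1, fragment_count_probs = c(`2` = 1),
                  dual_positive_fragments = FALSE, noise = noise_off)
  sim <- simulate_field(p)
  tr <- detect_cilia(sim$field)
  m <- match_traces(tr, sim$truth$cilia)
  for (i in which(m$matched)) {
    o <- orient_trace(tr[[i]], sim$field)
    expect_equal(count_fragments(sim$field, o, exclude_traces = tr[-i]), 0L)
    expect_equal(count_fragments(sim$field, o, exclude_traces = tr[-i],
                                 require_membrane = FALSE), 2L)
  }
})

test_that("field summaries assign cilia to nuclei and handle edge cases", {
  # constructed assignment: 10 nuclei, 6 cilia on 6 distinct nuclei
  cent <- cbind(seq(20, 200, by = 20), seq(20, 200, by = 20))
  nuclei <- list(count = 10L, centroids = cent)
  mk_tr <- function(r, c) cilium_trace(cbind(seq(r, r + 5), seq(c, c + 5)))
  traces <- lapply(1:6, function(i) mk_tr(cent[i, 1] + 4, cent[i, 2] + 4))
  fs <- summarize_field(traces, nuclei, pixel_size_um = 0.1)
  expect_equal(fs$n_ciliated, 6L)
  expect_equal(fs$ciliation_fraction, 0.6)
  # two cilia near the same nucleus count that nucleus once
  traces2 <- c(traces, list(mk_tr(cent[1, 1] - 9, cent[1, 2] - 9)))
  fs2 <- summarize_field(traces2, nuclei, pixel_size_um = 0.1)
  expect_equal(fs2$n_ciliated, 6L)
  # no nuclei: counts reported, fraction flagged undefined
  fs3 <- summarize_field(traces, NULL, pixel_size_um = 0.1)
  expect_false(fs3$fraction_defined)
  expect_true(is.na(fs3$ciliation_fraction))
  expect_equal(fs3$n_traces, 6L)
})

test_that("tip positivity follows the distal-over-shaft fold rule", {
  flat <- structure(list(marker = "m", bin_means = rep(5, 10), n_samples = 30,
                         background = 1), class = "binned_profile")
  expect_false(call_tip_positive(flat))
  bump <- flat
  bump$bin_means <- c(rep(4, 9), 10)  # distal 3x the background-subtracted shaft
  expect_true(call_tip_positive(bump))
  # ambiguous orientation: both-direction agreement required
  expect_false(call_tip_positive(flat, orientation_ambiguous = TRUE))
  expect_true(is.na(call_tip_positive(bump, orientation_ambiguous = TRUE)))
})

test_that("tip calls discriminate enriched from uniform markers at SNR 5", {
  mk <- list(tipm = marker_spec("tip_bump", amplitude = 2.5),
             unim = marker_spec("uniform"))
  tip_calls <- c(); uni_calls <- c()
  for (s in 1:6) {
    sim <- simulate_field(sim_params(seed = 950 + s, n_cells = 4,
                                     ciliation_prob = 1, length_mean_um = 5,
                                     length_sd_um = 1, marker_specs = mk,
                                     noise = snr_noise(5)))
    q <- quantify_field(sim$field)
    tip_calls <- c(tip_calls, q$records$tip_positive_tipm)
    uni_calls <- c(uni_calls, q$records$tip_positive_unim)
  }
  expect_gte(mean(tip_calls, na.rm = TRUE), 0.9)      # sensitivity
  expect_gte(1 - mean(uni_calls, na.rm = TRUE), 0.9)  # specificity
})

test_that("longer-cilia condition yields the right group-difference sign", {
  pa <- sim_params(seed = 500, length_mean_um = 2, ciliation_prob = 1)
  pb <- sim_params(seed = 501, length_mean_um = 4, ciliation_prob = 1)
  pair <- simulate_condition_pair(pa, pb, n_fields = 4)
  len <- function(set) unlist(lapply(set, function(s) {
    vapply(detect_cilia(s$field), trace_length, 1.0,
           pixel_size_um = s$field$pixel_size_um)
  }))
  la <- len(pair$a); lb <- len(pair$b)
  expect_gt(mean(lb), mean(la))
  expect_lt(t_test_unpaired(la, lb)$table$p_value, 0.05)
})
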