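# Automated detection: single-structure precision, null fields, multi-cilium
# matching, trace orientation, nucleus counting.

test_that("a noiseless straight cilium is traced end-to-end", {
  p <- sim_params(seed = 5, n_cells = 1, ciliation_prob = 1,
                  curvature_max = 1e-6, length_mean_um = 5,
                  length_sd_um = 1e-4, field_shape = c(192L, 192L),
                  noise = noise_off)
  sim <- simulate_field(p)
  tr <- detect_cilia(sim$field)
  expect_length(tr, 1L)
  m <- match_traces(tr, sim$truth$cilia, max_dist_px = 1)
  expect_true(all(m$matched))
  expect_equal(trace_length(tr[[1L]], 0.1), 5, tolerance = 0.02)
})

test_that("a pure-background field yields no traces at default threshold", {
  set.seed(99)
  img <- matrix(100 + rnorm(192 * 192, 0, 10), 192, 192)
  img <- pmax(img, 0)
  f <- field_image(list(axoneme = img), 0.1, "noisefield")
  expect_length(detect_cilia(f), 0L)
})

test_that("multiple cilia at SNR 5 are recovered 1:1 against truth", {
  n_tr <- 0L; n_truth <- 0L; n_matched <- 0L
  for (s in 1:5) {
    sim <- simulate_field(sim_params(seed = 400 + s, n_cells = 5,
                                     ciliation_prob = 1,
                                     length_mean_um = 4,
                                     noise = snr_noise(5)))
    tr <- detect_cilia(sim$field)
    m <- match_traces(tr, sim$truth$cilia)
    n_tr <- n_tr + length(tr)
    n_truth <- n_truth + nrow(sim$truth$cilia)
    n_matched <- n_matched + sum(m$matched)
  }
  expect_gte(n_matched / n_truth, 0.9)   # recall
  expect_gte(n_matched / n_tr, 0.9)      # precision
})

test_that("trace invariants hold on detected traces", {
  sim <- simulate_field(sim_params(seed = 61, noise = snr_noise(5)))
  for (tr in detect_cilia(sim$field)) {
    expect_gte(nrow(tr$points), 2L)
    steps <- sqrt(rowSums(diff(tr$points)^2))
    expect_lte(max(steps), sqrt(2) + 1e-6)
    key <- paste(tr$mask[, 1L], tr$mask[, 2L])
    rast <- unique(round(tr$points))
    expect_true(all(paste(rast[, 1L], rast[, 2L]) %in% key))
  }
})

test_that("orientation follows the basal-body punctum", {
  sim <- simulate_field(sim_params(seed = 21, n_cells = 3, ciliation_prob = 1,
                                   noise = snr_noise(8)))
  tr <- detect_cilia(sim$field)
  m <- match_traces(tr, sim$truth$cilia)
  for (i in which(m$matched)) {
    o <- orient_trace(tr[[i]], sim$field)
    expect_true(o$oriented)
    j <- m$truth_row[i]
    ends <- o$points[c(1L, nrow(o$points)), ]
    d_base_first <- sqrt(sum((ends[1L, ] - c(sim$truth$cilia$base_r[j],
                                             sim$truth$cilia$base_c[j]))^2))
    d_base_last <- sqrt(sum((ends[2L, ] - c(sim$truth$cilia$base_r[j],
                                            sim$truth$cilia$base_c[j]))^2))
    expect_lt(d_base_first, d_base_last)
  }
})

test_that("orientation is flagged ambiguous without basal-body evidence", {
  f <- bar_field(sigma = 1)
  tr <- orient_trace(bar_trace(), f)
  expect_false(tr$oriented)
  expect_true(tr$orientation_ambiguous)
})

test_that("an equidistant punctum tie breaks toward the brighter end", {
  # punctum exactly equidistant from both ends of a horizontal bar, but a
  # second dimmer blob sits at the right end: integrated 3-px intensity wins
  nr <- 41; nc <- 61
  bb <- matrix(10, nr, nc)
  bb[31, 31] <- 500           # equidistant from (20,10) and (20,50)
  bb[21, 51] <- 80            # extra basal signal at end B
  ax <- matrix(100, nr, nc); ax[21, 11:51] <- 400
  f <- field_image(list(axoneme = ax, basal_body = bb), 0.1, "tie")
  tr <- cilium_trace(cbind(rep(20, 41), 10:50), field_id = "tie")
  o <- orient_trace(tr, f)
  expect_true(o$oriented)
  expect_equal(o$points[1L, ], c(20, 50))  # base = brighter end B
})

test_that("nuclei are counted with area filtering and empty-field nulls", {
  # constructed: 10 disjoint disks
  img <- matrix(50, 200, 200)
  centers <- expand.grid(r = c(30, 100, 170), c = c(30, 100, 170))[1:9, ]
  centers <- rbind(centers, data.frame(r = 135, c = 135))
  for (k in seq_len(nrow(centers))) {
    idx <- ciliametrics:::disk_indices(c(200, 200),
                                       c(centers$r[k], centers$c[k]), 17)
    img[idx] <- 250
  }
  f <- field_image(list(axoneme = matrix(50, 200, 200), nucleus = img), 0.1)
  got <- count_nuclei(f)
  expect_equal(got$count, 10L)
  expect_equal(nrow(got$centroids), 10L)
  # empty noisy field
  set.seed(4)
  empty <- field_image(list(axoneme = matrix(50, 128, 128),
                            nucleus = pmax(matrix(50 + rnorm(128^2, 0, 8),
                                                  128, 128), 0)), 0.1)
  expect_equal(count_nuclei(empty)$count, 0L)
  # simulated fields at density: within 2% of truth
  n_det <- 0L; n_true <- 0L
  for (s in 1:10) {
    sim <- simulate_field(sim_params(seed = 800 + s, noise = snr_noise(5)))
    n_det <- n_det + count_nuclei(sim$field)$count
    n_true <- n_true + nrow(sim$truth$cells)
  }
  expect_lte(abs(n_det - n_true) / n_true, 0.02)
})

test_that("missing channels raise classed errors", {
  f <- bar_field(role = "membrane")
  expect_error(count_nuclei(f), class = "ciliametrics_missing_channel")
  expect_error(detect_cilia(field_image(list(axoneme = matrix(1, 8, 8)), 0.1),
                            detection_config(detection_channel = "membrane")),
               class = "ciliametrics_missing_channel")
})
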