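# Simulator: determinism, truth-image consistency, stated-world behaviour.

test_that("identical parameters give bit-identical fields and truth", {
  p <- sim_params(seed = 17, fragment_prob = 0.5,
                  marker_specs = list(M = marker_spec("tip_bump")))
  a <- simulate_field(p)
  b <- simulate_field(p)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth$cilia, b$truth$cilia)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("a single straight noiseless cilium renders with exact truth", {
  p <- sim_params(seed = 5, n_cells = 1, ciliation_prob = 1,
                  curvature_max = 1e-6, length_mean_um = 5,
                  length_sd_um = 1e-4, field_shape = c(192L, 192L),
                  noise = noise_off)
  sim <- simulate_field(p)
  expect_equal(nrow(sim$truth$cilia), 1L)
  expect_equal(sim$truth$cilia$length_um, 5, tolerance = 1e-3)
  # true arc length equals a numeric re-integration of the control points
  ctrl <- sim$truth$control_points[[1L]]
  t <- seq(0, 1, length.out = 4001)
  B <- cbind((1 - t)^2 * ctrl[1, 1] + 2 * t * (1 - t) * ctrl[2, 1] + t^2 * ctrl[3, 1],
             (1 - t)^2 * ctrl[1, 2] + 2 * t * (1 - t) * ctrl[2, 2] + t^2 * ctrl[3, 2])
  num_len <- sum(sqrt(rowSums(diff(B)^2))) * p$pixel_size_um
  expect_equal(sim$truth$cilia$length_um, num_len, tolerance = 1e-6)
  # exactly one connected axoneme component in the noiseless rendered mask
  ax <- sim$truth$ideal$axoneme
  comp <- ciliametrics:::label_components(ax > p$background_level[["axoneme"]])
  expect_equal(max(comp), 1L)
})

test_that("fragment_prob = 0 gives zero true fragments everywhere", {
  sim <- simulate_field(sim_params(seed = 23, fragment_prob = 0))
  expect_true(all(sim$truth$cilia$n_fragments == 0L))
})

test_that("noiseless axoneme mask components equal cilia plus fragments", {
  p <- sim_params(seed = 31, n_cells = 4, ciliation_prob = 1,
                  fragment_prob = 1, noise = noise_off)
  sim <- simulate_field(p)
  ax <- sim$truth$ideal$axoneme
  comp <- ciliametrics:::label_components(ax > p$background_level[["axoneme"]])
  expect_equal(max(comp),
               nrow(sim$truth$cilia) + sum(sim$truth$cilia$n_fragments))
})

test_that("ciliated count over 200 cells stays in the binomial 99% band", {
  # 99% interval for Binomial(200, 0.6), computed from qbinom
  lo <- qbinom(0.005, 200, 0.6)
  hi <- qbinom(0.995, 200, 0.6)
  n_cil <- 0L; n_cells <- 0L
  for (s in 1:34) {
    sim <- simulate_field(sim_params(seed = 2200 + s))
    n_cil <- n_cil + sim$truth$n_ciliated
    n_cells <- n_cells + nrow(sim$truth$cells)
  }
  frac_expected <- (n_cil / n_cells) * 200
  expect_gte(frac_expected, lo)
  expect_lte(frac_expected, hi)
})

test_that("rendered noiseless image equals background + blurred structures", {
  p <- sim_params(seed = 9, n_cells = 2, field_shape = c(160L, 160L),
                  noise = noise_off)
  sim <- simulate_field(p)
  for (ch in names(sim$field$channels)) {
    expect_equal(sim$field$channels[[ch]],
                 ciliametrics:::gaussian_blur(sim$truth$ideal[[ch]],
                                              p$psf_sigma_px),
                 tolerance = 1e-9)
  }
})

test_that("parameter validation rejects invalid stated worlds", {
  expect_error(sim_params(), "seed")
  expect_error(sim_params(seed = 1, ciliation_prob = 1.2), "probabilities")
  expect_error(sim_params(seed = 1, length_mean_um = -1), "positive support")
  expect_error(sim_params(seed = 1, fragment_gap_um = 0.05), "fragment_gap_um")
  expect_error(
    simulate_field(sim_params(seed = 1, field_shape = c(40L, 40L),
                              n_cells = 16L)),
    class = "ciliametrics_placement_error")
})

test_that("condition pairs are deterministic and handle the empty case", {
  pa <- sim_params(seed = 101)
  pb <- sim_params(seed = 101)
  pair <- simulate_condition_pair(pa, pb, n_fields = 2)
  expect_identical(pair$a[[1L]]$field$channels, pair$b[[1L]]$field$channels)
  expect_identical(pair$a[[2L]]$truth$cilia, pair$b[[2L]]$truth$cilia)
  empty <- simulate_condition_pair(pa, sim_params(seed = 7), n_fields = 0)
  expect_length(empty$a, 0L)
  expect_length(empty$b, 0L)
  # different seeds give different fields
  pair2 <- simulate_condition_pair(pa, sim_params(seed = 999), n_fields = 1)
  expect_false(identical(pair2$a[[1L]]$field$channels,
                         pair2$b[[1L]]$field$channels))
})

test_that("ground truth writes per-cilium CSV and per-field JSON", {
  sim <- simulate_field(sim_params(seed = 55, fragment_prob = 0.5))
  dir <- withr::local_tempdir()
  paths <- write_ground_truth(sim$truth, dir)
  back <- read.csv(paths$cilia_csv)
  expect_equal(nrow(back), nrow(sim$truth$cilia))
  expect_equal(back$length_um, sim$truth$cilia$length_um, tolerance = 1e-12)
  js <- jsonlite::fromJSON(paths$field_json)
  expect_equal(js$n_ciliated, sim$truth$n_ciliated)
})
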