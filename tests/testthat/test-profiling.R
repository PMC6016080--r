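# Intensity profiling: transverse sampling, arc-length binning, densitometry,
# background normalization — checked against independent brute-force oracles.

test_that("uniform images sample to the uniform value in both modes", {
  f <- bar_field()  # content irrelevant; replace with constant
  f$channels$axoneme[] <- 42
  tr <- bar_trace()
  for (mode in c("normal", "literal_rows")) {
    s <- sample_path_intensity(f, tr, "axoneme",
                               profile_config(transverse_mode = mode))
    expect_true(all(abs(s$value - 42) < 1e-12))
  }
})

test_that("above/on/below rows average as stated for a horizontal path", {
  img <- matrix(0, 16, 40)
  img[9, ] <- 1; img[10, ] <- 2; img[11, ] <- 3  # rows above/on/below (1-based)
  f <- field_image(list(axoneme = img), 0.1)
  tr <- cilium_trace(cbind(rep(9, 30), 5:34))     # 0-based row 9 = on-path
  for (mode in c("normal", "literal_rows")) {
    s <- sample_path_intensity(f, tr, "axoneme",
                               profile_config(transverse_mode = mode))
    expect_true(all(abs(s$value - 2) < 1e-12))
  }
})

test_that("diagonal paths match the brute-force nearest-pixel oracle", {
  set.seed(21)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  f <- field_image(list(axoneme = img), 0.1)
  pts <- cbind(seq(10, 40, by = sqrt(0.5)), seq(10, 40, by = sqrt(0.5)))
  tr <- cilium_trace(pts)
  for (mode in c("normal", "literal_rows")) {
    cfg <- profile_config(transverse_mode = mode, interp = "nearest")
    got <- sample_path_intensity(f, tr, "axoneme", cfg)
    want <- oracle_sample_path(img, tr$points, 3L, mode)
    expect_equal(got$value, want, tolerance = 1e-12)
  }
  # the two modes genuinely differ on a 45-degree path over a gradient
  grad <- outer(1:64, 1:64, function(r, c) 10 * r)
  fg <- field_image(list(axoneme = grad), 0.1)
  sn <- sample_path_intensity(fg, tr, "axoneme",
                              profile_config(transverse_mode = "normal",
                                             interp = "nearest"))
  sl <- sample_path_intensity(fg, tr, "axoneme",
                              profile_config(transverse_mode = "literal_rows",
                                             interp = "nearest"))
  expect_false(isTRUE(all.equal(sn$value, sl$value)))
})

test_that("the 20-sample worked example bins to 1.5, 3.5, ..., 19.5", {
  samples <- data.frame(s = seq(0, 1, length.out = 20), value = 1:20)
  prof <- bin_profile(samples)
  expect_equal(prof$bin_means, seq(1.5, 19.5, by = 2), tolerance = 1e-12)
  # constants are preserved
  const <- data.frame(s = seq(0, 1, length.out = 25), value = rep(3.7, 25))
  expect_true(all(abs(bin_profile(const)$bin_means - 3.7) < 1e-12))
})

test_that("bin assignment matches the floor oracle for awkward counts", {
  set.seed(31)
  for (n in c(23, 10, 37, 101)) {
    v <- runif(n)
    s <- seq(0, 1, length.out = n)
    got <- bin_profile(data.frame(s = s, value = v))$bin_means
    expect_equal(got, oracle_bin_means(s, v), tolerance = 1e-12)
  }
})

test_that("profiles too short to fill every bin are rejected, not padded", {
  expect_error(bin_profile(data.frame(s = seq(0, 1, length.out = 5),
                                      value = 1:5)),
               class = "ciliametrics_too_short_to_bin")
  # enough samples but a gap in arc positions
  s <- c(seq(0, 0.4, length.out = 8), seq(0.6, 1, length.out = 8))
  expect_error(bin_profile(data.frame(s = s, value = 1:16)),
               class = "ciliametrics_too_short_to_bin")
})

test_that("mean of bins equals mean of samples when counts divide evenly", {
  set.seed(41)
  for (m in c(2, 5, 13)) {
    n <- 10 * m
    v <- rnorm(n, 100, 20)
    prof <- bin_profile(data.frame(s = seq(0, 1, length.out = n), value = v))
    expect_lt(abs(mean(prof$bin_means) - mean(v)) / abs(mean(v)), 1e-9)
  }
})

test_that("reversing a trace reverses the bins exactly", {
  set.seed(51)
  n <- 40
  v <- runif(n)
  s <- seq(0, 1, length.out = n)
  fwd <- bin_profile(data.frame(s = s, value = v))$bin_means
  rev_ <- bin_profile(data.frame(s = s, value = rev(v)))$bin_means
  expect_equal(rev_, rev(fwd), tolerance = 1e-12)
})

test_that("mean gray value is exactly sum over count", {
  img <- matrix(0, 6, 6)
  img[1, 1] <- 1; img[2, 2] <- 2; img[3, 3] <- 3; img[4, 4] <- 4
  mask <- cbind(0:3, 0:3)  # 0-based coordinates of the four pixels
  expect_equal(mean_gray_value(img, mask), 2.5)
  # uniform selection
  u <- matrix(7.7, 5, 5)
  expect_equal(mean_gray_value(u, u > 0), 7.7)
  # random mask on a seeded random image vs an independent summation
  set.seed(61)
  ri <- matrix(rnorm(400), 20, 20)
  rm <- matrix(runif(400) < 0.3, 20, 20)
  acc <- 0; cnt <- 0
  for (i in 1:20) for (j in 1:20) if (rm[i, j]) { acc <- acc + ri[i, j]; cnt <- cnt + 1 }
  expect_equal(mean_gray_value(ri, rm), acc / cnt, tolerance = 1e-12)
  expect_error(mean_gray_value(ri, matrix(FALSE, 20, 20)), "empty")
})

test_that("normalization is 1 on uniform images and 2 for a 2x bar", {
  f <- bar_field()
  f$channels$axoneme[] <- 55
  tr <- bar_trace()
  expect_equal(normalized_cilium_intensity(f, tr, "axoneme"), 1.0,
               tolerance = 1e-12)
  f2 <- bar_field(amp = 100, bg = 100, half_width = 2, sigma = 0)
  expect_equal(normalized_cilium_intensity(f2, bar_trace(), "axoneme"), 2.0,
               tolerance = 1e-9)
})

test_that("profile matrices stack oriented records and reject all-ambiguous", {
  mk_prof <- function(v) structure(list(marker = "m", bin_means = v,
                                        n_samples = 30, background = 0),
                                   class = "binned_profile")
  profs <- lapply(1:3, function(i) mk_prof(rep(i, 10)))
  m <- profile_group_matrix(profs)
  expect_equal(dim(m), c(3L, 10L))
  expect_equal(m[, 1L], 1:3 * 1.0)
  expect_message(
    m2 <- profile_group_matrix(profs, ambiguous = c(FALSE, TRUE, FALSE)),
    "excluded 1")
  expect_equal(nrow(m2), 2L)
  expect_error(profile_group_matrix(profs, ambiguous = rep(TRUE, 3)),
               class = "ciliametrics_no_profiles")
})

test_that("tip-enriched vs uniform group differences land in distal bins", {
  mk <- list(tipm = marker_spec("tip_bump", amplitude = 2.5),
             unim = marker_spec("uniform"))
  profs_t <- list(); profs_u <- list()
  for (s in 1:4) {
    sim <- simulate_field(sim_params(seed = 970 + s, n_cells = 4,
                                     ciliation_prob = 1, length_mean_um = 5,
                                     marker_specs = mk, noise = snr_noise(5)))
    q <- quantify_field(sim$field)
    keep <- !vapply(q$profiles$tipm, is.null, TRUE)
    profs_t <- c(profs_t, q$profiles$tipm[keep])
    profs_u <- c(profs_u, q$profiles$unim[keep])
  }
  mt <- profile_group_matrix(profs_t)
  mu <- profile_group_matrix(profs_u)
  delta <- abs(colMeans(mt) - colMeans(mu))
  expect_true(which.max(delta) %in% 9:10)
})
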