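# Synthetic multi-channel cilia fields with full ground truth.
#
# The simulator emulates the staining geometry of a ciliated-cell
# immunofluorescence field: an acetylated-tubulin-like axoneme channel and an
# Arl13B-like membrane channel co-localized along each cilium (the membrane
# sheath slightly wider than the axoneme), a gamma-tubulin-like basal-body
# punctum at each cilium base, DAPI-like nuclear disks, optional marker
# channels with uniform or tip/base-enriched axial profiles, and optional
# detached distal fragments positive in BOTH axoneme and membrane channels
# (membrane-bounded fragments). Structures are rendered crisply, blurred by a
# Gaussian PSF, then degraded by Poisson shot noise and Gaussian read noise.

#' Specify a marker's axial enrichment model
#'
#' Axial profile along normalized arc position s in [0, 1] (0 = base,
#' 1 = tip): `uniform` is flat; `tip_bump` / `base_bump` add a plateau of
#' the given fold-amplitude over `position_frac` +/- `width_frac` (the
#' defaults enrich the distal 10 percent of arc length; the PSF supplies the
#' physical roll-off when the marker is rendered).
#'
#' @param type One of "uniform", "tip_bump", "base_bump".
#' @param amplitude Fold-enrichment over the uniform baseline attained on
#'   the plateau (>= 1).
#' @param position_frac Plateau center as a fraction of arc length.
#' @param width_frac Plateau half-width as a fraction of arc length.
#' @return A `marker_spec` list.
#' @export
marker_spec <- function(type = c("uniform", "tip_bump", "base_bump"),
                        amplitude = 2.5, position_frac = NULL,
                        width_frac = 0.05) {
  type <- match.arg(type)
  if (is.null(position_frac)) {
    position_frac <- switch(type, uniform = NA_real_, tip_bump = 0.95,
                            base_bump = 0.05)
  }
  if (type != "uniform" && (amplitude < 1 || width_frac <= 0)) {
    stopf("bump markers need amplitude >= 1 and width_frac > 0")
  }
  structure(list(type = type, amplitude = amplitude,
                 position_frac = position_frac, width_frac = width_frac),
            class = "marker_spec")
}

# Axial profile function f(s) (fold over baseline) for a marker spec.
marker_profile_fun <- function(spec) {
  if (spec$type == "uniform") return(function(s) rep(1, length(s)))
  a <- spec$amplitude; p <- spec$position_frac; w <- spec$width_frac
  function(s) 1 + (a - 1) * (abs(s - p) <= w)
}

#' Simulation parameters for one condition
#'
#' Defaults describe a parental-like line imaged at high magnification:
#' 38.4 x 38.4 um fields (384 px at 0.1 um/px, a stated convention since
#' acquisition metadata gives the objective NA but not the pixel size), six
#' cells per field, ciliation probability 0.6, lognormal cilium lengths with
#' mean 3 um and SD 1 um, gentle curvature, no fragmentation, Poisson +
#' Gaussian camera noise. A resistant-like condition is obtained by raising
#' `ciliation_prob`, `length_mean_um` and `fragment_prob`.
#'
#' @param seed Mandatory RNG seed (integer).
#' @param field_shape (rows, cols) in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param n_cells Cells placed per field.
#' @param ciliation_prob Probability a cell carries a cilium.
#' @param length_mean_um,length_sd_um Mean and SD (natural scale, um) of the
#'   lognormal cilium length distribution.
#' @param curvature_max Maximum unsigned curvature of the centerline (1/um).
#' @param fragment_prob Probability a cilium sheds detached distal fragments.
#' @param fragment_count_probs Named probabilities for the fragment count
#'   (names are counts).
#' @param fragment_gap_um Edge displacement of the first fragment from the
#'   tip; must exceed `psf_sigma_px * pixel_size_um` so fragments are
#'   resolvable at zero noise.
#' @param fragment_len_um,fragment_spacing_um Fragment segment length and
#'   center-to-center spacing of successive fragments.
#' @param dual_positive_fragments Render fragments in both axoneme and
#'   membrane channels (membrane-bounded, the default); `FALSE` renders
#'   axoneme-only debris as distractors.
#' @param marker_specs Named list of [marker_spec()]s; each adds a channel.
#' @param channel_intensities Named foreground amplitudes; missing marker
#'   entries default to 200.
#' @param background_level Scalar or per-channel named background offset.
#' @param psf_sigma_px Gaussian PSF sigma in pixels.
#' @param noise List with `poisson` (logical), `gain` (photons per intensity
#'   unit) and `read_sd` (Gaussian read noise SD).
#' @param nucleus_radius_um,axoneme_width_um Structural radii.
#' @return A validated `sim_params` object.
#' @export
sim_params <- function(seed,
                       field_shape = c(384L, 384L),
                       pixel_size_um = 0.1,
                       n_cells = 6L,
                       ciliation_prob = 0.6,
                       length_mean_um = 3,
                       length_sd_um = 1,
                       curvature_max = 0.3,
                       fragment_prob = 0,
                       fragment_count_probs = c(`1` = 1, `2` = 1, `3` = 1) / 3,
                       fragment_gap_um = 1.0,
                       fragment_len_um = 0.4,
                       fragment_spacing_um = 1.0,
                       dual_positive_fragments = TRUE,
                       marker_specs = list(),
                       channel_intensities = c(axoneme = 300, membrane = 300,
                                               basal_body = 500, nucleus = 200),
                       background_level = 100,
                       psf_sigma_px = 1.0,
                       noise = list(poisson = TRUE, gain = 1, read_sd = 10),
                       nucleus_radius_um = 2.5,
                       axoneme_width_um = 0.25) {
  if (missing(seed) || !is_scalar_num(seed)) stopf("seed is mandatory")
  probs <- c(ciliation_prob, fragment_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (length_mean_um <= 0 || length_sd_um <= 0) {
    stopf("length distribution must have positive support")
  }
  if (fragment_gap_um <= psf_sigma_px * pixel_size_um) {
    stopf("fragment_gap_um must exceed psf_sigma_px * pixel_size_um")
  }
  if (!is.null(names(marker_specs)) || length(marker_specs) == 0L) {
    for (m in names(marker_specs)) {
      if (!inherits(marker_specs[[m]], "marker_spec")) {
        stopf("marker_specs[['%s']] must be a marker_spec", m)
      }
      if (!m %in% names(channel_intensities)) {
        channel_intensities[m] <- 200
      }
    }
  } else stopf("marker_specs must be a named list")
  roles <- c("axoneme", "membrane", "basal_body", "nucleus", names(marker_specs))
  bg <- if (length(background_level) == 1L) {
    stats::setNames(rep(background_level, length(roles)), roles)
  } else background_level
  if (!all(roles %in% names(bg))) stopf("background_level missing channels")
  p <- list(seed = as.integer(seed), field_shape = as.integer(field_shape),
            pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
            ciliation_prob = ciliation_prob, length_mean_um = length_mean_um,
            length_sd_um = length_sd_um, curvature_max = curvature_max,
            fragment_prob = fragment_prob,
            fragment_count_probs = fragment_count_probs,
            fragment_gap_um = fragment_gap_um,
            fragment_len_um = fragment_len_um,
            fragment_spacing_um = fragment_spacing_um,
            dual_positive_fragments = isTRUE(dual_positive_fragments),
            marker_specs = marker_specs,
            channel_intensities = channel_intensities,
            background_level = bg[roles], psf_sigma_px = psf_sigma_px,
            noise = noise, nucleus_radius_um = nucleus_radius_um,
            axoneme_width_um = axoneme_width_um)
  structure(p, class = "sim_params")
}

#' Noise settings that realize a target SNR
#'
#' SNR is defined as foreground amplitude over the background noise SD
#' (shot noise at the background level plus read noise).
#'
#' @param params A `sim_params`.
#' @param snr Target signal-to-noise ratio (amplitude of the axoneme channel).
#' @param poisson Keep Poisson shot noise on (default) or off.
#' @return A noise list to pass as `noise` to [sim_params()].
#' @export
noise_for_snr <- function(params, snr, poisson = TRUE) {
  a <- params$channel_intensities[["axoneme"]]
  b <- params$background_level[["axoneme"]]
  gain <- params$noise$gain
  shot_var <- if (poisson) b / gain else 0
  target_var <- (a / snr)^2
  if (target_var < shot_var) {
    stopf("shot noise alone exceeds the requested SNR; raise snr or lower gain")
  }
  list(poisson = poisson, gain = gain, read_sd = sqrt(target_var - shot_var))
}

# Quadratic Bezier sampled at arc-uniform positions. Returns a list with
# points (n x 2), arc positions, tangent angles, and the total length from a
# dense numeric integration.
bezier_arc <- function(P0, P1, P2, spacing_px = 0.2, n_dense = 2001L) {
  t <- seq(0, 1, length.out = n_dense)
  B <- cbind((1 - t)^2 * P0[1L] + 2 * t * (1 - t) * P1[1L] + t^2 * P2[1L],
             (1 - t)^2 * P0[2L] + 2 * t * (1 - t) * P1[2L] + t^2 * P2[2L])
  arc <- polyline_arc(B)
  total <- arc[length(arc)]
  n_out <- max(2L, ceiling(total / spacing_px) + 1L)
  s_out <- seq(0, total, length.out = n_out)
  r <- stats::approx(arc, B[, 1L], xout = s_out)$y
  c_ <- stats::approx(arc, B[, 2L], xout = s_out)$y
  pts <- cbind(r, c_, deparse.level = 0)
  d <- diff(pts)
  ang <- atan2(d[, 1L], d[, 2L])
  list(points = pts, arc = s_out, total = total, tangent = c(ang, ang[length(ang)]))
}

# Build a quadratic Bezier of exact arc length L (px) starting at `base`
# heading at angle theta0 with signed bend alpha; control legs are rescaled
# about P0 until the numerically integrated length matches L.
make_cilium_curve <- function(base, theta0, L_px, alpha) {
  u <- function(th) c(sin(th), cos(th))  # (row, col) direction
  leg <- L_px / 2
  P0 <- base
  P1 <- P0 + leg * u(theta0)
  P2 <- P1 + leg * u(theta0 + alpha)
  for (k in 1:3) {
    bz <- bezier_arc(P0, P1, P2)
    sc <- L_px / bz$total
    P1 <- P0 + (P1 - P0) * sc
    P2 <- P0 + (P2 - P0) * sc
  }
  bz <- bezier_arc(P0, P1, P2)
  list(control = rbind(P0, P1, P2), curve = bz)
}

# Pixels whose centers lie within radius_px of a densely sampled polyline,
# measured transversely (flat end caps: a pixel must sit within a thin axial
# band of its generating sample, so the rendered structure ends at the true
# endpoints instead of extending one radius past them). Returns linear
# (1-based) pixel indices and the normalized arc position of the nearest
# generating sample.
rasterize_curve <- function(shape, pts, s_frac, radius_px, axial_tol = 0.15) {
  pr <- pts[, 1L]; pc <- pts[, 2L]
  n <- length(pr)
  if (n >= 2L) {
    i_prev <- c(1L, seq_len(n - 1L)); i_next <- c(2:n, n)
    tg <- cbind(pr[i_next] - pr[i_prev], pc[i_next] - pc[i_prev])
    tl <- sqrt(rowSums(tg^2)); tl[tl == 0] <- 1
    tg <- tg / tl
  } else {
    tg <- cbind(rep(0, n), rep(0, n))
  }
  R <- as.integer(ceiling(radius_px + 0.5))
  offs <- expand.grid(dr = -R:R, dc = -R:R)
  offs <- offs[offs$dr^2 + offs$dc^2 <= (R + 0.5)^2, ]
  m <- nrow(offs)
  cand_r <- rep(round(pr), times = m) + rep(offs$dr, each = n)
  cand_c <- rep(round(pc), times = m) + rep(offs$dc, each = n)
  src_r <- rep(pr, times = m); src_c <- rep(pc, times = m)
  dr <- cand_r - src_r; dc <- cand_c - src_c
  axial <- dr * rep(tg[, 1L], times = m) + dc * rep(tg[, 2L], times = m)
  d <- sqrt(pmax(dr^2 + dc^2 - axial^2, 0))
  s <- rep(s_frac, times = m)
  keep <- d <= radius_px & abs(axial) <= axial_tol &
    cand_r >= 0 & cand_r < shape[1L] & cand_c >= 0 & cand_c < shape[2L]
  if (!any(keep)) return(list(idx = integer(), s = numeric()))
  idx <- cand_r[keep] + 1L + cand_c[keep] * shape[1L]
  ord <- order(idx, d[keep])
  idx <- idx[ord]; s <- s[keep][ord]
  first <- !duplicated(idx)
  list(idx = as.integer(idx[first]), s = s[first])
}

disk_indices <- function(shape, center, radius_px) {
  r0 <- max(0L, floor(center[1L] - radius_px))
  r1 <- min(shape[1L] - 1L, ceiling(center[1L] + radius_px))
  c0 <- max(0L, floor(center[2L] - radius_px))
  c1 <- min(shape[2L] - 1L, ceiling(center[2L] + radius_px))
  if (r1 < r0 || c1 < c0) return(integer())
  g <- expand.grid(r = r0:r1, c = c0:c1)
  g <- g[(g$r - center[1L])^2 + (g$c - center[2L])^2 <= radius_px^2, ]
  as.integer(g$r + 1L + g$c * shape[1L])
}

#' Simulate one multi-channel field with ground truth
#'
#' Deterministic in `(params, seed)`: identical parameters give bit-identical
#' images and truth tables.
#'
#' @param params A [sim_params()] object.
#' @param field_id Identifier given to the simulated field.
#' @return A list with elements `field` (a `field_image`) and `truth`
#'   (a `ground_truth`: per-cell and per-cilium tables, centerlines, control
#'   points, fragment centroids, marker specs, and the parameter echo).
#' @export
simulate_field <- function(params, field_id = sprintf("sim%06d", params$seed)) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  nr <- p$field_shape[1L]; nc <- p$field_shape[2L]
  px <- p$pixel_size_um
  with_seed(p$seed, {
    grid_n <- ceiling(sqrt(p$n_cells))
    cell_h <- nr / grid_n; cell_w <- nc / grid_n
    if (min(cell_h, cell_w) * px < 2 * p$nucleus_radius_um + 2) {
      stopf(paste("field too small to place %d cells of nucleus radius",
                  "%.2f um: enlarge field_shape or reduce n_cells"),
            p$n_cells, p$nucleus_radius_um,
            class = "ciliametrics_placement_error")
    }
    roles <- c("axoneme", "membrane", "basal_body", "nucleus",
               names(p$marker_specs))
    ideal <- lapply(stats::setNames(roles, roles), function(ch) {
      matrix(p$background_level[[ch]], nr, nc)
    })
    ax_rad <- (p$axoneme_width_um / 2) / px
    mem_rad <- ax_rad + 1
    cells <- data.frame(cell_id = seq_len(p$n_cells), nucleus_r = NA_real_,
                        nucleus_c = NA_real_, ciliated = FALSE)
    cilia <- list(); centerlines <- list(); controls <- list(); frags <- list()
    meanlog <- log(p$length_mean_um^2 /
                     sqrt(p$length_mean_um^2 + p$length_sd_um^2))
    sdlog <- sqrt(log(1 + (p$length_sd_um / p$length_mean_um)^2))
    cid <- 0L
    for (i in seq_len(p$n_cells)) {
      gr <- (i - 1L) %/% grid_n; gc <- (i - 1L) %% grid_n
      center <- c((gr + 0.5 + stats::runif(1, -0.12, 0.12)) * cell_h,
                  (gc + 0.5 + stats::runif(1, -0.12, 0.12)) * cell_w)
      cells$nucleus_r[i] <- center[1L]; cells$nucleus_c[i] <- center[2L]
      nuc_idx <- disk_indices(c(nr, nc), center, p$nucleus_radius_um / px)
      ideal$nucleus[nuc_idx] <- pmax(ideal$nucleus[nuc_idx],
                                     p$background_level[["nucleus"]] +
                                       p$channel_intensities[["nucleus"]])
      cells$ciliated[i] <- stats::runif(1) < p$ciliation_prob
      if (!cells$ciliated[i]) next
      L_um <- stats::rlnorm(1, meanlog, sdlog)
      L_um <- min(max(L_um, 0.5), 10)
      kappa <- stats::runif(1, -p$curvature_max, p$curvature_max)
      n_frag <- 0L
      if (p$fragment_prob > 0 && stats::runif(1) < p$fragment_prob) {
        counts <- as.integer(names(p$fragment_count_probs))
        n_frag <- counts[sample.int(length(counts), 1L,
                                    prob = p$fragment_count_probs)]
      }
      frag_extent_um <- if (n_frag > 0L) {
        p$fragment_gap_um + p$fragment_len_um +
          (n_frag - 1L) * p$fragment_spacing_um
      } else 0
      # choose an emanation angle that keeps cilium + fragments in-field
      ok <- FALSE
      for (try in 1:80) {
        phi <- stats::runif(1, 0, 2 * pi)
        base <- center + (p$nucleus_radius_um + 0.5) / px *
          c(sin(phi), cos(phi))
        alpha <- kappa * L_um  # total turning angle
        cc <- make_cilium_curve(base, phi, L_um / px, alpha)
        tipdir <- cc$curve$tangent[length(cc$curve$tangent)]
        ext <- cc$curve$points[nrow(cc$curve$points), ] +
          (frag_extent_um / px + 2) * c(sin(tipdir), cos(tipdir))
        allpts <- rbind(cc$curve$points, ext)
        if (all(allpts[, 1L] >= 2 & allpts[, 1L] <= nr - 3 &
                allpts[, 2L] >= 2 & allpts[, 2L] <= nc - 3)) {
          ok <- TRUE; break
        }
        if (try %% 20L == 0L) L_um <- L_um * 0.85  # shrink if cornered
      }
      if (!ok) next  # leave the cell unciliated rather than truncate
      cid <- cid + 1L
      curve <- cc$curve
      s_frac <- curve$arc / curve$total
      body <- rasterize_curve(c(nr, nc), curve$points, s_frac, ax_rad)
      memb <- rasterize_curve(c(nr, nc), curve$points, s_frac, mem_rad)
      amp <- p$channel_intensities
      ideal$axoneme[body$idx] <- pmax(ideal$axoneme[body$idx],
                                      p$background_level[["axoneme"]] +
                                        amp[["axoneme"]])
      ideal$membrane[memb$idx] <- pmax(ideal$membrane[memb$idx],
                                       p$background_level[["membrane"]] +
                                         amp[["membrane"]])
      bb_center <- base - 0.3 / px * c(sin(phi), cos(phi))
      bb_idx <- disk_indices(c(nr, nc), bb_center, 1.5)
      ideal$basal_body[bb_idx] <- pmax(ideal$basal_body[bb_idx],
                                       p$background_level[["basal_body"]] +
                                         amp[["basal_body"]])
      # markers fill the cilium's full width (the sheath), so a measurement
      # band along the centerline stays inside marker-positive pixels
      for (m in names(p$marker_specs)) {
        spec <- p$marker_specs[[m]]
        f <- marker_profile_fun(spec)
        ideal[[m]][memb$idx] <- pmax(ideal[[m]][memb$idx],
                                     p$background_level[[m]] +
                                       amp[[m]] * f(memb$s))
        # tip/base enrichments are protein caps centered on the cilium end:
        # they extend one plateau half-width past the geometric end, so the
        # PSF does not halve the on-path signal at the end itself
        if (spec$type %in% c("tip_bump", "base_bump")) {
          ext_len <- spec$width_frac * curve$total
          if (ext_len > 0.5) {
            if (spec$type == "tip_bump") {
              endp <- curve$points[nrow(curve$points), ]
              ang <- curve$tangent[length(curve$tangent)]
              dirv <- c(sin(ang), cos(ang))
            } else {
              endp <- curve$points[1L, ]
              ang <- curve$tangent[1L]
              dirv <- -c(sin(ang), cos(ang))
            }
            tt <- seq(0.2, ext_len, by = 0.2)
            ext_pts <- cbind(endp[1L] + tt * dirv[1L], endp[2L] + tt * dirv[2L])
            er <- rasterize_curve(c(nr, nc), ext_pts, rep(1, length(tt)), mem_rad)
            ideal[[m]][er$idx] <- pmax(ideal[[m]][er$idx],
                                       p$background_level[[m]] +
                                         amp[[m]] * spec$amplitude)
          }
        }
      }
      # detached distal fragments
      frag_cent <- matrix(numeric(), 0L, 2L)
      if (n_frag > 0L) {
        tipdir <- curve$tangent[length(curve$tangent)]
        tip <- curve$points[nrow(curve$points), ]
        udir <- c(sin(tipdir), cos(tipdir))
        perp <- c(cos(tipdir), -sin(tipdir))
        for (j in seq_len(n_frag)) {
          cdist <- (p$fragment_gap_um + p$fragment_len_um / 2 +
                      (j - 1L) * p$fragment_spacing_um) / px
          jit <- stats::rnorm(1, 0, 0.1 / px)
          fc <- tip + cdist * udir + jit * perp
          half <- (p$fragment_len_um / 2) / px
          fpts <- cbind(seq(fc[1L] - half * udir[1L], fc[1L] + half * udir[1L],
                            length.out = 20L),
                        seq(fc[2L] - half * udir[2L], fc[2L] + half * udir[2L],
                            length.out = 20L))
          fr <- rasterize_curve(c(nr, nc), fpts, rep(1, 20L), ax_rad)
          fm <- rasterize_curve(c(nr, nc), fpts, rep(1, 20L), mem_rad)
          ideal$axoneme[fr$idx] <- pmax(ideal$axoneme[fr$idx],
                                        p$background_level[["axoneme"]] +
                                          amp[["axoneme"]])
          if (p$dual_positive_fragments) {
            ideal$membrane[fm$idx] <- pmax(ideal$membrane[fm$idx],
                                           p$background_level[["membrane"]] +
                                             amp[["membrane"]])
          }
          frag_cent <- rbind(frag_cent, fc)
        }
      }
      cilia[[cid]] <- data.frame(
        cilium_id = cid, cell_id = i,
        base_r = base[1L], base_c = base[2L],
        tip_r = curve$points[nrow(curve$points), 1L],
        tip_c = curve$points[nrow(curve$points), 2L],
        length_um = curve$total * px, curvature = kappa,
        n_fragments = n_frag)
      centerlines[[cid]] <- curve$points
      controls[[cid]] <- cc$control
      frags[[cid]] <- frag_cent
    }
    cilia_df <- if (cid > 0L) do.call(rbind, cilia) else
      data.frame(cilium_id = integer(), cell_id = integer(), base_r = numeric(),
                 base_c = numeric(), tip_r = numeric(), tip_c = numeric(),
                 length_um = numeric(), curvature = numeric(),
                 n_fragments = integer())
    # some cells may have failed placement; truth reflects what was rendered
    cells$ciliated <- cells$cell_id %in% cilia_df$cell_id
    channels <- lapply(stats::setNames(roles, roles), function(ch) {
      img <- gaussian_blur(ideal[[ch]], p$psf_sigma_px)
      if (isTRUE(p$noise$poisson) && p$noise$gain > 0) {
        img <- matrix(stats::rpois(length(img), pmax(img, 0) * p$noise$gain) /
                        p$noise$gain, nr, nc)
      }
      if (p$noise$read_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, p$noise$read_sd),
                            nr, nc)
      }
      pmax(img, 0)
    })
    field <- field_image(channels, px, field_id = field_id,
                         metadata = list(simulated = TRUE, seed = p$seed))
    truth <- structure(
      list(field_id = field_id, params = p, cells = cells, cilia = cilia_df,
           centerlines = centerlines, control_points = controls,
           fragment_centroids = frags,
           n_ciliated = sum(cells$ciliated),
           ideal = ideal),
      class = "ground_truth")
    list(field = field, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth '%s'> %d cells, %d ciliated, %d cilia rows\n",
              x$field_id, nrow(x$cells), x$n_ciliated, nrow(x$cilia)))
  invisible(x)
}

#' Simulate labeled field sets for two conditions
#'
#' Stands in for a parental-vs-resistant comparison. Per-field seeds are
#' derived deterministically from each condition's master seed, so the two
#' sets are disjoint unless the conditions share parameters and seed.
#'
#' @param params_a,params_b [sim_params()] for the two conditions.
#' @param n_fields Number of fields per condition (0 gives empty sets).
#' @return A list with elements `a` and `b`, each a list of
#'   `simulate_field()` results.
#' @export
simulate_condition_pair <- function(params_a, params_b, n_fields) {
  sim_set <- function(params, label) {
    lapply(seq_len(n_fields), function(i) {
      pi <- params
      pi$seed <- derive_seed(params$seed, i)
      simulate_field(pi, field_id = sprintf("%s_f%03d", label, i))
    })
  }
  list(a = sim_set(params_a, "a"), b = sim_set(params_b, "b"))
}

#' Write ground truth as per-cilium CSV and per-field JSON
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory.
#' @return Invisible list of written paths.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(truth$field_id, "_truth_cilia.csv"))
  js <- file.path(dir, paste0(truth$field_id, "_truth.json"))
  utils::write.csv(truth$cilia, csv, row.names = FALSE)
  jsonlite::write_json(
    list(field_id = truth$field_id, n_cells = nrow(truth$cells),
         n_ciliated = truth$n_ciliated, cells = truth$cells,
         params = truth$params[setdiff(names(truth$params), "marker_specs")],
         marker_specs = lapply(truth$params$marker_specs, unclass)),
    js, auto_unbox = TRUE, digits = NA)
  invisible(list(cilia_csv = csv, field_json = js))
}
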