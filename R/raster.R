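# Low-level raster operations on plain numeric matrices.
#
# Images are matrices indexed [row, col]. All user-facing coordinates are
# 0-based with pixel centers at integer positions; conversion to R's 1-based
# indexing happens inside these helpers.

# result[i, j] = m[i + dr, j + dc]; out-of-range positions take `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_src <- max(1L, 1L + dr):min(nr, nr + dr)
  c_src <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(r_src) == 0L || length(c_src) == 0L) return(out)
  out[r_src - dr, c_src - dc] <- m[r_src, c_src]
  out
}

# Separable Gaussian blur implemented as banded-matrix multiplication.
# Edge handling: kernel truncated at the border and renormalized, so constant
# images are preserved exactly.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  blur_band <- function(n) {
    r <- ceiling(4 * sigma)
    d <- outer(seq_len(n), seq_len(n), "-")
    K <- exp(-d^2 / (2 * sigma^2))
    K[abs(d) > r] <- 0
    K / rowSums(K)
  }
  Kr <- blur_band(nrow(img))
  Kc <- blur_band(ncol(img))
  Kr %*% img %*% t(Kc)
}

# 2D convolution via FFT, 'same' output, zero padding.
conv2_same <- function(a, k) {
  na <- dim(a); nk <- dim(k)
  np <- na + nk - 1L
  pa <- matrix(0, np[1L], np[2L]); pa[seq_len(na[1L]), seq_len(na[2L])] <- a
  pk <- matrix(0, np[1L], np[2L]); pk[seq_len(nk[1L]), seq_len(nk[2L])] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    prod(np)
  off <- (nk - 1L) %/% 2L
  full[off[1L] + seq_len(na[1L]), off[2L] + seq_len(na[2L])]
}

disk_kernel <- function(radius_px) {
  r <- max(0L, as.integer(ceiling(radius_px)))
  d <- outer((-r):r, (-r):r, function(i, j) sqrt(i^2 + j^2))
  (d <= radius_px + 1e-9) * 1
}

# Binary dilation by a disk of the given pixel radius. Small radii use
# shifted-matrix union (cheap, exact); large radii fall back to FFT
# convolution with a disk kernel.
dilate_disk <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  if (radius_px <= 6) {
    r <- as.integer(ceiling(radius_px))
    out <- matrix(FALSE, nrow(mask), ncol(mask))
    for (dr in -r:r) for (dc in -r:r) {
      if (dr^2 + dc^2 > radius_px^2 + 1e-9) next
      out <- out | shift_mat(mask, dr, dc, FALSE)
    }
    return(out)
  }
  conv2_same(mask * 1, disk_kernel(radius_px)) > 0.5
}

# Connected-component labelling (8- or 4-connectivity). Returns an integer
# matrix: 0 for background, 1..k for components (labelled in first-pixel order).
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(matrix(0L, nr, nc))
  vid <- integer(nr * nc)
  vid[fg] <- seq_along(fg)
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  IM <- matrix(seq_len(nr * nc), nr, nc)
  for (s in shifts) {
    dr <- s[1L]; dc <- s[2L]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0L) seq_len(nc - dc) else (1L - dc):nc
    i1 <- IM[r1, c1, drop = FALSE]
    i2 <- IM[r1 + dr, c1 + dc, drop = FALSE]
    both <- mask[i1] & mask[i2]
    if (any(both)) edges[[length(edges) + 1L]] <- cbind(vid[i1[both]], vid[i2[both]])
  }
  el <- if (length(edges)) do.call(rbind, edges) else matrix(integer(), 0L, 2L)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  # relabel so component ids follow first-pixel (column-major) order
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  out <- matrix(0L, nr, nc)
  out[fg] <- relab[memb]
  out
}

# Fill holes: background components (4-connected) not touching the border.
fill_holes <- function(mask) {
  lab <- label_components(!mask, connectivity = 4L)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

# Zhang-Suen thinning to a 1-pixel-wide skeleton.
skeletonize <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2L:(nrow(mask) + 1L), 2L:(ncol(mask) + 1L)] <- mask * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
      P <- list(
        shift_mat(m, -1L, 0L), shift_mat(m, -1L, 1L), shift_mat(m, 0L, 1L),
        shift_mat(m, 1L, 1L), shift_mat(m, 1L, 0L), shift_mat(m, 1L, -1L),
        shift_mat(m, 0L, -1L), shift_mat(m, -1L, -1L)
      )
      B <- Reduce(`+`, P)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) {
        nxt <- P[[if (i == 8L) 1L else i + 1L]]
        A <- A + (P[[i]] == 0L & nxt == 1L)
      }
      if (step == 1L) {
        c1 <- P[[1L]] * P[[3L]] * P[[5L]]
        c2 <- P[[3L]] * P[[5L]] * P[[7L]]
      } else {
        c1 <- P[[1L]] * P[[3L]] * P[[7L]]
        c2 <- P[[1L]] * P[[5L]] * P[[7L]]
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 == 0L & c2 == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2L:(nrow(mask) + 1L), 2L:(ncol(mask) + 1L)] > 0L
}

# Bilinear interpolation at 0-based subpixel (row, col) positions, clamped to
# the image domain.
interp_bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 0), nr - 1)
  c <- pmin(pmax(c, 0), nc - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  fr <- r - r0; fc <- c - c0
  v00 <- img[cbind(r0 + 1, c0 + 1)]
  v01 <- img[cbind(r0 + 1, c1 + 1)]
  v10 <- img[cbind(r1 + 1, c0 + 1)]
  v11 <- img[cbind(r1 + 1, c1 + 1)]
  v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
}

# Nearest-pixel lookup at 0-based positions (used by the oracle-compatible
# sampling mode). Out-of-image positions return NA.
interp_nearest <- function(img, r, c) {
  ri <- round(r); ci <- round(c)
  ok <- ri >= 0 & ri <= nrow(img) - 1 & ci >= 0 & ci <= ncol(img) - 1
  out <- rep(NA_real_, length(r))
  if (any(ok)) out[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
  out
}

# Robust background level and spread: median and scaled MAD.
robust_background <- function(img) {
  med <- stats::median(img)
  list(level = med, spread = stats::mad(img, center = med))
}

# Foreground threshold at k robust sigmas over background. On (near-)noiseless
# images the MAD collapses to ~0; fall back to a fixed fraction of the dynamic
# range above background so that crisp synthetic structures still segment.
robust_threshold <- function(img, k) {
  bg <- robust_background(img)
  floor_spread <- (max(img) - bg$level) / (4 * k)
  bg$level + k * max(bg$spread, floor_spread, 1e-12)
}

# Otsu threshold for roughly bimodal intensity histograms (nucleus channel).
otsu_threshold <- function(img, n_bins = 256L) {
  rng <- range(img)
  if (diff(rng) <= 0) return(rng[1L])
  h <- graphics::hist(img, breaks = seq(rng[1L], rng[2L], length.out = n_bins + 1L),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# Local maxima strictly above a threshold (8-neighbourhood, >= neighbours).
local_maxima <- function(img, threshold) {
  keep <- img > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    keep <- keep & img >= shift_mat(img, dr, dc, fill = -Inf)
  }
  which(keep, arr.ind = TRUE) - 1L
}
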