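# Internal helpers shared across modules.

# Run code with a deterministic RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed < 2^31 from a master seed and an index, deterministically.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483629)
}

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "ciliametrics_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Euclidean length of a polyline given as an n x 2 matrix (row, col).
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

# Cumulative arc position of each vertex of a polyline, starting at 0.
polyline_arc <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  d <- diff(pts)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

# Resample a polyline to (approximately) uniform arc spacing, keeping both ends.
# spacing is in the same units as the coordinates.
resample_polyline <- function(pts, spacing = 1.0) {
  if (nrow(pts) > 2L) {  # drop zero-length segments
    step <- sqrt(rowSums(diff(pts)^2))
    pts <- pts[c(TRUE, step > 1e-12), , drop = FALSE]
  }
  arc <- polyline_arc(pts)
  total <- arc[length(arc)]
  if (total <= 0) return(pts[1L, , drop = FALSE])
  n_out <- max(2L, as.integer(round(total / spacing)) + 1L)
  s_out <- seq(0, total, length.out = n_out)
  r <- stats::approx(arc, pts[, 1L], xout = s_out)$y
  c_ <- stats::approx(arc, pts[, 2L], xout = s_out)$y
  cbind(r, c_, deparse.level = 0)
}

# Moving-average smoothing of path coordinates with endpoint preservation.
smooth_polyline <- function(pts, window = 5L) {
  n <- nrow(pts)
  if (n < 3L || window < 3L) return(pts)
  half <- window %/% 2L
  out <- pts
  for (k in 2L:(n - 1L)) {
    i0 <- max(1L, k - half)
    i1 <- min(n, k + half)
    out[k, ] <- colMeans(pts[i0:i1, , drop = FALSE])
  }
  out
}
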