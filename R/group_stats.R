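# Group comparisons used for the figures: unpaired t tests for two groups,
# Tukey's HSD for three or more, and per-bin t tests for profile matrices.
# Statistics and p-values are computed from their closed forms via the base
# distribution functions (pt, ptukey), not by delegating to t.test/TukeyHSD.

new_group_comparison <- function(measure, method, table, groups, flags = character()) {
  structure(list(measure = measure, method = method, table = table,
                 groups = groups, flags = flags),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s, method = %s\n", x$measure, x$method))
  print(x$table, digits = 4)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Two-sided unpaired t test
#'
#' Classic pooled-variance Student test by default (the "unpaired t test" of
#' the figure legends); Welch's unequal-variance variant by flag.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2, finite.
#' @param variant `"student"` (default) or `"welch"`.
#' @param measure Label carried on the result.
#' @return A `group_comparison` with a one-row table: statistic, df,
#'   p_value, means, SDs, n. Degenerate zero-variance inputs are flagged:
#'   equal means give p = 1, unequal means give p = 0.
#' @export
t_test_unpaired <- function(values_a, values_b,
                            variant = c("student", "welch"),
                            measure = "measure") {
  variant <- match.arg(variant)
  for (v in list(values_a, values_b)) {
    if (length(v) < 2L) stopf("each group needs n >= 2")
    if (!all(is.finite(v))) stopf("values must be finite")
  }
  n1 <- length(values_a); n2 <- length(values_b)
  m1 <- mean(values_a); m2 <- mean(values_b)
  v1 <- stats::var(values_a); v2 <- stats::var(values_b)
  flags <- character()
  if (variant == "student") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se > 0) {
      (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else NA_real_
  }
  if (se == 0) {
    flags <- "degenerate_variance"
    if (m1 == m2) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(m1 - m2) * Inf; p <- 0
    }
  } else {
    tstat <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  tab <- data.frame(statistic = tstat, df = df, p_value = p,
                    mean_a = m1, mean_b = m2, sd_a = sqrt(v1), sd_b = sqrt(v2),
                    n_a = n1, n_b = n2)
  new_group_comparison(measure, paste0("t_test_", variant), tab,
                       groups = data.frame(group = c("a", "b"), n = c(n1, n2)),
                       flags = flags)
}

#' Tukey's honestly-significant-difference test
#'
#' All pairwise comparisons of >= 3 groups with family-wise-adjusted
#' p-values from the studentized-range distribution. A subset of pairs can
#' be reported (as figure legends often do) while the adjustment still spans
#' the full family. With exactly two groups the function defers to
#' [t_test_unpaired()] with a warning.
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param pairs Optional character matrix / list of c(group1, group2) pairs
#'   to report.
#' @param measure Label carried on the result.
#' @return A `group_comparison` with one row per reported pair: difference
#'   of means, studentized-range q, adjusted p.
#' @export
tukey_hsd <- function(groups, pairs = NULL, measure = "measure") {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stopf("groups must be a named list")
  }
  if (length(groups) == 2L) {
    warning("only two groups: deferring to the unpaired t test")
    return(t_test_unpaired(groups[[1L]], groups[[2L]], measure = measure))
  }
  if (length(groups) < 3L) stopf("tukey_hsd needs >= 3 groups")
  ns <- vapply(groups, length, 1L)
  if (any(ns < 2L)) stopf("each group needs n >= 2")
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, 1.0)
  vars <- vapply(groups, stats::var, 1.0)
  df <- N - k
  mse <- sum((ns - 1) * vars) / df
  all_pairs <- utils::combn(names(groups), 2L)
  rows <- lapply(seq_len(ncol(all_pairs)), function(j) {
    g1 <- all_pairs[1L, j]; g2 <- all_pairs[2L, j]
    diffm <- means[[g2]] - means[[g1]]
    se <- sqrt(mse / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- if (se > 0) abs(diffm) / se else if (diffm == 0) 0 else Inf
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group_1 = g1, group_2 = g2, diff = diffm,
               se = se, q = q, p_adj = p,
               mean_1 = means[[g1]], mean_2 = means[[g2]],
               sd_1 = sqrt(vars[[g1]]), sd_2 = sqrt(vars[[g2]]),
               n_1 = ns[[g1]], n_2 = ns[[g2]])
  })
  tab <- do.call(rbind, rows)
  if (!is.null(pairs)) {
    if (is.list(pairs)) pairs <- do.call(rbind, pairs)
    keep <- vapply(seq_len(nrow(tab)), function(i) {
      any((pairs[, 1L] == tab$group_1[i] & pairs[, 2L] == tab$group_2[i]) |
            (pairs[, 2L] == tab$group_1[i] & pairs[, 1L] == tab$group_2[i]))
    }, TRUE)
    tab <- tab[keep, , drop = FALSE]
  }
  new_group_comparison(measure, "tukey_hsd", tab,
                       groups = data.frame(group = names(groups), n = ns))
}

#' Per-bin unpaired t tests for two profile matrices
#'
#' One test per arc-length bin, proximal to distal. No cross-bin
#' multiplicity adjustment by default (ten raw per-bin p-values, as
#' conventionally reported); Bonferroni available by flag.
#'
#' @param matrix_a,matrix_b Cilia x bins matrices ([profile_group_matrix()]).
#' @param variant t-test variant.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @param measure Label prefix.
#' @return A `group_comparison` whose table has one row per bin.
#' @export
per_bin_tests <- function(matrix_a, matrix_b,
                          variant = c("student", "welch"),
                          adjust = c("none", "bonferroni"),
                          measure = "profile") {
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  if (ncol(matrix_a) != ncol(matrix_b)) {
    stopf("profile matrices have different bin counts (%d vs %d)",
          ncol(matrix_a), ncol(matrix_b))
  }
  nb <- ncol(matrix_a)
  rows <- lapply(seq_len(nb), function(j) {
    ct <- t_test_unpaired(matrix_a[, j], matrix_b[, j], variant = variant)
    cbind(data.frame(bin = j), ct$table)
  })
  tab <- do.call(rbind, rows)
  if (adjust == "bonferroni") tab$p_value <- pmin(1, tab$p_value * nb)
  new_group_comparison(measure, paste0("per_bin_t_", variant, "_", adjust),
                       tab,
                       groups = data.frame(group = c("a", "b"),
                                           n = c(nrow(matrix_a), nrow(matrix_b))))
}
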