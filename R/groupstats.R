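# The study's comparison battery: one-way ANOVA with Bonferroni post hoc
# tests, exact Mann-Whitney U, and exact Wilcoxon signed-rank, with the
# small-sample conventions stated in the documentation.

#' One-way ANOVA with Bonferroni post hoc pairwise t tests
#'
#' Classical one-way analysis of variance across groups, followed by all
#' pairwise pooled-variance two-sample t tests with Bonferroni correction:
#' each raw pairwise p is multiplied by the number of pairs performed and
#' capped at 1.
#'
#' @param values numeric measurements.
#' @param group group label per measurement (>= 2 levels, each with >= 2
#'   values).
#' @return An object of class `anova_battery`: list with `anova`
#'   (`statistic`, `df`, `p`, `method`), `pairwise` (`group1`, `group2`,
#'   `t`, `p_raw`, `p_bonf`), and `k` (number of pairwise comparisons).
#' @export
oneway_anova_bonferroni <- function(values, group) {
  check_numeric(values, "values")
  group <- factor(group)
  if (nlevels(group) < 2) {
    stop("oneway_anova_bonferroni: need at least 2 groups", call. = FALSE)
  }
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    stop(sprintf("oneway_anova_bonferroni: group(s) with fewer than 2 values: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  fstat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  # constant data: zero between- and within-group variance, F is 0/0
  if (stats::var(values) == 0 || !is.finite(fstat)) { fstat <- 0; p <- 1 }

  pairs <- utils::combn(levels(group), 2)
  k <- ncol(pairs)
  pw <- lapply(seq_len(k), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x <- values[group == g1]; y <- values[group == g2]
    tt <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(tt) || !is.finite(tt$p.value)) {
      data.frame(group1 = g1, group2 = g2, t = 0, p_raw = 1, p_bonf = 1)
    } else {
      data.frame(group1 = g1, group2 = g2, t = unname(tt$statistic),
                 p_raw = tt$p.value, p_bonf = min(1, tt$p.value * k))
    }
  })
  structure(list(anova = data.frame(statistic = fstat,
                                    df1 = tab[["Df"]][1],
                                    df2 = tab[["Df"]][2],
                                    p = p, method = "anova_f"),
                 pairwise = do.call(rbind, pw), k = k),
            class = "anova_battery")
}

#' @export
print.anova_battery <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$statistic, x$anova$p))
  cat(sprintf("Bonferroni post hoc (%d pairwise comparisons):\n", x$k))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

# Two-sided p as twice the smaller exact tail, capped at 1.
two_sided_from_tails <- function(p_le, p_ge) {
  min(1, 2 * min(p_le, p_ge))
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic uses
#' mid-ranks for ties. For tie-free data with combined size at most
#' `exact_limit` the two-sided p value is exact (twice the smaller tail of
#' the exact null distribution of U, capped at 1). With ties, a seeded
#' Monte-Carlo permutation p value over group-label reassignments is
#' reported. Beyond the exact size limit a normal approximation with
#' continuity and tie correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_limit maximum combined sample size for the exact mode.
#' @param n_perm number of permutations in the tie case.
#' @param seed RNG seed for the permutation mode.
#' @return A list of class `exact_test`: `statistic` (U for `x`),
#'   `p_two_sided`, `method`, `mode` (`"exact"`, `"permutation"`,
#'   `"normal_approx"`), `n`, `note`.
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 25, n_perm = 10000,
                               seed = 1L) {
  check_numeric(x, "x"); check_numeric(y, "y")
  if (!length(x) || !length(y)) {
    stop("mann_whitney_exact: both samples must be non-empty", call. = FALSE)
  }
  m <- length(x); n <- length(y)
  z <- c(x, y)
  r <- rank(z)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(z))
  note <- if (ties) "ties present (mid-ranks)" else ""

  if (!ties && m + n <= exact_limit) {
    p <- two_sided_from_tails(stats::pwilcox(u, m, n),
                              1 - stats::pwilcox(u - 1, m, n))
    mode <- "exact"
  } else if (ties) {
    set.seed(seed)
    center <- m * n / 2
    obs <- abs(u - center)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(m + n, m)
      ub <- sum(r[idx]) - m * (m + 1) / 2
      if (abs(ub - center) >= obs - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
    mode <- "permutation"
  } else {
    mu <- m * n / 2
    tie_tab <- table(z)
    sig2 <- m * n / 12 *
      ((m + n + 1) - sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1)))
    zstat <- (abs(u - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-zstat))
    mode <- "normal_approx"
  }
  structure(list(statistic = u, p_two_sided = p, method = "mannwhitney_exact",
                 mode = mode, n = c(m, n), note = note),
            class = "exact_test")
}

# Null distribution of twice the positive-rank sum over doubled mid-ranks
# (doubling makes mid-ranks integral), by generating-function convolution:
# returns the probability vector over support 0..sum(2r).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  p <- numeric(total + 1)
  p[1] <- 1
  for (r2 in ranks2) {
    shifted <- c(rep(0, r2), p[seq_len(total + 1 - r2)])
    p <- (p + shifted) / 2
  }
  p
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired-difference test with the classic zero-drop convention: zero
#' differences are removed (noted in the output), the remaining absolute
#' differences are mid-ranked, and W is the sum of ranks of positive
#' differences. For up to `m_exact` nonzero differences the two-sided p is
#' exact, computed from the full null distribution of W over all sign
#' assignments (obtained by convolution, which also handles mid-rank ties);
#' beyond that a normal approximation with tie correction is used.
#'
#' @param diffs numeric vector of paired differences.
#' @param m_exact maximum number of nonzero differences for the exact mode.
#' @return A list of class `exact_test`: `statistic` (W), `p_two_sided`,
#'   `method`, `mode`, `n` (nonzero pairs), `note`.
#' @export
wilcoxon_signed_rank_exact <- function(diffs, m_exact = 20) {
  check_numeric(diffs, "diffs")
  n_zero <- sum(diffs == 0)
  d <- diffs[diffs != 0]
  m <- length(d)
  if (m == 0) stop("wilcoxon_signed_rank_exact: no nonzero pairs", call. = FALSE)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  note <- c(if (n_zero) sprintf("%d zero difference(s) dropped", n_zero),
            if (any(duplicated(abs(d)))) "ties present (mid-ranks)")
  note <- paste(note, collapse = "; ")

  if (m <= m_exact) {
    probs <- signed_rank_null(round(2 * r))
    w2 <- round(2 * w)
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):length(probs)])
    p <- two_sided_from_tails(p_le, p_ge)
    mode <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    zstat <- (abs(w - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-zstat))
    mode <- "normal_approx"
  }
  structure(list(statistic = w, p_two_sided = p,
                 method = "wilcoxon_exact", mode = mode, n = m, note = note),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %g, two-sided p = %.4g, n = %s\n",
              x$method, x$mode, x$statistic, x$p_two_sided,
              paste(x$n, collapse = "/")))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
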