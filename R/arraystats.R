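# Dual-channel antibody-microarray processing: replicate aggregation,
# MA computation, rank-invariant lowess normalization, empirical-Bayes
# moderated contrasts, FDR control, classification, and clustering order.

#' Aggregate quadruplicate spot intensities
#'
#' Collapses replicate spots to one intensity per sample, antibody, and
#' channel: optional local-background subtraction, then the median across
#' replicate spots, floored at a small positive `epsilon` so downstream
#' log2 transforms stay finite. The replicate coefficient of variation is
#' reported for quality assessment.
#'
#' @param spots long-format `data.frame` with columns `sample_id`,
#'   `antibody_id`, `channel` (`"sample"`/`"reference"`), `intensity`, and
#'   optionally `background`.
#' @param epsilon positive floor applied after background subtraction.
#' @return A `data.frame` with one row per sample x antibody x channel:
#'   `sample_id`, `antibody_id`, `channel`, `intensity`, `cv`, `n_spots`.
#'   Combinations whose spots are all missing carry `intensity = NA`.
#' @export
aggregate_replicates <- function(spots, epsilon = 1) {
  check_columns(spots, c("sample_id", "antibody_id", "channel", "intensity"),
                "aggregate_replicates")
  stopifnot(epsilon > 0)
  vals <- spots$intensity
  if ("background" %in% names(spots)) {
    vals <- vals - ifelse(is.na(spots$background), 0, spots$background)
  }
  vals <- pmax(vals, epsilon)
  key <- interaction(spots$sample_id, spots$antibody_id, spots$channel,
                     drop = TRUE, sep = "\r")
  med <- tapply(vals, key, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  })
  cv <- tapply(vals, key, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) NA_real_ else stats::sd(v) / mean(v)
  })
  n <- tapply(vals, key, function(v) sum(is.finite(v)))
  parts <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  out <- data.frame(sample_id = parts[, 1], antibody_id = parts[, 2],
                    channel = parts[, 3], intensity = as.numeric(med),
                    cv = as.numeric(cv), n_spots = as.integer(n))
  rownames(out) <- NULL
  out[order(out$sample_id, out$antibody_id, out$channel), ]
}

#' M and A values from aggregated dual-channel intensities
#'
#' Computes, per antibody and sample, the log-ratio
#' `M = log2(sample/reference)` and average log-intensity
#' `A = 0.5 * log2(sample * reference)` of the aggregated channels.
#'
#' @param agg output of [aggregate_replicates()].
#' @return A list with matrices `m_values` and `a_values`
#'   (antibodies x samples).
#' @export
ma_values <- function(agg) {
  check_columns(agg, c("sample_id", "antibody_id", "channel", "intensity"),
                "ma_values")
  samp <- agg[agg$channel == "sample", ]
  ref <- agg[agg$channel == "reference", ]
  if (!nrow(samp) || !nrow(ref)) {
    stop("ma_values: both 'sample' and 'reference' channels are required",
         call. = FALSE)
  }
  to_matrix <- function(d) {
    tapply(d$intensity, list(d$antibody_id, d$sample_id), identity)
  }
  s <- to_matrix(samp)
  r <- to_matrix(ref)[rownames(s), colnames(s), drop = FALSE]
  list(m_values = log2(s / r), a_values = 0.5 * log2(s * r))
}

#' Rank-invariant lowess normalization of dual-channel arrays
#'
#' Removes smooth intensity-dependent dye bias from each array. Per array,
#' the rank-invariant antibody set is selected as those whose rank differs
#' between the two channels by at most `rank_tol * n` ranks — antibodies
#' unlikely to be differentially abundant. A locally weighted regression of
#' M on A is fitted over that set and the fitted trend (linearly
#' interpolated across A) subtracted from all M values of the array. If the
#' invariant set is smaller than `min_invariant` antibodies the array falls
#' back to global-median centering with a warning.
#'
#' @param ma list with `m_values` and `a_values` matrices, e.g. from
#'   [ma_values()].
#' @param span lowess smoother span.
#' @param rank_tol rank-invariance tolerance as a fraction of the number of
#'   antibodies.
#' @param min_invariant minimum invariant-set size before falling back.
#' @return An object of class `normalized_ma`: list with `m_values`
#'   (normalized), `a_values`, `invariant` (logical matrix of selected
#'   antibodies per array), `span`, `rank_tol`.
#' @export
normalize_ma <- function(ma, span = 0.4, rank_tol = 0.05, min_invariant = 10) {
  m <- ma$m_values; a <- ma$a_values
  stopifnot(is.matrix(m), is.matrix(a), all(dim(m) == dim(a)))
  if (nrow(m) < 20) {
    warning("normalize_ma: fewer than 20 antibodies; fit may be unstable",
            call. = FALSE)
  }
  inv <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  mn <- m
  for (j in seq_len(ncol(m))) {
    ok <- is.finite(m[, j]) & is.finite(a[, j])
    # channel log-intensities recovered from (M, A)
    rs <- rank(a[ok, j] + m[ok, j] / 2)
    rr <- rank(a[ok, j] - m[ok, j] / 2)
    sel <- abs(rs - rr) / sum(ok) <= rank_tol
    inv[ok, j][sel] <- TRUE
    if (sum(sel) < min_invariant) {
      warning(sprintf(
        "normalize_ma: array '%s' invariant set has %d antibodies (< %d); %s",
        colnames(m)[j], sum(sel), min_invariant,
        "falling back to global-median centering"), call. = FALSE)
      mn[ok, j] <- m[ok, j] - stats::median(m[ok, j])
      next
    }
    xs <- a[ok, j]
    fit <- stats::lowess(xs[sel], m[ok, j][sel], f = span)
    # refinement pass: rank-near-invariant antibodies that are actually
    # regulated betray themselves by large residuals around the first trend;
    # drop them and refit so they cannot drag the curve (classic invariant-set
    # iteration)
    res <- m[ok, j][sel] -
      stats::approx(fit$x, fit$y, xout = xs[sel], rule = 2, ties = mean)$y
    madr <- stats::median(abs(res))
    thresh <- if (madr > 0) 5 * madr else 1e-8
    keep <- abs(res) <= thresh
    if (sum(keep) >= min_invariant && any(!keep)) {
      sel[sel] <- keep
      inv[ok, j] <- sel
      fit <- stats::lowess(xs[sel], m[ok, j][sel], f = span)
    }
    trend <- stats::approx(fit$x, fit$y, xout = xs, rule = 2, ties = mean)$y
    # extend the trend linearly beyond the invariant A-range using the end
    # segment slopes, so extreme-intensity antibodies are not left with the
    # edge bias a constant extension would produce
    nfit <- length(fit$x)
    if (nfit >= 2) {
      lo <- xs < fit$x[1]; hi <- xs > fit$x[nfit]
      slope_lo <- (fit$y[2] - fit$y[1]) / (fit$x[2] - fit$x[1])
      slope_hi <- (fit$y[nfit] - fit$y[nfit - 1]) /
        (fit$x[nfit] - fit$x[nfit - 1])
      if (is.finite(slope_lo)) {
        trend[lo] <- fit$y[1] + slope_lo * (xs[lo] - fit$x[1])
      }
      if (is.finite(slope_hi)) {
        trend[hi] <- fit$y[nfit] + slope_hi * (xs[hi] - fit$x[nfit])
      }
    }
    mn[ok, j] <- m[ok, j] - trend
  }
  structure(list(m_values = mn, a_values = a, invariant = inv,
                 span = span, rank_tol = rank_tol),
            class = "normalized_ma")
}

#' @export
print.normalized_ma <- function(x, ...) {
  cat(sprintf("normalized dual-channel array: %d antibodies x %d samples\n",
              nrow(x$m_values), ncol(x$m_values)))
  cat(sprintf("  lowess span %.2f, rank-invariance tolerance %.3f, median invariant set %d\n",
              x$span, x$rank_tol, stats::median(colSums(x$invariant))))
  invisible(x)
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up false-discovery-rate adjustment of raw p values: ordered p values
#' are scaled by n/i, cumulative minima enforced from the largest rank down,
#' capped at 1, and mapped back to the input order. Inputs must lie in
#' (0, 1].
#'
#' @param p numeric vector of raw p values in (0, 1].
#' @return Adjusted p values in input order.
#' @export
bh_adjust <- function(p) {
  check_numeric(p, "p")
  check_that(p > 0 & p <= 1, "p", "must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classification thresholds for differential abundance
#'
#' Two published variants are supported. The default (`"results"`) calls a
#' protein differential when |logFC| > 0.5 and adjusted p < 0.05, and
#' noteworthy when |logFC| > 0.5 with adjusted p in [0.05, 0.9). The
#' `"methods"` preset uses the stricter adjusted p < 0.005 for differential
#' calls and defines noteworthy by effect size alone, 0.25 < |logFC| <= 0.5
#' (at adjusted p < 0.005). All four numbers are configurable.
#'
#' @param preset `"results"` (default) or `"methods"`.
#' @param lfc absolute log2-fold-change cutoff for differential calls.
#' @param alpha adjusted-p cutoff for differential calls.
#' @param noteworthy_alpha upper adjusted-p bound for noteworthy calls
#'   (results preset).
#' @param noteworthy_lfc_low lower |logFC| bound for noteworthy calls
#'   (methods preset).
#' @return A list of thresholds with class `abundance_thresholds`.
#' @export
classification_thresholds <- function(preset = c("results", "methods"),
                                      lfc = 0.5,
                                      alpha = NULL,
                                      noteworthy_alpha = 0.9,
                                      noteworthy_lfc_low = 0.25) {
  preset <- match.arg(preset)
  if (is.null(alpha)) alpha <- if (preset == "results") 0.05 else 0.005
  structure(list(preset = preset, lfc = lfc, alpha = alpha,
                 noteworthy_alpha = noteworthy_alpha,
                 noteworthy_lfc_low = noteworthy_lfc_low),
            class = "abundance_thresholds")
}

#' Classify antibodies from fold change and adjusted p
#'
#' @param log_fc log2 fold changes.
#' @param p_adj adjusted p values.
#' @param thresholds a [classification_thresholds()] object.
#' @return A factor with levels `differential`, `noteworthy`,
#'   `nonsignificant`.
#' @examples
#' classify_abundance(0.6, 0.01)  # differential
#' classify_abundance(0.6, 0.5)   # noteworthy
#' @export
classify_abundance <- function(log_fc, p_adj,
                               thresholds = classification_thresholds()) {
  stopifnot(inherits(thresholds, "abundance_thresholds"))
  th <- thresholds
  cls <- rep("nonsignificant", length(log_fc))
  if (th$preset == "results") {
    cls[abs(log_fc) > th$lfc & p_adj < th$noteworthy_alpha] <- "noteworthy"
    cls[abs(log_fc) > th$lfc & p_adj < th$alpha] <- "differential"
  } else {
    cls[abs(log_fc) > th$noteworthy_lfc_low & abs(log_fc) <= th$lfc &
          p_adj < th$alpha] <- "noteworthy"
    cls[abs(log_fc) > th$lfc & p_adj < th$alpha] <- "differential"
  }
  factor(cls, levels = c("differential", "noteworthy", "nonsignificant"))
}

#' Empirical-Bayes moderated contrast of normalized log-ratios
#'
#' Fits, per antibody, an ordinary least-squares cell-means model over the
#' condition labels and tests a linear contrast of condition means with an
#' empirical-Bayes moderated t statistic. The residual variance of each
#' antibody is shrunk toward a prior estimated across antibodies:
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)`, with prior degrees of
#' freedom `d0` and prior variance `s0^2` estimated by the method of
#' moments on `log(s2)` (matching the standard scaled-inverse-chi-square
#' empirical-Bayes construction). The moderated statistic
#' `t = log_fc / sqrt(s2_post * c' (X'X)^-1 c)` is referred to a t
#' distribution on `d0 + d` degrees of freedom.
#'
#' Setting `d0 = 0` disables moderation (ordinary t per antibody);
#' a non-finite moments estimate of `d0` is treated as an infinite,
#' fully pooled prior.
#'
#' @param m matrix of normalized log2 ratios (antibodies x samples), e.g.
#'   `normalize_ma(...)$m_values`.
#' @param condition character or factor of length `ncol(m)` assigning each
#'   sample to a condition (for example `"ALI_TPP_t6"`, `"baseline"`).
#' @param contrast named numeric contrast over condition levels, e.g.
#'   `c(ALI_TPP_t6 = 1, baseline = -1)`; omitted levels get weight 0.
#' @param d0 optional override of the prior degrees of freedom.
#' @param thresholds a [classification_thresholds()] object for the
#'   classification column.
#' @return An object of class `moderated_contrast`: a `data.frame` with
#'   columns `antibody_id`, `log_fc`, `t`, `df_total`, `p_raw`, `p_adj`,
#'   `class`, and attributes `d0`, `s0_2`, `df_residual`, `contrast`.
#' @export
moderated_contrast <- function(m, condition, contrast, d0 = NULL,
                               thresholds = classification_thresholds()) {
  stopifnot(is.matrix(m))
  condition <- factor(condition)
  if (length(condition) != ncol(m)) {
    stop("moderated_contrast: 'condition' must label every column of 'm'",
         call. = FALSE)
  }
  used <- names(contrast)[contrast != 0]
  missing_lv <- setdiff(used, levels(condition))
  if (length(missing_lv)) {
    stop(sprintf("moderated_contrast: contrast names not in conditions: %s",
                 paste(missing_lv, collapse = ", ")), call. = FALSE)
  }
  small <- used[table(condition)[used] < 2]
  if (length(small)) {
    stop(sprintf("moderated_contrast: condition(s) with fewer than 2 samples: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  X <- stats::model.matrix(~ 0 + condition)
  colnames(X) <- levels(condition)
  n <- ncol(m); k <- qr(X)$rank
  d <- n - k
  if (d <= 0) {
    stop("moderated_contrast: zero residual degrees of freedom; pool conditions or add samples",
         call. = FALSE)
  }
  cvec <- stats::setNames(rep(0, nlevels(condition)), levels(condition))
  cvec[names(contrast)] <- contrast

  xtx_inv <- solve(crossprod(X))
  beta <- m %*% X %*% xtx_inv          # antibodies x levels (cell means)
  resid <- m - beta %*% t(X)
  s2 <- rowSums(resid^2) / d
  log_fc <- drop(beta %*% cvec)
  var_scale <- drop(t(cvec) %*% xtx_inv %*% cvec)

  # hyperparameters by moments on log(s2); zero-variance antibodies excluded
  pos <- s2 > 0 & is.finite(s2)
  if (is.null(d0)) {
    z <- log(s2[pos])
    e <- z - digamma(d / 2) + log(d / 2)
    evar <- stats::var(e)
    t2 <- evar - trigamma(d / 2)
    if (is.finite(t2) && t2 > 0) {
      d0 <- 2 * trigamma_inverse(t2)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_2 <- exp(mean(e))
    }
  } else {
    s0_2 <- if (any(pos)) exp(mean(log(s2[pos]))) else NA_real_
  }
  if (!is.finite(d0)) {
    d0 <- Inf
    s2_post <- rep(s0_2, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  }
  df_total <- d0 + d
  tstat <- log_fc / sqrt(s2_post * var_scale)
  p_raw <- 2 * stats::pt(-abs(tstat), df = df_total)
  p_raw <- pmin(pmax(p_raw, .Machine$double.xmin), 1)
  p_adj <- bh_adjust(p_raw)
  cls <- classify_abundance(log_fc, p_adj, thresholds)

  out <- data.frame(antibody_id = rownames(m), log_fc = log_fc, t = tstat,
                    df_total = df_total, p_raw = p_raw, p_adj = p_adj,
                    class = cls, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "df_residual") <- d
  attr(out, "contrast") <- cvec
  attr(out, "thresholds") <- thresholds
  class(out) <- c("moderated_contrast", "data.frame")
  out
}

#' @export
print.moderated_contrast <- function(x, ...) {
  cv <- attr(x, "contrast")
  cat(sprintf("moderated contrast (%s): %d antibodies\n",
              paste(sprintf("%+g*%s", cv[cv != 0], names(cv)[cv != 0]),
                    collapse = " "), nrow(x)))
  cat(sprintf("  prior df d0 = %.2f, prior variance s0^2 = %.4f, residual df = %d\n",
              attr(x, "d0"), attr(x, "s0_2"), attr(x, "df_residual")))
  print(table(x$class))
  invisible(x)
}

#' @export
summary.moderated_contrast <- function(object, n = 10, ...) {
  print(object)
  cat(sprintf("top %d antibodies by adjusted p:\n", n))
  o <- order(object$p_adj, object$p_raw)
  print(utils::head(as.data.frame(object)[o, ], n))
  invisible(object)
}

#' @export
coef.moderated_contrast <- function(object, ...) {
  stats::setNames(object$log_fc, object$antibody_id)
}

#' Row/column orderings for a clustered heatmap
#'
#' Centers and scales each antibody row to mean 0 and standard deviation 1,
#' then orders rows and columns by agglomerative hierarchical clustering
#' (average linkage on Euclidean distance), as used to render expression
#' heatmaps. Zero-variance rows are set to all-zero with a warning.
#'
#' @param m numeric matrix (antibodies x samples), at least 2 x 2.
#' @return A list with `scaled` (the z-scored matrix), `row_order`,
#'   `col_order`, `row_hclust`, `col_hclust`.
#' @export
cluster_order <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("cluster_order: need at least 2 antibodies and 2 samples",
         call. = FALSE)
  }
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    warning(sprintf("cluster_order: %d zero-variance antibody row(s) scaled to zero",
                    sum(zero)), call. = FALSE)
    sdv[zero] <- 1
  }
  z <- (m - mu) / sdv
  z[zero, ] <- 0
  rh <- stats::hclust(stats::dist(z), method = "average")
  ch <- stats::hclust(stats::dist(t(z)), method = "average")
  list(scaled = z, row_order = rh$order, col_order = ch$order,
       row_hclust = rh, col_hclust = ch)
}
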