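test_that("replicate aggregation takes the background-floored median", {
  mk <- function(int, bg = NULL) {
    d <- data.frame(sample_id = "s1", antibody_id = "ab1",
                    channel = "sample", replicate = seq_along(int),
                    intensity = int)
    if (!is.null(bg)) d$background <- bg
    d
  }
  expect_equal(aggregate_replicates(mk(rep(100, 4)))$intensity, 100)
  expect_equal(aggregate_replicates(mk(c(1, 2, 3, 100)))$intensity, 2.5)
  expect_equal(aggregate_replicates(mk(50, bg = 60))$intensity, 1)  # floored
  expect_true(is.na(aggregate_replicates(mk(rep(NA_real_, 4)))$intensity))
  cvd <- aggregate_replicates(mk(c(90, 100, 110, 100)))
  expect_equal(cvd$cv, sd(c(90, 100, 110, 100)) / 100)
  expect_equal(cvd$n_spots, 4L)
})

test_that("identical channels give zero M before and after normalization", {
  set.seed(1)
  n <- 60
  intens <- 2^runif(n, 6, 14)
  spots <- rbind(
    data.frame(sample_id = "s1", antibody_id = sprintf("a%02d", 1:n),
               channel = "sample", replicate = 1, intensity = intens),
    data.frame(sample_id = "s1", antibody_id = sprintf("a%02d", 1:n),
               channel = "reference", replicate = 1, intensity = intens))
  ma <- ma_values(aggregate_replicates(spots))
  expect_equal(unname(ma$m_values[, 1]), rep(0, n))
  norm <- normalize_ma(ma)
  expect_equal(max(abs(norm$m_values)), 0, tolerance = 1e-10)
})

test_that("rank-invariant lowess removes a planted smooth dye bias", {
  set.seed(42)
  n <- 300
  a <- matrix(runif(n, 6, 14), ncol = 1,
              dimnames = list(sprintf("a%03d", 1:n), "s1"))
  m <- 0.3 + 0.1 * a            # pure intensity-dependent bias, null truth
  norm <- normalize_ma(list(m_values = m, a_values = a))
  inv <- norm$invariant[, 1]
  expect_gt(sum(inv), 100)
  expect_lt(median(abs(norm$m_values[inv, 1])), 0.02)
})

test_that("tiny invariant sets fall back to median centering with a warning", {
  set.seed(5)
  n <- 40
  a <- matrix(rnorm(n, 10), ncol = 1, dimnames = list(paste0("a", 1:n), "s1"))
  m <- matrix(rnorm(n, 2), ncol = 1, dimnames = dimnames(a))
  expect_warning(norm <- normalize_ma(list(m_values = m, a_values = a),
                                      rank_tol = 0), "median centering")
  expect_equal(median(norm$m_values[, 1]), 0)
})

test_that("planted effects survive normalization within 0.1 log2 units", {
  run_case <- function(seed, spot_sd) {
    cfg <- cohort_config(n_per_group = c(ALI_TPP = 5, ALI_PEEP5 = 5),
                         array = list(n_antibodies = 200L, frac_effect = 0.05,
                                      effect_size = 1.0, residual_sd = 0,
                                      spot_sd = spot_sd))
    sim <- simulate_array(cfg, seed = seed)
    ma <- ma_values(aggregate_replicates(sim$spots))
    norm <- normalize_ma(ma)
    meta <- unique(sim$spots[, c("sample_id", "group", "timepoint")])
    meta <- meta[match(colnames(norm$m_values), meta$sample_id), ]
    eff_cols <- meta$group == "ALI_TPP" & meta$timepoint == "t6"
    ref_cols <- meta$timepoint == "baseline"
    contrast_est <- function(m) {
      rowMeans(m[, eff_cols, drop = FALSE]) -
        rowMeans(m[, ref_cols, drop = FALSE])
    }
    truth <- sim$truth[match(rownames(ma$m_values), sim$truth$antibody_id), ]
    list(est = contrast_est(norm$m_values),
         shift = contrast_est(norm$m_values) -
           contrast_est(ma$m_values - truth$dye_bias),
         planted = truth$planted)
  }
  # no measurement noise: every planted contrast recovered within 0.1 and
  # every null contrast exactly zero after bias removal
  r0 <- run_case(9, spot_sd = 0)
  expect_true(all(abs(r0$est[r0$planted] - 1.0) < 0.1))
  expect_equal(max(abs(r0$est[!r0$planted])), 0, tolerance = 1e-8)
  # spot-level noise: normalization itself never moves a planted contrast by
  # more than 0.1 log2 units relative to exact bias subtraction
  r1 <- run_case(9, spot_sd = 0.1)
  expect_lt(max(abs(r1$shift[r1$planted])), 0.1)
  expect_lt(abs(mean(r1$est[!r1$planted])), 0.05)
})

test_that("moderated contrast is null for identical group means", {
  set.seed(2)
  m <- matrix(rnorm(50 * 8, sd = 0.5), 50, 8,
              dimnames = list(sprintf("a%02d", 1:50), sprintf("s%d", 1:8)))
  cond <- rep(c("g1", "g2"), each = 4)
  shift <- rnorm(50)
  m <- m + shift            # same shift in both groups
  fit <- moderated_contrast(m, cond, c(g1 = 1, g2 = -1))
  expect_lt(max(abs(fit$log_fc)), 1.5)
  expect_gt(mean(fit$p_raw), 0.3)   # roughly uniform
  expect_true(all(fit$p_adj >= fit$p_raw))
  expect_true(all(fit$p_raw > 0 & fit$p_raw <= 1))
})

test_that("disabling moderation reproduces the ordinary two-sample t", {
  set.seed(8)
  m <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(sprintf("a%02d", 1:30), sprintf("s%d", 1:10)))
  cond <- rep(c("g1", "g2"), each = 5)
  fit <- moderated_contrast(m, cond, c(g1 = 1, g2 = -1), d0 = 0)
  for (i in c(1, 7, 30)) {
    o <- ordinary_t_oracle(m[i, 1:5], m[i, 6:10])
    expect_equal(fit$t[i], o$t)
    expect_equal(fit$p_raw[i], o$p)
  }
})

test_that("an infinite prior fully pools the variance", {
  set.seed(13)
  m <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(sprintf("a%02d", 1:40), sprintf("s%d", 1:8)))
  cond <- rep(c("g1", "g2"), each = 4)
  fit <- moderated_contrast(m, cond, c(g1 = 1, g2 = -1), d0 = Inf)
  s0 <- attr(fit, "s0_2")
  expect_equal(fit$t, fit$log_fc / sqrt(s0 * (1 / 4 + 1 / 4)))
})

test_that("moderated statistics agree with the established empirical-Bayes fit", {
  library(limma)
  set.seed(21)
  m <- matrix(rnorm(200 * 10, sd = rep(sqrt(1 / rgamma(200, 4, 4)), 10)),
              200, 10, dimnames = list(sprintf("a%03d", 1:200),
                                       sprintf("s%d", 1:10)))
  m[1:10, 6:10] <- m[1:10, 6:10] + 2
  cond <- rep(c("base", "treat"), each = 5)
  fit <- moderated_contrast(m, cond, c(treat = 1, base = -1))
  design <- model.matrix(~ 0 + factor(cond, levels = c("base", "treat")))
  colnames(design) <- c("base", "treat")
  lfit <- eBayes(contrasts.fit(lmFit(m, design),
                               makeContrasts(treat - base, levels = design)))
  expect_equal(fit$log_fc, unname(lfit$coefficients[, 1]), tolerance = 1e-8)
  expect_equal(attr(fit, "d0"), lfit$df.prior, tolerance = 0.05)
  expect_equal(fit$t, unname(lfit$t[, 1]), tolerance = 1e-3)
  expect_equal(fit$p_raw, unname(lfit$p.value[, 1]), tolerance = 1e-3)
})

test_that("moderated contrast rejects degenerate designs", {
  m <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(paste0("a", 1:20), paste0("s", 1:4)))
  expect_error(moderated_contrast(m, rep(c("g1", "g2"), c(1, 3)),
                                  c(g1 = 1, g2 = -1)), "fewer than 2")
  expect_error(moderated_contrast(m, rep("g1", 4), c(g1 = 1, g9 = -1)),
               "not in conditions")
  expect_error(moderated_contrast(m, paste0("g", 1:4 %/% 1),
                                  c(g1 = 1, g2 = -1)), "fewer than 2")
})

test_that("BH adjustment validates input and matches the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.05)),
               c(0.04, 0.05, 0.05, 0.05))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("classification follows the configured thresholds", {
  expect_equal(as.character(classify_abundance(0.6, 0.01)), "differential")
  expect_equal(as.character(classify_abundance(0.6, 0.5)), "noteworthy")
  expect_equal(as.character(classify_abundance(0.6, 0.95)), "nonsignificant")
  expect_equal(as.character(classify_abundance(0.0, 0.001)), "nonsignificant")
  th <- classification_thresholds("methods")
  expect_equal(th$alpha, 0.005)
  expect_equal(as.character(classify_abundance(0.4, 0.001, th)), "noteworthy")
  expect_equal(as.character(classify_abundance(0.6, 0.001, th)), "differential")
  expect_equal(as.character(classify_abundance(0.6, 0.01, th)), "nonsignificant")
})

test_that("cluster ordering scales rows and separates planted blocks", {
  set.seed(30)
  m <- matrix(rnorm(20 * 6, sd = 0.1), 20, 6,
              dimnames = list(sprintf("a%02d", 1:20), sprintf("s%d", 1:6)))
  m[, 1:3] <- m[, 1:3] + 2   # two opposite sample blocks
  m[, 4:6] <- m[, 4:6] - 2
  cl <- cluster_order(m)
  expect_equal(unname(rowMeans(cl$scaled)), rep(0, 20), tolerance = 1e-9)
  expect_equal(unname(apply(cl$scaled, 1, sd)), rep(1, 20), tolerance = 1e-9)
  expect_true(all(diff(cl$col_order %in% 1:3 * 1) %in% c(0, 1, -1)))
  blocks <- cl$col_order %in% 1:3
  expect_equal(sum(rle(blocks)$lengths %in% 3), 2)  # contiguous blocks of 3
  # identical samples end up adjacent
  m2 <- m; m2[, 2] <- m2[, 1]
  cl2 <- cluster_order(m2)
  pos <- match(1:2, cl2$col_order)
  expect_equal(abs(diff(pos)), 1)
  # zero-variance rows are flagged and zeroed
  m3 <- m; m3[1, ] <- 5
  expect_warning(cl3 <- cluster_order(m3), "zero-variance")
  expect_equal(unname(cl3$scaled[1, ]), rep(0, 6))
})
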