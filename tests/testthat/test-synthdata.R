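test_that("single-compartment pressures follow the generative formula", {
  p <- single_compartment_pressures(peep = 5, tidal_volume_ml = 300, crs = 30)
  expect_equal(p$p_plat, 15)
  expect_equal(p$p_peak, 15)
  expect_equal(single_compartment_pressures(5, 300, 30, resistive = 8)$p_peak, 23)
  expect_error(single_compartment_pressures(5, 300, crs = -1), "crs")
})

test_that("noiseless titrated arm reaches the hand-solved fixed point", {
  cfg <- cohort_config(n_per_group = c(ALI_TPP = 1L),
                       mechanics = list(pressure_sd = 0, es_sd = 0,
                                        body_weight_sd = 0))
  m <- simulate_mechanics(cfg, seed = 1)
  # chest wall p_es_exp = 4.7 + 0.45 * PEEP; hand-iterating the rule:
  # 5 (TPP -1.95, low) -> round(6.95 + 1.5) = 8 (TPP -0.3, low)
  #   -> round(8.3 + 1.5) = 10 (TPP 0.8, in band) -> stays 10
  peep_fix <- 5
  for (i in 1:10) {
    pes <- 4.7 + 0.45 * peep_fix
    if (peep_fix - pes < 0 || peep_fix - pes > 3) {
      peep_fix <- round(pes + 1.5)
    }
  }
  t6 <- m[m$timepoint == "t6", ]
  expect_equal(t6$peep, peep_fix)
  expect_equal(t6$peep, 10)
  tpp <- t6$peep - t6$p_es_exp
  expect_true(tpp >= 0 && tpp <= 3)
})

test_that("generated driving pressure concentrates on its configured expectation", {
  cfg <- cohort_config(n_per_group = c(ALI_PEEP5 = 200L))
  m <- derive_mechanics_table(simulate_mechanics(cfg, seed = 7))
  t6 <- m[m$timepoint == "t6", ]
  # fixed PEEP 5, injured compliance 25: E[delta_p] = E[vt]/25 = 12 with
  # vt = 6 mL/kg of a 50 +/- 6 kg pig; plateau noise is mean-zero
  expected <- 6 * 50 / 25
  se <- sd(t6$delta_p) / sqrt(nrow(t6))
  expect_lt(abs(mean(t6$delta_p) - expected), 2 * se + 0.05)
})

test_that("histology generator matches its closed-form expectation", {
  cfg <- cohort_config(n_per_group = c(ALI_PEEP5 = 9L),
                       histology = list(n_fields = 20, n_samples_per_side = 30))
  h <- simulate_histology(cfg, seed = 3)
  left <- h[h$lung_side == "left", ]      # 9*30*20 = 5400 fields
  pts <- categorize_field(left$alveolar_neutrophils,
                          left$interstitial_neutrophils,
                          left$septal_thickening_fold)
  obs <- modified_lis(pts)$score
  r <- cfg$histology$rates$ALI_PEEP5$left
  expect_lt(abs(obs - expected_modified_lis(r$lambda_alv, r$lambda_int,
                                            r$fold_meanlog, r$fold_sdlog)),
            0.02)
})

test_that("degenerate histology rates force the score extremes", {
  rates0 <- list(lambda_alv = 0, lambda_int = 0,
                 fold_meanlog = 0, fold_sdlog = 1e-9)  # fold == 1
  cfg <- cohort_config(n_per_group = c(SHAM_PEEP5 = 2L),
                       histology = list(rates = list(SHAM_PEEP5 = list(
                         left = rates0, right = rates0))))
  h <- simulate_histology(cfg, seed = 5)
  side <- lis_side_scores(h)
  expect_equal(side$lis, rep(0, 4))
  expect_equal(expected_modified_lis(0, 0, 0, 1e-9), 0)
  # all-maximal category probabilities give the 0.72 ceiling
  expect_equal(expected_modified_lis(1e6, 1e6, log(100), 1e-9), 0.72)
})

test_that("HRCT generator matches its closed-form expectation", {
  expect_equal(expected_hrct_score(c(1, 1, 1, 1)), 250)
  al <- c(0.8, 2.4, 4.2, 0.9)
  cfg <- cohort_config(n_per_group = c(ALI_PEEP5 = 4L),
                       hrct = list(n_regions = 700,
                                   alphas = list(ALI_PEEP5 = list(
                                     left = list(expiratory = al,
                                                 inspiratory = al),
                                     right = list(expiratory = al,
                                                  inspiratory = al)))))
  h <- simulate_hrct(cfg, seed = 11)
  s <- hrct_side_scores(h)
  # all 16 animal/side/hold cells share alpha: pool the 11200 regions
  expect_lt(abs(mean(s$score) - expected_hrct_score(al)), 1)
  # concentration mass on normal pins every region near 100
  cfg2 <- cohort_config(n_per_group = c(ALI_PEEP5 = 1L),
                        hrct = list(n_regions = 5,
                                    alphas = list(ALI_PEEP5 = list(
                                      left = list(expiratory = c(5000, 1e-3, 1e-3, 1e-3),
                                                  inspiratory = c(5000, 1e-3, 1e-3, 1e-3)),
                                      right = list(expiratory = c(5000, 1e-3, 1e-3, 1e-3),
                                                   inspiratory = c(5000, 1e-3, 1e-3, 1e-3))))))
  h2 <- simulate_hrct(cfg2, seed = 2)
  expect_lt(max(abs(hrct_side_scores(h2)$score - 100)), 1)
})

test_that("noiseless array generation recovers planted effects exactly", {
  cfg <- cohort_config(n_per_group = c(ALI_TPP = 2L, ALI_PEEP5 = 2L),
                       array = list(n_antibodies = 30L, frac_effect = 0,
                                    effect_size = 0, residual_sd = 0,
                                    spot_sd = 0, bias = c(0, 0)))
  sim <- simulate_array(cfg, seed = 1)
  ma <- ma_values(aggregate_replicates(sim$spots))
  expect_equal(max(abs(ma$m_values)), 0)
  # a planted +1 effect with no noise is recovered exactly from raw M
  cfg2 <- cohort_config(n_per_group = c(ALI_TPP = 2L, ALI_PEEP5 = 2L),
                        array = list(n_antibodies = 30L, frac_effect = 0.2,
                                     effect_size = 1.0, residual_sd = 0,
                                     spot_sd = 0, bias = c(0, 0)))
  sim2 <- simulate_array(cfg2, seed = 2)
  ma2 <- ma_values(aggregate_replicates(sim2$spots))
  meta <- unique(sim2$spots[, c("sample_id", "group", "timepoint")])
  meta <- meta[match(colnames(ma2$m_values), meta$sample_id), ]
  eff <- meta$group == "ALI_TPP" & meta$timepoint == "t6"
  lfc <- rowMeans(ma2$m_values[, eff, drop = FALSE])
  expect_equal(unname(lfc[sim2$truth$planted]),
               rep(1, sum(sim2$truth$planted)))
  expect_equal(unname(lfc[!sim2$truth$planted]),
               rep(0, sum(!sim2$truth$planted)))
})

test_that("the generator is deterministic given config and seed", {
  cfg <- cohort_config(n_per_group = c(ALI_PEEP5 = 2L, ALI_TPP = 2L,
                                       SHAM_PEEP5 = 2L),
                       array = list(n_antibodies = 40L))
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a$mechanics, b$mechanics)
  expect_identical(a$histology, b$histology)
  expect_identical(a$hrct, b$hrct)
  expect_identical(a$array, b$array)
  c2 <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(a$mechanics, c2$mechanics))
})

test_that("generated tables round-trip through the module readers", {
  cfg <- cohort_config(n_per_group = c(ALI_PEEP5 = 2L, ALI_TPP = 2L,
                                       SHAM_PEEP5 = 2L),
                       array = list(n_antibodies = 40L))
  sim <- simulate_cohort(cfg, seed = 17)
  f <- tempfile(fileext = ".tsv")
  write.table(sim$mechanics, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(f)
  derived <- derive_mechanics_table(back)
  expect_equal(derived$delta_p, back$p_plat - back$peep)
  write.table(sim$histology, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(lis_side_scores(read.delim(f)))
  write.table(sim$hrct, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(hrct_side_scores(read.delim(f)))
  unlink(f)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(mechanics = list(groups = list(
    ALI_PEEP5 = list(crs_injured = -5, resistive = 1, rr = 20,
                     es_intercept = 1, es_slope = 0.4,
                     peep_strategy = "fixed", fixed_peep = 5)))),
    "compliance")
  expect_error(cohort_config(n_per_group = c(NOSUCH = 3L)), "NOSUCH")
})
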