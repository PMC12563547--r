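# Synthetic-cohort generator: virtual pigs with mechanics time courses,
# histology fields, HRCT regions, and dual-channel array intensities, with
# known ground truth for every pipeline stage.

#' Configuration of a synthetic asymmetric-lung-injury cohort
#'
#' Returns the full parameter set of the cohort generator. The `"paper"`
#' preset is calibrated so that group summaries of the generated data land
#' near the published t6 group means: two injury arms (fixed PEEP 5 vs
#' TPP-guided PEEP, n = 6 each) and a small sham arm (n = 2), a left-sided
#' (lavaged) lung injury, histology field rates giving a modified lung
#' injury score near 0.55 on the injured side versus 0.27-0.30 on the
#' non-injured side, HRCT pattern mixtures giving side scores near 260
#' (injured) versus 115-145 (non-injured), and array intensities with
#' planted effects in the TPP arm at t6 plus a smooth intensity-dependent
#' dye bias.
#'
#' Mechanics use a single-compartment model: `p_plat = peep + vt/crs`,
#' `p_peak = p_plat + resistive`, with a linear chest-wall response
#' `p_es_exp = es_intercept + es_slope * peep` and an inspiratory esophageal
#' swing `vt / cw_compliance`. Injury reduces respiratory-system compliance;
#' PEEP above 5 cmH2O recruits the injured lung at `recruit_gain`
#' mL/cmH2O per cmH2O, capped at the healthy compliance.
#'
#' @param preset currently only `"paper"`.
#' @param n_per_group named integer vector of animals per group.
#' @param seed default seed recorded in the config (simulators take their
#'   own `seed` argument).
#' @param mechanics,histology,hrct,array named lists of overrides merged
#'   into the preset parameter blocks.
#' @param dropout if `TRUE`, each injury-arm animal is excluded with the
#'   configured probability (emulating pneumothorax-style dropouts);
#'   default off.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(preset = "paper",
                          n_per_group = c(ALI_PEEP5 = 6L, ALI_TPP = 6L,
                                          SHAM_PEEP5 = 2L),
                          seed = 42L,
                          mechanics = list(), histology = list(),
                          hrct = list(), array = list(),
                          dropout = FALSE) {
  preset <- match.arg(preset)
  mech_default <- list(
    body_weight_kg = 50, body_weight_sd = 6,
    vt_ml_per_kg = 6, fio2 = 0.4, cw_compliance = 55,
    crs_healthy = 37.5, recruit_gain = 1.7,
    pressure_sd = 1.5, es_sd = 1.0,
    groups = list(
      ALI_PEEP5  = list(crs_injured = 25, resistive = 12.8, rr = 25,
                        es_intercept = 4.7, es_slope = 0.45,
                        peep_strategy = "fixed", fixed_peep = 5),
      ALI_TPP    = list(crs_injured = 25, resistive = 10.0, rr = 25,
                        es_intercept = 4.7, es_slope = 0.45,
                        peep_strategy = "titrated", fixed_peep = 5),
      SHAM_PEEP5 = list(crs_injured = 37.5, resistive = 7.3, rr = 22,
                        es_intercept = 1.05, es_slope = 0.45,
                        peep_strategy = "fixed", fixed_peep = 5)))
  histo_default <- list(
    n_fields = 20, n_samples_per_side = 3,
    rates = list(
      ALI_PEEP5 = list(
        left  = list(lambda_alv = 7.0, lambda_int = 5.0,
                     fold_meanlog = log(3.0), fold_sdlog = 0.5),
        right = list(lambda_alv = 1.6, lambda_int = 1.3,
                     fold_meanlog = log(1.6), fold_sdlog = 0.4)),
      ALI_TPP = list(
        left  = list(lambda_alv = 6.5, lambda_int = 4.8,
                     fold_meanlog = log(2.9), fold_sdlog = 0.5),
        right = list(lambda_alv = 1.4, lambda_int = 1.2,
                     fold_meanlog = log(1.6), fold_sdlog = 0.4)),
      SHAM_PEEP5 = list(
        left  = list(lambda_alv = 2.0, lambda_int = 1.6,
                     fold_meanlog = log(1.7), fold_sdlog = 0.4),
        right = list(lambda_alv = 2.0, lambda_int = 1.6,
                     fold_meanlog = log(1.7), fold_sdlog = 0.4))))
  hrct_default <- list(
    n_regions = 3,
    alphas = list(
      ALI_PEEP5 = list(
        left  = list(expiratory  = c(0.8, 2.4, 4.2, 0.9),
                     inspiratory = c(0.7, 2.2, 4.4, 1.0)),
        right = list(expiratory  = c(5.5, 1.6, 0.6, 0.2),
                     inspiratory = c(6.4, 1.2, 0.3, 0.1))),
      ALI_TPP = list(
        left  = list(expiratory  = c(0.8, 2.4, 4.2, 0.9),
                     inspiratory = c(0.7, 2.2, 4.4, 1.0)),
        right = list(expiratory  = c(6.8, 1.0, 0.3, 0.1),
                     inspiratory = c(7.0, 0.8, 0.15, 0.05))),
      SHAM_PEEP5 = list(
        left  = list(expiratory  = c(8.0, 0.7, 0.2, 0.1),
                     inspiratory = c(8.4, 0.5, 0.08, 0.02)),
        right = list(expiratory  = c(8.0, 0.7, 0.2, 0.1),
                     inspiratory = c(8.4, 0.5, 0.08, 0.02)))))
  array_default <- list(
    n_antibodies = 300L, n_replicates = 4L,
    frac_effect = 0.05, effect_size = 2.0,
    effect_group = "ALI_TPP", effect_timepoint = "t6",
    residual_sd = 0.5, spot_sd = 0.1,
    bias = c(0.3, 0.1),          # dye bias b0 + b1 * A on the sample channel
    baseline_meanlog2 = 10, baseline_sdlog2 = 2)

  cfg <- list(preset = preset,
              n_per_group = n_per_group,
              timepoints = c("baseline", paste0("t", 0:6)),
              seed = seed,
              mechanics = utils::modifyList(mech_default, mechanics),
              histology = utils::modifyList(histo_default, histology),
              hrct = utils::modifyList(hrct_default, hrct),
              array = utils::modifyList(array_default, array),
              dropout = dropout, dropout_prob = 0.18)
  stopifnot(all(cfg$n_per_group >= 1), !is.null(names(cfg$n_per_group)))
  with(cfg$mechanics, stopifnot(pressure_sd >= 0, es_sd >= 0,
                                crs_healthy > 0, cw_compliance > 0))
  stopifnot(cfg$array$frac_effect >= 0, cfg$array$frac_effect <= 1,
            cfg$array$residual_sd >= 0, cfg$array$spot_sd >= 0)
  for (g in names(cfg$n_per_group)) {
    gm <- cfg$mechanics$groups[[g]]
    if (is.null(gm)) stop(sprintf("cohort_config: no mechanics parameters for group '%s'", g))
    if (gm$crs_injured <= 0) stop("cohort_config: compliance must be positive")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("synthetic cohort config ('%s' preset): %s; timepoints %s\n",
              x$preset,
              paste(sprintf("%s n=%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", "),
              paste(x$timepoints, collapse = ", ")))
  invisible(x)
}

cohort_animals <- function(config) {
  ids <- unlist(lapply(names(config$n_per_group), function(g) {
    paste0(g, "_", seq_len(config$n_per_group[[g]]))
  }))
  groups <- rep(names(config$n_per_group), config$n_per_group)
  data.frame(animal_id = ids, group = groups)
}

#' Static single-compartment airway pressures
#'
#' The generative model behind the mechanics simulator:
#' `p_plat = peep + tidal_volume_ml / crs` and
#' `p_peak = p_plat + resistive`.
#'
#' @param peep applied PEEP, cmH2O.
#' @param tidal_volume_ml tidal volume, mL.
#' @param crs respiratory-system compliance, mL/cmH2O (> 0).
#' @param resistive resistive pressure increment of the peak over the
#'   plateau, cmH2O.
#' @return A list with `p_plat` and `p_peak`.
#' @export
single_compartment_pressures <- function(peep, tidal_volume_ml, crs,
                                         resistive = 0) {
  check_that(crs > 0, "crs", "must be positive")
  p_plat <- peep + tidal_volume_ml / crs
  list(p_plat = p_plat, p_peak = p_plat + resistive)
}

#' Simulate per-animal ventilator readings over the study time course
#'
#' Generates one hold-maneuver reading per animal and timepoint (baseline
#' plus hourly t0-t6). Baseline readings are pre-injury (healthy
#' compliance); from t0 onward the injury arms carry the reduced injured
#' compliance. The fixed arms keep PEEP constant; the titrated arm applies
#' [titrate_peep()] hourly against the linear chest-wall response, so PEEP
#' converges to the band fixed point.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A `data.frame` with one row per animal x timepoint, columns
#'   `animal_id`, `group`, `timepoint`, `p_peak`, `p_plat`, `peep`,
#'   `p_es_insp`, `p_es_exp`, `tidal_volume_ml`, `resp_rate`, `fio2`,
#'   `body_weight_kg`, `crs_reported`, `resistance_reported`.
#' @export
simulate_mechanics <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  mc <- config$mechanics
  animals <- cohort_animals(config)
  policy <- titration_policy()
  rows <- list()
  for (i in seq_len(nrow(animals))) {
    g <- animals$group[i]
    gm <- mc$groups[[g]]
    bw <- round(stats::rnorm(1, mc$body_weight_kg, mc$body_weight_sd))
    vt <- round(mc$vt_ml_per_kg * bw / 10) * 10
    peep <- gm$fixed_peep
    last_pes <- NA_real_
    for (tp in config$timepoints) {
      injured <- tp != "baseline" && gm$crs_injured < mc$crs_healthy
      crs0 <- if (injured) gm$crs_injured else mc$crs_healthy
      if (gm$peep_strategy == "titrated" && !(tp %in% c("baseline", "t0"))) {
        peep <- titrate_peep(peep, last_pes, policy)
      }
      crs_eff <- min(mc$crs_healthy,
                     crs0 + if (injured) mc$recruit_gain * max(0, peep - 5) else 0)
      pres <- single_compartment_pressures(peep, vt, crs_eff, gm$resistive)
      p_plat <- pres$p_plat + stats::rnorm(1, 0, mc$pressure_sd)
      p_plat <- max(p_plat, peep)
      p_peak <- max(p_plat, pres$p_peak + stats::rnorm(1, 0, mc$pressure_sd))
      pes_exp <- gm$es_intercept + gm$es_slope * peep +
        stats::rnorm(1, 0, mc$es_sd)
      pes_insp <- pes_exp + vt / mc$cw_compliance +
        stats::rnorm(1, 0, mc$es_sd / 2)
      last_pes <- pes_exp
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = animals$animal_id[i], group = g, timepoint = tp,
        p_peak = p_peak, p_plat = p_plat, peep = peep,
        p_es_insp = pes_insp, p_es_exp = pes_exp,
        tidal_volume_ml = vt, resp_rate = gm$rr, fio2 = mc$fio2,
        body_weight_kg = bw, crs_reported = crs_eff,
        resistance_reported = gm$resistive / 0.75)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Closed-form expected modified lung injury score
#'
#' Expectation of the per-field modified score under the generative model:
#' Poisson neutrophil counts and a log-normal septal-thickening fold. Used
#' as the analytic oracle for the histology simulator.
#'
#' @param lambda_alv,lambda_int Poisson means of the two neutrophil counts.
#' @param fold_meanlog,fold_sdlog log-normal parameters of the thickening
#'   fold.
#' @param denominator per-field denominator (100 by default).
#' @return The expected score.
#' @export
expected_modified_lis <- function(lambda_alv, lambda_int, fold_meanlog,
                                  fold_sdlog, denominator = 100) {
  e_count <- function(lam) {
    p1 <- stats::ppois(5, lam) - stats::ppois(0, lam)
    p2 <- 1 - stats::ppois(5, lam)
    p1 + 2 * p2
  }
  p_mid <- stats::plnorm(4, fold_meanlog, fold_sdlog) -
    stats::plnorm(2, fold_meanlog, fold_sdlog)
  p_high <- 1 - stats::plnorm(4, fold_meanlog, fold_sdlog)
  e_c <- p_mid + 2 * p_high
  (20 * e_count(lambda_alv) + 14 * e_count(lambda_int) + 2 * e_c) / denominator
}

#' Simulate per-field histology observations
#'
#' Draws, for every animal, lung side, and tissue sample, `n_fields`
#' high-power fields with Poisson alveolar and interstitial neutrophil
#' counts and a log-normal septal-thickening fold, at the side- and
#' group-specific rates of the config (the lavaged left lung carries the
#' injury rates in the injury arms).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed, or `NULL`.
#' @return A `data.frame` with one row per field: `animal_id`, `group`,
#'   `lung_side`, `sample_id`, `field`, `alveolar_neutrophils`,
#'   `interstitial_neutrophils`, `septal_thickening_fold`.
#' @export
simulate_histology <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  hc <- config$histology
  animals <- cohort_animals(config)
  rows <- list()
  for (i in seq_len(nrow(animals))) {
    g <- animals$group[i]
    for (side in c("left", "right")) {
      r <- hc$rates[[g]][[side]]
      if (is.null(r)) stop(sprintf("simulate_histology: no rates for %s/%s", g, side))
      for (s in seq_len(hc$n_samples_per_side)) {
        nf <- hc$n_fields
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = animals$animal_id[i], group = g, lung_side = side,
          sample_id = sprintf("S%d", s), field = seq_len(nf),
          alveolar_neutrophils = stats::rpois(nf, r$lambda_alv),
          interstitial_neutrophils = stats::rpois(nf, r$lambda_int),
          septal_thickening_fold = stats::rlnorm(nf, r$fold_meanlog,
                                                 r$fold_sdlog))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Closed-form expected HRCT region score under Dirichlet extents
#'
#' `100 * sum(weights * alpha) / sum(alpha)` for extents drawn as
#' `Dirichlet(alpha) * 100`.
#'
#' @param alpha Dirichlet concentration vector over the four grades
#'   (normal, ground glass, consolidation, bronchodilatation).
#' @param weights grade weights, see [hrct_weights()].
#' @return The expected region (and hence side) score.
#' @export
expected_hrct_score <- function(alpha, weights = hrct_weights()) {
  stopifnot(length(alpha) == length(weights), all(alpha > 0))
  100 * sum(weights * alpha) / sum(alpha)
}

#' Simulate per-region HRCT pattern extents
#'
#' Draws, for every animal, side, and hold maneuver, `n_regions` regions
#' with pattern extents `Dirichlet(alpha) * 100` at the group/side/hold
#' concentrations of the config.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed, or `NULL`.
#' @return A `data.frame` with one row per region: `animal_id`, `group`,
#'   `lung_side`, `hold`, `region_id`, `normal_pct`, `ggo_pct`,
#'   `consolidation_pct`, `bronchodil_pct`.
#' @export
simulate_hrct <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  hc <- config$hrct
  animals <- cohort_animals(config)
  rows <- list()
  for (i in seq_len(nrow(animals))) {
    g <- animals$group[i]
    for (side in c("left", "right")) {
      for (hold in c("expiratory", "inspiratory")) {
        alpha <- hc$alphas[[g]][[side]][[hold]]
        if (is.null(alpha)) {
          stop(sprintf("simulate_hrct: no concentrations for %s/%s/%s",
                       g, side, hold))
        }
        ext <- rdirichlet(hc$n_regions, alpha) * 100
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = animals$animal_id[i], group = g, lung_side = side,
          hold = hold, region_id = seq_len(hc$n_regions),
          normal_pct = ext[, 1], ggo_pct = ext[, 2],
          consolidation_pct = ext[, 3], bronchodil_pct = ext[, 4])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a dual-channel antibody-array experiment
#'
#' Generates spot-level intensities for a reference-design dual-color
#' experiment: per-antibody log-normal baseline abundances shared by the
#' pooled reference channel; sample channels add a biological residual, a
#' planted group-by-timepoint effect on a flagged antibody subset, and a
#' smooth intensity-dependent dye bias (`b0 + b1 * A` on the log2 scale);
#' each channel is printed in replicate spots with multiplicative spot
#' noise. A ground-truth table flags the planted antibodies.
#'
#' @param config a [cohort_config()]; sampled at `baseline` and `t6`.
#' @param seed integer seed, or `NULL`.
#' @return A list with `spots` (long `data.frame`: `sample_id`, `group`,
#'   `timepoint`, `antibody_id`, `replicate`, `channel`, `intensity`) and
#'   `truth` (`antibody_id`, `planted`, `effect_size`).
#' @export
simulate_array <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  ac <- config$array
  animals <- cohort_animals(config)
  n_ab <- ac$n_antibodies
  ab_ids <- sprintf("AB%03d", seq_len(n_ab))
  n_planted <- round(ac$frac_effect * n_ab)
  planted <- rep(FALSE, n_ab)
  if (n_planted > 0) planted[sample.int(n_ab, n_planted)] <- TRUE
  a0 <- stats::rnorm(n_ab, ac$baseline_meanlog2, ac$baseline_sdlog2)

  samples <- expand.grid(animal_id = animals$animal_id,
                         timepoint = c("baseline", "t6"),
                         stringsAsFactors = FALSE)
  samples$group <- animals$group[match(samples$animal_id, animals$animal_id)]
  samples$sample_id <- paste(samples$animal_id, samples$timepoint, sep = "_")

  rows <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    eff <- planted * ac$effect_size *
      (samples$group[s] == ac$effect_group &
         samples$timepoint[s] == ac$effect_timepoint)
    bio <- stats::rnorm(n_ab, 0, ac$residual_sd)
    log2_sample <- a0 + eff + bio + ac$bias[1] + ac$bias[2] * a0
    log2_ref <- a0
    nr <- ac$n_replicates
    spot_noise <- function() stats::rnorm(n_ab * nr, 0, ac$spot_sd)
    rows[[s]] <- data.frame(
      sample_id = samples$sample_id[s], group = samples$group[s],
      timepoint = samples$timepoint[s],
      antibody_id = rep(ab_ids, times = 2 * nr),
      replicate = rep(rep(seq_len(nr), each = n_ab), times = 2),
      channel = rep(c("sample", "reference"), each = n_ab * nr),
      intensity = 2^c(rep(log2_sample, nr) + spot_noise(),
                      rep(log2_ref, nr) + spot_noise()))
  }
  list(spots = do.call(rbind, rows),
       truth = data.frame(antibody_id = ab_ids, planted = planted,
                          effect_size = ifelse(planted, ac$effect_size, 0),
                          baseline_log2 = a0,
                          dye_bias = ac$bias[1] + ac$bias[2] * a0))
}

#' Simulate a complete study dataset
#'
#' Runs all four generators from a single seed (one RNG stream, so the
#' bundle is fully deterministic given config and seed) and applies the
#' optional dropout flag.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return A list with `mechanics`, `histology`, `hrct`, `array` (spots +
#'   truth), `excluded` (dropped animal ids, empty unless
#'   `config$dropout`), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 42L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  excluded <- character(0)
  if (isTRUE(config$dropout)) {
    animals <- cohort_animals(config)
    ali <- animals$animal_id[animals$group != "SHAM_PEEP5"]
    excluded <- ali[stats::runif(length(ali)) < config$dropout_prob]
  }
  out <- list(mechanics = simulate_mechanics(config, seed = NULL),
              histology = simulate_histology(config, seed = NULL),
              hrct = simulate_hrct(config, seed = NULL),
              array = simulate_array(config, seed = NULL),
              excluded = excluded, config = config)
  if (length(excluded)) {
    keep <- function(d) d[!d$animal_id %in% excluded, , drop = FALSE]
    out$mechanics <- keep(out$mechanics)
    out$histology <- keep(out$histology)
    out$hrct <- keep(out$hrct)
    out$array$spots <- out$array$spots[!sub("_(baseline|t6)$", "",
      out$array$spots$sample_id) %in% excluded, , drop = FALSE]
  }
  out
}
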