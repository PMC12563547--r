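# Modified Ichikado HRCT lung injury score: extent-weighted region scores,
# per-side averaging, and expiratory-vs-inspiratory recruitability.

#' Weight table for the modified Ichikado HRCT score
#'
#' The scoring retains the ordinal grades for normal attenuation (1),
#' ground-glass opacity (2) and consolidation (3), and merges the two
#' traction-bronchiectasis grades of the original system into a single
#' "bronchodilatation" grade with weight 4. Honeycombing is excluded: scans
#' in the early exudative phase are not expected to show it.
#'
#' @param normal,ground_glass,consolidation,bronchodilatation grade weights.
#' @return A named numeric vector of weights.
#' @export
hrct_weights <- function(normal = 1, ground_glass = 2, consolidation = 3,
                         bronchodilatation = 4) {
  w <- c(normal = normal, ground_glass = ground_glass,
         consolidation = consolidation, bronchodilatation = bronchodilatation)
  check_numeric(w, "weights")
  w
}

#' Score one CT region from pattern extents
#'
#' The region score is the extent-weighted sum over pattern grades,
#' `sum(weight(grade) * extent_percent(grade))`, so a fully normal region
#' scores 100 and a fully bronchodilatated region 400 under the default
#' weights. Extents are percentages of the region area and must sum to 100
#' within `tol`.
#'
#' @param extents named numeric vector of extents (percent) over the grades
#'   in `weights`.
#' @param weights a weight table from [hrct_weights()].
#' @param tol allowed deviation of `sum(extents)` from 100 (percent).
#' @return The region score (dimensionless).
#' @examples
#' region_score(c(consolidation = 60, normal = 40))  # 220
#' @export
region_score <- function(extents, weights = hrct_weights(), tol = 0.5) {
  check_numeric(extents, "extents")
  check_that(extents >= 0, "extents", "must be non-negative")
  unknown <- setdiff(names(extents), names(weights))
  if (length(unknown)) {
    stop(sprintf("region_score: unknown grade(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (abs(sum(extents) - 100) > tol) {
    stop(sprintf("region_score: extents sum to %.2f, expected 100 +/- %.2f",
                 sum(extents), tol), call. = FALSE)
  }
  sum(weights[names(extents)] * extents)
}

#' Per-side HRCT scores from a region table
#'
#' Scores every region and averages regions to one representative score per
#' animal, lung side, and hold maneuver.
#'
#' @param regions a `data.frame` with one row per region: `animal_id`,
#'   `lung_side` (`"left"`/`"right"`), `hold` (`"expiratory"`/
#'   `"inspiratory"`), `region_id`, and extent columns `normal_pct`,
#'   `ggo_pct`, `consolidation_pct`, `bronchodil_pct`.
#' @param weights a weight table from [hrct_weights()].
#' @param tol extent-sum tolerance passed to [region_score()].
#' @return A `data.frame` with one row per animal x side x hold:
#'   `animal_id`, `lung_side`, `hold`, `n_regions`, `score`.
#' @export
hrct_side_scores <- function(regions, weights = hrct_weights(), tol = 0.5) {
  cols <- c("animal_id", "lung_side", "hold", "region_id",
            "normal_pct", "ggo_pct", "consolidation_pct", "bronchodil_pct")
  check_columns(regions, cols, "hrct_side_scores")
  scores <- vapply(seq_len(nrow(regions)), function(i) {
    region_score(c(normal = regions$normal_pct[i],
                   ground_glass = regions$ggo_pct[i],
                   consolidation = regions$consolidation_pct[i],
                   bronchodilatation = regions$bronchodil_pct[i]),
                 weights = weights, tol = tol)
  }, numeric(1))
  d <- data.frame(animal_id = regions$animal_id, lung_side = regions$lung_side,
                  hold = regions$hold, score = scores)
  agg <- stats::aggregate(score ~ animal_id + lung_side + hold, data = d,
                          FUN = mean)
  n <- stats::aggregate(score ~ animal_id + lung_side + hold, data = d,
                        FUN = length)
  agg$n_regions <- n$score
  rownames(agg) <- NULL
  agg[order(agg$animal_id, agg$lung_side, agg$hold),
      c("animal_id", "lung_side", "hold", "n_regions", "score")]
}

#' Recruitability from expiratory vs inspiratory hold scores
#'
#' The difference between the expiratory-hold and inspiratory-hold score of
#' the same lung indexes recruitability: regions that aerate at the
#' inspiratory hold lower its score, so a positive delta means recruitable
#' lung.
#'
#' @param side_scores output of [hrct_side_scores()] containing both holds
#'   for each animal and side.
#' @return A `data.frame` with `animal_id`, `lung_side`, `expiratory`,
#'   `inspiratory`, `delta` (expiratory minus inspiratory).
#' @export
recruitability <- function(side_scores) {
  check_columns(side_scores, c("animal_id", "lung_side", "hold", "score"),
                "recruitability")
  key <- interaction(side_scores$animal_id, side_scores$lung_side, drop = TRUE)
  out <- lapply(split(side_scores, key), function(d) {
    e <- d$score[d$hold == "expiratory"]
    i <- d$score[d$hold == "inspiratory"]
    if (length(e) != 1 || length(i) != 1) {
      stop(sprintf("recruitability: animal %s side %s lacks a matched hold pair",
                   d$animal_id[1], d$lung_side[1]), call. = FALSE)
    }
    data.frame(animal_id = d$animal_id[1], lung_side = d$lung_side[1],
               expiratory = e, inspiratory = i, delta = e - i)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
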