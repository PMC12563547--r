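# Histological lung injury scoring: per-field categorisation and the
# modified (three-component) and original (five-component) injury scores.

#' Categorise a histology field into injury points
#'
#' Converts raw per-field observations into the ordinal points used by the
#' lung injury score. Neutrophil counts (alveolar and interstitial) are
#' binned none -> 0 points, 1-5 -> 1 point, >5 -> 2 points. Alveolar septal
#' thickening is binned <2x -> 0 points, 2-4x (inclusive) -> 1 point,
#' >4x -> 2 points.
#'
#' @param alveolar_neutrophils,interstitial_neutrophils non-negative integer
#'   counts per high-power field.
#' @param septal_thickening_fold septal thickening as a fold change relative
#'   to normal septa (>= 0).
#' @return A `data.frame` with integer point columns `a`, `b`, `c`.
#' @examples
#' categorize_field(7, 5, 3.0)  # a = 2, b = 1, c = 1
#' @export
categorize_field <- function(alveolar_neutrophils, interstitial_neutrophils,
                             septal_thickening_fold) {
  check_numeric(alveolar_neutrophils, "alveolar_neutrophils")
  check_numeric(interstitial_neutrophils, "interstitial_neutrophils")
  check_numeric(septal_thickening_fold, "septal_thickening_fold")
  check_that(alveolar_neutrophils >= 0 &
               alveolar_neutrophils == round(alveolar_neutrophils),
             "alveolar_neutrophils", "must be a non-negative integer")
  check_that(interstitial_neutrophils >= 0 &
               interstitial_neutrophils == round(interstitial_neutrophils),
             "interstitial_neutrophils", "must be a non-negative integer")
  check_that(septal_thickening_fold >= 0, "septal_thickening_fold",
             "must be non-negative")
  bin_count <- function(x) ifelse(x == 0, 0L, ifelse(x <= 5, 1L, 2L))
  bin_fold  <- function(x) ifelse(x < 2, 0L, ifelse(x <= 4, 1L, 2L))
  data.frame(a = bin_count(alveolar_neutrophils),
             b = bin_count(interstitial_neutrophils),
             c = bin_fold(septal_thickening_fold))
}

check_points <- function(x, field) {
  check_numeric(x, field)
  check_that(x %in% c(0, 1, 2), field, "must contain points in {0, 1, 2}")
}

#' Modified lung injury score
#'
#' Computes the modified lung injury score from per-field points for
#' alveolar neutrophils (A, weight 20), interstitial neutrophils (B, weight
#' 14), and septal thickening (C, weight 2):
#' `score = sum(20 A + 14 B + 2 C) / (n_fields * D)`.
#'
#' The score drops the hyaline-membrane and proteinaceous-debris components
#' of the original five-component score, because they are not expected in
#' the early exudative phase of acute lung injury. Two denominator
#' conventions are supported: `"per_field_100"` (default) keeps the original
#' 100-point per-field normalization, so the score ranges from 0 to 0.72
#' (the documented range); `"per_field_72"` divides by the maximum
#' attainable 72 points per field, so the score ranges to 1.
#'
#' @param fields a `data.frame` with point columns `a`, `b`, `c`
#'   (each in {0, 1, 2}); at least one row.
#' @param denominator denominator convention, see Details.
#' @return An object of class `lis_result`: a list with `score`, `n_fields`,
#'   `variant`, `denominator`.
#' @examples
#' fields <- data.frame(a = rep(2, 20), b = rep(2, 20), c = rep(2, 20))
#' modified_lis(fields)$score  # 0.72
#' @export
modified_lis <- function(fields, denominator = c("per_field_100", "per_field_72")) {
  denominator <- match.arg(denominator)
  check_columns(fields, c("a", "b", "c"), "modified_lis")
  if (nrow(fields) < 1) stop("modified_lis: at least one field required", call. = FALSE)
  check_points(fields$a, "a"); check_points(fields$b, "b"); check_points(fields$c, "c")
  d <- if (denominator == "per_field_100") 100 else 72
  total <- sum(20 * fields$a + 14 * fields$b + 2 * fields$c)
  structure(list(score = total / (nrow(fields) * d),
                 n_fields = nrow(fields),
                 variant = "modified", denominator = denominator),
            class = "lis_result")
}

#' Original five-component lung injury score
#'
#' The standardized score from which the modified score derives, with
#' components A (alveolar neutrophils, weight 20), B (interstitial
#' neutrophils, 14), C (hyaline membranes, 7), D (proteinaceous debris, 7),
#' E (septal thickening, 2), normalized by 100 points per field; range 0-1.
#'
#' @param fields a `data.frame` with point columns `a`..`e` in {0, 1, 2}.
#' @return An object of class `lis_result`.
#' @export
ats_lis <- function(fields) {
  check_columns(fields, c("a", "b", "c", "d", "e"), "ats_lis")
  if (nrow(fields) < 1) stop("ats_lis: at least one field required", call. = FALSE)
  for (f in c("a", "b", "c", "d", "e")) check_points(fields[[f]], f)
  total <- sum(20 * fields$a + 14 * fields$b + 7 * fields$c +
                 7 * fields$d + 2 * fields$e)
  structure(list(score = total / (nrow(fields) * 100),
                 n_fields = nrow(fields),
                 variant = "ats_original", denominator = "per_field_100"),
            class = "lis_result")
}

#' @export
print.lis_result <- function(x, ...) {
  cat(sprintf("%s lung injury score: %.4f (%d fields, denominator %s)\n",
              x$variant, x$score, x$n_fields, x$denominator))
  invisible(x)
}

#' Per-side lung injury scores from a field table
#'
#' Scores each tissue sample (20 random high-power fields per sample by the
#' study's convention) and averages the three site samples per lung side to
#' one value per animal and side, the unit entering the side comparison.
#'
#' @param fields a `data.frame` with one row per field: `animal_id`,
#'   `lung_side` (`"left"`/`"right"`), `sample_id`, and either point columns
#'   `a`, `b`, `c` or raw columns `alveolar_neutrophils`,
#'   `interstitial_neutrophils`, `septal_thickening_fold` (binned via
#'   [categorize_field()]).
#' @param denominator passed to [modified_lis()].
#' @return A `data.frame` with one row per animal and side: `animal_id`,
#'   `lung_side`, `n_samples`, `lis`.
#' @export
lis_side_scores <- function(fields, denominator = "per_field_100") {
  check_columns(fields, c("animal_id", "lung_side", "sample_id"), "lis_side_scores")
  if (!all(c("a", "b", "c") %in% names(fields))) {
    pts <- categorize_field(fields$alveolar_neutrophils,
                            fields$interstitial_neutrophils,
                            fields$septal_thickening_fold)
    fields <- cbind(fields, pts)
  }
  key <- interaction(fields$animal_id, fields$lung_side, fields$sample_id,
                     drop = TRUE)
  per_sample <- do.call(rbind, lapply(split(fields, key), function(d) {
    data.frame(animal_id = d$animal_id[1], lung_side = d$lung_side[1],
               lis = modified_lis(d, denominator = denominator)$score)
  }))
  agg <- stats::aggregate(lis ~ animal_id + lung_side, data = per_sample,
                          FUN = mean)
  n <- stats::aggregate(lis ~ animal_id + lung_side, data = per_sample,
                        FUN = length)
  agg$n_samples <- n$lis
  rownames(agg) <- NULL
  agg[order(agg$animal_id, agg$lung_side), c("animal_id", "lung_side",
                                             "n_samples", "lis")]
}

#' Pair left and right lung values per animal
#'
#' Builds the paired table for the within-animal left-vs-right comparison
#' (Wilcoxon signed-rank). Animals missing a side are excluded with a
#' warning.
#'
#' @param side_table a `data.frame` with columns `animal_id`, `lung_side`,
#'   and a value column.
#' @param value name of the value column (default `"lis"`).
#' @return A `data.frame` with columns `animal_id`, `left`, `right`, `diff`
#'   (left minus right).
#' @export
side_pairs <- function(side_table, value = "lis") {
  check_columns(side_table, c("animal_id", "lung_side", value), "side_pairs")
  wide <- lapply(split(side_table, side_table$animal_id), function(d) {
    l <- d[[value]][d$lung_side == "left"]
    r <- d[[value]][d$lung_side == "right"]
    if (length(l) != 1 || length(r) != 1) return(NULL)
    data.frame(animal_id = d$animal_id[1], left = l, right = r, diff = l - r)
  })
  dropped <- names(wide)[vapply(wide, is.null, logical(1))]
  if (length(dropped)) {
    warning(sprintf("side_pairs: excluding unpaired animal(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  out <- do.call(rbind, wide[!vapply(wide, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
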