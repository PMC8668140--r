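#' Conditioned taste aversion ratio (day 2 / day 1 intake)
#'
#' The strength of a conditioned taste aversion is quantified as day-2 Boost
#' consumption divided by day-1 consumption for the same animal; lower values
#' mean stronger aversion. Subjects that did not drink the minimum day-1
#' volume (default 1 mL) were never conditioned and are ineligible.
#'
#' @param intake_d1 Day-1 intake in mL.
#' @param intake_d2 Day-2 intake in mL.
#' @param min_d1 Minimum day-1 intake for eligibility (mL).
#' @return The dimensionless D2/D1 ratio.
#' @export
#' @examples
#' cta_ratio(10, 2)   # 0.2, strong aversion
cta_ratio <- function(intake_d1, intake_d2, min_d1 = 1) {
  if (any(intake_d1 < 0) || any(intake_d2 < 0)) stop_value("intakes must be >= 0")
  if (any(intake_d1 < min_d1)) {
    abort(sprintf("day-1 intake %.3g mL below the %.3g mL eligibility minimum",
                  min(intake_d1), min_d1),
          class = "fosnet_ineligible_error")
  }
  intake_d2 / intake_d1
}

#' Weight-adjusted intake
#'
#' Converts an intake volume to mL per kg body weight, the standard dosing
#' convention used to compare consumption across animals of different size.
#'
#' @param intake Intake in mL.
#' @param body_weight Body weight in grams (> 0).
#' @return Intake in mL/kg.
#' @export
#' @examples
#' weight_adjusted_intake(10, 250)  # 40 mL/kg
weight_adjusted_intake <- function(intake, body_weight) {
  if (any(body_weight <= 0)) stop_value("body_weight must be positive")
  if (any(intake < 0)) stop_value("intake must be >= 0")
  intake / (body_weight / 1000)
}

#' Score CTA behavior for a table of subjects
#'
#' Applies [cta_ratio()] and [weight_adjusted_intake()] to every subject.
#' Ineligible subjects (day-1 intake below `min_d1`) are kept in the output
#' with `eligible = FALSE` and an `NA` ratio, and listed in the `excluded`
#' attribute rather than raising an error.
#'
#' @param behavior A behavior tibble (see [load_behavior_table()]).
#' @param min_d1 Minimum day-1 intake in mL.
#' @return Tibble with `subject_id, sex, condition, licl_dose, eligible,
#'   d2_d1_ratio, intake_per_kg_d1`.
#' @export
score_cta <- function(behavior, min_d1 = 1) {
  require_columns(behavior, c("subject_id", "sex", "condition", "body_weight",
                              "intake_d1", "intake_d2", "licl_dose"),
                  "behavior table")
  eligible <- behavior$intake_d1 >= min_d1
  out <- tibble::tibble(
    subject_id = behavior$subject_id,
    sex = behavior$sex,
    condition = behavior$condition,
    licl_dose = behavior$licl_dose,
    eligible = eligible,
    d2_d1_ratio = ifelse(eligible, behavior$intake_d2 / behavior$intake_d1, NA_real_),
    intake_per_kg_d1 = weight_adjusted_intake(behavior$intake_d1,
                                              behavior$body_weight)
  )
  structure(out, excluded = behavior$subject_id[!eligible],
            class = class(out))
}

#' Block-percentage scoring of ultrasonic vocalizations
#'
#' A 1-minute block counts as vocalization-positive when the animal emitted
#' more than `thr55` 55 kHz calls, or more than `thr22` 22 kHz calls, in that
#' block (strictly greater than, per the scoring rule; `strict = FALSE`
#' relaxes both to greater-or-equal). Each channel's score is the percentage
#' of the 10 one-minute blocks that were positive, so scores are multiples of
#' 10. The emitter class records which channels were expressed at all.
#'
#' @param counts55,counts22 Length-10 non-negative integer vectors of
#'   per-minute 55 kHz and 22 kHz call counts.
#' @param thr55 Per-block 55 kHz call threshold (default 10).
#' @param thr22 Per-block 22 kHz call threshold (default 1).
#' @param strict Require counts strictly above the threshold (default).
#' @return List with `pct_blocks_55`, `pct_blocks_22` and `emitter_class`
#'   (`"none"`, `"only55"`, `"only22"` or `"both"`).
#' @export
#' @examples
#' usv_block_score(c(12, 11, rep(0, 8)), rep(0, 10))
usv_block_score <- function(counts55, counts22, thr55 = 10, thr22 = 1,
                            strict = TRUE) {
  for (v in list(counts55, counts22)) {
    if (length(v) != 10L) stop_schema("expected exactly 10 one-minute blocks per channel")
    if (any(v < 0) || any(v != floor(v))) stop_value("call counts must be non-negative integers")
  }
  hit <- if (strict) {
    list(counts55 > thr55, counts22 > thr22)
  } else {
    list(counts55 >= thr55, counts22 >= thr22)
  }
  pct55 <- 100 * sum(hit[[1]]) / 10
  pct22 <- 100 * sum(hit[[2]]) / 10
  cls <- if (pct55 > 0 && pct22 > 0) "both"
         else if (pct55 > 0) "only55"
         else if (pct22 > 0) "only22"
         else "none"
  list(pct_blocks_55 = pct55, pct_blocks_22 = pct22, emitter_class = cls)
}

#' Score a wide USV table
#'
#' Applies [usv_block_score()] to every row of a wide per-minute count table
#' (see [load_usv_table()] for the schema).
#'
#' @param usv USV tibble with `min55_1..min55_10` and `min22_1..min22_10`.
#' @inheritParams usv_block_score
#' @return Tibble with `subject_id, sex, condition, pct_blocks_55,
#'   pct_blocks_22, emitter_class`.
#' @export
score_usv <- function(usv, thr55 = 10, thr22 = 1, strict = TRUE) {
  require_columns(usv, c("subject_id", "sex", "condition",
                         paste0("min55_", 1:10), paste0("min22_", 1:10)),
                  "USV table")
  m55 <- as.matrix(usv[, paste0("min55_", 1:10)])
  m22 <- as.matrix(usv[, paste0("min22_", 1:10)])
  res <- lapply(seq_len(nrow(usv)), function(i) {
    usv_block_score(m55[i, ], m22[i, ], thr55 = thr55, thr22 = thr22,
                    strict = strict)
  })
  tibble::tibble(
    subject_id = usv$subject_id,
    sex = usv$sex,
    condition = usv$condition,
    pct_blocks_55 = vapply(res, `[[`, numeric(1), "pct_blocks_55"),
    pct_blocks_22 = vapply(res, `[[`, numeric(1), "pct_blocks_22"),
    emitter_class = vapply(res, `[[`, character(1), "emitter_class")
  )
}

#' Tally of emitting animals by condition, emitter class and sex
#'
#' Counts, for each condition, the number of animals of each sex whose
#' emitter class was 22 kHz only, both 22 and 55 kHz, or 55 kHz only.
#' Non-emitters do not occupy a cell; their per-condition counts are kept in
#' the `none` attribute so that animals are conserved. Row totals count the
#' emitting animals per condition.
#'
#' @param scores Tibble with `subject_id, sex, condition, emitter_class`
#'   (e.g. from [score_usv()]).
#' @param conditions Row order; defaults to the task conditions followed by
#'   any others present.
#' @return Tibble with one row per condition and columns
#'   `only22_F, only22_M, both_F, both_M, only55_F, only55_M, total`.
#' @export
tally_emitters <- function(scores, conditions = NULL) {
  require_columns(scores, c("subject_id", "sex", "condition", "emitter_class"),
                  "USV score table")
  if (any(duplicated(scores$subject_id))) {
    stop_integrity("each subject must be scored exactly once")
  }
  if (!all(scores$emitter_class %in% c("none", "only22", "only55", "both"))) {
    stop_value("unknown emitter_class")
  }
  if (is.null(conditions)) {
    known <- condition_codes()
    present <- unique(scores$condition)
    conditions <- c(intersect(known, present), setdiff(present, known))
  }
  cell <- function(cond, cls, sx) {
    sum(scores$condition == cond & scores$emitter_class == cls & scores$sex == sx)
  }
  out <- tibble::tibble(
    condition = conditions,
    only22_F = unname(vapply(conditions, cell, integer(1), cls = "only22", sx = "F")),
    only22_M = unname(vapply(conditions, cell, integer(1), cls = "only22", sx = "M")),
    both_F   = unname(vapply(conditions, cell, integer(1), cls = "both", sx = "F")),
    both_M   = unname(vapply(conditions, cell, integer(1), cls = "both", sx = "M")),
    only55_F = unname(vapply(conditions, cell, integer(1), cls = "only55", sx = "F")),
    only55_M = unname(vapply(conditions, cell, integer(1), cls = "only55", sx = "M"))
  )
  out$total <- as.integer(rowSums(out[, -1]))
  none <- vapply(conditions, function(cond) {
    sum(scores$condition == cond & scores$emitter_class == "none")
  }, integer(1))
  structure(out, none = stats::setNames(none, conditions), class = class(out))
}

#' Summarize time-sampled nausea scores for one subject and behavior
#'
#' Nausea-associated behaviors (pica, lying-on-belly, ptosis) are scored 0-3
#' in two consecutive 15-second blocks every 5 minutes for 1 hour, so a
#' complete session has 24 blocks and a maximum total score of 72. Both the
#' accumulated score and the per-block mean are reported; partial sessions
#' are allowed and `n_blocks_observed` records how many blocks were scored.
#'
#' @param scores Integer vector of block scores, each in 0..3, at most 24.
#' @return List with `total_score`, `mean_block_score`, `n_blocks_observed`.
#' @export
#' @examples
#' nausea_summary(c(3, 2, 1, 0))
nausea_summary <- function(scores) {
  if (length(scores) == 0L) stop_value("no observations")
  if (length(scores) > 24L) stop_value("a session has at most 24 blocks (12 epochs x 2)")
  if (!all(scores %in% 0:3)) stop_value("scores must be integers in 0..3")
  total <- sum(scores)
  list(total_score = as.integer(total),
       mean_block_score = total / length(scores),
       n_blocks_observed = length(scores))
}

#' Summarize a long nausea observation table
#'
#' Applies [nausea_summary()] per subject and behavior.
#'
#' @param nausea Long tibble (see [load_nausea_table()]).
#' @return Tibble with `subject_id, behavior, total_score, mean_block_score,
#'   n_blocks_observed`.
#' @export
score_nausea <- function(nausea) {
  require_columns(nausea, c("subject_id", "behavior", "epoch_index",
                            "block_index", "score"), "nausea table")
  nausea %>%
    dplyr::group_by(.data$subject_id, .data$behavior) %>%
    dplyr::summarise(
      total_score = as.integer(sum(.data$score)),
      mean_block_score = mean(.data$score),
      n_blocks_observed = dplyr::n(),
      .groups = "drop"
    )
}
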