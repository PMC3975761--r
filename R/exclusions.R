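# Outlier identification: excessive part-1 missingness, then top/bottom
# 0.5% of the energy-intake to basal-metabolic-rate ratio, with stage-wise
# accounting.

#' Basal metabolic rate from Schofield coefficients
#'
#' Linear prediction `slope * weight + intercept` (MJ/day) from the sex- and
#' age-band-specific coefficient table shipped in the data model. Age bands
#' are half-open `[age_lo, age_hi)`; an age outside the table's coverage is
#' an explicit error — no extrapolation.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years.
#' @param weight Body weight in kg (> 0).
#' @param table The data model's `schofield` table (`sex`, `age_lo`,
#'   `age_hi`, `slope`, `intercept`).
#' @return BMR in MJ/day.
#' @export
schofield_bmr <- function(sex, age, weight, table) {
  if (is.na(weight) || weight <= 0) {
    stop("weight must be > 0 for BMR prediction", call. = FALSE)
  }
  if (is.na(age)) stop("age is required for BMR prediction", call. = FALSE)
  band <- table[table$sex == sex & age >= table$age_lo & age < table$age_hi,
                , drop = FALSE]
  if (nrow(band) != 1L) {
    stop("no Schofield age band covers sex=", sex, ", age=", age,
         call. = FALSE)
  }
  band$slope * weight + band$intercept
}

#' Flag excessive part-1 missingness
#'
#' @param intake An `ffq_intake` (or anything with `missing_line_count`).
#' @param threshold Minimum number of missing part-1 lines that triggers
#'   exclusion; the conventional cut-off is 10 or more.
#' @return `TRUE` iff the participant should be excluded.
#' @export
flag_missing_lines <- function(intake, threshold = 10L) {
  intake$missing_line_count >= threshold
}

#' Flag the extreme tails of the EI:BMR ratio
#'
#' Ranks eligible participants by their energy-intake to BMR ratio and flags
#' the `floor(tail * n)` lowest and `floor(tail * n)` highest. Ties are
#' broken by participant id so that runs are deterministic. Rank-based, so
#' invariant to any monotone transform of the ratios.
#'
#' @param energies Data frame with columns `participant_id` and `ratio`.
#' @param tail Fraction per tail, in (0, 0.5); default 0.005 (0.5%).
#' @return Character vector of flagged participant ids.
#' @export
flag_ratio_tails <- function(energies, tail = 0.005) {
  stopifnot(nrow(energies) > 0, tail > 0, tail < 0.5)
  n <- nrow(energies)
  k <- floor(tail * n)
  if (k == 0L) return(character(0))
  ord <- order(energies$ratio, energies$participant_id)
  ids <- energies$participant_id[ord]
  unique(c(ids[seq_len(k)], ids[seq.int(n - k + 1L, n)]))
}

#' Energy intake, BMR and their ratio for a cohort
#'
#' Reads the designated kJ energy nutrient from each intake, predicts BMR
#' from the Schofield table, and forms the dimensionless ratio
#' `(EI/1000) / BMR` (kJ/day converted to MJ/day; factor 1000 exact).
#' Participants whose age or weight is missing or outside the Schofield
#' coverage get `NA` ratios and are reported as BMR-ineligible by
#' [apply_exclusions()] rather than silently imputed.
#'
#' @param intakes List of `ffq_intake`.
#' @param records List of `ffq_participant`, aligned by participant id.
#' @param dm An `ffq_data_model`.
#' @return Data frame: `participant_id`, `EI_kj`, `BMR_mj`, `ratio`.
#' @export
participant_energies <- function(intakes, records, dm) {
  rec_ids <- vapply(records, `[[`, "", "participant_id")
  out <- lapply(intakes, function(int) {
    rec <- records[[match(int$participant_id, rec_ids)]]
    ei <- unname(int$totals[dm$energy_kj_nutrient_id])
    bmr <- tryCatch(
      schofield_bmr(rec$sex, rec$age, rec$weight, dm$schofield),
      error = function(e) NA_real_)
    data.frame(participant_id = int$participant_id, EI_kj = ei,
               BMR_mj = bmr, ratio = (ei / 1000) / bmr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(data.frame(
    participant_id = character(0), EI_kj = numeric(0), BMR_mj = numeric(0),
    ratio = numeric(0), stringsAsFactors = FALSE))))
}

#' Stage-wise outlier exclusion
#'
#' Fixed stage order: questionnaires with `missing_threshold` or more
#' missing part-1 lines are excluded first; the EI:BMR ratio tails are then
#' computed on the remaining eligible set (participants lacking the age or
#' weight needed for BMR are flagged ineligible and kept). The accounting
#' identity `final_n = returned_n - stage1_n - stage2_n` is verified before
#' returning.
#'
#' @param intakes List of `ffq_intake`.
#' @param records List of `ffq_participant`, aligned by id.
#' @param dm An `ffq_data_model`.
#' @param config List: `missing_threshold` (default 10), `tail_fraction`
#'   (default 0.005).
#' @return An `ffq_exclusion_report`: ids per stage (with per-sex counts),
#'   BMR-ineligible ids, remaining ids, and the `accounting` tuple
#'   `(returned_n, stage1_n, stage2_n, final_n)`.
#' @export
apply_exclusions <- function(intakes, records, dm,
                             config = list()) {
  cfg <- list(missing_threshold = 10L, tail_fraction = 0.005)
  cfg[names(config)] <- config

  ids <- vapply(intakes, `[[`, "", "participant_id")
  rec_ids <- vapply(records, `[[`, "", "participant_id")
  sex_of <- stats::setNames(vapply(records, `[[`, "", "sex"), rec_ids)

  stage1 <- ids[vapply(intakes, flag_missing_lines, logical(1),
                       threshold = cfg$missing_threshold)]

  keep1 <- !(ids %in% stage1)
  energies <- participant_energies(intakes[keep1], records, dm)
  ineligible <- energies$participant_id[is.na(energies$ratio)]
  eligible <- energies[!is.na(energies$ratio), , drop = FALSE]
  stage2 <- if (nrow(eligible)) {
    flag_ratio_tails(eligible, tail = cfg$tail_fraction)
  } else {
    character(0)
  }

  remaining <- setdiff(ids, c(stage1, stage2))
  acct <- exclusion_accounting(length(ids), length(stage1), length(stage2))
  stopifnot(acct[["final_n"]] == length(remaining))

  per_sex <- function(who) table(factor(unname(sex_of[who]),
                                        levels = c("male", "female")))
  structure(list(
    stage1_missing_lines = stage1,
    stage1_by_sex = per_sex(stage1),
    stage2_ei_bmr = stage2,
    stage2_by_sex = per_sex(stage2),
    ineligible_bmr = ineligible,
    remaining = remaining,
    energies = energies,
    accounting = acct
  ), class = "ffq_exclusion_report")
}

#' Stage-wise exclusion accounting identity
#'
#' The bookkeeping used to report an analytical sample: questionnaires
#' returned, minus those excluded for missingness, minus those excluded in
#' the EI:BMR tails, equals the final analytical n.
#'
#' @param returned_n,stage1_n,stage2_n Counts per stage.
#' @return Named numeric vector `(returned_n, stage1_n, stage2_n, final_n)`
#'   with `final_n = returned_n - stage1_n - stage2_n`.
#' @export
exclusion_accounting <- function(returned_n, stage1_n, stage2_n) {
  c(returned_n = returned_n, stage1_n = stage1_n, stage2_n = stage2_n,
    final_n = returned_n - stage1_n - stage2_n)
}

#' @export
print.ffq_exclusion_report <- function(x, ...) {
  a <- x$accounting
  cat("FFQ exclusion report\n")
  cat("  returned:            ", a[["returned_n"]], "\n")
  cat("  stage 1 (missing):   ", a[["stage1_n"]], "\n")
  cat("  stage 2 (EI:BMR):    ", a[["stage2_n"]], "\n")
  cat("  BMR-ineligible kept: ", length(x$ineligible_bmr), "\n")
  cat("  final analytical n:  ", a[["final_n"]], "\n")
  invisible(x)
}

#' Serialise an exclusion report
#'
#' One row per excluded or ineligible participant: id, stage, reason and the
#' triggering value (missing-line count or EI:BMR ratio).
#'
#' @param report An `ffq_exclusion_report`.
#' @param intakes The intake list the report was computed from.
#' @param path Output CSV path.
#' @return Number of rows written, invisibly.
#' @export
write_exclusions <- function(report, intakes, path) {
  ids <- vapply(intakes, `[[`, "", "participant_id")
  miss <- stats::setNames(
    vapply(intakes, `[[`, 0L, "missing_line_count"), ids)
  ratio <- stats::setNames(report$energies$ratio,
                           report$energies$participant_id)
  block <- function(who, stage, reason, value) {
    data.frame(id = who, stage = rep(stage, length(who)),
               reason = rep(reason, length(who)), value = value,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    block(report$stage1_missing_lines, 1L, "missing_lines",
          unname(miss[report$stage1_missing_lines])),
    block(report$stage2_ei_bmr, 2L, "ei_bmr_tail",
          unname(ratio[report$stage2_ei_bmr])),
    block(report$ineligible_bmr, NA_integer_, "bmr_ineligible",
          rep(NA_real_, length(report$ineligible_bmr))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(nrow(rows))
}
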