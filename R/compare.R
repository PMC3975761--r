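# Comparison machinery: per-variable summary statistics, reference-based
# quintile cut-points, and quintile-shift tabulation between two runs.

#' Summary statistics for one intake variable
#'
#' @param values Non-empty numeric vector.
#' @return List with `n`, `mean`, `sd` (sample, n-1 denominator), `median`
#'   (midpoint of the two central order statistics for even n), `minimum`,
#'   `maximum`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) {
    stop("summarize_values requires a non-empty vector without NA",
         call. = FALSE)
  }
  list(n = length(values), mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       median = stats::median(values), minimum = min(values),
       maximum = max(values))
}

#' Quintile cut-points from a reference run
#'
#' The 20th/40th/60th/80th percentiles of the reference values, under a
#' named percentile policy. The default (`type = 7`, inclusive linear
#' interpolation between closest ranks) is R's standard definition; the
#' `type` argument is exposed so users can match the convention of other
#' statistical software.
#'
#' @param reference Numeric vector, length >= 5.
#' @param type Percentile definition passed to [stats::quantile()].
#' @return Ascending numeric vector of 4 cut-points.
#' @export
quintile_cutpoints <- function(reference, type = 7) {
  if (length(reference) < 5L) {
    stop("need at least 5 reference values for quintile cut-points",
         call. = FALSE)
  }
  unname(stats::quantile(reference, probs = c(0.2, 0.4, 0.6, 0.8),
                         type = type, names = FALSE))
}

#' Assign quintiles against fixed cut-points
#'
#' Boundary rule: a value equal to cut-point k belongs to quintile k (ties
#' go to the lower quintile); monotone in the value.
#'
#' @param values Numeric vector.
#' @param cutpoints Ascending numeric vector of 4 cut-points.
#' @return Integer vector of quintiles in 1..5.
#' @export
quintile_assign <- function(values, cutpoints) {
  stopifnot(length(cutpoints) == 4L, !is.unsorted(cutpoints))
  1L + rowSums(outer(values, cutpoints, ">"))
}

#' Quintile-shift report between two runs
#'
#' Bins both runs' values with cut-points derived from the REFERENCE run
#' only (so the comparison is asymmetric by construction) and counts the
#' participants whose quintile differs, and differs by more than one.
#'
#' @param reference_values,new_values Numeric vectors aligned by `ids`.
#' @param ids Participant ids (used for the alignment check).
#' @param variable Optional variable label carried into the report.
#' @param type Percentile policy for the cut-points.
#' @return An `ffq_shift_report`: `variable`, `cutpoints`, `n`, `n_changed`,
#'   `pct_changed`, `n_changed_gt1`, `pct_changed_gt1`.
#' @export
quintile_shift <- function(reference_values, new_values, ids,
                           variable = NA_character_, type = 7) {
  n <- length(ids)
  if (length(reference_values) != n || length(new_values) != n) {
    stop("reference, new and id vectors must be aligned (equal length)",
         call. = FALSE)
  }
  cp <- quintile_cutpoints(reference_values, type = type)
  qr <- quintile_assign(reference_values, cp)
  qn <- quintile_assign(new_values, cp)
  d <- abs(qn - qr)
  structure(list(
    variable = variable, cutpoints = cp, n = n,
    n_changed = sum(d > 0L), pct_changed = 100 * sum(d > 0L) / n,
    n_changed_gt1 = sum(d > 1L), pct_changed_gt1 = 100 * sum(d > 1L) / n
  ), class = "ffq_shift_report")
}

#' @export
print.ffq_shift_report <- function(x, ...) {
  cat("Quintile shift", if (!is.na(x$variable)) paste0(" (", x$variable, ")"),
      ": n=", x$n, ", changed=", x$n_changed,
      sprintf(" (%.1f%%)", x$pct_changed), ", changed >1=", x$n_changed_gt1,
      sprintf(" (%.1f%%)", x$pct_changed_gt1), "\n", sep = "")
  invisible(x)
}

#' Compare two processing runs variable by variable
#'
#' Takes two wide (output-1) tables from different processing
#' configurations, aligned by participant id, and produces — per variable
#' and optionally per stratum (e.g. sex) — the summary statistics of both
#' runs plus the quintile-shift counts under cut-points from the designated
#' reference run.
#'
#' @param run_a,run_b Format-1 data frames (`participant_id` + variables).
#' @param reference `"A"` or `"B"`: which run supplies the cut-points.
#' @param by Optional named character/factor vector, participant id ->
#'   stratum; cut-points are computed per stratum.
#' @param variables Variables to compare; default all shared numeric
#'   columns.
#' @param type Percentile policy.
#' @return Data frame with one row per variable (x stratum).
#' @export
compare_runs <- function(run_a, run_b, reference = "A", by = NULL,
                         variables = NULL, type = 7) {
  ids <- run_a$participant_id
  if (!setequal(ids, run_b$participant_id)) {
    stop("runs do not cover the same participants", call. = FALSE)
  }
  run_b <- run_b[match(ids, run_b$participant_id), , drop = FALSE]
  if (is.null(variables)) {
    variables <- intersect(setdiff(names(run_a), "participant_id"),
                           setdiff(names(run_b), "participant_id"))
  }
  strata <- if (is.null(by)) {
    factor(rep("all", length(ids)))
  } else {
    factor(unname(by[ids]))
  }
  rows <- list()
  for (s in levels(strata)) {
    sel <- strata == s
    for (v in variables) {
      a <- run_a[[v]][sel]; b <- run_b[[v]][sel]
      ref <- if (identical(reference, "A")) a else b
      new <- if (identical(reference, "A")) b else a
      sh <- quintile_shift(ref, new, ids[sel], variable = v, type = type)
      sa <- summarize_values(a); sb <- summarize_values(b)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, variable = v, n = sh$n,
        median_a = sa$median, mean_a = sa$mean, sd_a = sa$sd,
        min_a = sa$minimum, max_a = sa$maximum,
        median_b = sb$median, mean_b = sb$mean, sd_b = sb$sd,
        min_b = sb$minimum, max_b = sb$maximum,
        n_changed = sh$n_changed, pct_changed = sh$pct_changed,
        n_changed_gt1 = sh$n_changed_gt1,
        pct_changed_gt1 = sh$pct_changed_gt1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
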