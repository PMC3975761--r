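# The four output granularities and the machine-readable run log.
#
# Output 1: one row per participant, wide (nutrients then food groups).
# Output 2: the same data in long format (participant, variable, value).
# Output 3: one row per participant x questionnaire line, with grams.
# Output 4: one row per participant x line x food code, with grams.

output_variables <- function(dm) {
  c(dm$nutrient_dictionary$nutrient_id, dm$group_scheme)
}

#' Build an output table
#'
#' Pure constructor for the four output formats; [emit()] serialises the
#' result. Column order is nutrient-dictionary order then group-scheme
#' order, stable across runs.
#'
#' @param intakes List of `ffq_intake`.
#' @param format Integer 1-4.
#' @param dm An `ffq_data_model`.
#' @return A data frame.
#' @export
intake_table <- function(intakes, format, dm) {
  format <- as.integer(format)
  stopifnot(format %in% 1:4)
  vars <- output_variables(dm)
  empty_row <- function(cols) {
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols), check.names = FALSE)
    df
  }
  if (format == 1L) {
    if (!length(intakes)) {
      return(cbind(data.frame(participant_id = character(0),
                              stringsAsFactors = FALSE), empty_row(vars)))
    }
    mat <- do.call(rbind, lapply(intakes, function(x) x$totals[vars]))
    df <- data.frame(participant_id = vapply(intakes, `[[`, "",
                                             "participant_id"),
                     stringsAsFactors = FALSE, check.names = FALSE)
    cbind(df, as.data.frame(mat, check.names = FALSE))
  } else if (format == 2L) {
    if (!length(intakes)) {
      return(data.frame(participant_id = character(0),
                        variable = character(0), value = numeric(0),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(intakes, function(x) {
      data.frame(participant_id = x$participant_id, variable = vars,
                 value = unname(x$totals[vars]), stringsAsFactors = FALSE)
    }))
  } else if (format == 3L) {
    if (!length(intakes)) {
      return(cbind(data.frame(participant_id = character(0),
                              meal_id = integer(0), grams = numeric(0),
                              stringsAsFactors = FALSE), empty_row(vars)))
    }
    do.call(rbind, lapply(intakes, function(x) {
      cbind(data.frame(participant_id = x$participant_id,
                       stringsAsFactors = FALSE),
            x$lines[, c("meal_id", "grams", vars)])
    }))
  } else {
    if (!length(intakes)) {
      return(cbind(data.frame(participant_id = character(0),
                              meal_id = integer(0), food_code = character(0),
                              food_group = character(0), grams = numeric(0),
                              stringsAsFactors = FALSE),
                   empty_row(dm$nutrient_dictionary$nutrient_id)))
    }
    do.call(rbind, lapply(intakes, function(x) {
      cbind(data.frame(participant_id = x$participant_id,
                       stringsAsFactors = FALSE),
            x$foods[, c("meal_id", "food_code", "food_group", "grams",
                        dm$nutrient_dictionary$nutrient_id)])
    }))
  }
}

#' Pivot a long (output 2) table back to wide (output 1)
#'
#' @param long A format-2 data frame.
#' @return A format-1-shaped data frame (participants in first-appearance
#'   order, variables in first-appearance order).
#' @export
pivot_output2 <- function(long) {
  ids <- unique(long$participant_id)
  vars <- unique(long$variable)
  wide <- data.frame(participant_id = ids, stringsAsFactors = FALSE,
                     check.names = FALSE)
  for (v in vars) {
    sub <- long[long$variable == v, ]
    wide[[v]] <- sub$value[match(ids, sub$participant_id)]
  }
  wide
}

#' Write an output file with its run log
#'
#' Serialises one of the four output formats as CSV and writes the run log
#' alongside it (same basename, `.log` extension), mirroring the convention
#' that every output file is accompanied by a log recording notes and error
#' messages with date-and-time stamps. Values are rounded only here, at
#' serialisation, to `round_digits` significant digits.
#'
#' @param intakes List of `ffq_intake`.
#' @param format Integer 1-4.
#' @param path Output CSV path.
#' @param dm An `ffq_data_model`.
#' @param log An `ffq_run_log` (from [compute_cohort()]); `NULL` writes a
#'   log with only the output note.
#' @param round_digits Significant digits at serialisation; `NA` disables
#'   rounding.
#' @return Number of data rows written, invisibly.
#' @export
emit <- function(intakes, format, path, dm, log = NULL, round_digits = 6) {
  df <- intake_table(intakes, format, dm)
  if (!is.na(round_digits)) {
    num <- vapply(df, is.numeric, logical(1)) & names(df) != "meal_id"
    df[num] <- lapply(df[num], signif, digits = round_digits)
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write output file ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  if (is.null(log)) {
    log <- data.frame(timestamp = character(0), level = character(0),
                      participant_id = character(0), message = character(0),
                      stringsAsFactors = FALSE)
    class(log) <- c("ffq_run_log", "data.frame")
  }
  note <- data.frame(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    level = "NOTE", participant_id = "-",
    message = paste0("output ", format, ": ", nrow(df), " rows written to ",
                     basename(path)),
    stringsAsFactors = FALSE)
  full <- rbind(as.data.frame(log), note)
  write_run_log(full, sub("\\.[^.]*$", ".log", path))
  invisible(nrow(df))
}

#' Write a run log
#'
#' Fixed line grammar `<ISO8601>\t<LEVEL>\t<id>\t<message>` (tab-separated;
#' `-` for entries not tied to a participant), machine-readable line by
#' line.
#'
#' @param log An `ffq_run_log` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(log, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", log$timestamp, log$level,
                   log$participant_id, log$message)
  writeLines(lines, path)
  invisible(path)
}

#' Read a run log
#'
#' @param path Path to a `.log` file written by [write_run_log()].
#' @return An `ffq_run_log` data frame.
#' @export
read_run_log <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 4L
  if (any(bad)) {
    stop("malformed log line(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(
    timestamp = vapply(parts, `[[`, "", 1L),
    level = vapply(parts, `[[`, "", 2L),
    participant_id = vapply(parts, `[[`, "", 3L),
    message = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE)
  class(df) <- c("ffq_run_log", "data.frame")
  df
}

#' Per-participant missing-frequency counts from a run log
#'
#' The engine logs one "part 1 missing frequencies: n" note per participant;
#' this recovers the counts from the log alone, which is what makes the
#' missing-line exclusion auditable after the fact.
#'
#' @param log An `ffq_run_log`.
#' @return Named integer vector, participant id -> missing-line count.
#' @export
missing_counts_from_log <- function(log) {
  sel <- grepl("^part 1 missing frequencies: ", log$message)
  counts <- as.integer(sub("^part 1 missing frequencies: ", "",
                           log$message[sel]))
  stats::setNames(counts, log$participant_id[sel])
}
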