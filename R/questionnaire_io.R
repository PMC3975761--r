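# Cohort-file parsing: part-1 frequency cells with their sentinel
# conventions, part-2 detail answers, participant demographics.

#' Parse a single part-1 frequency cell
#'
#' Implements the hand-keyed cell conventions of the questionnaire grid:
#' digits `1`..`9` are answered frequency categories; `-9` (or an empty
#' cell) marks a frequency that was not recorded; `-4` is the legacy code
#' used when two frequencies were ticked, retained as a distinct status but
#' treated as missing downstream; a dual answer written `a;b` in one cell
#' keeps the first value. Both ASCII hyphen-minus and the Unicode minus
#' sign are accepted.
#'
#' @param cell Character scalar, the raw cell text.
#' @return A list with `status` (one of `"answered"`, `"missing"`,
#'   `"legacy_missing"`), `code` (integer 1-9 when answered, else `NA`),
#'   `raw` (original text) and `dual` (`TRUE` when an `a;b` form was
#'   collapsed to its first value).
#' @export
parse_frequency_cell <- function(cell) {
  raw <- if (is.na(cell)) "" else as.character(cell)
  x <- gsub("−", "-", trimws(raw))  # Unicode minus -> hyphen-minus
  if (x == "" || x == "-9") {
    return(list(status = "missing", code = NA_integer_, raw = raw,
                dual = FALSE))
  }
  if (x == "-4") {
    return(list(status = "legacy_missing", code = NA_integer_, raw = raw,
                dual = FALSE))
  }
  if (grepl(";", x, fixed = TRUE)) {
    first <- strsplit(x, ";", fixed = TRUE)[[1]][1]
    inner <- parse_frequency_cell(first)
    inner$raw <- raw
    inner$dual <- TRUE
    return(inner)
  }
  if (grepl("^[1-9]$", x)) {
    return(list(status = "answered", code = as.integer(x), raw = raw,
                dual = FALSE))
  }
  stop("unrecognised frequency cell value: '", raw, "'", call. = FALSE)
}

#' Expected cohort-file header for a data model
#'
#' The cohort CSV carries, per participant: identifier, sex, age, body
#' weight, one frequency cell per questionnaire line (`q1`..`qL`), then the
#' part-2 answers — milk free text and amount category, up to four cereal
#' free texts, frying- and baking-fat free texts, four "None/No" box flags
#' and four optional pre-assigned food codes.
#'
#' @param dm An `ffq_data_model`.
#' @return Character vector of column names.
#' @export
cohort_header <- function(dm) {
  c("id", "sex", "age", "weight",
    paste0("q", seq_len(nrow(dm$lines))),
    "milk_text", "milk_amount",
    paste0("cereal", 1:4),
    "frying_fat_text", "baking_fat_text",
    paste0("none_", ffq_kinds),
    paste0("pre_", ffq_kinds))
}

blank_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  x
}

#' Read a cohort file
#'
#' Parses a comma-separated cohort file into participant records, routing
#' every frequency cell through [parse_frequency_cell()]. Malformed rows
#' are skipped and reported in the issues table, never silently dropped;
#' dual-frequency cells (`a;b`) keep their first value and add an
#' informational issue. A duplicate participant id or a header that does
#' not match [cohort_header()] for the data model is fatal.
#'
#' @param path Path to the cohort CSV.
#' @param dm The `ffq_data_model` the file is keyed against (fixes the
#'   number of frequency columns).
#' @return A list with `records` (list of `ffq_participant`) and `issues`
#'   (data frame: `row`, `column`, `level`, `message`).
#' @export
read_cohort <- function(path, dm) {
  stopifnot(inherits(dm, "ffq_data_model"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  expected <- cohort_header(dm)
  if (!identical(names(raw), expected)) {
    stop("cohort header does not match the data model (expected ",
         length(expected), " columns for ", nrow(dm$lines),
         " questionnaire lines)", call. = FALSE)
  }
  if (anyDuplicated(raw$id)) {
    stop("duplicate participant id in cohort file: ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "),
         call. = FALSE)
  }

  qcols <- paste0("q", seq_len(nrow(dm$lines)))
  records <- vector("list", nrow(raw))
  issues <- list()
  add_issue <- function(row, column, level, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, column = column, level = level, message = message,
      stringsAsFactors = FALSE)
  }

  keep <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    rec <- tryCatch({
      sex <- tolower(trimws(row$sex))
      if (!sex %in% c("male", "female")) {
        stop("sex must be 'male' or 'female', got '", row$sex, "'",
             call. = FALSE)
      }
      age <- suppressWarnings(as.numeric(row$age))
      weight <- suppressWarnings(as.numeric(row$weight))
      if (!is.na(age) && age <= 0) stop("age must be > 0", call. = FALSE)
      if (!is.na(weight) && weight <= 0) {
        stop("weight must be > 0", call. = FALSE)
      }

      part1 <- vector("list", length(qcols))
      for (j in seq_along(qcols)) {
        fv <- tryCatch(parse_frequency_cell(row[[qcols[j]]]),
                       error = function(e) {
          stop("row ", i, ", column ", qcols[j], ": ", conditionMessage(e),
               call. = FALSE)
        })
        if (fv$dual) {
          add_issue(i, qcols[j], "note",
                    paste0("dual frequency '", fv$raw,
                           "' collapsed to first value ", fv$code))
        }
        part1[[j]] <- fv
      }
      part1 <- data.frame(
        status = vapply(part1, `[[`, "", "status"),
        code = vapply(part1, `[[`, NA_integer_, "code"),
        raw = vapply(part1, `[[`, "", "raw"),
        stringsAsFactors = FALSE)

      cereal_texts <- blank_to_na(unlist(row[paste0("cereal", 1:4)]))
      cereal_texts <- cereal_texts[!is.na(cereal_texts)]
      none_flags <- vapply(ffq_kinds, function(k) {
        v <- trimws(as.character(row[[paste0("none_", k)]]))
        v %in% c("1", "TRUE", "true", "yes")
      }, logical(1))
      pre <- vapply(ffq_kinds, function(k) {
        v <- blank_to_na(row[[paste0("pre_", k)]])
        if (is.na(v)) NA_character_ else v
      }, character(1))

      structure(list(
        participant_id = trimws(row$id),
        sex = sex, age = age, weight = weight,
        part1 = part1,
        part2 = list(
          milk_text = blank_to_na(row$milk_text),
          milk_amount_code = suppressWarnings(
            as.integer(blank_to_na(row$milk_amount))),
          cereal_texts = unname(cereal_texts),
          frying_fat_text = blank_to_na(row$frying_fat_text),
          baking_fat_text = blank_to_na(row$baking_fat_text),
          none_boxes = ffq_kinds[none_flags],
          preassigned_codes = pre[!is.na(pre)]
        )
      ), class = "ffq_participant")
    }, error = function(e) {
      add_issue(i, "-", "error",
                paste0("row ", i, " skipped: ", conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) {
      records[[i]] <- rec
      keep[i] <- TRUE
    }
  }

  issues <- if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(row = integer(0), column = character(0),
               level = character(0), message = character(0),
               stringsAsFactors = FALSE)
  }
  list(records = records[keep], issues = issues)
}

#' @export
print.ffq_participant <- function(x, ...) {
  n_missing <- sum(x$part1$status != "answered")
  cat("FFQ participant ", x$participant_id, " (", x$sex, ", age ", x$age,
      ", weight ", x$weight, " kg)\n", sep = "")
  cat("  part-1 lines: ", nrow(x$part1), " (", n_missing, " missing)\n",
      sep = "")
  invisible(x)
}
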