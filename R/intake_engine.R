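# The defining computation: frequency multiplier x portion weight ->
# grams/day per line; proportional (or equal-split) apportioning to food
# codes; cooking-fat substitution for modified "without fat" foods;
# composition join; food-group accumulation as pseudonutrients.

fat_tags <- c("frying_fat", "baking_fat")

#' Daily grams consumed for one questionnaire line
#'
#' An answered frequency category contributes its occurrences-per-day
#' multiplier times the line's portion weight; a missing (or legacy
#' dual-frequency) cell contributes zero — missingness is penalised by the
#' exclusions module, never imputed by the engine.
#'
#' @param fv A frequency value from [parse_frequency_cell()] (or a one-row
#'   slice of a participant's `part1` table).
#' @param line One row of the data model's `lines` table.
#' @param scheme The frequency scheme (`code`, `multiplier`).
#' @return Grams per day (numeric scalar).
#' @export
line_daily_grams <- function(fv, line, scheme) {
  status <- fv$status
  if (!identical(status, "answered")) return(0)
  mult <- scheme$multiplier[match(fv$code, scheme$code)]
  mult * line$portion_g
}

#' Apportion a line's daily grams to food codes
#'
#' Non-tagged lines split their grams across the line's mappings by
#' proportion. Milk-tagged lines first replace each substitutable slot's
#' food code with the participant's resolved milk code. Cereal-tagged lines
#' ignore their static mappings and split the grams equally across the 1-4
#' resolved cereal codes. Output grams always sum to the input grams, except
#' when a slot resolves to the `NONE` sentinel (no consumption), which is
#' dropped.
#'
#' @param grams Grams per day for the line (from [line_daily_grams()]).
#' @param line One row of the data model's `lines` table.
#' @param res A part-2 resolution (the `resolution` element of
#'   [resolve_part2()]).
#' @param dm The `ffq_data_model` (supplies the line's mappings).
#' @return Data frame with columns `food_code`, `grams`,
#'   `fat_uptake_g_per_100g`.
#' @export
apportion_to_foods <- function(grams, line, res, dm) {
  tag <- line$part2_tag
  if (identical(tag, "cereal")) {
    codes <- setdiff(res$cereal_codes, ffq_sentinels[["none"]])
    if (!length(codes)) {
      return(data.frame(food_code = character(0), grams = numeric(0),
                        fat_uptake_g_per_100g = numeric(0),
                        stringsAsFactors = FALSE))
    }
    return(data.frame(food_code = codes, grams = grams / length(codes),
                      fat_uptake_g_per_100g = 0, stringsAsFactors = FALSE))
  }
  m <- dm$mappings[dm$mappings$meal_id == line$meal_id, , drop = FALSE]
  codes <- m$food_code
  if (identical(tag, "milk")) {
    codes[m$substitutable] <- res$milk_code
  }
  out <- data.frame(food_code = codes, grams = grams * m$proportion,
                    fat_uptake_g_per_100g = m$fat_uptake_g_per_100g,
                    stringsAsFactors = FALSE)
  out[out$food_code != ffq_sentinels[["none"]], , drop = FALSE]
}

#' Add the cooking-fat entry for a modified without-fat food
#'
#' Modified home-baked and fried foods are carried in the composition table
#' without their fat; the participant's resolved frying or baking fat (per
#' the line's part-2 tag) is added back as a separate food entry of
#' `grams * uptake / 100` grams per day. The `NO_FAT` sentinel (a ticked
#' "None/No" box) and a zero uptake yield no fat entry.
#'
#' @param food_code,grams The without-fat food entry.
#' @param fat_uptake_g_per_100g Grams of added fat per 100 g of the food.
#' @param line One row of the data model's `lines` table (its tag selects
#'   frying vs baking fat).
#' @param res A part-2 resolution.
#' @return Data frame of emitted entries (`food_code`, `grams`): the food
#'   itself plus, when applicable, the fat entry.
#' @export
apply_fat_substitution <- function(food_code, grams, fat_uptake_g_per_100g,
                                   line, res) {
  out <- data.frame(food_code = food_code, grams = grams,
                    stringsAsFactors = FALSE)
  tag <- line$part2_tag
  if (fat_uptake_g_per_100g > 0 && tag %in% fat_tags) {
    fat_code <- if (identical(tag, "frying_fat")) {
      res$frying_fat_code
    } else {
      res$baking_fat_code
    }
    if (!identical(fat_code, ffq_sentinels[["no_fat"]]) && grams > 0) {
      out <- rbind(out, data.frame(
        food_code = fat_code, grams = grams * fat_uptake_g_per_100g / 100,
        stringsAsFactors = FALSE))
    }
  }
  out
}

default_engine_opts <- function(opts = list()) {
  base <- list(text_matching = TRUE, strict = FALSE)
  base[names(opts)] <- opts
  base
}

#' Compute one participant's daily intakes
#'
#' Composes part-2 resolution, line-level gram computation (including the
#' milk-amount factor on milk-tagged lines), apportioning to food codes,
#' cooking-fat substitution, the composition join (grams x per-100g / 100)
#' and food-group accumulation (group intake = grams of member foods — the
#' pseudonutrient treatment) into the four-granularity result.
#'
#' Food codes without a composition record contribute zero nutrients and an
#' ERROR log entry; nothing is fatal unless `opts$strict` is set.
#'
#' @param rec An `ffq_participant`.
#' @param dm An `ffq_data_model`.
#' @param opts List of engine options: `text_matching` (default `TRUE`),
#'   `strict` (promote unknown-code errors to fatal, default `FALSE`).
#' @return A list with `intake` (class `ffq_intake`: `participant_id`,
#'   `totals` — named vector over nutrients then groups, `lines`, `foods`,
#'   `missing_line_count`) and `log` (data frame `level`, `participant_id`,
#'   `message`).
#' @export
compute_participant <- function(rec, dm, opts = list()) {
  stopifnot(inherits(rec, "ffq_participant"), inherits(dm, "ffq_data_model"))
  opts <- default_engine_opts(opts)
  pid <- rec$participant_id
  log_level <- character(0); log_msg <- character(0)
  add_log <- function(level, message) {
    log_level <<- c(log_level, level)
    log_msg <<- c(log_msg, message)
  }

  r2 <- resolve_part2(rec$part2, dm, text_matching = opts$text_matching)
  for (k in seq_len(nrow(r2$notes))) {
    add_log(if (r2$notes$level[k] == "error") "ERROR" else "NOTE",
            r2$notes$message[k])
  }
  res <- r2$resolution

  milk_factor <- 1
  mac <- rec$part2$milk_amount_code
  if (!is.na(mac)) {
    hit <- match(mac, dm$milk_amounts$code)
    if (is.na(hit)) {
      add_log("ERROR", paste0("milk amount category ", mac,
                              " not in milk_amounts table; factor 1 used"))
    } else {
      milk_factor <- dm$milk_amounts$factor[hit]
    }
  }

  nutr_ids <- dm$nutrient_dictionary$nutrient_id
  comp_mat <- as.matrix(dm$composition[, nutr_ids, drop = FALSE])
  rownames(comp_mat) <- dm$composition$food_code
  group_of <- stats::setNames(dm$composition$food_group,
                              dm$composition$food_code)

  rows <- list()
  for (i in seq_len(nrow(dm$lines))) {
    ln <- dm$lines[i, ]
    fv <- rec$part1[i, ]
    grams <- line_daily_grams(fv, ln, dm$frequency_scheme)
    if (identical(ln$part2_tag, "milk")) grams <- grams * milk_factor
    app <- apportion_to_foods(grams, ln, res, dm)
    for (j in seq_len(nrow(app))) {
      ent <- apply_fat_substitution(app$food_code[j], app$grams[j],
                                    app$fat_uptake_g_per_100g[j], ln, res)
      ent$meal_id <- ln$meal_id
      rows[[length(rows) + 1L]] <- ent
    }
  }
  foods <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(food_code = character(0), grams = numeric(0),
               meal_id = integer(0), stringsAsFactors = FALSE)
  }

  known <- foods$food_code %in% rownames(comp_mat)
  for (fc in unique(foods$food_code[!known])) {
    add_log("ERROR", paste0("food code ", fc,
                            " does not have any nutrient data attached"))
    if (opts$strict) {
      stop("food code ", fc, " has no nutrient data (strict mode)",
           call. = FALSE)
    }
  }
  nut <- matrix(0, nrow = nrow(foods), ncol = length(nutr_ids),
                dimnames = list(NULL, nutr_ids))
  if (any(known)) {
    nut[known, ] <- comp_mat[foods$food_code[known], , drop = FALSE] *
      foods$grams[known] / 100
  }
  foods$food_group <- ifelse(known, unname(group_of[foods$food_code]),
                             NA_character_)
  foods <- cbind(foods[, c("meal_id", "food_code", "food_group", "grams")],
                 as.data.frame(nut))

  # Line-level roll-up: grams (incl. added fat), nutrients, per-group grams.
  grp <- dm$group_scheme
  line_ids <- dm$lines$meal_id
  lines_out <- data.frame(meal_id = line_ids)
  mi <- factor(foods$meal_id, levels = line_ids)
  lines_out$grams <- as.numeric(tapply(foods$grams, mi, sum, default = 0))
  for (nid in nutr_ids) {
    lines_out[[nid]] <- as.numeric(tapply(foods[[nid]], mi, sum,
                                          default = 0))
  }
  for (g in grp) {
    sel <- !is.na(foods$food_group) & foods$food_group == g
    lines_out[[g]] <- as.numeric(tapply(
      ifelse(sel, foods$grams, 0), mi, sum, default = 0))
  }

  totals_nutr <- colSums(nut)
  totals_grp <- vapply(grp, function(g) {
    sum(foods$grams[!is.na(foods$food_group) & foods$food_group == g])
  }, numeric(1))
  totals <- c(totals_nutr, totals_grp)

  missing_line_count <- sum(rec$part1$status != "answered")
  add_log("NOTE", paste0("part 1 missing frequencies: ", missing_line_count))

  intake <- structure(list(
    participant_id = pid,
    totals = totals,
    lines = lines_out,
    foods = foods,
    missing_line_count = missing_line_count
  ), class = "ffq_intake")

  list(intake = intake,
       log = data.frame(level = log_level,
                        participant_id = rep(pid, length(log_level)),
                        message = log_msg, stringsAsFactors = FALSE))
}

#' Compute intakes for a whole cohort
#'
#' Order-preserving map of [compute_participant()] over the records, with a
#' timestamped run log aggregating every participant's entries. A failing
#' participant is logged and skipped; the cohort never aborts.
#'
#' @param records List of `ffq_participant` (from [read_cohort()]).
#' @param dm An `ffq_data_model`.
#' @param opts Engine options (see [compute_participant()]).
#' @return A list with `intakes` (list of `ffq_intake`) and `log` (class
#'   `ffq_run_log`).
#' @export
compute_cohort <- function(records, dm, opts = list()) {
  intakes <- list()
  log_parts <- list()
  for (rec in records) {
    out <- tryCatch(compute_participant(rec, dm, opts), error = function(e) {
      list(intake = NULL,
           log = data.frame(level = "ERROR",
                            participant_id = rec$participant_id,
                            message = paste0("participant skipped: ",
                                             conditionMessage(e)),
                            stringsAsFactors = FALSE))
    })
    if (!is.null(out$intake)) intakes[[length(intakes) + 1L]] <- out$intake
    log_parts[[length(log_parts) + 1L]] <- out$log
  }
  log_df <- do.call(rbind, c(log_parts, list(
    data.frame(level = character(0), participant_id = character(0),
               message = character(0), stringsAsFactors = FALSE))))
  log_df$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  log_df <- log_df[, c("timestamp", "level", "participant_id", "message")]
  class(log_df) <- c("ffq_run_log", "data.frame")
  list(intakes = intakes, log = log_df)
}

#' @export
print.ffq_intake <- function(x, ...) {
  cat("FFQ intake for participant ", x$participant_id, "\n", sep = "")
  cat("  missing part-1 lines: ", x$missing_line_count, "\n", sep = "")
  cat("  daily totals:\n")
  print(round(x$totals, 3))
  invisible(x)
}
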