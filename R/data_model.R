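#' @keywords internal
"_PACKAGE"

# Sentinel food codes understood by the engine: NO_FAT suppresses the added
# cooking-fat entry for modified "without fat" foods; NONE drops a part-2
# substituted slot entirely (participant consumes none of that item).
ffq_sentinels <- c(no_fat = "NO_FAT", none = "NONE")

#' Sentinel food codes
#'
#' Food-code sentinels produced by part-2 resolution and honoured by the
#' intake engine: `"NO_FAT"` (a ticked "None/No" cooking-fat box; no fat is
#' added to modified without-fat foods) and `"NONE"` (no consumption of a
#' substituted item; the slot contributes zero grams).
#'
#' @return Named character vector of sentinel codes.
#' @export
ffq_sentinel_codes <- function() ffq_sentinels

# Part-2 answer kinds, in canonical order.
ffq_kinds <- c("milk", "cereal", "frying_fat", "baking_fat")

#' Default frequency-category multipliers
#'
#' The nine consumption-frequency categories of a semi-quantitative FFQ and
#' their occurrences-per-day multipliers. Codes run 1 ("never or less than
#' once a month", multiplier 0) to 9 ("6+ times per day"). The multipliers
#' are an editable convention shipped as data, not code: category labels
#' constrain but do not fix the midpoints, so month-based categories use the
#' mean month length (30.44 days) and week-based ones sevenths.
#'
#' @return A data frame with columns `code`, `label`, `multiplier`.
#' @export
default_frequency_scheme <- function() {
  data.frame(
    code = 1:9,
    label = c(
      "never or less than once a month", "1-3 per month", "once a week",
      "2-4 per week", "5-6 per week", "once a day", "2-3 per day",
      "4-5 per day", "6+ per day"
    ),
    multiplier = c(0, 2 / 30.44, 1 / 7, 3 / 7, 5.5 / 7, 1, 2.5, 4.5, 6),
    stringsAsFactors = FALSE
  )
}

# Required bundle tables (reference_<kind>.csv handled separately).
ffq_bundle_tables <- c(
  lines = "lines.csv", mappings = "mappings.csv",
  frequencies = "frequencies.csv", composition = "composition.csv",
  nutrients = "nutrients.csv", groups = "groups.csv",
  defaults = "defaults.csv", schofield = "schofield.csv",
  milk_amounts = "milk_amounts.csv"
)

read_bundle_csv <- function(path, file) {
  fp <- file.path(path, file)
  if (!file.exists(fp)) {
    stop("data-model bundle is missing required table '", file, "'",
         call. = FALSE)
  }
  utils::read.csv(fp, stringsAsFactors = FALSE, colClasses = NA,
                  check.names = FALSE)
}

#' Load a data-model bundle
#'
#' Reads the delimited-text tables that drive all computation — questionnaire
#' lines with portion weights, frequency multipliers, line-to-food-code
#' mappings with proportions, the food composition table (per 100 g edible
#' food), food-group scheme, part-2 reference lists with default codes,
#' Schofield BMR coefficients and the milk-amount factor table — and returns
#' them as a validated `ffq_data_model` object. Keeping the processing
#' algorithm separate from these text files is what makes the tool
#' customisable for different study populations.
#'
#' Food codes referenced by a mapping or reference list but absent from the
#' composition table are collected as warnings (they process as zero
#' nutrients and are logged at run time), not errors. Structural defects —
#' a missing table, duplicate line or frequency identifiers, mapping
#' proportions that do not sum to 1 — are fatal.
#'
#' @param path Directory containing the bundle CSV files.
#' @param energy_kj Nutrient identifier designated as energy intake in kJ,
#'   read by the exclusions module. Must exist in the nutrient dictionary.
#' @param proportion_tol Tolerance for the per-line proportion sum-to-1
#'   check. Text files carry short decimals, so the default is tight.
#' @return An object of class `ffq_data_model`: a list with elements
#'   `frequency_scheme`, `lines`, `mappings`, `composition`,
#'   `reference_lists`, `schofield`, `nutrient_dictionary`, `group_scheme`,
#'   `milk_amounts`, `energy_kj_nutrient_id` and `missing_codes` (the
#'   referenced-but-absent food codes).
#' @seealso [validate_data_model()], [write_data_model()],
#'   [generate_data_model()]
#' @export
load_data_model <- function(path, energy_kj = "energy_kj",
                            proportion_tol = 1e-9) {
  if (!dir.exists(path)) {
    stop("data-model bundle directory not found: ", path, call. = FALSE)
  }
  tabs <- lapply(ffq_bundle_tables, read_bundle_csv, path = path)

  freq <- tabs$frequencies
  freq$code <- as.integer(freq$code)
  freq$multiplier <- as.numeric(freq$multiplier)
  freq <- freq[order(freq$code), , drop = FALSE]
  if (anyDuplicated(freq$code)) {
    stop("duplicate frequency code in frequencies.csv", call. = FALSE)
  }
  if (!identical(freq$code, 1:9)) {
    stop("frequency codes must be exactly 1..9", call. = FALSE)
  }
  if (freq$multiplier[1] != 0) {
    stop("frequency code 1 ('never') must have multiplier 0", call. = FALSE)
  }
  if (is.unsorted(freq$multiplier)) {
    stop("frequency multipliers must be non-decreasing in code",
         call. = FALSE)
  }

  lines <- tabs$lines
  lines$meal_id <- as.integer(lines$meal_id)
  lines$portion_g <- as.numeric(lines$portion_g)
  if (anyDuplicated(lines$meal_id)) {
    dup <- lines$meal_id[duplicated(lines$meal_id)]
    stop("duplicate meal_id in lines.csv: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(lines$portion_g <= 0)) {
    stop("portion_g must be > 0 for every line", call. = FALSE)
  }

  maps <- tabs$mappings
  maps$meal_id <- as.integer(maps$meal_id)
  maps$proportion <- as.numeric(maps$proportion)
  maps$substitutable <- as.logical(maps$substitutable)
  maps$fat_uptake_g_per_100g <- as.numeric(maps$fat_uptake_g_per_100g)
  for (mid in lines$meal_id) {
    m <- maps[maps$meal_id == mid, , drop = FALSE]
    if (nrow(m) < 1L || nrow(m) > 6L) {
      stop("meal_id ", mid, " must map to 1-6 food codes (has ", nrow(m),
           ")", call. = FALSE)
    }
    s <- sum(m$proportion)
    if (abs(s - 1) > proportion_tol) {
      stop("mapping proportions for meal_id ", mid, " sum to ", s,
           ", not 1", call. = FALSE)
    }
  }
  if (any(!maps$meal_id %in% lines$meal_id)) {
    stop("mappings.csv references meal_id absent from lines.csv",
         call. = FALSE)
  }

  comp <- tabs$composition
  comp$food_code <- as.character(comp$food_code)
  nutr <- tabs$nutrients
  nutr$nutrient_id <- as.character(nutr$nutrient_id)
  groups <- as.character(tabs$groups$group)
  nutr_cols <- setdiff(names(comp), c("food_code", "food_group"))
  if (!setequal(nutr_cols, nutr$nutrient_id)) {
    stop("composition.csv nutrient columns do not match nutrients.csv",
         call. = FALSE)
  }
  comp <- comp[, c("food_code", "food_group", nutr$nutrient_id)]
  if (!energy_kj %in% nutr$nutrient_id) {
    stop("designated energy nutrient '", energy_kj,
         "' absent from nutrient dictionary", call. = FALSE)
  }

  defaults <- tabs$defaults
  defaults$kind <- as.character(defaults$kind)
  defaults$none_allowed <- as.logical(defaults$none_allowed)
  ref_lists <- list()
  for (kind in ffq_kinds) {
    fp <- file.path(path, paste0("reference_", kind, ".csv"))
    drow <- defaults[defaults$kind == kind, , drop = FALSE]
    if (!file.exists(fp) || nrow(drow) != 1L) next
    entries_df <- utils::read.csv(fp, stringsAsFactors = FALSE)
    entries <- as.character(entries_df$food_code)
    names(entries) <- normalize_name(entries_df$name)
    if (anyDuplicated(names(entries))) {
      stop("duplicate normalized names in reference_", kind, ".csv",
           call. = FALSE)
    }
    ref_lists[[kind]] <- list(
      kind = kind, entries = entries,
      default_code = as.character(drow$default_code),
      none_allowed = isTRUE(drow$none_allowed)
    )
  }

  scho <- tabs$schofield
  scho$sex <- as.character(scho$sex)
  for (col in c("age_lo", "age_hi", "slope", "intercept")) {
    scho[[col]] <- as.numeric(scho[[col]])
  }

  milk_amounts <- tabs$milk_amounts
  milk_amounts$code <- as.integer(milk_amounts$code)
  milk_amounts$factor <- as.numeric(milk_amounts$factor)

  dm <- structure(list(
    frequency_scheme = freq,
    lines = lines,
    mappings = maps,
    composition = comp,
    reference_lists = ref_lists,
    schofield = scho,
    nutrient_dictionary = nutr,
    group_scheme = groups,
    milk_amounts = milk_amounts,
    energy_kj_nutrient_id = energy_kj,
    missing_codes = character(0)
  ), class = "ffq_data_model")

  referenced <- unique(c(
    maps$food_code,
    unlist(lapply(ref_lists, function(r) c(r$entries, r$default_code)))
  ))
  referenced <- setdiff(referenced, ffq_sentinels)
  dm$missing_codes <- sort(setdiff(referenced, comp$food_code))
  dm
}

#' Validate a data model
#'
#' Checks every invariant of the data model — frequency scheme shape,
#' mapping arity and proportion sums, non-negative nutrient amounts, food
#' groups drawn from the declared scheme, reference lists present for every
#' part-2 tag in use, default codes resolvable, Schofield age bands
#' contiguous and non-overlapping per sex — and reports findings rather than
#' throwing. An empty report means the model is internally consistent.
#'
#' @param dm An `ffq_data_model`.
#' @return A data frame with columns `severity` (`"error"` or `"warning"`)
#'   and `message`; zero rows iff the model is fully valid.
#' @export
validate_data_model <- function(dm) {
  stopifnot(inherits(dm, "ffq_data_model"))
  sev <- character(0); msg <- character(0)
  add <- function(s, m) {
    sev <<- c(sev, s); msg <<- c(msg, m)
  }

  fr <- dm$frequency_scheme
  if (!identical(sort(fr$code), 1:9)) {
    add("error", "frequency codes are not exactly 1..9")
  }
  if (length(fr$multiplier) && fr$multiplier[which.min(fr$code)] != 0) {
    add("error", "frequency code 1 multiplier is not 0")
  }
  if (is.unsorted(fr$multiplier[order(fr$code)])) {
    add("error", "frequency multipliers are not non-decreasing")
  }
  if (any(fr$multiplier < 0)) add("error", "negative frequency multiplier")

  for (i in seq_len(nrow(dm$lines))) {
    ln <- dm$lines[i, ]
    m <- dm$mappings[dm$mappings$meal_id == ln$meal_id, , drop = FALSE]
    if (nrow(m) < 1L || nrow(m) > 6L) {
      add("error", paste0("meal_id ", ln$meal_id, ": ", nrow(m),
                          " mappings (must be 1-6)"))
    }
    if (nrow(m) && abs(sum(m$proportion) - 1) > 1e-9) {
      add("error", paste0("meal_id ", ln$meal_id,
                          ": mapping proportions sum to ", sum(m$proportion)))
    }
    if (ln$portion_g <= 0) {
      add("error", paste0("meal_id ", ln$meal_id, ": portion_g not > 0"))
    }
    tag <- ln$part2_tag
    if (tag != "none" && is.null(dm$reference_lists[[tag]])) {
      add("error", paste0("meal_id ", ln$meal_id, ": part2_tag '", tag,
                          "' has no matching reference list"))
    }
  }
  if (any(dm$mappings$proportion < 0 | dm$mappings$proportion > 1)) {
    add("error", "mapping proportion outside [0, 1]")
  }
  if (any(dm$mappings$fat_uptake_g_per_100g < 0)) {
    add("error", "negative fat_uptake_g_per_100g")
  }

  comp <- dm$composition
  nutr_ids <- dm$nutrient_dictionary$nutrient_id
  for (nid in nutr_ids) {
    bad <- comp$food_code[!is.na(comp[[nid]]) & comp[[nid]] < 0]
    for (fc in bad) {
      add("error", paste0("food_code ", fc, ": negative amount for nutrient ",
                          nid))
    }
  }
  bad_grp <- comp$food_code[!comp$food_group %in% dm$group_scheme]
  for (fc in bad_grp) {
    add("error", paste0("food_code ", fc,
                        ": food_group not in declared group scheme"))
  }
  if (anyDuplicated(comp$food_code)) {
    add("error", "duplicate food_code in composition table")
  }

  for (kind in names(dm$reference_lists)) {
    rl <- dm$reference_lists[[kind]]
    if (!rl$default_code %in% comp$food_code) {
      add("error", paste0("reference list '", kind, "': default_code ",
                          rl$default_code, " absent from composition table"))
    }
  }

  for (sx in unique(dm$schofield$sex)) {
    bands <- dm$schofield[dm$schofield$sex == sx, , drop = FALSE]
    bands <- bands[order(bands$age_lo), , drop = FALSE]
    if (any(bands$slope < 0)) {
      add("error", paste0("schofield: negative slope for sex ", sx))
    }
    if (nrow(bands) > 1L &&
        any(abs(bands$age_lo[-1L] - bands$age_hi[-nrow(bands)]) > 1e-9)) {
      add("error", paste0("schofield: age bands for sex ", sx,
                          " are not contiguous"))
    }
  }

  for (fc in dm$missing_codes) {
    add("warning", paste0("food_code ", fc,
                          " is referenced but has no composition record"))
  }

  data.frame(severity = sev, message = msg, stringsAsFactors = FALSE)
}

#' Write a data model back to a bundle directory
#'
#' Serialises an `ffq_data_model` to the same delimited-text layout read by
#' [load_data_model()], so that `load_data_model(write_data_model(dm, d))`
#' round-trips field-for-field.
#'
#' @param dm An `ffq_data_model`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_data_model <- function(dm, path) {
  stopifnot(inherits(dm, "ffq_data_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file) {
    utils::write.csv(df, file.path(path, file), row.names = FALSE)
  }
  w(dm$frequency_scheme, "frequencies.csv")
  w(dm$lines, "lines.csv")
  w(dm$mappings, "mappings.csv")
  w(dm$composition, "composition.csv")
  w(dm$nutrient_dictionary, "nutrients.csv")
  w(data.frame(group = dm$group_scheme, stringsAsFactors = FALSE),
    "groups.csv")
  defaults <- do.call(rbind, lapply(dm$reference_lists, function(rl) {
    data.frame(kind = rl$kind, default_code = rl$default_code,
               none_allowed = rl$none_allowed, stringsAsFactors = FALSE)
  }))
  w(defaults, "defaults.csv")
  for (kind in names(dm$reference_lists)) {
    rl <- dm$reference_lists[[kind]]
    w(data.frame(name = names(rl$entries),
                 food_code = unname(rl$entries), stringsAsFactors = FALSE),
      paste0("reference_", kind, ".csv"))
  }
  w(dm$schofield, "schofield.csv")
  w(dm$milk_amounts, "milk_amounts.csv")
  invisible(path)
}

#' @export
print.ffq_data_model <- function(x, ...) {
  cat("FFQ data model\n")
  cat("  lines:      ", nrow(x$lines), "\n")
  cat("  food codes: ", nrow(x$composition), "\n")
  cat("  nutrients:  ", nrow(x$nutrient_dictionary), "\n")
  cat("  groups:     ", length(x$group_scheme), "\n")
  cat("  reference lists:", paste(names(x$reference_lists), collapse = ", "),
      "\n")
  if (length(x$missing_codes)) {
    cat("  codes lacking nutrient data:",
        paste(x$missing_codes, collapse = ", "), "\n")
  }
  invisible(x)
}
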