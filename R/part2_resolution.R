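# Part-2 resolution: free text, ticked "None/No" boxes, pre-assigned codes
# and defaults -> the food codes substituted into tagged part-1 lines.

#' Normalize a free-text food name
#'
#' Case-folds, strips punctuation and collapses internal whitespace so that
#' hand-written variants ("Corn Flakes!", "corn  flakes") meet the reference
#' list on equal terms. Idempotent: `normalize_name(normalize_name(x))`
#' equals `normalize_name(x)`.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^[:alnum:][:space:]]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

resolve_one_kind <- function(kind, texts, pre, none_ticked, dm,
                             text_matching, add_note) {
  rl <- dm$reference_lists[[kind]]
  if (is.null(rl)) {
    stop("no reference list for part-2 kind '", kind, "'", call. = FALSE)
  }
  none_sentinel <- if (kind %in% c("frying_fat", "baking_fat")) {
    ffq_sentinels[["no_fat"]]
  } else {
    ffq_sentinels[["none"]]
  }

  # Precedence: pre-assigned code > None/No box > exact normalized match >
  # default. A pre-assigned code absent from the composition table is an
  # error note and falls through.
  if (!is.na(pre)) {
    if (pre %in% dm$composition$food_code) {
      return(list(code = pre, provenance = "preassigned"))
    }
    add_note("error", paste0(kind, ": pre-assigned code '", pre,
                             "' absent from composition table; ",
                             "falling through"))
  }
  if (none_ticked && isTRUE(rl$none_allowed)) {
    if (length(texts)) {
      add_note("note", paste0(kind, ": both None/No box and text present; ",
                              "None/No box takes precedence"))
    }
    return(list(code = none_sentinel, provenance = "none_box"))
  }
  if (text_matching && length(texts)) {
    hit <- rl$entries[normalize_name(texts[1])]
    if (!is.na(hit)) {
      return(list(code = unname(hit), provenance = "matched_text"))
    }
  }
  add_note("note", paste0(kind, ": default code ", rl$default_code,
                          " assigned"))
  list(code = rl$default_code, provenance = "default")
}

#' Resolve part-2 answers to food codes
#'
#' Turns a participant's part-2 detail answers into the milk, breakfast
#' cereal and cooking-fat food codes substituted into tagged part-1 lines.
#' Per kind the precedence is: pre-assigned code, then a ticked "None/No"
#' box (where the reference list allows one), then an exact match of the
#' normalized free text against the reference list, then the default code.
#' Every default assignment emits a log note. Up to four distinct cereal
#' codes are kept (order preserved, duplicates dropped, extras truncated
#' with a note); a "None/No" cooking-fat box yields the `NO_FAT` sentinel so
#' no fat is added to modified without-fat foods.
#'
#' Matching is exact-after-normalization only: the manual step of comparing
#' nutrient profiles for unclear matches is a human judgement, and
#' auto-assigning fuzzy matches would make runs irreproducible. Disabling
#' `text_matching` forces every kind without a pre-assigned code or None/No
#' box onto its default — the mechanism used to study the effect of text
#' matching on intakes.
#'
#' @param part2 The `part2` element of an `ffq_participant`.
#' @param dm An `ffq_data_model`.
#' @param text_matching Logical; match free text against reference lists
#'   (`TRUE`, the default) or skip straight to defaults.
#' @return A list with `resolution` (fields `milk_code`, `cereal_codes`,
#'   `frying_fat_code`, `baking_fat_code`, `provenance` — one provenance per
#'   kind) and `notes` (data frame `level`, `message`).
#' @export
resolve_part2 <- function(part2, dm, text_matching = TRUE) {
  notes_level <- character(0); notes_msg <- character(0)
  add_note <- function(level, message) {
    notes_level <<- c(notes_level, level)
    notes_msg <<- c(notes_msg, message)
  }
  pre <- part2$preassigned_codes
  get_pre <- function(kind) {
    if (kind %in% names(pre)) pre[[kind]] else NA_character_
  }
  none <- function(kind) kind %in% part2$none_boxes

  milk <- resolve_one_kind("milk",
    if (is.na(part2$milk_text)) character(0) else part2$milk_text,
    get_pre("milk"), none("milk"), dm, text_matching, add_note)
  fry <- resolve_one_kind("frying_fat",
    if (is.na(part2$frying_fat_text)) character(0) else part2$frying_fat_text,
    get_pre("frying_fat"), none("frying_fat"), dm, text_matching, add_note)
  bake <- resolve_one_kind("baking_fat",
    if (is.na(part2$baking_fat_text)) character(0) else part2$baking_fat_text,
    get_pre("baking_fat"), none("baking_fat"), dm, text_matching, add_note)

  # Cereal: each text resolved independently; dedup, keep order, cap at 4.
  rl <- dm$reference_lists[["cereal"]]
  cereal_prov <- NULL
  cereal_codes <- character(0)
  if (!is.na(p <- get_pre("cereal"))) {
    if (p %in% dm$composition$food_code) {
      cereal_codes <- p
      cereal_prov <- "preassigned"
    } else {
      add_note("error", paste0("cereal: pre-assigned code '", p,
                               "' absent from composition table; ",
                               "falling through"))
    }
  }
  if (is.null(cereal_prov) && none("cereal") && isTRUE(rl$none_allowed)) {
    cereal_codes <- ffq_sentinels[["none"]]
    cereal_prov <- "none_box"
  }
  if (is.null(cereal_prov)) {
    if (text_matching && length(part2$cereal_texts)) {
      hits <- rl$entries[normalize_name(part2$cereal_texts)]
      cereal_codes <- unique(unname(hits[!is.na(hits)]))
    }
    if (length(cereal_codes)) {
      cereal_prov <- "matched_text"
      if (length(cereal_codes) > 4L) {
        add_note("note", paste0("cereal: ", length(cereal_codes),
                                " matched codes truncated to 4"))
        cereal_codes <- cereal_codes[1:4]
      }
    } else {
      cereal_codes <- rl$default_code
      cereal_prov <- "default"
      add_note("note", paste0("cereal: default code ", rl$default_code,
                              " assigned"))
    }
  }

  resolution <- list(
    milk_code = milk$code,
    cereal_codes = cereal_codes,
    frying_fat_code = fry$code,
    baking_fat_code = bake$code,
    provenance = c(milk = milk$provenance, cereal = cereal_prov,
                   frying_fat = fry$provenance, baking_fat = bake$provenance)
  )
  list(resolution = resolution,
       notes = data.frame(level = notes_level, message = notes_msg,
                          stringsAsFactors = FALSE))
}
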