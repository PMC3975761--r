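# Deliberately naive reference implementation of the intake computation:
# scalar triple loops over lines, mapping slots and nutrients, reading the
# data-model tables directly. Kept independent of the engine's vectorised
# path so the two can disagree.

oracle_participant_totals <- function(rec, dm, text_matching = TRUE) {
  res <- resolve_part2(rec$part2, dm, text_matching)$resolution
  sent <- ffq_sentinel_codes()

  milk_factor <- 1
  if (!is.na(rec$part2$milk_amount_code)) {
    row <- which(dm$milk_amounts$code == rec$part2$milk_amount_code)
    if (length(row) == 1L) milk_factor <- dm$milk_amounts$factor[row]
  }

  nutr_ids <- dm$nutrient_dictionary$nutrient_id
  totals <- stats::setNames(rep(0, length(nutr_ids)), nutr_ids)
  groups <- stats::setNames(rep(0, length(dm$group_scheme)), dm$group_scheme)
  grams_apportioned <- 0

  add_food <- function(code, grams) {
    row <- which(dm$composition$food_code == code)
    if (length(row) == 1L) {
      for (nid in nutr_ids) {
        totals[nid] <<- totals[nid] +
          grams * dm$composition[[nid]][row] / 100
      }
      g <- dm$composition$food_group[row]
      groups[g] <<- groups[g] + grams
    }
  }

  for (i in seq_len(nrow(dm$lines))) {
    line <- dm$lines[i, ]
    fv <- rec$part1[i, ]
    if (fv$status != "answered") next
    mult <- dm$frequency_scheme$multiplier[
      dm$frequency_scheme$code == fv$code]
    grams <- mult * line$portion_g
    if (line$part2_tag == "milk") grams <- grams * milk_factor

    if (line$part2_tag == "cereal") {
      codes <- res$cereal_codes[res$cereal_codes != sent[["none"]]]
      for (code in codes) {
        add_food(code, grams / length(codes))
        grams_apportioned <- grams_apportioned + grams / length(codes)
      }
      next
    }
    maps <- dm$mappings[dm$mappings$meal_id == line$meal_id, , drop = FALSE]
    for (j in seq_len(nrow(maps))) {
      code <- maps$food_code[j]
      if (line$part2_tag == "milk" && maps$substitutable[j]) {
        code <- res$milk_code
      }
      if (code == sent[["none"]]) next
      g <- grams * maps$proportion[j]
      add_food(code, g)
      grams_apportioned <- grams_apportioned + g
      uptake <- maps$fat_uptake_g_per_100g[j]
      if (uptake > 0 && line$part2_tag %in% c("frying_fat", "baking_fat")) {
        fat_code <- if (line$part2_tag == "frying_fat") {
          res$frying_fat_code
        } else {
          res$baking_fat_code
        }
        if (fat_code != sent[["no_fat"]] && g > 0) {
          add_food(fat_code, g * uptake / 100)
        }
      }
    }
  }
  list(totals = c(totals, groups), grams_apportioned = grams_apportioned)
}

rel_err <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  ifelse(s == 0, d, d / s)
}
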