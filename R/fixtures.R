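# Seeded synthetic fixtures: a toy data-model bundle and cohort files with
# the statistical structure the engine assumes (missingness, dual
# frequencies, free-text noise), so every module is testable offline.

ffq_group_names <- c(
  "alcoholic_beverages", "cereals_and_cereal_products",
  "eggs_and_egg_dishes", "fats_and_oils", "fish_and_fish_products",
  "fruit", "meat_and_meat_products", "milk_and_milk_products",
  "non_alcoholic_beverages", "nuts_and_seeds", "potatoes",
  "soups_and_sauces", "sugars", "vegetables")

base_nutrients <- data.frame(
  nutrient_id = c("energy_kcal", "energy_kj", "protein_g", "fat_g",
                  "carbohydrate_g", "fibre_g", "calcium_mg",
                  "vitamin_c_mg"),
  name = c("Energy", "Energy", "Protein", "Fat", "Carbohydrate",
           "Englyst fibre", "Calcium", "Vitamin C"),
  unit = c("kcal", "kJ", "g", "g", "g", "g", "mg", "mg"),
  stringsAsFactors = FALSE)

# Schofield (1985) adult coefficient bands, MJ/day = slope * kg + intercept.
schofield_adult_table <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 3L),
    age_lo = rep(c(18, 30, 60), 2L),
    age_hi = rep(c(30, 60, 120), 2L),
    slope = c(0.063, 0.048, 0.049, 0.062, 0.034, 0.038),
    intercept = c(2.896, 3.653, 2.459, 2.036, 3.538, 2.755),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic fixture
#'
#' @param n_lines Questionnaire lines (>= 5; the first four carry the milk,
#'   cereal, frying-fat and baking-fat part-2 tags).
#' @param n_foods Food codes in the composition table (>= 12; ten are the
#'   named milk/cereal/fat/without-fat specials).
#' @param n_nutrients Nutrients (>= 8; the first eight are the named base
#'   set including both energy units).
#' @param n_participants Cohort size (>= 1).
#' @param missing_cell_rate,dual_frequency_rate Per-cell probabilities of a
#'   missing sentinel (`-9`, empty or `-4`) and of a dual `a;b` answer.
#' @param text_typo_rate Probability that a part-2 free text carries a
#'   single-character typo (guaranteeing exact-match failure, hence a
#'   default-code assignment).
#' @param seed Integer seed; one seed drives all randomness.
#' @return An `ffq_fixture_spec` list.
#' @export
fixture_spec <- function(n_lines = 10L, n_foods = 12L, n_nutrients = 8L,
                         n_participants = 50L, missing_cell_rate = 0.02,
                         dual_frequency_rate = 0.01, text_typo_rate = 0.1,
                         seed = 1L) {
  stopifnot(n_lines >= 5L, n_foods >= 12L, n_nutrients >= 8L,
            n_participants >= 1L)
  rates <- c(missing_cell_rate, dual_frequency_rate, text_typo_rate)
  stopifnot(all(rates >= 0), all(rates <= 1))
  structure(list(
    n_lines = as.integer(n_lines), n_foods = as.integer(n_foods),
    n_nutrients = as.integer(n_nutrients),
    n_participants = as.integer(n_participants),
    missing_cell_rate = missing_cell_rate,
    dual_frequency_rate = dual_frequency_rate,
    text_typo_rate = text_typo_rate, seed = as.integer(seed)
  ), class = "ffq_fixture_spec")
}

#' Fixture presets
#'
#' `"toy"` is the default desk-scale spec (10 lines, 12 foods, 8 nutrients);
#' `"fullscale"` has the shape of the real instrument — 130 lines, 46
#' nutrients, 14 food groups — with synthetic content.
#'
#' @param preset `"toy"` or `"fullscale"`.
#' @param seed Integer seed.
#' @return An `ffq_fixture_spec`.
#' @export
fixture_preset <- function(preset = c("toy", "fullscale"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "toy") {
    fixture_spec(seed = seed)
  } else {
    fixture_spec(n_lines = 130L, n_foods = 60L, n_nutrients = 46L,
                 n_participants = 200L, seed = seed)
  }
}

special_foods <- data.frame(
  food_code = c("M01", "M02", "C01", "C02", "C03", "FAT1", "FAT2", "FAT3",
                "FAT4", "W01"),
  food_group = c("milk_and_milk_products", "milk_and_milk_products",
                 "cereals_and_cereal_products", "cereals_and_cereal_products",
                 "cereals_and_cereal_products", "fats_and_oils",
                 "fats_and_oils", "fats_and_oils", "fats_and_oils",
                 "meat_and_meat_products"),
  stringsAsFactors = FALSE)

#' Generate a synthetic data-model bundle
#'
#' Writes a complete bundle to `dir` and returns it loaded. The bundle
#' always contains at least one milk-, cereal-, frying-fat- and
#' baking-fat-tagged line, a modified without-fat food with nonzero fat
#' uptake on both fat-tagged lines, reference lists with defaults, the full
#' adult Schofield coefficient table and the milk-amount factor table; it
#' passes [validate_data_model()] with zero errors. Deterministic in the
#' spec's seed (same seed, byte-identical bundle).
#'
#' @param spec An `ffq_fixture_spec`.
#' @param dir Output directory.
#' @return The loaded `ffq_data_model`, invisibly visible.
#' @export
generate_data_model <- function(spec, dir) {
  stopifnot(inherits(spec, "ffq_fixture_spec"))
  set.seed(spec$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  nutr <- base_nutrients
  if (spec$n_nutrients > nrow(nutr)) {
    extra_ids <- sprintf("nutrient_%02d", seq.int(nrow(nutr) + 1L,
                                                  spec$n_nutrients))
    nutr <- rbind(nutr, data.frame(
      nutrient_id = extra_ids,
      name = paste("Synthetic nutrient", seq_along(extra_ids)),
      unit = "mg", stringsAsFactors = FALSE))
  }

  n_generic <- spec$n_foods - nrow(special_foods)
  generic <- data.frame(
    food_code = sprintf("F%02d", seq_len(n_generic)),
    food_group = sample(ffq_group_names, n_generic, replace = TRUE),
    stringsAsFactors = FALSE)
  foods <- rbind(special_foods, generic)

  kcal <- round(stats::runif(nrow(foods), 20, 600), 1)
  comp <- data.frame(food_code = foods$food_code,
                     food_group = foods$food_group,
                     stringsAsFactors = FALSE)
  comp$energy_kcal <- kcal
  comp$energy_kj <- round(kcal * 4.184, 1)
  for (nid in setdiff(nutr$nutrient_id, c("energy_kcal", "energy_kj"))) {
    comp[[nid]] <- round(stats::runif(nrow(foods), 0, 50), 2)
  }

  portion_pool <- c(30, 40, 60, 80, 100, 120, 140, 150, 200)
  kinds <- c("medium serving", "standard unit", "household measure")
  tags <- c("milk", "cereal", "frying_fat", "baking_fat",
            rep("none", spec$n_lines - 4L))
  lines <- data.frame(
    meal_id = seq_len(spec$n_lines),
    label = sprintf("line %02d (%s)", seq_len(spec$n_lines), tags),
    portion_g = c(150, 40, 100, 80,
                  sample(portion_pool, spec$n_lines - 4L, replace = TRUE)),
    portion_kind = c("household measure", "medium serving",
                     "medium serving", "medium serving",
                     sample(kinds, spec$n_lines - 4L, replace = TRUE)),
    part2_tag = tags, stringsAsFactors = FALSE)

  prop_patterns <- list(1, c(0.5, 0.5), c(0.7, 0.3), c(0.25, 0.25, 0.5))
  # pool for untagged lines: generic foods plus the non-default specials
  static_pool <- c(generic$food_code, "C02", "C03", "FAT3", "FAT4")
  maps <- list(
    data.frame(meal_id = 1L, food_code = "M01", proportion = 1,
               substitutable = TRUE, fat_uptake_g_per_100g = 0,
               stringsAsFactors = FALSE),
    data.frame(meal_id = 2L, food_code = "C01", proportion = 1,
               substitutable = TRUE, fat_uptake_g_per_100g = 0,
               stringsAsFactors = FALSE),
    data.frame(meal_id = 3L, food_code = "W01", proportion = 1,
               substitutable = FALSE, fat_uptake_g_per_100g = 10,
               stringsAsFactors = FALSE),
    data.frame(meal_id = 4L, food_code = "W01", proportion = 1,
               substitutable = FALSE, fat_uptake_g_per_100g = 8,
               stringsAsFactors = FALSE))
  for (mid in seq.int(5L, spec$n_lines)) {
    pat <- prop_patterns[[sample.int(length(prop_patterns), 1L)]]
    codes <- sample(static_pool, length(pat))
    maps[[length(maps) + 1L]] <- data.frame(
      meal_id = mid, food_code = codes, proportion = pat,
      substitutable = FALSE, fat_uptake_g_per_100g = 0,
      stringsAsFactors = FALSE)
  }
  maps <- do.call(rbind, maps)

  w <- function(df, file) {
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  w(default_frequency_scheme(), "frequencies.csv")
  w(lines, "lines.csv")
  w(maps, "mappings.csv")
  w(comp, "composition.csv")
  w(nutr, "nutrients.csv")
  w(data.frame(group = ffq_group_names, stringsAsFactors = FALSE),
    "groups.csv")
  w(data.frame(name = c("Skimmed Milk", "Whole Milk"),
               food_code = c("M01", "M02"), stringsAsFactors = FALSE),
    "reference_milk.csv")
  w(data.frame(name = c("Cornflakes", "Muesli", "Porridge"),
               food_code = c("C01", "C02", "C03"), stringsAsFactors = FALSE),
    "reference_cereal.csv")
  w(data.frame(name = c("Vegetable Oil", "Lard"),
               food_code = c("FAT1", "FAT3"), stringsAsFactors = FALSE),
    "reference_frying_fat.csv")
  w(data.frame(name = c("Butter", "Margarine"),
               food_code = c("FAT2", "FAT4"), stringsAsFactors = FALSE),
    "reference_baking_fat.csv")
  w(data.frame(kind = c("milk", "cereal", "frying_fat", "baking_fat"),
               default_code = c("M01", "C01", "FAT1", "FAT2"),
               none_allowed = c(FALSE, FALSE, TRUE, TRUE),
               stringsAsFactors = FALSE),
    "defaults.csv")
  w(schofield_adult_table(), "schofield.csv")
  w(data.frame(code = 1:4, factor = c(0.5, 1, 1.5, 2)), "milk_amounts.csv")

  load_data_model(dir)
}

typo <- function(x) {
  pos <- sample.int(nchar(x), 1L)
  paste0(substr(x, 1L, pos - 1L), "x",
         substr(x, pos + 1L, nchar(x)))
}

ref_names <- function(dm, kind) {
  # Display forms recoverable from the bundle's normalized names.
  names(dm$reference_lists[[kind]]$entries)
}

#' Generate a synthetic cohort file
#'
#' One row per participant: sex, age drawn uniformly on 40-79 years, body
#' weight, per-line frequency codes (weighted towards the lower
#' categories), missing/legacy sentinels and dual `a;b` answers injected at
#' the spec's rates, part-2 free text drawn from the bundle's reference
#' names with single-character typos at `text_typo_rate`, occasional
#' "None/No" fat boxes and milk-amount categories. Deterministic in the
#' spec's seed.
#'
#' @param dm The `ffq_data_model` the cohort is keyed against.
#' @param spec An `ffq_fixture_spec`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
generate_cohort <- function(dm, spec, path) {
  stopifnot(inherits(dm, "ffq_data_model"),
            inherits(spec, "ffq_fixture_spec"))
  set.seed(spec$seed + 131071L)
  n <- spec$n_participants
  L <- nrow(dm$lines)

  freq_prob <- c(0.25, 0.2, 0.15, 0.12, 0.1, 0.08, 0.05, 0.03, 0.02)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  age <- sample(40:79, n, replace = TRUE)
  weight <- round(pmax(40, stats::rnorm(n, ifelse(sex == "male", 78, 68),
                                        12)), 1)

  cells <- matrix("", nrow = n, ncol = L)
  for (i in seq_len(n)) {
    codes <- sample(1:9, L, replace = TRUE, prob = freq_prob)
    cell <- as.character(codes)
    u <- stats::runif(L)
    dual <- u < spec$dual_frequency_rate
    miss <- !dual & u < spec$dual_frequency_rate + spec$missing_cell_rate
    if (any(dual)) {
      second <- sample(1:9, sum(dual), replace = TRUE)
      cell[dual] <- paste0(codes[dual], ";", second)
    }
    if (any(miss)) {
      cell[miss] <- sample(c("-9", "", "-4"), sum(miss), replace = TRUE,
                           prob = c(0.5, 0.3, 0.2))
    }
    cells[i, ] <- cell
  }

  pick_text <- function(kind) {
    nm <- sample(ref_names(dm, kind), n, replace = TRUE)
    has_typo <- stats::runif(n) < spec$text_typo_rate
    nm[has_typo] <- vapply(nm[has_typo], typo, "")
    nm
  }
  milk_text <- pick_text("milk")
  cereal1 <- pick_text("cereal")
  cereal2 <- ifelse(stats::runif(n) < 0.4, pick_text("cereal"), "")
  frying <- pick_text("frying_fat")
  baking <- pick_text("baking_fat")
  none_fry <- as.integer(stats::runif(n) < 0.05)
  none_bake <- as.integer(stats::runif(n) < 0.05)
  milk_amount <- sample(c("", "1", "2", "3", "4"), n, replace = TRUE,
                        prob = c(0.3, 0.1, 0.35, 0.15, 0.1))

  df <- data.frame(
    id = sprintf("P%05d", seq_len(n)), sex = sex, age = age,
    weight = weight, stringsAsFactors = FALSE)
  for (j in seq_len(L)) df[[paste0("q", j)]] <- cells[, j]
  df$milk_text <- milk_text
  df$milk_amount <- milk_amount
  df$cereal1 <- cereal1
  df$cereal2 <- cereal2
  df$cereal3 <- ""
  df$cereal4 <- ""
  df$frying_fat_text <- frying
  df$baking_fat_text <- baking
  df$none_milk <- 0L
  df$none_cereal <- 0L
  df$none_frying_fat <- none_fry
  df$none_baking_fat <- none_bake
  df$pre_milk <- ""
  df$pre_cereal <- ""
  df$pre_frying_fat <- ""
  df$pre_baking_fat <- ""
  stopifnot(identical(names(df), cohort_header(dm)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
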