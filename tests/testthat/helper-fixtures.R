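# Hand-written micro data-model bundle with round numbers, so expected
# intakes are hand-computable. Five lines: milk-tagged, cereal-tagged,
# frying-fat-tagged (without-fat food, uptake 10 g/100 g), a 0.7/0.3 split
# line, and a single-food line (60 g portion, 250 kcal/100 g).

micro_composition <- function() {
  df <- data.frame(
    food_code = c("A", "B", "M1", "M2", "C1", "C2", "C3", "C4", "C5",
                  "FT1", "FT2", "W1"),
    food_group = c("fruit", "fruit", "milk_and_milk_products",
                   "milk_and_milk_products",
                   rep("cereals_and_cereal_products", 5),
                   "fats_and_oils", "fats_and_oils",
                   "meat_and_meat_products"),
    energy_kcal = c(250, 100, 50, 64, 370, 350, 380, 330, 360, 900, 737,
                    200),
    energy_kj = c(1046, 418.4, 209.2, 267.8, 1548, 1464, 1590, 1381, 1506,
                  3766, 3083, 836.8),
    protein_g = c(5, 2, 3.4, 3.3, 8, 10, 11, 9, 10.5, 0, 0.5, 12),
    stringsAsFactors = FALSE)
  df
}

write_micro_bundle <- function(dir = tempfile("bundle")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file) {
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  w(default_frequency_scheme(), "frequencies.csv")
  w(data.frame(
    meal_id = 1:5,
    label = c("milk on its own", "breakfast cereal", "fried dish",
              "mixed fruit", "single fruit"),
    portion_g = c(100, 40, 50, 100, 60),
    portion_kind = c("household measure", "medium serving",
                     "medium serving", "medium serving", "standard unit"),
    part2_tag = c("milk", "cereal", "frying_fat", "none", "none"),
    stringsAsFactors = FALSE), "lines.csv")
  w(data.frame(
    meal_id = c(1L, 2L, 3L, 4L, 4L, 5L),
    food_code = c("M1", "C1", "W1", "A", "B", "A"),
    proportion = c(1, 1, 1, 0.7, 0.3, 1),
    substitutable = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    fat_uptake_g_per_100g = c(0, 0, 10, 0, 0, 0),
    stringsAsFactors = FALSE), "mappings.csv")
  w(micro_composition(), "composition.csv")
  w(data.frame(nutrient_id = c("energy_kcal", "energy_kj", "protein_g"),
               name = c("Energy", "Energy", "Protein"),
               unit = c("kcal", "kJ", "g"), stringsAsFactors = FALSE),
    "nutrients.csv")
  w(data.frame(group = c("fruit", "milk_and_milk_products",
                         "cereals_and_cereal_products", "fats_and_oils",
                         "meat_and_meat_products"),
               stringsAsFactors = FALSE), "groups.csv")
  w(data.frame(name = c("skimmed milk", "whole milk"),
               food_code = c("M1", "M2"), stringsAsFactors = FALSE),
    "reference_milk.csv")
  w(data.frame(name = c("cornflakes", "muesli", "porridge", "bran flakes",
                        "oat crunch"),
               food_code = c("C1", "C2", "C3", "C4", "C5"),
               stringsAsFactors = FALSE), "reference_cereal.csv")
  w(data.frame(name = "vegetable oil", food_code = "FT1",
               stringsAsFactors = FALSE), "reference_frying_fat.csv")
  w(data.frame(name = "butter", food_code = "FT2",
               stringsAsFactors = FALSE), "reference_baking_fat.csv")
  w(data.frame(kind = c("milk", "cereal", "frying_fat", "baking_fat"),
               default_code = c("M1", "C1", "FT1", "FT2"),
               none_allowed = c(FALSE, FALSE, TRUE, TRUE),
               stringsAsFactors = FALSE), "defaults.csv")
  w(data.frame(sex = rep(c("male", "female"), each = 3L),
               age_lo = rep(c(18, 30, 60), 2L),
               age_hi = rep(c(30, 60, 120), 2L),
               slope = c(0.063, 0.048, 0.049, 0.062, 0.034, 0.038),
               intercept = c(2.896, 3.653, 2.459, 2.036, 3.538, 2.755),
               stringsAsFactors = FALSE), "schofield.csv")
  w(data.frame(code = 1:4, factor = c(0.5, 1, 1.5, 2)), "milk_amounts.csv")
  dir
}

micro_dm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_data_model(write_micro_bundle())
    cache
  }
})

# Patch one bundle CSV (by data frame transform) in a fresh copy.
tweak_bundle <- function(src, file, fn) {
  dst <- tempfile("bundle")
  dir.create(dst)
  file.copy(list.files(src, full.names = TRUE), dst)
  fp <- file.path(dst, file)
  df <- utils::read.csv(fp, stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(fn(df), fp, row.names = FALSE)
  dst
}

default_part2 <- function() {
  list(milk_text = NA_character_, milk_amount_code = NA_integer_,
       cereal_texts = character(0), frying_fat_text = NA_character_,
       baking_fat_text = NA_character_, none_boxes = character(0),
       preassigned_codes = character(0))
}

# Build a participant record directly from raw frequency cell strings.
make_participant <- function(cells, part2 = list(), id = "T001",
                             sex = "male", age = 50, weight = 80) {
  fvs <- lapply(cells, parse_frequency_cell)
  part1 <- data.frame(
    status = vapply(fvs, `[[`, "", "status"),
    code = vapply(fvs, `[[`, NA_integer_, "code"),
    raw = vapply(fvs, `[[`, "", "raw"),
    stringsAsFactors = FALSE)
  p2 <- default_part2()
  p2[names(part2)] <- part2
  structure(list(participant_id = id, sex = sex, age = age,
                 weight = weight, part1 = part1, part2 = p2),
            class = "ffq_participant")
}

# A toy generated bundle + cohort shared across test files.
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(seed = 42L)
      dir <- tempfile("toy")
      dm <- generate_data_model(spec, dir)
      cohort_path <- tempfile(fileext = ".csv")
      generate_cohort(dm, spec, cohort_path)
      cache <<- list(spec = spec, dir = dir, dm = dm,
                     cohort_path = cohort_path,
                     cohort = read_cohort(cohort_path, dm))
    }
    cache
  }
})
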