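test_that("line grams = frequency multiplier x portion weight", {
  dm <- micro_dm()
  scheme <- dm$frequency_scheme
  line <- list(portion_g = 60, part2_tag = "none")
  expect_equal(line_daily_grams(list(status = "answered", code = 6L),
                                line, scheme), 60)
  expect_equal(line_daily_grams(list(status = "answered", code = 1L),
                                line, scheme), 0)
  line140 <- list(portion_g = 140)
  expect_equal(line_daily_grams(list(status = "answered", code = 4L),
                                line140, scheme), 3 / 7 * 140)
  expect_equal(line_daily_grams(list(status = "missing",
                                     code = NA_integer_), line, scheme), 0)
  expect_equal(line_daily_grams(list(status = "legacy_missing",
                                     code = NA_integer_), line, scheme), 0)
})

test_that("apportioning splits by proportion, equally for cereals, and conserves grams", {
  dm <- micro_dm()
  res <- resolve_part2(default_part2(), dm)$resolution

  line4 <- dm$lines[4, ]  # A 0.7 / B 0.3
  app <- apportion_to_foods(100, line4, res, dm)
  expect_equal(app$food_code, c("A", "B"))
  expect_equal(app$grams, c(70, 30))

  app0 <- apportion_to_foods(0, line4, res, dm)
  expect_equal(app0$grams, c(0, 0))

  res2 <- res
  res2$cereal_codes <- c("C1", "C2")
  line2 <- dm$lines[2, ]
  app2 <- apportion_to_foods(80, line2, res2, dm)
  expect_equal(app2$food_code, c("C1", "C2"))
  expect_equal(app2$grams, c(40, 40))

  set.seed(21)
  for (i in 1:25) {
    g <- stats::runif(1, 0, 500)
    ln <- dm$lines[sample.int(5, 1), ]
    out <- apportion_to_foods(g, ln, res2, dm)
    expect_equal(sum(out$grams), g, tolerance = 1e-12)
  }
})

test_that("fat substitution adds grams x uptake / 100 at the resolved fat code", {
  dm <- micro_dm()
  res <- resolve_part2(default_part2(), dm)$resolution
  line3 <- dm$lines[3, ]  # frying_fat tag

  out <- apply_fat_substitution("W1", 50, 10, line3, res)
  expect_equal(out$food_code, c("W1", "FT1"))
  expect_equal(out$grams, c(50, 5))

  res_nofat <- res
  res_nofat$frying_fat_code <- unname(ffq_sentinel_codes()["no_fat"])
  out2 <- apply_fat_substitution("W1", 50, 10, line3, res_nofat)
  expect_equal(out2$food_code, "W1")

  out3 <- apply_fat_substitution("W1", 50, 0, line3, res)
  expect_equal(out3$food_code, "W1")
})

test_that("hand-computable participants produce the expected totals", {
  dm <- micro_dm()

  # all 'never': zero everything
  never <- make_participant(rep("1", 5))
  int0 <- compute_participant(never, dm)$intake
  expect_true(all(int0$totals == 0))
  expect_equal(int0$missing_line_count, 0L)

  # only line 5 once/day: 60 g of food A at 250 kcal/100 g -> 150 kcal/day
  solo <- make_participant(c("1", "1", "1", "1", "6"))
  int1 <- compute_participant(solo, dm)$intake
  expect_equal(unname(int1$totals["energy_kcal"]), 150)
  expect_equal(unname(int1$totals["fruit"]), 60)

  # line 3 once/day: 50 g fried food + 5 g default frying fat
  fried <- make_participant(c("1", "1", "6", "1", "1"))
  int2 <- compute_participant(fried, dm)$intake
  expect_equal(unname(int2$totals["energy_kcal"]),
               50 * 200 / 100 + 5 * 900 / 100)
  expect_equal(unname(int2$totals["fats_and_oils"]), 5)
  expect_equal(unname(int2$totals["meat_and_meat_products"]), 50)

  # milk-amount category 4 doubles milk-tagged line grams
  milk <- make_participant(c("6", "1", "1", "1", "1"),
                           part2 = list(milk_amount_code = 4L))
  int3 <- compute_participant(milk, dm)$intake
  expect_equal(unname(int3$totals["milk_and_milk_products"]), 200)
  expect_equal(unname(int3$totals["energy_kcal"]), 200 * 50 / 100)
})

test_that("missing lines contribute nothing but are counted", {
  dm <- micro_dm()
  a <- make_participant(c("1", "6", "1", "1", "6"))
  b <- make_participant(c("-9", "6", "1", "1", "6"))
  ia <- compute_participant(a, dm)$intake
  ib <- compute_participant(b, dm)$intake
  expect_equal(ib$totals, ia$totals)
  expect_equal(ia$missing_line_count, 0L)
  expect_equal(ib$missing_line_count, 1L)
})

test_that("unknown food codes contribute zero nutrients and one ERROR entry", {
  src <- write_micro_bundle()
  orphan <- tweak_bundle(src, "composition.csv", function(df) {
    df[df$food_code != "A", , drop = FALSE]
  })
  dm <- load_data_model(orphan)
  rec <- make_participant(c("1", "1", "1", "6", "1"))
  out <- compute_participant(rec, dm)
  # B still contributes: 30 g x 100 kcal/100 g
  expect_equal(unname(out$intake$totals["energy_kcal"]), 30)
  expect_equal(unname(out$intake$totals["fruit"]), 30)
  err <- out$log[out$log$level == "ERROR", ]
  expect_equal(sum(grepl("food code A", err$message)), 1L)
  expect_error(compute_participant(rec, dm, list(strict = TRUE)),
               "strict")
})

test_that("engine totals match the naive triple-loop oracle across seeded cohorts", {
  for (seed in 1:30) {
    spec <- fixture_spec(n_participants = 2L, seed = seed)
    dir <- tempfile()
    dm <- generate_data_model(spec, dir)
    path <- tempfile(fileext = ".csv")
    generate_cohort(dm, spec, path)
    co <- read_cohort(path, dm)
    for (rec in co$records) {
      eng <- compute_participant(rec, dm)$intake
      ora <- oracle_participant_totals(rec, dm)
      expect_lt(max(rel_err(eng$totals[names(ora$totals)], ora$totals)),
                1e-9)
    }
  }
})

test_that("mass is conserved: food grams (net of added fat) equal answered multiplier x portion", {
  dm <- micro_dm()
  scheme <- dm$frequency_scheme
  set.seed(31)
  for (i in 1:20) {
    cells <- as.character(sample(1:9, 5, replace = TRUE))
    rec <- make_participant(cells,
                            part2 = list(none_boxes = c("frying_fat",
                                                        "baking_fat")))
    int <- compute_participant(rec, dm)$intake
    expected <- sum(scheme$multiplier[as.integer(cells)] * dm$lines$portion_g)
    expect_equal(sum(int$foods$grams), expected, tolerance = 1e-12)
    expect_equal(sum(int$lines$grams), expected, tolerance = 1e-12)
  }
})

test_that("nutrient totals are linear in the composition table", {
  fx <- toy_fixture()
  scaled_dir <- tweak_bundle(fx$dir, "composition.csv", function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) x * 3)
    df
  })
  dm3 <- load_data_model(scaled_dir)
  rec <- fx$cohort$records[[1]]
  base <- compute_participant(rec, fx$dm)$intake
  scaled <- compute_participant(rec, dm3)$intake
  nutr <- fx$dm$nutrient_dictionary$nutrient_id
  grp <- fx$dm$group_scheme
  expect_equal(scaled$totals[nutr], 3 * base$totals[nutr])
  expect_equal(scaled$totals[grp], base$totals[grp])
})

test_that("cohort computation preserves order and is permutation-equivariant", {
  fx <- toy_fixture()
  recs <- fx$cohort$records[1:10]
  run <- compute_cohort(recs, fx$dm)
  expect_length(run$intakes, 10L)
  ids <- vapply(run$intakes, `[[`, "", "participant_id")
  expect_equal(ids, vapply(recs, `[[`, "", "participant_id"))

  perm <- c(7, 2, 9, 1, 5, 3, 10, 4, 8, 6)
  run_p <- compute_cohort(recs[perm], fx$dm)
  for (k in seq_along(perm)) {
    expect_equal(run_p$intakes[[k]]$totals, run$intakes[[perm[k]]]$totals)
  }
  expect_true(all(ids %in% run$log$participant_id))
})

test_that("the text-matching toggle changes only participants with non-default part-2 answers", {
  dm <- micro_dm()
  # matched text differing from the default
  matched <- make_participant(c("6", "6", "6", "1", "1"),
                              part2 = list(milk_text = "whole milk",
                                           cereal_texts = "muesli"))
  # text that cannot match (typo) -> default either way
  typod <- make_participant(c("6", "6", "6", "1", "1"),
                            part2 = list(milk_text = "whxle milk",
                                         cereal_texts = "muxsli"))
  for (rec in list(typod)) {
    on_ <- compute_participant(rec, dm, list(text_matching = TRUE))$intake
    off <- compute_participant(rec, dm, list(text_matching = FALSE))$intake
    expect_equal(on_$totals, off$totals)
  }
  on_ <- compute_participant(matched, dm, list(text_matching = TRUE))$intake
  off <- compute_participant(matched, dm, list(text_matching = FALSE))$intake
  expect_false(isTRUE(all.equal(on_$totals, off$totals)))
})
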