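# Minimal stand-ins for intake/record pairs, for exclusion-stage tests.
fake_intake <- function(id, ei_kj, missing = 0L) {
  structure(list(participant_id = id,
                 totals = c(energy_kj = ei_kj),
                 missing_line_count = as.integer(missing)),
            class = "ffq_intake")
}
fake_record <- function(id, sex = "male", age = 50, weight = 80) {
  structure(list(participant_id = id, sex = sex, age = age,
                 weight = weight), class = "ffq_participant")
}

test_that("Schofield BMR reproduces hand arithmetic from the coefficient table", {
  dm <- micro_dm()
  expect_equal(schofield_bmr("female", 45, 65, dm$schofield),
               0.034 * 65 + 3.538)  # 5.748 MJ/day
  expect_equal(schofield_bmr("male", 70, 80, dm$schofield),
               0.049 * 80 + 2.459)  # 6.379 MJ/day
  expect_error(schofield_bmr("male", 70, 0, dm$schofield), "weight")
  expect_error(schofield_bmr("male", 15, 80, dm$schofield), "age band")
  expect_error(schofield_bmr("female", NA, 60, dm$schofield), "age")
})

test_that("the missing-line threshold is a sharp >= boundary", {
  expect_true(flag_missing_lines(fake_intake("x", 0, missing = 10)))
  expect_false(flag_missing_lines(fake_intake("x", 0, missing = 9)))
  expect_false(flag_missing_lines(fake_intake("x", 0, missing = 0)))
  expect_true(flag_missing_lines(fake_intake("x", 0, missing = 130)))
  expect_true(flag_missing_lines(fake_intake("x", 0, missing = 3),
                                 threshold = 3L))
})

tail_oracle <- function(energies, tail) {
  n <- nrow(energies)
  k <- floor(tail * n)
  if (k == 0) return(character(0))
  ord <- order(energies$ratio, energies$participant_id)
  sorted <- energies[ord, ]
  c(sorted$participant_id[seq_len(k)],
    sorted$participant_id[seq.int(n - k + 1, n)])
}

test_that("ratio tails match a full-sort oracle, including floor semantics and ties", {
  set.seed(5)
  for (n in c(100L, 1000L, 25102L)) {
    e <- data.frame(participant_id = sprintf("P%06d", sample.int(n)),
                    ratio = stats::runif(n, 0.3, 3),
                    stringsAsFactors = FALSE)
    got <- flag_ratio_tails(e, tail = 0.005)
    expect_setequal(got, tail_oracle(e, 0.005))
    expect_length(got, 2L * floor(0.005 * n))
  }
  # n = 100 with 0.5% tails: floor(0.5) = 0 flagged per tail
  e100 <- data.frame(participant_id = sprintf("P%03d", 1:100),
                     ratio = stats::runif(100), stringsAsFactors = FALSE)
  expect_length(flag_ratio_tails(e100, tail = 0.005), 0L)

  # all ratios equal: deterministic by id order
  etie <- data.frame(participant_id = sprintf("P%04d", sample.int(1000)),
                     ratio = 1, stringsAsFactors = FALSE)
  got <- flag_ratio_tails(etie, tail = 0.005)
  expect_length(got, 10L)
  expect_setequal(got, tail_oracle(etie, 0.005))
  expect_identical(got, flag_ratio_tails(etie[sample.int(1000), ],
                                         tail = 0.005))
})

test_that("tail flags are invariant to monotone transforms of the ratio", {
  set.seed(6)
  e <- data.frame(participant_id = sprintf("P%04d", 1:1000),
                  ratio = stats::rlnorm(1000), stringsAsFactors = FALSE)
  base <- flag_ratio_tails(e, tail = 0.01)
  e2 <- e; e2$ratio <- exp(e$ratio)
  e3 <- e; e3$ratio <- rank(e$ratio, ties.method = "first")
  expect_setequal(flag_ratio_tails(e2, tail = 0.01), base)
  expect_setequal(flag_ratio_tails(e3, tail = 0.01), base)
})

test_that("stages apply in order with exact accounting", {
  dm <- micro_dm()
  set.seed(7)
  n <- 200L
  ids <- sprintf("P%04d", 1:n)
  missing <- integer(n)
  missing[sample.int(n, 12L)] <- sample(10:20, 12L, replace = TRUE)
  ei <- stats::runif(n, 4000, 14000)
  intakes <- Map(fake_intake, ids, ei, missing)
  records <- lapply(ids, fake_record)

  rep <- apply_exclusions(intakes, records, dm,
                          config = list(tail_fraction = 0.05))
  expect_length(rep$stage1_missing_lines, 12L)
  expect_length(rep$stage2_ei_bmr, 2L * floor(0.05 * 188))
  expect_length(intersect(rep$stage1_missing_lines, rep$stage2_ei_bmr), 0L)

  # staged oracle: tails computed on the post-stage-1 set only
  keep <- !(ids %in% rep$stage1_missing_lines)
  bmr <- 0.048 * 80 + 3.653
  e <- data.frame(participant_id = ids[keep],
                  ratio = (ei[keep] / 1000) / bmr, stringsAsFactors = FALSE)
  expect_setequal(rep$stage2_ei_bmr, tail_oracle(e, 0.05))

  a <- rep$accounting
  expect_equal(unname(a["final_n"]),
               unname(a["returned_n"] - a["stage1_n"] - a["stage2_n"]))
  expect_length(rep$remaining, a[["final_n"]])
})

test_that("participants lacking weight or age are BMR-ineligible, flagged, kept", {
  dm <- micro_dm()
  ids <- sprintf("P%03d", 1:20)
  intakes <- Map(fake_intake, ids, stats::runif(20, 5000, 12000))
  records <- lapply(ids, fake_record)
  records[[3]]$weight <- NA_real_
  records[[8]]$age <- NA_real_
  rep <- apply_exclusions(intakes, records, dm,
                          config = list(tail_fraction = 0.2))
  expect_setequal(rep$ineligible_bmr, c("P003", "P008"))
  expect_false(any(c("P003", "P008") %in% rep$stage2_ei_bmr))
  expect_true(all(c("P003", "P008") %in% rep$remaining))
  # tails drawn from the 18 eligible: floor(0.2*18)=3 per tail
  expect_length(rep$stage2_ei_bmr, 6L)
})

test_that("no exclusions leaves everyone, and the report serialises", {
  dm <- micro_dm()
  ids <- sprintf("P%03d", 1:50)
  intakes <- Map(fake_intake, ids, stats::runif(50, 5000, 12000))
  records <- lapply(ids, fake_record)
  rep <- apply_exclusions(intakes, records, dm)  # floor(0.005*50)=0
  expect_setequal(rep$remaining, ids)
  expect_equal(unname(rep$accounting["final_n"]), 50)

  path <- tempfile(fileext = ".csv")
  write_exclusions(rep, intakes, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 0L)
})
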