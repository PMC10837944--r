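# Reference verification: membership, chi-square, fallback re-mining.

test_that("membership confirmation is order-insensitive", {
  ref <- reference_pairs("eicu", data.frame(code_a = c("I10", "E78"),
                                            code_b = c("N17", "AKI")))
  pairs <- data.frame(item_a = c("N17", "AKI", "AKI"),
                      item_b = c("I10", "E78", "K21"))
  expect_equal(confirm_by_membership(pairs, ref), c(TRUE, TRUE, FALSE))
  empty <- reference_pairs("none", data.frame(code_a = character(),
                                              code_b = character()))
  expect_equal(confirm_by_membership(pairs, empty), c(FALSE, FALSE, FALSE))
})

test_that("confirmation is monotone in the reference set", {
  pairs <- data.frame(item_a = c("AKI", "AKI"), item_b = c("I10", "E78"))
  small <- reference_pairs("r", data.frame(code_a = "AKI", code_b = "I10"))
  big <- reference_pairs("r", data.frame(code_a = c("AKI", "AKI"),
                                         code_b = c("I10", "E78")))
  expect_true(all(confirm_by_membership(pairs, small) <=
                    confirm_by_membership(pairs, big)))
})

test_that("chi-square matches the closed form and the printed example", {
  r <- chi_square_2x2(30, 20, 10, 40)
  expect_equal(r$statistic, 100 * (30 * 40 - 20 * 10)^2 / (50 * 50 * 40 * 60),
               tolerance = 1e-12)
  expect_equal(r$statistic, 16.667, tolerance = 1e-3)
  expect_lt(r$p_value, 0.05)
  # perfectly proportional table: statistic 0, p = 1
  r0 <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # degenerate margin
  expect_true(is.na(chi_square_2x2(0, 0, 5, 5)$statistic))
  expect_error(chi_square_2x2(-1, 0, 0, 5), ">= 0")
})

test_that("chi-square agrees with stats::chisq.test to 1e-9 relative", {
  set.seed(5)
  for (rep in 1:30) {
    cells <- rpois(4, lambda = sample(5:60, 1)) + 1
    got <- chi_square_2x2(cells[1], cells[2], cells[3], cells[4])
    m <- matrix(cells, 2, byrow = TRUE)
    want <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-9)
    expect_equal(got$p_value, unname(want$p.value), tolerance = 1e-9)
  }
})

test_that("cohd_confirm requires mapping, presence and significance", {
  ref <- cohd_reference(
    concept_map = data.frame(icd10 = c("AKI", "I10", "E78"),
                             concept_id = 1:3),
    cooccurrence = data.frame(code_a = "AKI", code_b = "I10",
                              n_ab = 30, n_a_only = 20, n_b_only = 10,
                              n_neither = 40))
  ok <- cohd_confirm(ref, "AKI", "I10")
  expect_true(ok$mapped && ok$present && ok$confirmed)
  expect_equal(ok$statistic, 16.6667, tolerance = 1e-3)
  # mapped but no counts
  miss <- cohd_confirm(ref, "AKI", "E78")
  expect_true(miss$mapped)
  expect_false(miss$present || miss$confirmed)
  # unmapped code
  expect_false(cohd_confirm(ref, "AKI", "S09")$mapped)
})

# 20-patient fixture for the fallback worked example: S09 fails ID-3
# concept mapping, but patients carry S09.11/S09.31 whose subcategory
# S09.1 is present and significant in the reference counts.
fallback_fixture <- function() {
  n <- 20
  ids <- sprintf("f%02d", 1:n)
  rows <- list()
  for (i in 1:n) {
    codes <- c("I10", "E78")
    if (i <= 10) codes <- c(codes, "S0911", "S0931")  # AKI patients carry S09x
    rows[[i]] <- data.frame(id = ids[i], icd_version = 10L, code = codes)
  }
  list(diagnoses = do.call(rbind, rows),
       labels = data.frame(id = ids, stage = rep(c(1, 0), each = 10)))
}

cohd_s09_reference <- function(map_codes = c("AKI", "I10", "E78", "S091")) {
  cohd_reference(
    concept_map = data.frame(icd10 = map_codes,
                             concept_id = seq_along(map_codes)),
    cooccurrence = data.frame(code_a = "AKI", code_b = "S091",
                              n_ab = 30, n_a_only = 20, n_b_only = 10,
                              n_neither = 40))
}

test_that("the S09 fallback confirms the category through ID-4", {
  fx <- fallback_fixture()
  ref <- cohd_s09_reference()
  v <- fallback_match(c("AKI", "S09"), fx$diagnoses, fx$labels, ref,
                      thresholds = mining_thresholds(0.08, 0, 1))
  expect_true(v$confirmed)
  expect_equal(v$matched_level, "ID4")
  expect_equal(v$statistic, 16.6667, tolerance = 1e-3)
})

test_that("unmapped ID-4 expansions descend to ID-5", {
  fx <- fallback_fixture()
  ref <- cohd_reference(
    concept_map = data.frame(icd10 = c("AKI", "I10", "E78", "S0911"),
                             concept_id = 1:4),
    cooccurrence = data.frame(code_a = "AKI", code_b = "S0911",
                              n_ab = 30, n_a_only = 20, n_b_only = 10,
                              n_neither = 40))
  v <- fallback_match(c("AKI", "S09"), fx$diagnoses, fx$labels, ref,
                      thresholds = mining_thresholds(0.08, 0, 1))
  expect_true(v$confirmed)
  expect_equal(v$matched_level, "ID5")
})

test_that("a partner that maps at ID-3 is never replaced", {
  fx <- fallback_fixture()
  ref <- cohd_reference(
    concept_map = data.frame(icd10 = c("AKI", "S09"), concept_id = 1:2),
    cooccurrence = data.frame(code_a = "AKI", code_b = "S09",
                              n_ab = 30, n_a_only = 20, n_b_only = 10,
                              n_neither = 40))
  v <- fallback_match(c("AKI", "S09"), fx$diagnoses, fx$labels, ref)
  expect_equal(v$matched_level, "ID3")
  expect_true(v$confirmed)
})

test_that("no expansions means verdict none", {
  fx <- fallback_fixture()
  # partner K21 never appears at finer levels in the fixture
  ref <- cohd_s09_reference()
  v <- fallback_match(c("AKI", "K21"), fx$diagnoses, fx$labels, ref)
  expect_false(v$confirmed)
  expect_equal(v$matched_level, "none")
})

test_that("validate_pairs combines sources; any source confirms", {
  fx <- fallback_fixture()
  pairs <- data.frame(item_a = "AKI", item_b = c("I10", "E78", "S09"),
                      stringsAsFactors = FALSE)
  eicu <- reference_pairs("eicu", data.frame(code_a = "AKI", code_b = "E78"))
  ref <- cohd_s09_reference()
  v <- validate_pairs(pairs, eicu = eicu, cohd = ref, cohort = fx$diagnoses,
                      labels = fx$labels,
                      thresholds = mining_thresholds(0.08, 0, 1),
                      literature = data.frame(code = "I10", confirmed = TRUE))
  expect_equal(v$final, c("confirmed", "confirmed", "confirmed"))
  expect_equal(v$eicu, c(FALSE, TRUE, FALSE))
  expect_equal(v$cohd, c(FALSE, FALSE, TRUE))
  expect_equal(v$literature[1], TRUE)
  expect_equal(v$matched_level, c("none", "none", "ID4"))
})

test_that("consistency table margins sum to the pair count", {
  v <- data.frame(eicu = c(TRUE, TRUE, FALSE),
                  cohd = c(TRUE, FALSE, FALSE),
                  literature = c(FALSE, FALSE, TRUE))
  ct <- consistency_table(v)
  expect_equal(as.vector(ct$table), c(1, 0, 1, 1))  # column-major: TT, FT, TF, FF
  expect_equal(sum(ct$table), 3)
  expect_equal(ct$residual, c(literature = 1L, unconfirmed = 0L))
  # empty input
  ct0 <- consistency_table(data.frame(eicu = logical(), cohd = logical(),
                                      literature = logical()))
  expect_equal(sum(ct0$table), 0)
  expect_equal(ct0$total, 0)
})
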