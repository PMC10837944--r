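# Stage-stratified risk factors and organ-crosstalk scoring.

test_that("organ classification follows the bundled ranges", {
  expect_equal(organ_of(c("I48", "I50", "I25")), rep("heart", 3))
  expect_equal(organ_of("I10"), "other")  # hypertension excluded from heart
  expect_equal(organ_of(c("J96", "J44")), rep("lung", 2))
  expect_equal(organ_of("K72"), "liver")
  expect_equal(organ_of(c("G93", "I63")), rep("brain", 2))
  expect_equal(organ_of("K21"), "gut")
  expect_equal(organ_of("E78"), "other")
})

test_that("overlapping organ ranges are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("range_start,range_end,organ", "I05,I52,heart", "I40,I60,lung"),
             path)
  expect_error(organ_classes(path), "overlap")
})

test_that("the hand-computed heart score is 0.10", {
  pairs <- data.frame(item_a = "AKI", item_b = c("I48", "I50"),
                      sup = c(0.12, 0.10), kulc = c(0.5, 0.4))
  rep <- crosstalk_scores(pairs)
  expect_equal(rep$scores$score[rep$scores$organ == "heart"], 0.10,
               tolerance = 1e-12)
  # no liver pairs: score 0
  expect_equal(rep$scores$score[rep$scores$organ == "liver"], 0)
})

test_that("scores are order-invariant, additive, and ignore zero-weight pairs", {
  set.seed(4)
  partners <- c("I48", "I50", "J96", "J44", "K72", "K21", "E78")
  pairs <- data.frame(item_a = "AKI", item_b = partners,
                      sup = runif(7, .05, .3), kulc = runif(7, .1, .6))
  s1 <- crosstalk_scores(pairs)$scores
  s2 <- crosstalk_scores(pairs[sample(7), ])$scores
  expect_equal(s1, s2)
  # splitting the heart pairs into two disjoint pseudo-classes preserves sums
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("range_start,range_end,organ",
               "I48,I48,heartA", "I50,I50,heartB"), path)
  split_scores <- crosstalk_scores(pairs, organ_classes(path))$scores
  expect_equal(sum(split_scores$score[split_scores$organ %in% c("heartA", "heartB")]),
               s1$score[s1$organ == "heart"], tolerance = 1e-12)
  # zero-weight pair changes no score (it does count as a pair)
  pairs0 <- rbind(pairs, data.frame(item_a = "AKI", item_b = "I49",
                                    sup = 0.1, kulc = 0))
  s0 <- crosstalk_scores(pairs0)$scores
  expect_equal(s0$score[match(s1$organ, s0$organ)], s1$score)
})

test_that("top-3 contributing pairs are ranked by sup*kulc", {
  pairs <- data.frame(item_a = "AKI", item_b = c("I48", "I50", "I25", "I42"),
                      sup = c(.3, .2, .1, .05), kulc = c(.5, .5, .5, .5))
  tp <- crosstalk_scores(pairs)$top_pairs$heart
  expect_equal(nrow(tp), 3)
  expect_equal(tp$item_b, c("I48", "I50", "I25"))
})

test_that("stage-specific mining isolates stage-bound associations", {
  # stage-3 patients systematically carry E10; stages 1-2 do not
  set.seed(9)
  n <- 400
  ids <- sprintf("s%03d", 1:n)
  stage <- rep(c(0, 1, 2, 3), each = 100)
  rows <- list()
  for (i in 1:n) {
    codes <- sample(c("K21", "B18", "F10"), 2)
    # shared AKI associations: enriched in every AKI stage over stage 0
    p_shared <- if (stage[i] > 0) 0.9 else 0.4
    if (runif(1) < p_shared) codes <- c(codes, "I10")
    if (runif(1) < p_shared) codes <- c(codes, "E78")
    if (stage[i] == 3 && runif(1) < 0.9) codes <- c(codes, "E10")
    if (stage[i] != 3 && runif(1) < 0.02) codes <- c(codes, "E10")
    rows[[i]] <- data.frame(id = ids[i], icd_version = 10L, code = codes)
  }
  cohort <- do.call(rbind, rows)
  labels <- data.frame(id = ids, stage = stage)
  th <- mining_thresholds(0.02, 0, 1)
  lists <- stage_specific_pairs(cohort, labels, thresholds = th)
  expect_true("E10" %in% lists$stage3$partner)
  expect_false("E10" %in% lists$stage1$partner)
  expect_false("E10" %in% lists$stage2$partner)
  expect_equal(severe_risk_factors(lists), "E10")
  # shared associations appear in every stage list
  expect_true(all(c("I10", "E78") %in% lists$stage1$partner))
  expect_true(all(c("I10", "E78") %in% lists$stage3$partner))
})

test_that("severe_risk_factors is a plain set difference", {
  mk <- function(p) data.frame(item_a = "AKI", item_b = p)
  lists <- list(stage1 = mk(c("A01", "B01")), stage2 = mk(c("B01", "C01")),
                stage3 = mk(c("C01", "D01")))
  expect_equal(severe_risk_factors(lists), "D01")
  same <- list(stage1 = mk("A01"), stage2 = mk("A01"), stage3 = mk("A01"))
  expect_equal(severe_risk_factors(same), character(0))
  # a stage with no patients yields an empty list and a warning
  cohort <- data.frame(id = c("a", "b"), icd_version = 10L,
                       code = c("I10", "I10"))
  cohort <- rbind(cohort, data.frame(id = c("a", "b"), icd_version = 10L,
                                     code = c("E78", "E78")))
  labels <- data.frame(id = c("a", "b"), stage = c(1, 0))
  w <- capture_warnings(l2 <- stage_specific_pairs(
    cohort, labels, thresholds = mining_thresholds(0, 0, 0)))
  expect_true(any(grepl("stage-2", w)))
  expect_equal(nrow(l2$stage2), 0)
})

test_that("shared planted pairs surface in all stage lists", {
  cfg <- sim_config(1200, seed = 31, stage_mix = c(0.4, 0.2, 0.2, 0.2),
                    code_catalog = default_code_catalog(30, c(0.15, 0.3)),
                    horizon = 36,
                    planted_pairs = data.frame(item_a = "AKI", item_b = "A10",
                                               lift = 1.5))
  b <- generate_cohort(cfg)
  # truth labels stand in for stage_cohort output (exact recovery is
  # asserted in the staging tests)
  lists <- stage_specific_pairs(b, b$truth_labels,
                                thresholds = mining_thresholds(0.02, 0, 1))
  for (s in names(lists)) expect_true("A10" %in% lists[[s]]$partner)
})
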