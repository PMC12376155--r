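test_that("summary percentages behave on degenerate tables", {
  ident <- confusion_table3(diag(c(40L, 40L, 40L)))
  s <- table_summaries(ident)
  expect_identical(s$overall_accuracy, 100)
  expect_identical(unname(s$recall), c(100, 100, 100))
  expect_identical(unname(s$precision), c(100, 100, 100))

  # an empty row/column is undefined, not zero
  m <- matrix(c(10L, 0L, 0L, 0L, 0L, 0L, 5L, 0L, 10L), 3L, 3L, byrow = TRUE)
  s2 <- table_summaries(confusion_table3(m))
  expect_true(is.na(s2$recall[["B"]]))
  expect_true(is.na(s2$precision[["B"]]))
  expect_error(table_summaries(confusion_table3(matrix(0L, 3, 3))), "empty")
})

test_that("reported percentages round half away from zero to one decimal", {
  # 55.049...% and 92.501...% style boundaries via explicit counts
  tab <- confusion_table3(matrix(c(1L, 0L, 0L, 0L, 1L, 1L, 0L, 0L, 5L),
                                 3L, 3L, byrow = TRUE))
  s <- table_summaries(tab)
  expect_identical(s$recall[["B"]], 50)
  expect_identical(iira:::round_half_away(0.05, 1), 0.1)
  expect_identical(iira:::round_half_away(89.25, 1), 89.3)
  expect_identical(iira:::round_half_away(-0.05, 1), -0.1)
})

test_that("self-comparison puts all confusion mass on the diagonal", {
  cohort <- generate_cohort(cohort_config(n = 80, seed = 3))
  tab <- confusion_grouping(cohort, "full")
  expect_identical(sum(tab), 80L)
  expect_identical(sum(diag(unclass(tab))), 80L)
  err <- completeness_error_by_nli(cohort, "full")
  expect_true(all(err$error_pct == 0))
})

test_that("a true B case with absent S1 lands in the (B, A) cell", {
  b <- pivot_exam(level_ord("T4"), motor_grades = c(rep(5L, 5L), rep(0L, 5L)))
  b$lt["S4_5", ] <- 1L
  tab <- confusion_grouping(list(b), "s1sub")
  expect_identical(unclass(tab)["B", "A"], 1L)
  expect_identical(sum(tab), 1L)
})

test_that("confusion tables are additive under cohort concatenation", {
  a <- generate_cohort(cohort_config(n = 60, seed = 4))
  b <- generate_cohort(cohort_config(n = 60, seed = 5))
  ta <- unclass(confusion_grouping(a, "s1sub"))
  tb <- unclass(confusion_grouping(b, "s1sub"))
  tab <- unclass(confusion_grouping(c(a, b), "s1sub"))
  expect_identical(tab, ta + tb)
})

test_that("completeness error by NLI matches a per-case recount and flags the stratum", {
  cohort <- generate_cohort(cohort_config(n = 200, seed = 6))
  err <- completeness_error_by_nli(cohort, "s1sub")
  truth <- lapply(cohort, classify)
  nli <- vapply(truth, `[[`, character(1), "nli")
  expect_setequal(err$nli, unique(nli))  # absent levels absent, not 0%
  for (i in seq_len(nrow(err))) {
    idx <- which(nli == err$nli[i])
    wrong <- vapply(idx, function(j) {
      (ais_grouping_with_s1(cohort[[j]]) == "A") != truth[[j]]$complete
    }, logical(1))
    expect_identical(err$error_pct[i],
                     iira:::round_half_away(100 * mean(wrong)))
    expect_identical(err$n[i], length(idx))
  }
  expect_identical(err$t10_or_rostral,
                   level_ord(err$nli) <= level_ord("T10"))

  # forced misclassification: every case B-by-S4-5 with S1 absent
  forced <- lapply(1:5, function(i) {
    e <- pivot_exam(level_ord("T12"),
                    motor_grades = c(rep(5L, 5L), rep(0L, 5L)),
                    case_id = paste0("f", i))
    e$lt["S4_5", ] <- 1L
    e
  })
  err_f <- completeness_error_by_nli(forced, "s1sub")
  expect_identical(err_f$nli, "T12")
  expect_identical(err_f$error_pct, 100)
})

test_that("upper-extremity weakness frequencies match a direct recount", {
  normal_arms <- generate_cohort(cohort_config(
    n = 60, seed = 14, nli_mixture = c(cervical = 0, thoracic = 1,
                                       lumbosacral = 0)))
  ue <- ue_weakness_by_sensory_level(normal_arms)
  expect_true(all(ue$weakness_pct == 0))

  # every T2-sensory-level case with one weak hand muscle
  weak <- lapply(1:4, function(i) {
    e <- pivot_exam(level_ord("T2"), motor_grades = rep(5L, 10L),
                    case_id = paste0("w", i))
    e$motor["C8", "R"] <- 4L
    e
  })
  ue_w <- ue_weakness_by_sensory_level(weak)
  expect_identical(ue_w$sensory_level, "T2")
  expect_identical(ue_w$weakness_pct, 100)
  expect_identical(ue_w$n, 4L)

  # mixed cohort against brute force
  mixed <- generate_cohort(cohort_config(n = 150, seed = 15))
  got <- ue_weakness_by_sensory_level(mixed)
  lvl <- vapply(mixed, function(e) {
    ord_level(min(level_ord(c(sensory_level(e, "R"), sensory_level(e, "L")))))
  }, character(1))
  arm_weak <- vapply(mixed, function(e) {
    any(e$motor[c("C5", "C6", "C7", "C8", "T1"), ] < 5L)
  }, logical(1))
  for (i in seq_len(nrow(got))) {
    idx <- lvl == got$sensory_level[i] &
      level_ord(lvl) >= level_ord("T2")
    expect_identical(got$weakness_pct[i],
                     iira:::round_half_away(100 * mean(arm_weak[idx])))
  }
})

test_that("item-count statistics use the sample standard deviation", {
  mock <- function(total, anorectal_omitted, nli, ais) {
    list(counts = c(motor = 20L, sensory = total - 22L, anorectal = 2L,
                    total = total),
         anorectal_omitted = anorectal_omitted,
         classification = list(nli = nli, ais = ais))
  }
  one <- item_count_summary(list(mock(46L, FALSE, "C4", "A")))
  expect_identical(one$overall$mean_items, 46)
  expect_true(is.na(one$overall$sd_items))
  expect_equal(one$overall$fraction_of_full, 46 / 134)

  two <- item_count_summary(list(mock(40L, TRUE, "C4", "A"),
                                 mock(44L, FALSE, "T6", "B")))
  expect_identical(two$overall$mean_items, 42)
  expect_equal(two$overall$sd_items, sqrt(8), tolerance = 1e-12)
  expect_identical(two$overall$anorectal_omitted_pct, 50)
  expect_identical(two$by_band$group, c("cervical", "thoracic"))
  expect_error(item_count_summary(list()), "no results")
})
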