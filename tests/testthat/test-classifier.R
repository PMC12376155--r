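test_that("sensory level is the most caudal dermatome normal with normal rostrum", {
  e <- normal_exam()
  expect_identical(sensory_level(e, "R"), "INT")

  e2 <- normal_exam()
  e2$lt["C7", "R"] <- 1L
  expect_identical(sensory_level(e2, "R"), "C6")
  expect_identical(sensory_level(e2, "L"), "INT")

  e3 <- normal_exam()
  e3$pp["C2", "L"] <- 0L
  expect_identical(sensory_level(e3, "L"), "C1")
})

test_that("motor level follows key muscles where present, sensation elsewhere", {
  expect_identical(motor_level(normal_exam(), "R"), "INT")

  # C5 = 5, C6 = 3, everything caudal 0: lowest key muscle >= 3 with
  # intact rostrum
  e <- pivot_exam(28L, motor_grades = c(5L, 3L, rep(0L, 8L)),
                  dap = TRUE, vac = TRUE)
  expect_identical(sensory_level(e, "R"), "INT")
  expect_identical(motor_level(e, "R"), "C6")

  # all key muscles 5, sensory level T6: motor follows sensory in the
  # thoracic segments
  e2 <- pivot_exam(level_ord("T6"), motor_grades = rep(5L, 10L))
  expect_identical(sensory_level(e2, "R"), "T6")
  expect_identical(motor_level(e2, "R"), "T6")
})

test_that("sacral sparing reads S4-5 sensation, DAP and VAC", {
  e <- pivot_exam(level_ord("T6"))
  expect_identical(sacral_sparing(e), list(sensory = FALSE, motor = FALSE))

  e$lt["S4_5", "R"] <- 1L
  expect_identical(sacral_sparing(e), list(sensory = TRUE, motor = FALSE))

  e2 <- pivot_exam(level_ord("T6"), vac = TRUE)
  expect_identical(sacral_sparing(e2), list(sensory = FALSE, motor = TRUE))
})

test_that("AIS grades follow the completeness and motor-incomplete rules", {
  # no sacral sparing -> A
  a <- pivot_exam(level_ord("C6"), motor_grades = c(5L, 5L, rep(0L, 8L)))
  cla <- classify(a)
  expect_identical(cla$nli, "C6")
  expect_true(cla$complete)
  expect_identical(cla$ais, "A")

  # S4-5 sensation, no VAC, no qualifying motor sparing -> B
  b <- pivot_exam(level_ord("T4"), motor_grades = c(rep(5L, 5L), rep(0L, 5L)))
  b$lt["S4_5", ] <- 1L
  clb <- classify(b)
  expect_identical(clb$ais, "B")
  expect_false(clb$complete)

  # VAC present, NLI C4, exactly half of the key muscles below the NLI
  # at grade >= 3 -> D (verified by explicit recount)
  d <- pivot_exam(level_ord("C4"),
                  motor_grades = c(3L, 3L, 3L, 4L, 5L, rep(0L, 5L)),
                  vac = TRUE)
  cld <- classify(d)
  expect_identical(cld$nli, "C4")
  below <- match(key_muscles(), spinal_levels()) > level_ord("C4")
  expect_identical(sum(d$motor[below, ] >= 3L), 10L)
  expect_identical(2L * sum(below), 20L)
  expect_identical(cld$ais, "D")
  # one muscle fewer at >= 3 tips the split to C
  c_ex <- d
  c_ex$motor["C5", "R"] <- 2L
  expect_identical(classify(c_ex)$ais, "C")
})

test_that("a fully normal exam classifies as (INT, E) and E needs every item maximal", {
  cl <- classify(normal_exam())
  expect_identical(cl$nli, "INT")
  expect_identical(cl$ais, "E")
  e <- normal_exam()
  e$dap <- FALSE
  expect_false(classify(e)$ais == "E")
})

test_that("classification agrees with the brute-force oracle on a pivot grid", {
  km_pos <- match(key_muscles(), spinal_levels())
  for (pivot in 0:28) {
    for (caudal in 0:1) {
      for (sacral in list(c(FALSE, FALSE), c(TRUE, FALSE),
                          c(FALSE, TRUE), c(TRUE, TRUE))) {
        graded <- ifelse(km_pos <= pivot, 5L, caudal)
        for (grades in list(rep(0L, 10L), rep(5L, 10L), graded)) {
          e <- pivot_exam(pivot, caudal = caudal, motor_grades = grades,
                          dap = sacral[1], vac = sacral[2])
          got <- classify(e)
          want <- oracle_classify(e)
          lab <- sprintf("pivot=%d caudal=%d", pivot, caudal)
          expect_identical(unname(got$sensory_level), unname(want$sensory_level), label = lab)
          expect_identical(unname(got$motor_level), unname(want$motor_level), label = lab)
          expect_identical(got$nli, want$nli, label = lab)
          expect_identical(got$complete, want$complete, label = lab)
          expect_identical(got$ais, want$ais, label = lab)
        }
      }
    }
  }
})

test_that("classification agrees with the oracle on generated and unstructured exams", {
  cohort <- generate_cohort(cohort_config(n = 150, seed = 2024))
  withr::with_seed(77, extras <- lapply(1:100, function(i) random_exam()))
  for (e in c(cohort, extras)) {
    got <- classify(e)
    want <- oracle_classify(e)
    expect_identical(got$nli, want$nli)
    expect_identical(got$ais, want$ais)
    expect_identical(got$complete, want$complete)
  }
})

test_that("classification is deterministic and worsening sensation never moves the NLI caudally", {
  cohort <- generate_cohort(cohort_config(n = 60, seed = 31))
  withr::with_seed(32, {
    for (e in cohort) {
      base <- classify(e)
      expect_identical(classify(e), base)  # pure function
      for (rep in 1:5) {
        side <- sample(c("R", "L"), 1)
        pos <- sample.int(28L, 1)
        mod <- sample(c("lt", "pp"), 1)
        if (e[[mod]][pos, side] == 0L) next
        worse <- e
        worse[[mod]][pos, side] <- worse[[mod]][pos, side] - 1L
        expect_lte(level_ord(classify(worse)$nli), level_ord(base$nli))
      }
    }
  })
})

test_that("completeness is equivalent to grade A and groupings are consistent", {
  cohort <- generate_cohort(cohort_config(n = 150, seed = 55))
  for (e in cohort) {
    cl <- classify(e)
    expect_identical(cl$complete, cl$ais == "A")
    expect_true(ais_group(cl$ais) %in% c("A", "B", "CD"))
  }
  expect_identical(ais_group(c("A", "B", "C", "D")), c("A", "B", "CD", "CD"))
})
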