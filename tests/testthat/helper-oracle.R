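# Independent brute-force implementation of the classification rules,
# written predicate-first (maximal candidate satisfying an explicit
# predicate) rather than as a sequential walk, to cross-check classify().

DERM <- spinal_levels()
KM <- key_muscles()
KM_POS <- match(KM, DERM)

oracle_sensory_level <- function(exam, side) {
  normal <- exam$lt[, side] == 2L & exam$pp[, side] == 2L
  for (d in 28:0) {
    if (d == 0L || all(normal[seq_len(d)])) {
      return(if (d == 28L) "INT" else ord_level(d))
    }
  }
}

oracle_motor_level <- function(exam, side) {
  sens_normal <- exam$lt[, side] == 2L & exam$pp[, side] == 2L
  grades <- exam$motor[, side]
  intact <- function(pos) {
    k <- match(pos, KM_POS)
    if (!is.na(k)) grades[k] == 5L else sens_normal[pos]
  }
  ok_through <- function(d) {
    if (d == 0L) return(TRUE)
    for (pos in seq_len(d - 1L)) if (!intact(pos)) return(FALSE)
    k <- match(d, KM_POS)
    if (!is.na(k)) grades[k] >= 3L else sens_normal[d]
  }
  for (d in 28:0) {
    if (ok_through(d)) {
      full <- d == 28L && intact(28L)
      return(if (full) "INT" else ord_level(d))
    }
  }
}

oracle_classify <- function(exam) {
  sl <- vapply(c("R", "L"), function(s) oracle_sensory_level(exam, s),
               character(1))
  ml <- vapply(c("R", "L"), function(s) oracle_motor_level(exam, s),
               character(1))
  nli <- ord_level(min(level_ord(c(sl, ml))))
  s45 <- c(exam$lt["S4_5", ], exam$pp["S4_5", ])
  sens_sp <- any(s45 > 0L) || isTRUE(exam$dap)
  mot_sp <- isTRUE(exam$vac)
  complete <- !sens_sp && !mot_sp
  all_norm <- all(exam$lt == 2L) && all(exam$pp == 2L) &&
    all(exam$motor == 5L) && exam$dap && exam$vac
  mi <- mot_sp
  if (!mi && sens_sp) {
    for (s in c("R", "L")) {
      for (k in seq_along(KM)) {
        if (exam$motor[k, s] > 0L &&
            KM_POS[k] - level_ord(ml[[s]]) > 3L) mi <- TRUE
      }
    }
  }
  ais <- if (all_norm) "E" else if (complete) "A" else if (!mi) "B" else {
    below <- which(KM_POS > level_ord(nli))
    n_below <- 2L * length(below)
    strong <- sum(exam$motor[below, ] >= 3L)
    if (n_below == 0L || strong >= n_below / 2) "D" else "C"
  }
  list(sensory_level = sl, motor_level = ml, nli = nli,
       complete = complete, ais = ais)
}

# Random in-range (not clinically structured) exam, for schema round-trips
# and monotone-degradation style properties.
random_exam <- function(case_id = "rnd") {
  mk <- function(n, hi) matrix(sample(0:hi, n * 2L, replace = TRUE), n, 2L,
                               dimnames = list(NULL, c("R", "L")))
  lt <- mk(28L, 2L); pp <- mk(28L, 2L); mot <- mk(10L, 5L)
  rownames(lt) <- rownames(pp) <- DERM
  rownames(mot) <- KM
  full_exam(case_id, lt, pp, mot, sample(c(TRUE, FALSE), 1),
            sample(c(TRUE, FALSE), 1))
}

# Exam with both sides identical: normal through `level`, `caudal_score`
# below, a given motor vector, and explicit sacral findings.
pivot_exam <- function(pivot, caudal = 0L, motor_grades = rep(0L, 10L),
                       dap = FALSE, vac = FALSE, case_id = "pivot") {
  s <- matrix(caudal, 28L, 2L, dimnames = list(DERM, c("R", "L")))
  if (pivot > 0L) s[seq_len(pivot), ] <- 2L
  m <- matrix(as.integer(motor_grades), 10L, 2L,
              dimnames = list(KM, c("R", "L")))
  full_exam(case_id, s, s, m, dap, vac)
}
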