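# Full ISNCSCI classification: sensory/motor levels, NLI, sacral sparing,
# completeness and AIS grade.

#' Sensory level for one side
#'
#' The most caudal dermatome with light touch and pinprick both normal
#' (score 2) at that dermatome and at every dermatome rostral to it.
#' `"C1"` when C2 is abnormal in either modality; `"INT"` when sensation
#' is normal through S4-5.
#'
#' @param exam A [full_exam()].
#' @param side `"R"` or `"L"`.
#' @return Level name (possibly `"C1"` or `"INT"`).
#' @export
sensory_level <- function(exam, side = c("R", "L")) {
  side <- match.arg(side)
  abn <- which(exam$lt[, side] != 2L | exam$pp[, side] != 2L)
  if (!length(abn)) return("INT")
  ord_level(abn[1] - 1L)
}

#' Motor level for one side
#'
#' Determined by a rostral-to-caudal walk over the 28-segment ladder. A
#' segment is motor-intact when its key muscle grades 5, or -- in segments
#' without a key muscle (above C5, T2-L1, below S1) -- when its dermatome is
#' normal in both modalities ("motor follows sensory"). The motor level is
#' the most caudal intact segment, with the standard allowance that the
#' lowest key muscle graded 3 or 4 defines the level itself when everything
#' rostral is intact. `"INT"` when the walk reaches S4-5 fully intact.
#'
#' @inheritParams sensory_level
#' @return Level name (possibly `"C1"` or `"INT"`).
#' @export
motor_level <- function(exam, side = c("R", "L")) {
  side <- match.arg(side)
  lt <- exam$lt[, side]; pp <- exam$pp[, side]
  grades <- exam$motor[, side]
  ml <- C1_ORD
  for (pos in seq_along(DERMATOMES)) {
    km <- match(pos, KEY_MUSCLE_POS)
    if (!is.na(km)) {
      g <- grades[km]
      if (g == 5L) { ml <- pos; next }
      if (g >= 3L) ml <- pos         # lowest key muscle >= 3, rostral all intact
      break
    }
    if (lt[pos] == 2L && pp[pos] == 2L) { ml <- pos; next }
    break
  }
  if (ml == length(DERMATOMES)) ml <- INT_ORD  # intact through S4-5
  ord_level(ml)
}

#' Sacral sparing
#'
#' Sensory sparing: any S4-5 sensory score above 0 (either modality, either
#' side) or deep anal pressure present. Motor sparing: voluntary anal
#' contraction present.
#'
#' @inheritParams sensory_level
#' @return List with logical elements `sensory` and `motor`.
#' @export
sacral_sparing <- function(exam) {
  s45 <- c(exam$lt["S4_5", ], exam$pp["S4_5", ])
  list(sensory = any(s45 > 0L) || isTRUE(exam$dap),
       motor = isTRUE(exam$vac))
}

# Motor-incomplete status: VAC present, or sensory sacral sparing plus a key
# muscle with any activity more than three ladder levels below the
# ipsilateral motor level.
is_motor_incomplete <- function(exam, motor_ord, sens_sparing, vac) {
  if (vac) return(TRUE)
  if (!sens_sparing) return(FALSE)
  for (side in SIDES) {
    active <- exam$motor[, side] > 0L
    if (any(active & (KEY_MUSCLE_POS > motor_ord[side] + 3L))) return(TRUE)
  }
  FALSE
}

is_all_normal <- function(exam) {
  all(exam$lt == 2L) && all(exam$pp == 2L) && all(exam$motor == 5L) &&
    isTRUE(exam$dap) && isTRUE(exam$vac)
}

# C vs D split: among key muscle functions strictly below the single NLI
# (both sides pooled), grade D when at least half grade >= 3. When no key
# muscle lies below the NLI the condition is vacuously satisfied (D).
motor_grade_split <- function(exam, nli_ord) {
  below <- KEY_MUSCLE_POS > nli_ord
  n_below <- 2L * sum(below)
  if (n_below == 0L) return("D")
  strong <- sum(exam$motor[below, ] >= 3L)
  if (strong >= n_below / 2) "D" else "C"
}

#' Classify a full examination
#'
#' Computes per-side sensory and motor levels, the neurological level of
#' injury (most rostral of the four), sacral sparing, completeness, and the
#' AIS grade:
#' * `A` -- no sensory or motor sacral sparing (complete);
#' * `B` -- sensory sacral sparing without motor-incomplete status;
#' * `C`/`D` -- motor incomplete (VAC present, or sensory sparing plus key
#'   muscle activity more than three levels below the ipsilateral motor
#'   level); `D` when at least half of the key muscle functions below the
#'   NLI (both sides pooled) grade 3 or better, else `C`;
#' * `E` -- the entire examination is normal.
#'
#' A pure function: identical input always yields identical output.
#'
#' @param exam A [full_exam()].
#' @return An `isncsci_classification` list with elements `case_id`,
#'   `sensory_level` (named `R`/`L`), `motor_level`, `nli`,
#'   `sensory_sacral_sparing`, `motor_sacral_sparing`, `complete`, `ais`.
#' @export
classify <- function(exam) {
  sl <- c(R = sensory_level(exam, "R"), L = sensory_level(exam, "L"))
  ml <- c(R = motor_level(exam, "R"), L = motor_level(exam, "L"))
  ml_ord <- level_ord(ml); names(ml_ord) <- SIDES
  nli_ord <- min(level_ord(sl), ml_ord)
  ss <- sacral_sparing(exam)
  complete <- !ss$sensory && !ss$motor
  ais <- if (is_all_normal(exam)) {
    "E"
  } else if (complete) {
    "A"
  } else if (!is_motor_incomplete(exam, ml_ord, ss$sensory, isTRUE(exam$vac))) {
    "B"
  } else {
    motor_grade_split(exam, nli_ord)
  }
  structure(
    list(case_id = exam$case_id, sensory_level = sl, motor_level = ml,
         nli = ord_level(nli_ord), sensory_sacral_sparing = ss$sensory,
         motor_sacral_sparing = ss$motor, complete = complete, ais = ais),
    class = "isncsci_classification"
  )
}

#' @export
print.isncsci_classification <- function(x, ...) {
  cat(sprintf(
    "<isncsci_classification> %s\n  sensory R/L: %s/%s  motor R/L: %s/%s\n  NLI: %s  complete: %s  AIS: %s\n",
    x$case_id, x$sensory_level["R"], x$sensory_level["L"],
    x$motor_level["R"], x$motor_level["L"], x$nli, x$complete, x$ais))
  invisible(x)
}

#' Merge AIS grades into the three-way grouping
#'
#' Grades `C` and `D` are merged into `"CD"`; `A` and `B` map to themselves.
#' The normal grade `E` (never produced for generated cohorts) is treated as
#' incomplete and mapped to `"CD"`.
#'
#' @param ais Character vector of AIS grades.
#' @return Character vector over `"A"`, `"B"`, `"CD"`.
#' @export
ais_group <- function(ais) {
  stopifnot(all(ais %in% c("A", "B", "C", "D", "E")))
  ifelse(ais %in% c("A", "B"), ais, "CD")
}

#' Classify every exam in a cohort
#'
#' @param exams List of [full_exam()] objects.
#' @return Data frame with one row per case: levels, NLI, completeness, AIS.
#' @export
classify_cohort <- function(exams) {
  rows <- lapply(exams, function(e) {
    cl <- classify(e)
    data.frame(case_id = cl$case_id,
               sensory_level_r = cl$sensory_level[["R"]],
               sensory_level_l = cl$sensory_level[["L"]],
               motor_level_r = cl$motor_level[["R"]],
               motor_level_l = cl$motor_level[["L"]],
               nli = cl$nli, complete = cl$complete, ais = cl$ais,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
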