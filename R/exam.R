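# Full examination records and their validation.

new_full_exam <- function(case_id, lt, pp, motor, dap, vac) {
  structure(
    list(case_id = case_id, lt = lt, pp = pp, motor = motor,
         dap = dap, vac = vac),
    class = "full_exam"
  )
}

empty_sensory_matrix <- function() {
  matrix(NA_integer_, nrow = length(DERMATOMES), ncol = 2L,
         dimnames = list(DERMATOMES, SIDES))
}

empty_motor_matrix <- function() {
  matrix(NA_integer_, nrow = length(KEY_MUSCLES), ncol = 2L,
         dimnames = list(KEY_MUSCLES, SIDES))
}

#' Construct a full ISNCSCI examination record
#'
#' A valid record scores all 134 items: light touch and pinprick at the 28
#' dermatomes on both sides (0 = absent, 1 = impaired, 2 = normal), the ten
#' key muscles on both sides (0-5), and the two binary anorectal findings,
#' deep anal pressure (DAP) and voluntary anal contraction (VAC). "Not
#' testable" scores are not representable; exams containing them must be
#' excluded upstream.
#'
#' @param case_id Opaque case identifier.
#' @param lt,pp 28 x 2 integer matrices of sensory scores, rows in the order
#'   of [spinal_levels()], columns `R`, `L`.
#' @param motor 10 x 2 integer matrix of key muscle grades, rows in the order
#'   of [key_muscles()].
#' @param dap,vac Logical anorectal findings.
#' @return A `full_exam` object.
#' @export
full_exam <- function(case_id, lt, pp, motor, dap, vac) {
  exam <- new_full_exam(as.character(case_id)[1],
                        coerce_score_matrix(lt, empty_sensory_matrix()),
                        coerce_score_matrix(pp, empty_sensory_matrix()),
                        coerce_score_matrix(motor, empty_motor_matrix()),
                        as.logical(dap)[1], as.logical(vac)[1])
  problems <- exam_problems(exam)
  if (nrow(problems) > 0L) {
    stop("invalid full_exam (", nrow(problems), " problem(s)); first: ",
         problems$problem[1])
  }
  exam
}

coerce_score_matrix <- function(x, template) {
  if (is.matrix(x) && identical(dim(x), dim(template))) {
    storage.mode(x) <- "integer"
    dimnames(x) <- dimnames(template)
    return(x)
  }
  stop("score matrix must be ", nrow(template), " x 2")
}

# One row per violated constraint; empty data frame when the exam is valid.
exam_problems <- function(exam) {
  check_scores <- function(m, levels, label, hi) {
    out <- character(0)
    for (side in SIDES) {
      v <- m[, side]
      missing <- which(is.na(v))
      bad <- which(!is.na(v) & (v < 0L | v > hi))
      if (length(missing)) {
        out <- c(out, sprintf("missing %s at %s-%s", label,
                              levels[missing], side))
      }
      if (length(bad)) {
        out <- c(out, sprintf("out-of-range %s %d at %s-%s (must be 0-%d)",
                              label, v[bad], levels[bad], side, hi))
      }
    }
    out
  }
  probs <- c(
    check_scores(exam$lt, DERMATOMES, "LT score", 2L),
    check_scores(exam$pp, DERMATOMES, "PP score", 2L),
    check_scores(exam$motor, KEY_MUSCLES, "motor grade", 5L)
  )
  if (is.na(exam$dap)) probs <- c(probs, "missing anorectal item DAP")
  if (is.na(exam$vac)) probs <- c(probs, "missing anorectal item VAC")
  if (is.na(exam$case_id) || !nzchar(exam$case_id)) {
    probs <- c(probs, "missing case_id")
  }
  data.frame(problem = probs, stringsAsFactors = FALSE)
}

#' Validate a raw worksheet record
#'
#' Takes one parsed worksheet record -- a named list or vector using the flat
#' CSV column names (see [read_exams()]) -- and either returns a [full_exam()]
#' or, when the record violates the schema, a validation report listing every
#' violation (missing item, out-of-range score, unknown level name). Content
#' errors are reported, not raised; malformed input that cannot be interpreted
#' as a record at all raises an error.
#'
#' @param record Named list or vector of raw values.
#' @return A `full_exam`, or an `exam_validation_report` (a data frame of
#'   problems with the attempted `case_id` as an attribute).
#' @export
validate_exam <- function(record) {
  if (is.null(names(record)) || !length(record)) {
    stop("record must be a named list or vector of worksheet fields")
  }
  record <- as.list(record)
  known <- c("case_id", worksheet_columns())
  unknown <- setdiff(names(record), known)
  probs <- character(0)
  if (length(unknown)) {
    probs <- c(probs, sprintf("unknown field '%s'", unknown))
  }

  get_score <- function(field) {
    raw <- record[[field]]
    if (is.null(raw) || is.na(suppressWarnings(as.integer(raw)))) {
      return(NA_integer_)  # reported as missing by exam_problems()
    }
    as.integer(raw)
  }
  lt <- empty_sensory_matrix(); pp <- empty_sensory_matrix()
  motor <- empty_motor_matrix()
  for (side in SIDES) {
    s <- tolower(side)
    lt[, side] <- vapply(sprintf("lt_%s_%s", s, tolower(DERMATOMES)),
                         get_score, integer(1))
    pp[, side] <- vapply(sprintf("pp_%s_%s", s, tolower(DERMATOMES)),
                         get_score, integer(1))
    motor[, side] <- vapply(sprintf("motor_%s_%s", s, tolower(KEY_MUSCLES)),
                            get_score, integer(1))
  }
  as_flag <- function(field) {
    raw <- record[[field]]
    if (is.null(raw) || is.na(raw)) return(NA)
    if (is.logical(raw)) return(raw)
    v <- suppressWarnings(as.integer(raw))
    if (is.na(v) || !v %in% c(0L, 1L)) return(NA)
    v == 1L
  }
  case_id <- if (is.null(record$case_id)) NA_character_ else
    as.character(record$case_id)
  exam <- new_full_exam(case_id, lt, pp, motor, as_flag("dap"), as_flag("vac"))
  probs <- c(probs, exam_problems(exam)$problem)
  if (length(probs)) {
    structure(data.frame(problem = probs, stringsAsFactors = FALSE),
              case_id = case_id,
              class = c("exam_validation_report", "data.frame"))
  } else {
    exam
  }
}

#' @export
print.exam_validation_report <- function(x, ...) {
  cat("Invalid exam record", if (!is.na(attr(x, "case_id")))
    paste0("(case_id ", attr(x, "case_id"), ")"), "--",
    nrow(x), "problem(s):\n")
  cat(paste0("  - ", x$problem), sep = "\n")
  invisible(x)
}

#' @export
print.full_exam <- function(x, ...) {
  cat("<full_exam>", x$case_id, "\n")
  cat("  sensory (LT/PP) 28 dermatomes x R/L, motor 10 key muscles x R/L\n")
  cat("  DAP:", x$dap, " VAC:", x$vac, "\n")
  invisible(x)
}

is_full_exam <- function(x) inherits(x, "full_exam")

# A fully normal exam: every sensory score 2, every motor grade 5, DAP and
# VAC present. Useful as a construction baseline.
#' Fully normal examination
#'
#' Convenience constructor for an exam with every sensory score 2, every
#' key muscle grade 5, and both anorectal findings present.
#'
#' @param case_id Case identifier.
#' @return A `full_exam`.
#' @export
normal_exam <- function(case_id = "normal") {
  s <- empty_sensory_matrix(); s[] <- 2L
  m <- empty_motor_matrix(); m[] <- 5L
  new_full_exam(case_id, s, s, m, TRUE, TRUE)
}
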