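# Worksheet input/output: flat CSV (one row per case) and nested JSON.

#' Worksheet CSV column names
#'
#' Fixed column order of the flat worksheet schema: `case_id`, then
#' `lt_r_<level>` for the 28 dermatomes rostral to caudal, `lt_l_<level>`,
#' `pp_r_<level>`, `pp_l_<level>`, `motor_r_<muscle>`, `motor_l_<muscle>`,
#' `dap`, `vac`. Level tokens are lowercase; the S4-5 row is `s4_5`.
#'
#' @return Character vector of the 134 score columns (without `case_id`).
#' @export
worksheet_columns <- function() {
  lv <- tolower(DERMATOMES)
  km <- tolower(KEY_MUSCLES)
  c(paste0("lt_r_", lv), paste0("lt_l_", lv),
    paste0("pp_r_", lv), paste0("pp_l_", lv),
    paste0("motor_r_", km), paste0("motor_l_", km),
    "dap", "vac")
}

exam_to_row <- function(exam) {
  vals <- c(
    exam$lt[, "R"], exam$lt[, "L"],
    exam$pp[, "R"], exam$pp[, "L"],
    exam$motor[, "R"], exam$motor[, "L"],
    as.integer(exam$dap), as.integer(exam$vac)
  )
  names(vals) <- worksheet_columns()
  c(list(case_id = exam$case_id), as.list(vals))
}

#' Read full examinations from a worksheet file
#'
#' Reads a CSV or JSON worksheet (see [worksheet_columns()] for the CSV
#' schema; the JSON schema is an array of objects
#' `{case_id, lt:{r:{...}, l:{...}}, pp:{...}, motor:{...}, dap, vac}`).
#' Every record is validated; if any record is invalid the whole read fails
#' with an error citing the offending row numbers and problems -- invalid
#' rows are never silently dropped. Duplicate `case_id`s within one file are
#' rejected.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @return List of [full_exam()] objects, in file order.
#' @export
read_exams <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  records <- if (format == "csv") read_worksheet_csv(path) else
    read_worksheet_json(path)
  exams <- vector("list", length(records))
  failures <- character(0)
  for (i in seq_along(records)) {
    res <- validate_exam(records[[i]])
    if (inherits(res, "exam_validation_report")) {
      failures <- c(failures, sprintf(
        "row %d: %s", i, paste(res$problem, collapse = "; ")))
    } else {
      exams[[i]] <- res
    }
  }
  if (length(failures)) {
    stop("invalid exam record(s) in ", path, ":\n",
         paste0("  ", failures, collapse = "\n"))
  }
  ids <- vapply(exams, function(e) e$case_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate case_id within ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  exams
}

read_worksheet_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  expected <- c("case_id", worksheet_columns())
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop("worksheet ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

read_worksheet_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw)) stop("JSON worksheet must be an array of exam objects")
  lapply(raw, function(obj) {
    rec <- list(case_id = obj$case_id)
    for (side in c("r", "l")) {
      for (block in c("lt", "pp")) {
        for (lv in tolower(DERMATOMES)) {
          rec[[sprintf("%s_%s_%s", block, side, lv)]] <- obj[[block]][[side]][[lv]]
        }
      }
      for (km in tolower(KEY_MUSCLES)) {
        rec[[sprintf("motor_%s_%s", side, km)]] <- obj$motor[[side]][[km]]
      }
    }
    rec$dap <- obj$dap
    rec$vac <- obj$vac
    rec
  })
}

#' Write full examinations to a worksheet file
#'
#' Inverse of [read_exams()]: writing then reading reproduces the scores
#' exactly, preserving row order.
#'
#' @param exams List of [full_exam()] objects.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @export
write_exams <- function(exams, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  stopifnot(all(vapply(exams, is_full_exam, logical(1))))
  if (format == "csv") {
    rows <- lapply(exams, function(e) as.data.frame(exam_to_row(e)))
    df <- if (length(rows)) do.call(rbind, rows) else
      stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 135)),
                      c("case_id", worksheet_columns()))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    objs <- lapply(exams, function(e) {
      side_list <- function(m, levels) {
        lapply(stats::setNames(SIDES, c("r", "l")), function(s) {
          as.list(stats::setNames(unname(m[, s]), tolower(levels)))
        })
      }
      list(case_id = e$case_id,
           lt = side_list(e$lt, DERMATOMES),
           pp = side_list(e$pp, DERMATOMES),
           motor = side_list(e$motor, KEY_MUSCLES),
           dap = as.integer(e$dap), vac = as.integer(e$vac))
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE)
  }
  invisible(path)
}
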