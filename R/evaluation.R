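# Accuracy analyses: AIS-grouping confusion tables and summaries,
# completeness error by NLI, upper-extremity weakness frequencies, and
# item-count statistics for item-reduced runs.

AIS_GROUPS <- c("A", "B", "CD")

# Percentages are reported to one decimal, rounding half away from zero
# (base round() rounds half to even).
round_half_away <- function(x, digits = 1L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

determined_grouping <- function(exam, method) {
  switch(method,
    full = ais_group(classify(exam)$ais),
    s1sub = ais_grouping_with_s1(exam),
    iira = ais_group(run_iira(exam)$classification$ais)
  )
}

#' Confusion table of AIS groupings
#'
#' Truth is the grouping of the full classification engine; the determined
#' grouping comes from the named method: `"full"` (self-comparison),
#' `"s1sub"` (S1 substitution), or `"iira"` (item-reduced run).
#'
#' @param cohort List of [full_exam()] objects.
#' @param method One of `"full"`, `"s1sub"`, `"iira"`.
#' @return A 3 x 3 integer matrix of class `confusion_table3`, rows = true
#'   grouping, columns = determined grouping, over `A`, `B`, `CD`.
#' @export
confusion_grouping <- function(cohort, method = c("full", "s1sub", "iira")) {
  method <- match.arg(method)
  truth <- vapply(cohort, function(e) ais_group(classify(e)$ais), character(1))
  det <- vapply(cohort, determined_grouping, character(1), method = method)
  tab <- table(factor(truth, AIS_GROUPS), factor(det, AIS_GROUPS))
  out <- matrix(as.integer(tab), 3L, 3L,
                dimnames = list(true = AIS_GROUPS, determined = AIS_GROUPS))
  structure(out, class = c("confusion_table3", "matrix"))
}

#' Confusion table from counts
#'
#' Wraps a plain 3 x 3 count matrix (rows true A/B/CD, columns determined)
#' as a `confusion_table3`, e.g. to analyze published tables.
#'
#' @param counts 3 x 3 non-negative matrix.
#' @return A `confusion_table3`.
#' @export
confusion_table3 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(3L, 3L)), all(counts >= 0))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(true = AIS_GROUPS, determined = AIS_GROUPS)
  structure(counts, class = c("confusion_table3", "matrix"))
}

#' Accuracy summaries of a 3 x 3 confusion table
#'
#' Overall accuracy is the diagonal fraction; recall of a grouping is the
#' diagonal cell over its row sum (correct among true), precision over its
#' column sum (true among determined); cell fractions are each cell over
#' the total. All values are percentages rounded to one decimal, half away
#' from zero. Groupings with an empty row or column report `NA` (undefined),
#' never 0.
#'
#' @param table A `confusion_table3` (or plain 3 x 3 count matrix).
#' @return List with `total`, `overall_accuracy`, `recall`, `precision`
#'   (named over `A`, `B`, `CD`) and `cell_fraction` (3 x 3 matrix of
#'   percentages).
#' @export
table_summaries <- function(table) {
  m <- unclass(as.matrix(table))
  stopifnot(identical(dim(m), c(3L, 3L)))
  total <- sum(m)
  if (total == 0) stop("confusion table is empty")
  pct <- function(num, den) {
    ifelse(den > 0, round_half_away(100 * num / den), NA_real_)
  }
  diagm <- diag(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  cell <- round_half_away(100 * m / total)
  dimnames(cell) <- list(true = AIS_GROUPS, determined = AIS_GROUPS)
  list(
    total = total,
    overall_accuracy = pct(sum(diagm), total),
    recall = stats::setNames(pct(diagm, rs), AIS_GROUPS),
    precision = stats::setNames(pct(diagm, cs), AIS_GROUPS),
    cell_fraction = cell
  )
}

#' @export
print.confusion_table3 <- function(x, ...) {
  cat("AIS grouping confusion table (rows: true, cols: determined)\n")
  print(unclass(x))
  invisible(x)
}

#' Completeness error rate by neurological level
#'
#' Per true NLI, the percentage of cases whose injury completeness
#' (grade A vs. not A) under the method differs from the full-exam truth.
#' Levels with no cases are absent from the output, not reported as 0%.
#' The `t10_or_rostral` flag marks the stratum (NLI at or rostral to T10)
#' for which the substitution shortcut was originally proposed.
#'
#' @inheritParams confusion_grouping
#' @return Data frame with columns `nli`, `n`, `error_pct`,
#'   `t10_or_rostral`, ordered rostral to caudal.
#' @export
completeness_error_by_nli <- function(cohort,
                                      method = c("full", "s1sub", "iira")) {
  method <- match.arg(method)
  truth <- lapply(cohort, classify)
  nli <- vapply(truth, function(cl) cl$nli, character(1))
  true_complete <- vapply(truth, function(cl) cl$complete, logical(1))
  det_complete <- vapply(seq_along(cohort), function(i) {
    determined_grouping(cohort[[i]], method) == "A"
  }, logical(1))
  err <- det_complete != true_complete
  levels_present <- spinal_levels(sentinels = TRUE)
  levels_present <- levels_present[levels_present %in% nli]
  rows <- lapply(levels_present, function(lv) {
    idx <- nli == lv
    data.frame(nli = lv, n = sum(idx),
               error_pct = round_half_away(100 * mean(err[idx])),
               t10_or_rostral = level_ord(lv) <= level_ord("T10"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Upper-extremity weakness by most rostral sensory level
#'
#' For cases whose most rostral sensory level (over both sides) is T2 or
#' caudal, the percentage with any C5-T1 key muscle graded below 5. If
#' upper-extremity motor testing were omitted for such cases, their NLI
#' would be classified incorrectly.
#'
#' @param cohort List of [full_exam()] objects.
#' @return Data frame with columns `sensory_level`, `n`, `weakness_pct`,
#'   ordered rostral to caudal; levels with no cases are absent.
#' @export
ue_weakness_by_sensory_level <- function(cohort) {
  most_rostral <- vapply(cohort, function(e) {
    ord_level(min(level_ord(sensory_level(e, "R")),
                  level_ord(sensory_level(e, "L"))))
  }, character(1))
  ue <- KEY_MUSCLES %in% c("C5", "C6", "C7", "C8", "T1")
  weak <- vapply(cohort, function(e) any(e$motor[ue, ] < 5L), logical(1))
  keep <- level_ord(most_rostral) >= level_ord("T2")
  levels_present <- spinal_levels(sentinels = TRUE)
  levels_present <- levels_present[levels_present %in% most_rostral[keep]]
  rows <- lapply(levels_present, function(lv) {
    idx <- keep & most_rostral == lv
    data.frame(sensory_level = lv, n = sum(idx),
               weakness_pct = round_half_away(100 * mean(weak[idx])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Item-count statistics for item-reduced runs
#'
#' Descriptive statistics over the total observed-item counts of
#' [run_iira()] results: mean, sample standard deviation (n - 1), fraction
#' of the 134-item full exam, and the percentage of cases for which the
#' anorectal exam was omitted entirely, overall and stratified by NLI band
#' and by AIS grade (both from the item-reduced classification).
#'
#' @param results List of `iira_result` objects.
#' @return List with `overall` (one-row data frame) and `by_band`,
#'   `by_ais` (data frames).
#' @export
item_count_summary <- function(results) {
  if (!length(results)) stop("no results to summarize")
  totals <- vapply(results, function(r) r$counts[["total"]], numeric(1))
  omitted <- vapply(results, function(r) r$anorectal_omitted, logical(1))
  nli <- vapply(results, function(r) r$classification$nli, character(1))
  ais <- vapply(results, function(r) r$classification$ais, character(1))
  band <- cut(level_ord(nli), c(-1, 7.5, 19.5, Inf),
              labels = c("cervical", "thoracic", "lumbosacral"))
  stat_row <- function(idx) {
    data.frame(
      n = sum(idx),
      mean_items = mean(totals[idx]),
      sd_items = if (sum(idx) > 1L) stats::sd(totals[idx]) else NA_real_,
      fraction_of_full = mean(totals[idx]) / total_item_count(),
      anorectal_omitted_pct = round_half_away(100 * mean(omitted[idx]))
    )
  }
  by_group <- function(groups) {
    lv <- unique(as.character(groups))
    lv <- lv[order(match(lv, c("cervical", "thoracic", "lumbosacral",
                               "A", "B", "C", "D", "E")))]
    do.call(rbind, lapply(lv, function(g) {
      cbind(group = g, stat_row(as.character(groups) == g))
    }))
  }
  list(overall = stat_row(rep(TRUE, length(totals))),
       by_band = by_group(band),
       by_ais = by_group(ais))
}
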