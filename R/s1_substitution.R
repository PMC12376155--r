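# S1-substitution shortcut: replace the anorectal exam and S4-5 sensation
# with S1 sensory and motor findings when determining the AIS grouping.

#' Substitute sacral findings from S1
#'
#' Derives surrogate sacral findings from S1 alone, never consulting the
#' true S4-5, DAP or VAC values: an S1 sensory score of 1 or 2 in either
#' modality on either side substitutes for DAP present and S4-5 sensation
#' present (all four S1 sensory scores 0 substitutes absent); an S1 motor
#' grade of 1 through 5 on either side substitutes for VAC present (0
#' bilaterally substitutes absent).
#'
#' @param exam A [full_exam()].
#' @return List with logical `dap`, `vac`, and `s45_sensation`.
#' @export
substitute_sacral_from_s1 <- function(exam) {
  s1_sens <- c(exam$lt["S1", ], exam$pp["S1", ])
  s1_mot <- exam$motor["S1", ]
  sens_present <- any(s1_sens >= 1L)
  list(dap = sens_present, vac = any(s1_mot >= 1L),
       s45_sensation = sens_present)
}

#' Apply the S1 substitution to an examination
#'
#' Returns a copy of the exam whose S4-5 sensory scores, DAP and VAC are
#' replaced by the S1-derived surrogates (S4-5 scores become 1 when
#' substituted sensation is present, 0 otherwise). The rest of the exam is
#' untouched; classification of the result implements the shortcut.
#'
#' @param exam A [full_exam()].
#' @return A `full_exam` with substituted sacral findings.
#' @export
apply_s1_substitution <- function(exam) {
  sub <- substitute_sacral_from_s1(exam)
  s45 <- if (sub$s45_sensation) 1L else 0L
  exam$lt["S4_5", ] <- s45
  exam$pp["S4_5", ] <- s45
  exam$dap <- sub$dap
  exam$vac <- sub$vac
  exam
}

#' AIS grouping under the S1 substitution
#'
#' Classifies the exam with the substituted sacral findings and returns the
#' three-way AIS grouping (`A`, `B`, `CD`). The "NLI T10 or rostral"
#' applicability restriction is deliberately not enforced here; stratified
#' reporting by NLI is done in the evaluation functions, so the substitution
#' can be assessed at every level.
#'
#' @param exam A [full_exam()].
#' @return One of `"A"`, `"B"`, `"CD"`.
#' @export
ais_grouping_with_s1 <- function(exam) {
  ais_group(classify(apply_s1_substitution(exam))$ais)
}
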