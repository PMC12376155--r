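# Adaptive item-reduction: full motor testing, galloping sensory search,
# sacral confirmation, and anorectal items only when they can change the
# grade. The full exam acts as the responder; items are "observed" by
# reading its scores.

#' Galloping sensory search for one side
#'
#' Starting at C2, both modalities are tested together at each visited
#' dermatome. While the visited dermatome is normal in both modalities the
#' search jumps caudally by a stride of 4 (C2, C6, T2, T6, T10, L2, S1). At
#' the first dermatome abnormal in either modality, every untested dermatome
#' between the last all-normal visited dermatome and the abnormal one is
#' tested linearly (back-fill). The search ends there, or at S1 when S1 is
#' reached normal (S4-5 and, if needed, S2/S3 are handled by the sacral
#' phase of [run_iira()]).
#'
#' @param lt,pp Length-28 integer vectors of the responder's sensory scores
#'   for one side, rostral to caudal.
#' @return List with `visited` (ladder positions in visit order),
#'   `first_abnormal` (position of the first abnormal *visited* dermatome,
#'   or `NA` when S1 was reached normal).
#' @export
sensory_search <- function(lt, pp) {
  stopifnot(length(lt) == length(DERMATOMES), length(pp) == length(DERMATOMES))
  visited <- integer(0)
  pos <- 1L
  last_normal <- NA_integer_
  first_abn <- NA_integer_
  repeat {
    visited <- c(visited, pos)
    if (lt[pos] == 2L && pp[pos] == 2L) {
      last_normal <- pos
      if (pos == S1_POS) break
      pos <- pos + GALLOP_STRIDE
    } else {
      first_abn <- pos
      from <- if (is.na(last_normal)) pos else last_normal
      if (pos - from > 1L) visited <- c(visited, (from + 1L):(pos - 1L))
      break
    }
  }
  list(visited = visited, first_abnormal = first_abn)
}

#' Anorectal item requirement
#'
#' Decides which anorectal items are still needed once motor and sensory
#' phases (including S4-5) are complete. DAP is required when all four
#' observed S4-5 sensory scores are 0 (DAP could still establish sensory
#' sparing), or when the exam is a fully-normal candidate (everything
#' observed maximal), in which case DAP distinguishes grade E from D. VAC
#' is required unless the grade is already decided without it: sensory
#' sacral sparing present and key muscle activity more than three levels
#' below the ipsilateral motor level (motor-incomplete either way, and the
#' C/D split never consults VAC).
#'
#' @param s45_scores The four observed S4-5 sensory scores.
#' @param qualifying_motor_sparing Logical: key muscle grade above 0 more
#'   than three levels below the ipsilateral motor level on either side, as
#'   determined from observed items.
#' @param e_candidate Logical: every observed item so far is maximal.
#' @param dap Observed DAP value when already tested, else `NULL`; with
#'   `NULL` the VAC requirement is reported for the conservative case
#'   (sparing not established by DAP).
#' @return List with logical `need_dap` and `need_vac`.
#' @export
anorectal_requirement <- function(s45_scores, qualifying_motor_sparing,
                                  e_candidate = FALSE, dap = NULL) {
  stopifnot(length(s45_scores) == 4L)
  need_dap <- all(s45_scores == 0L) || isTRUE(e_candidate)
  sens_sparing <- any(s45_scores > 0L) || isTRUE(dap)
  need_vac <- !(sens_sparing && isTRUE(qualifying_motor_sparing))
  list(need_dap = need_dap, need_vac = need_vac)
}

#' Run the item-reduction algorithm against a full exam
#'
#' Executes, in order: (1) all 20 key muscles; (2) a per-side galloping
#' sensory search ([sensory_search()]), right side then left, both
#' modalities at each visited dermatome; (3) S4-5 light touch and pinprick
#' on both sides, with S2/S3 back-filled on a side whose search reached S1
#' normal but whose S4-5 proved abnormal; (4) anorectal items per
#' [anorectal_requirement()]. Classification is then computed on the
#' observed items, imputing every skipped dermatome inside a
#' confirmed-normal span as normal (2/2); dermatomes caudal to the first
#' observed abnormality remain untested and cannot influence the result.
#'
#' @param responder A valid [full_exam()] answering the item queries.
#' @return An `iira_result`: `classification` (an `isncsci_classification`
#'   computed from observed + imputed items), `log` (data frame of observed
#'   items in order), `counts` (named integer vector: `motor`, `sensory`,
#'   `anorectal`, `total`), `imputed_dermatomes` (data frame of
#'   dermatome/side pairs assumed normal), and `anorectal_omitted`.
#' @export
run_iira <- function(responder) {
  stopifnot(is_full_exam(responder))
  log_rows <- list()
  note <- function(kind, side, level, modality, value) {
    log_rows[[length(log_rows) + 1L]] <<- list(
      kind = kind, side = side, level = level,
      modality = modality, value = value)
  }

  # Phase 1: full motor testing.
  obs_motor <- empty_motor_matrix()
  for (side in SIDES) {
    for (i in seq_along(KEY_MUSCLES)) {
      obs_motor[i, side] <- responder$motor[i, side]
      note("motor", side, KEY_MUSCLES[i], NA, obs_motor[i, side])
    }
  }

  # Phase 2: per-side galloping sensory search.
  obs_lt <- empty_sensory_matrix()
  obs_pp <- empty_sensory_matrix()
  observe_sensory <- function(pos, side) {
    obs_lt[pos, side] <<- responder$lt[pos, side]
    obs_pp[pos, side] <<- responder$pp[pos, side]
    note("sensory", side, DERMATOMES[pos], "LT", obs_lt[pos, side])
    note("sensory", side, DERMATOMES[pos], "PP", obs_pp[pos, side])
  }
  reached_s1 <- c(R = FALSE, L = FALSE)
  for (side in SIDES) {
    search <- sensory_search(responder$lt[, side], responder$pp[, side])
    for (pos in search$visited) observe_sensory(pos, side)
    reached_s1[side] <- is.na(search$first_abnormal)
  }

  # Phase 3: S4-5 on both sides; back-fill S2/S3 where S1 was reached
  # normal but S4-5 is abnormal (the level then lies at S1, S2 or S3).
  for (side in SIDES) observe_sensory(S45_POS, side)
  for (side in SIDES) {
    s45_normal <- obs_lt[S45_POS, side] == 2L && obs_pp[S45_POS, side] == 2L
    if (reached_s1[side] && !s45_normal) {
      for (pos in (S1_POS + 1L):(S45_POS - 1L)) observe_sensory(pos, side)
    }
  }

  # Impute skipped dermatomes rostral to the first observed abnormality as
  # normal; leave everything caudal untested (scored 0 in the effective
  # exam, where it cannot affect level or grade logic).
  eff_lt <- obs_lt; eff_pp <- obs_pp
  imputed <- list()
  for (side in SIDES) {
    abn <- which(!is.na(obs_lt[, side]) &
                   (obs_lt[, side] != 2L | obs_pp[, side] != 2L))
    tail_start <- if (length(abn)) min(abn) else length(DERMATOMES) + 1L
    na_pos <- which(is.na(obs_lt[, side]))
    imp <- na_pos[na_pos < tail_start]
    eff_lt[imp, side] <- 2L
    eff_pp[imp, side] <- 2L
    eff_lt[setdiff(na_pos, imp), side] <- 0L
    eff_pp[setdiff(na_pos, imp), side] <- 0L
    if (length(imp)) {
      imputed[[side]] <- data.frame(side = side, level = DERMATOMES[imp],
                                    stringsAsFactors = FALSE)
    }
  }
  imputed <- if (length(imputed)) do.call(rbind, imputed) else
    data.frame(side = character(0), level = character(0))

  # Phase 4: anorectal items only where they can change the grade.
  s45_obs <- c(obs_lt[S45_POS, ], obs_pp[S45_POS, ])
  e_candidate <- all(eff_lt == 2L) && all(eff_pp == 2L) &&
    all(obs_motor == 5L)
  probe <- new_full_exam(responder$case_id, eff_lt, eff_pp, obs_motor,
                         FALSE, FALSE)
  ml_ord <- c(R = level_ord(motor_level(probe, "R")),
              L = level_ord(motor_level(probe, "L")))
  qualifying <- any(vapply(SIDES, function(side) {
    any(obs_motor[, side] > 0L & KEY_MUSCLE_POS > ml_ord[side] + 3L)
  }, logical(1)))

  req <- anorectal_requirement(s45_obs, qualifying, e_candidate)
  dap_val <- FALSE
  if (req$need_dap) {
    dap_val <- responder$dap
    note("anorectal", NA, "DAP", NA, as.integer(dap_val))
    req <- anorectal_requirement(s45_obs, qualifying, e_candidate,
                                 dap = dap_val)
  }
  vac_val <- FALSE
  if (req$need_vac) {
    vac_val <- responder$vac
    note("anorectal", NA, "VAC", NA, as.integer(vac_val))
  }

  eff_exam <- new_full_exam(responder$case_id, eff_lt, eff_pp, obs_motor,
                            dap_val, vac_val)
  cl <- classify(eff_exam)

  log <- do.call(rbind, lapply(log_rows, function(r) {
    data.frame(kind = r$kind, side = as.character(r$side),
               level = as.character(r$level),
               modality = as.character(r$modality),
               value = as.integer(r$value), stringsAsFactors = FALSE)
  }))
  log$order <- seq_len(nrow(log))
  counts <- c(
    motor = sum(log$kind == "motor"),
    sensory = sum(log$kind == "sensory"),
    anorectal = sum(log$kind == "anorectal")
  )
  counts <- c(counts, total = sum(counts))
  structure(
    list(classification = cl, log = log, counts = counts,
         imputed_dermatomes = imputed,
         anorectal_omitted = counts[["anorectal"]] == 0L),
    class = "iira_result"
  )
}

#' @export
print.iira_result <- function(x, ...) {
  cl <- x$classification
  cat(sprintf(
    "<iira_result> %s\n  NLI: %s  AIS: %s\n  items: %d (%d motor, %d sensory, %d anorectal) of %d\n",
    cl$case_id, cl$nli, cl$ais, x$counts[["total"]], x$counts[["motor"]],
    x$counts[["sensory"]], x$counts[["anorectal"]], total_item_count()))
  invisible(x)
}
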