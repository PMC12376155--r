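# Synthetic examination cohorts with controlled NLI/AIS distributions and
# lesion morphology. The generator constructs an exam for a target
# (NLI, AIS) pair and verifies the full classification engine recovers the
# target, resampling a bounded number of times.

BAND_POS <- list(
  cervical = 1L:7L,       # C2-C8 (NLI C1 is not generated)
  thoracic = 8L:19L,      # T1-T12
  lumbosacral = 20L:27L   # L1-S3
)

#' Cohort generator configuration
#'
#' Defaults reproduce the level-band and grade mixtures of the registry
#' population the generator emulates: NLI cervical 60.9%, thoracic 27.4%,
#' lumbosacral 11.7%; AIS A 33.5%, B 11.5%, C 15.9%, D 39.2%. Grade E is
#' never generated (cohorts of new injuries contain A-D only).
#'
#' @param n Number of exams.
#' @param seed Integer seed; the same configuration always produces the
#'   identical cohort.
#' @param nli_mixture Named probabilities over `cervical`, `thoracic`,
#'   `lumbosacral`.
#' @param ais_mixture Named probabilities over `A`, `B`, `C`, `D`.
#' @param asymmetry_prob Probability that a case has side-discordant
#'   sensory levels (left level displaced caudally).
#' @param asymmetry_max_offset Maximum caudal displacement, in levels.
#' @param isolated_deficit_prob Probability of a single abnormal dermatome
#'   (one side) immediately caudal to the sensory level, followed by a
#'   normal span before the lesion resumes -- the morphology that defeats
#'   galloping sensory searches.
#' @param zpp_span Candidate lengths (levels) of the partially impaired
#'   transition band below the sensory level; one is drawn per side.
#' @param diffuse_sparing_prob Probability that a sensory-incomplete case
#'   (grade B, C or D) carries patchy impaired sensation below the
#'   transition band down to S3, as incomplete injuries commonly do.
#'   Scores stay in 0-1, so the classification labels are unaffected.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n = 1L,
                          seed = 1L,
                          nli_mixture = c(cervical = 0.609, thoracic = 0.274,
                                          lumbosacral = 0.117),
                          ais_mixture = c(A = 0.335, B = 0.115,
                                          C = 0.159, D = 0.392),
                          asymmetry_prob = 0.10,
                          asymmetry_max_offset = 6L,
                          isolated_deficit_prob = 0.02,
                          zpp_span = 0:3,
                          diffuse_sparing_prob = 0.6) {
  stopifnot(n >= 1L, is.numeric(seed), length(seed) == 1L)
  # Mixtures quoted from published tables carry rounding (the default AIS
  # mixture sums to 1.001); accept within printing tolerance, renormalize.
  check_mixture <- function(p, nm, label) {
    if (!setequal(names(p), nm)) {
      stop(label, " must be named over {", paste(nm, collapse = ","), "}")
    }
    if (any(p < 0 | p > 1)) stop(label, " probabilities must lie in [0,1]")
    if (abs(sum(p) - 1) > 5e-3) stop(label, " must sum to 1")
    p[nm] / sum(p)
  }
  nli_mixture <- check_mixture(nli_mixture, names(BAND_POS), "nli_mixture")
  ais_mixture <- check_mixture(ais_mixture, c("A", "B", "C", "D"),
                               "ais_mixture")
  stopifnot(asymmetry_prob >= 0, asymmetry_prob <= 1,
            isolated_deficit_prob >= 0, isolated_deficit_prob <= 1,
            diffuse_sparing_prob >= 0, diffuse_sparing_prob <= 1,
            asymmetry_max_offset >= 0, all(zpp_span >= 0))
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         nli_mixture = nli_mixture, ais_mixture = ais_mixture,
         asymmetry_prob = asymmetry_prob,
         asymmetry_max_offset = as.integer(asymmetry_max_offset),
         isolated_deficit_prob = isolated_deficit_prob,
         zpp_span = as.integer(zpp_span),
         diffuse_sparing_prob = diffuse_sparing_prob),
    class = "cohort_config"
  )
}

# sample() without the scalar-x surprise.
pick <- function(v, k = 1L) v[sample.int(length(v), k)]

# Feasible NLI levels within a band for a grade. Grade C is infeasible
# where no key muscle lies below the NLI (S1-S3): the C/D half-rule is
# vacuously satisfied there and the grade is always D.
feasible_band_levels <- function(band, grade) {
  pos <- BAND_POS[[band]]
  if (grade == "C") pos <- pos[vapply(pos, function(p)
    any(KEY_MUSCLE_POS > p), logical(1))]
  DERMATOMES[pos]
}

# S4-5 scores as c(LT-R, LT-L, PP-R, PP-L); drawn per modality and applied
# to both sides, keeping non-asymmetric cases exactly side-symmetric.
s45_scores <- function(present) {
  if (!present) return(rep(0L, 4L))
  v <- sample(0:1, 2L, replace = TRUE)
  if (!any(v > 0L)) v[sample.int(2L, 1L)] <- 1L
  as.integer(v[c(1L, 1L, 2L, 2L)])
}

# One construction attempt; classification is verified by the caller.
build_candidate <- function(nli_pos, grade, config, case_id, allow_irregular) {
  asymmetric <- FALSE
  offset <- 0L
  if (allow_irregular && config$asymmetry_prob > 0 &&
      stats::runif(1) < config$asymmetry_prob) {
    offset <- pick(seq_len(max(1L, config$asymmetry_max_offset)))
    asymmetric <- TRUE
  }
  s_pos <- c(R = nli_pos, L = min(nli_pos + offset, 27L))
  if (s_pos[["L"]] == s_pos[["R"]]) asymmetric <- FALSE

  # The isolated deficit goes on the side whose sensory level determines
  # the NLI (right, by construction), the morphology of documented
  # galloping-search failures: the contralateral level and the dermatomes
  # caudal to the deficit can all be normal, hiding the deficit from a
  # striding search.
  deficit_side <- NA_character_
  if (allow_irregular && config$isolated_deficit_prob > 0 &&
      stats::runif(1) < config$isolated_deficit_prob) {
    deficit_side <- "R"
  }

  # Sensory-incomplete injuries often preserve patchy (impaired) sensation
  # below the level down to the sacral dermatomes; complete injuries do not.
  # Scores stay in {0,1}, so levels and grades are unaffected.
  diffuse_sparing <- grade != "A" &&
    stats::runif(1) < config$diffuse_sparing_prob

  build_side <- function(sp, with_deficit) {
    l <- integer(length(DERMATOMES))
    p <- integer(length(DERMATOMES))
    l[seq_len(sp)] <- 2L
    p[seq_len(sp)] <- 2L
    band_start <- sp + 1L
    placed <- FALSE
    if (with_deficit && sp + 3L <= 26L) {
      # single abnormal dermatome at sp+1, then a normal span, then the
      # lesion resumes; the true sensory level stays sp.
      l[sp + 1L] <- pick(0:1)
      p[sp + 1L] <- 2L
      span_end <- min(sp + 1L + pick(2:4), 26L)
      if (span_end > sp + 1L) {
        l[(sp + 2L):span_end] <- 2L
        p[(sp + 2L):span_end] <- 2L
      }
      band_start <- span_end + 1L
      placed <- TRUE
    }
    z <- pick(config$zpp_span)
    band_end <- band_start - 1L
    if (z > 0L && band_start <= 27L) {
      # transition band grades down monotonically (impaired, then absent)
      band_end <- min(band_start + z - 1L, 27L)
      band <- band_start:band_end
      l[band] <- sort(sample(0:1, length(band), replace = TRUE),
                      decreasing = TRUE)
      p[band] <- sort(sample(0:1, length(band), replace = TRUE),
                      decreasing = TRUE)
    }
    if (diffuse_sparing && band_end < 27L) {
      below <- (band_end + 1L):27L
      l[below] <- stats::rbinom(length(below), 1L, 0.5)
      p[below] <- stats::rbinom(length(below), 1L, 0.5)
    }
    list(l = l, p = p, placed = placed)
  }

  lt <- empty_sensory_matrix()
  pp <- empty_sensory_matrix()
  right <- build_side(s_pos[["R"]], identical(deficit_side, "R"))
  lt[, "R"] <- right$l
  pp[, "R"] <- right$p
  placed_deficit <- right$placed
  if (s_pos[["L"]] == s_pos[["R"]] && !placed_deficit) {
    # no irregularity: the exam is exactly side-symmetric
    lt[, "L"] <- right$l
    pp[, "L"] <- right$p
  } else {
    left <- build_side(s_pos[["L"]], FALSE)
    lt[, "L"] <- left$l
    pp[, "L"] <- left$p
  }

  # Key muscles (symmetric): grade 5 rostral to the NLI, 3-4 at a
  # key-segment NLI, grade-dependent pattern below.
  m <- integer(length(KEY_MUSCLES))
  m[KEY_MUSCLE_POS < nli_pos] <- 5L
  at_nli <- which(KEY_MUSCLE_POS == nli_pos)
  if (length(at_nli)) m[at_nli] <- pick(3:4)
  below_idx <- which(KEY_MUSCLE_POS > nli_pos)
  b1 <- length(below_idx)
  if (grade %in% c("C", "D") && b1 > 0L) {
    k <- if (grade == "D") pick(ceiling(b1 / 2):b1) else
      pick(0:(ceiling(b1 / 2) - 1L))
    strong <- pick(below_idx, k)
    m[strong] <- sample(3:5, k, replace = TRUE)
    m[setdiff(below_idx, strong)] <- sample(0:2, b1 - k, replace = TRUE)
  } else if (grade == "B" && b1 > 0L) {
    near <- below_idx[KEY_MUSCLE_POS[below_idx] <= nli_pos + 3L]
    if (length(near)) m[near] <- sample(0:2, length(near), replace = TRUE)
  }
  motor <- empty_motor_matrix()
  motor[, "R"] <- m
  motor[, "L"] <- m

  # Sacral findings per target grade. For motor-incomplete cases without
  # VAC, require qualifying key-muscle sparing (>3 levels below the motor
  # level) on BOTH sides, so the grade never hinges on one side alone.
  if (grade == "A") {
    s45 <- rep(0L, 4L); dap <- FALSE; vac <- FALSE
  } else if (grade == "B") {
    present <- stats::runif(1) < 0.85
    dap <- if (present) stats::runif(1) < 0.6 else TRUE
    s45 <- s45_scores(present)
    vac <- FALSE
  } else {
    probe <- new_full_exam(case_id, lt, pp, motor, FALSE, FALSE)
    ml <- c(level_ord(motor_level(probe, "R")),
            level_ord(motor_level(probe, "L")))
    margin_ok <- any(m > 0L & KEY_MUSCLE_POS > max(ml) + 3L)
    vac <- if (!margin_ok) TRUE else stats::runif(1) < 0.5
    present <- if (!vac) TRUE else stats::runif(1) < 0.7
    dap <- if (present) stats::runif(1) < 0.7 else stats::runif(1) < 0.3
    s45 <- s45_scores(present)
  }
  lt["S4_5", "R"] <- s45[1L]; lt["S4_5", "L"] <- s45[2L]
  pp["S4_5", "R"] <- s45[3L]; pp["S4_5", "L"] <- s45[4L]

  list(exam = new_full_exam(case_id, lt, pp, motor, dap, vac),
       asymmetric = asymmetric, isolated_deficit = placed_deficit)
}

#' Generate one examination with a target classification
#'
#' Constructs scores -- normal above the level, a partially impaired
#' transition band, absent below, sacral items per the target grade -- and
#' verifies that [classify()] recovers exactly the requested (NLI, AIS)
#' pair, resampling up to a bounded number of attempts (irregular features
#' such as asymmetry and isolated deficits are dropped in late attempts).
#' Infeasible targets (grade C at S1-S3, where no key muscle lies below the
#' NLI) raise an error naming the target. Draws from the current RNG state;
#' use [generate_cohort()] for seeded reproducibility.
#'
#' @param target_nli Target neurological level of injury (`C2` .. `S3`).
#' @param target_ais Target grade, one of `A`, `B`, `C`, `D`.
#' @param config A [cohort_config()] providing morphology parameters.
#' @param case_id Case identifier for the generated exam.
#' @return A [full_exam()] whose classification equals the target, with
#'   attributes `target_nli`, `target_ais`, `asymmetric`,
#'   `isolated_deficit`.
#' @export
generate_exam <- function(target_nli, target_ais = c("A", "B", "C", "D"),
                          config = cohort_config(), case_id = "case") {
  target_ais <- match.arg(target_ais)
  nli_pos <- level_ord(target_nli)
  if (nli_pos < 1L || nli_pos > 27L) {
    stop("target NLI must be one of C2..S3, got ", target_nli)
  }
  if (target_ais == "C" && !any(KEY_MUSCLE_POS > nli_pos)) {
    stop("infeasible target (", target_nli, ", C): no key muscle lies below ",
         "the NLI, so the C/D half-rule is vacuously satisfied and the ",
         "grade is always D")
  }
  max_attempts <- 60L
  for (attempt in seq_len(max_attempts)) {
    cand <- build_candidate(nli_pos, target_ais, config, case_id,
                            allow_irregular = attempt <= 40L)
    cl <- classify(cand$exam)
    if (cl$nli == target_nli && cl$ais == target_ais) {
      exam <- cand$exam
      attr(exam, "target_nli") <- target_nli
      attr(exam, "target_ais") <- target_ais
      attr(exam, "asymmetric") <- cand$asymmetric
      attr(exam, "isolated_deficit") <- cand$isolated_deficit
      return(exam)
    }
  }
  stop("could not construct an exam with target (", target_nli, ", ",
       target_ais, ") after ", max_attempts, " attempts")
}

#' Generate a seeded examination cohort
#'
#' Samples a grade from the AIS mixture and a level band from the NLI
#' mixture for each case, draws the level uniformly among the feasible
#' levels of the band for that grade, and constructs each exam with
#' [generate_exam()]. The same configuration (including seed) always
#' reproduces the identical cohort; the generator never touches the global
#' RNG state.
#'
#' @param config A [cohort_config()].
#' @return List of [full_exam()] objects of class `exam_cohort`, with the
#'   configuration attached as attribute `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    grades <- sample(names(config$ais_mixture), config$n, replace = TRUE,
                     prob = config$ais_mixture)
    bands <- sample(names(config$nli_mixture), config$n, replace = TRUE,
                    prob = config$nli_mixture)
    exams <- vector("list", config$n)
    for (i in seq_len(config$n)) {
      lvl <- pick(feasible_band_levels(bands[i], grades[i]))
      exams[[i]] <- generate_exam(lvl, grades[i], config,
                                  case_id = sprintf("case%06d", i))
    }
    structure(exams, class = c("exam_cohort", "list"), config = config)
  })
}

#' @export
print.exam_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<exam_cohort>", length(x), "exams (seed", cfg$seed, ")\n")
  invisible(x)
}
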