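# Level ordering and the 134-item universe.

# The 28 dermatome rows of the worksheet, rostral to caudal. S4 and S5 are
# examined as a single row (S4_5). C1 and INT ("intact") are sentinels used
# for level *results* only and never appear as exam rows.
DERMATOMES <- c(
  "C2", "C3", "C4", "C5", "C6", "C7", "C8",
  paste0("T", 1:12),
  paste0("L", 1:5),
  "S1", "S2", "S3", "S4_5"
)

# The ten key muscle functions per side, rostral to caudal.
KEY_MUSCLES <- c("C5", "C6", "C7", "C8", "T1", "L2", "L3", "L4", "L5", "S1")

SIDES <- c("R", "L")

# Ladder positions (1-based index into DERMATOMES) of the key-muscle segments.
KEY_MUSCLE_POS <- match(KEY_MUSCLES, DERMATOMES)

# Ordinal encoding for level arithmetic: C1 = 0 (rostral to every dermatome),
# C2..S4_5 = 1..28, INT = 29 (caudal to every dermatome).
C1_ORD <- 0L
INT_ORD <- length(DERMATOMES) + 1L

# Ladder positions used by the item-reduction search.
GALLOP_STRIDE <- 4L
S1_POS <- match("S1", DERMATOMES)     # 25
S45_POS <- match("S4_5", DERMATOMES)  # 28

#' Ordered spinal levels of the sensory examination
#'
#' @param sentinels If `TRUE`, include the `C1` and `INT` sentinels that can
#'   occur as level *results* (but never as exam rows).
#' @return Character vector of level names, rostral to caudal.
#' @export
spinal_levels <- function(sentinels = FALSE) {
  if (sentinels) c("C1", DERMATOMES, "INT") else DERMATOMES
}

#' Key muscle function levels
#'
#' @return Character vector of the ten key muscle levels, rostral to caudal.
#' @export
key_muscles <- function() KEY_MUSCLES

#' Ordinal position of a spinal level
#'
#' Maps level names to an integer ordinal on the rostral-to-caudal ladder:
#' `C1` is 0, `C2` through `S4_5` are 1 to 28, `INT` is 29. Rostral/caudal
#' comparisons between levels reduce to ordinary integer comparisons.
#'
#' @param level Character vector of level names.
#' @return Integer vector of ordinals.
#' @export
level_ord <- function(level) {
  ord <- match(level, DERMATOMES)
  ord[level == "C1"] <- C1_ORD
  ord[level == "INT"] <- INT_ORD
  if (anyNA(ord)) {
    stop("unknown spinal level(s): ", paste(level[is.na(ord)], collapse = ", "))
  }
  as.integer(ord)
}

#' @rdname level_ord
#' @param ord Integer ordinals as returned by `level_ord()`.
#' @export
ord_level <- function(ord) {
  out <- character(length(ord))
  out[ord == C1_ORD] <- "C1"
  out[ord == INT_ORD] <- "INT"
  body <- ord >= 1L & ord <= length(DERMATOMES)
  out[body] <- DERMATOMES[ord[body]]
  if (any(out == "")) stop("level ordinal out of range")
  out
}

#' The item universe of the full examination
#'
#' One row per scored exam item: 28 dermatomes x 2 sides x 2 sensory
#' modalities, 10 key muscles x 2 sides, and the two anorectal findings
#' (DAP, VAC). Each row is the unit in which exam items are counted.
#'
#' @return Data frame with columns `kind` (`"sensory"`, `"motor"`,
#'   `"anorectal"`), `side` (`"R"`, `"L"` or `NA`), `level`, `modality`
#'   (`"LT"`, `"PP"` or `NA`) and `anorectal_item` (`"DAP"`, `"VAC"` or `NA`).
#' @export
item_keys <- function() {
  sens <- expand.grid(
    level = DERMATOMES, side = SIDES, modality = c("LT", "PP"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  mot <- expand.grid(
    level = KEY_MUSCLES, side = SIDES,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  rbind(
    data.frame(kind = "sensory", side = sens$side, level = sens$level,
               modality = sens$modality, anorectal_item = NA_character_),
    data.frame(kind = "motor", side = mot$side, level = mot$level,
               modality = NA_character_, anorectal_item = NA_character_),
    data.frame(kind = "anorectal", side = NA_character_, level = NA_character_,
               modality = NA_character_, anorectal_item = c("DAP", "VAC"))
  )
}

#' Count exam items
#'
#' The full examination comprises 134 items: 112 sensory (28 dermatomes x
#' 2 sides x 2 modalities), 20 motor (10 key muscles x 2 sides), and 2
#' anorectal (DAP and VAC).
#'
#' @param kinds Which item kinds to count; defaults to all.
#' @return Integer count.
#' @examples
#' total_item_count()            # 134
#' total_item_count("sensory")   # 112
#' @export
total_item_count <- function(kinds = c("sensory", "motor", "anorectal")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  keys <- item_keys()
  sum(keys$kind %in% kinds)
}
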