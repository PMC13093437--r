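#' Developmental stage vocabularies
#'
#' Newborn fire salamanders are staged on two ordered character scales scored
#' from morphology: gill development, from dense elongated fimbriae to fully
#' reabsorbed gills (`L1 < L2 < P1 < P2`), and pigmentation, from uniform
#' larval coloration to sharply delimited yellow/black metamorphic pattern
#' (`L < LP < P`). These two closed vocabularies are the basis of all
#' downstream classification; any other token is rejected at parse time.
#'
#' @return Character vector of admissible codes, in developmental order.
#' @export
gill_stages <- function() c("L1", "L2", "P1", "P2")

#' @rdname gill_stages
#' @export
pigment_stages <- function() c("L", "LP", "P")

#' @rdname gill_stages
#' @export
offspring_phenotypes <- function() c("larva", "mixed", "juvenile")

# Normalize a stage token: case-insensitive, and all hyphen variants of the
# intermediate pigmentation stage ("L-P", including the Unicode hyphens some
# typeset sources use) collapse to "LP".
normalize_stage_token <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[-‐‑‒–—−]", "", x)
}

#' Parse gill and pigmentation stage tokens
#'
#' Tokens are case-insensitive; `"L-P"`, `"L‐P"` and `"LP"` all denote
#' the intermediate pigmentation stage. Empty strings and `NA` are treated as
#' missing (unstaged newborns occur when photographs are unusable); anything
#' else outside the vocabulary is an error naming the offending value.
#'
#' @param gill_text,pigment_text Character vectors of stage tokens.
#' @return A data.frame with factor columns `gill` and `pigment` whose levels
#'   are the ordered vocabularies of [gill_stages()] and [pigment_stages()].
#' @export
#' @examples
#' parse_stage_pair("l1", "L")
#' parse_stage_pair(c("P2", "L2"), c("p", "l-p"))
parse_stage_pair <- function(gill_text, pigment_text) {
  if (length(gill_text) != length(pigment_text)) {
    stopf("gill and pigment token vectors must have equal length")
  }
  g <- normalize_stage_token(gill_text)
  p <- normalize_stage_token(pigment_text)
  g[!nzchar(g) | is.na(g)] <- NA
  p[!nzchar(p) | is.na(p)] <- NA
  bad_g <- unique(g[!is.na(g) & !(g %in% gill_stages())])
  if (length(bad_g)) {
    stopf("unknown gill stage token(s): %s (admissible: %s)",
          paste(bad_g, collapse = ", "),
          paste(gill_stages(), collapse = ", "))
  }
  bad_p <- unique(p[!is.na(p) & !(p %in% pigment_stages())])
  if (length(bad_p)) {
    stopf("unknown pigmentation stage token(s): %s (admissible: %s)",
          paste(bad_p, collapse = ", "),
          paste(pigment_stages(), collapse = ", "))
  }
  data.frame(
    gill = factor(g, levels = gill_stages(), ordered = TRUE),
    pigment = factor(p, levels = pigment_stages(), ordered = TRUE)
  )
}

#' Classify a newborn's phenotype from its stage pair
#'
#' A newborn is a `larva` when pigmentation is at the early larval stage `L`
#' and gills are still functional in water (`L1` or `L2`); a `juvenile`
#' (terrestrial metamorph) when pigmentation is metamorphic (`P`) and gills
#' are essentially or completely reabsorbed (`P1` or `P2`). Every other
#' admissible pair is `mixed`: this single label covers both transitional
#' states (intermediate `LP` pigmentation with any gill stage) and
#' asynchronous development where gill and pigmentation stages disagree
#' markedly (e.g. `L2` gills with `P` pigmentation, or the converse).
#'
#' @param gill,pigment Stage codes (character or factor), recycled to common
#'   length. `NA` in either slot yields `NA` (unstaged newborn).
#' @return Factor with levels [offspring_phenotypes()].
#' @export
#' @examples
#' classify_offspring("L1", "L")   # larva
#' classify_offspring("P1", "P")   # juvenile
#' classify_offspring("L2", "P")   # mixed (asynchronous)
classify_offspring <- function(gill, pigment) {
  n <- max(length(gill), length(pigment))
  g <- as.character(rep_len(gill, n))
  p <- as.character(rep_len(pigment, n))
  ok_g <- is.na(g) | g %in% gill_stages()
  ok_p <- is.na(p) | p %in% pigment_stages()
  if (!all(ok_g, ok_p)) {
    stopf("inadmissible stage pair; parse tokens with parse_stage_pair() first")
  }
  out <- rep(NA_character_, n)
  staged <- !is.na(g) & !is.na(p)
  out[staged] <- "mixed"
  out[staged & p == "L" & g %in% c("L1", "L2")] <- "larva"
  out[staged & p == "P" & g %in% c("P1", "P2")] <- "juvenile"
  factor(out, levels = offspring_phenotypes())
}

#' Complete phenotype lookup over all stage pairs
#'
#' Enumerates the full 4 x 3 grid of gill-by-pigmentation combinations and
#' the phenotype each maps to. Pairs never observed in real datasets still
#' receive a label by the general rule.
#'
#' @return A 12-row data.frame with columns `gill`, `pigment`, `phenotype`.
#' @export
phenotype_table <- function() {
  grid <- expand.grid(gill = gill_stages(), pigment = pigment_stages(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$gill, gill_stages()),
                     match(grid$pigment, pigment_stages())), ]
  rownames(grid) <- NULL
  grid$phenotype <- classify_offspring(grid$gill, grid$pigment)
  grid
}
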