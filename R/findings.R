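# The findings grammar: semicolon-separated (organ[, morphology]) tokens,
# e.g. "tes tu; li ad; li ac" for tumors or "li; thyr" for organ-only
# hypertrophy findings. Organ codes may contain an internal space
# ("soft t sar"), so a tumor token splits on its LAST space.

#' Parse a findings cell
#'
#' Splits one cell of the compound table into its finding tokens. A dash
#' (`"-"` or `"–"`), empty string or `NA` means no findings. Tumor cells
#' carry an organ and a morphology per token; weight, hypertrophy and
#' hyperplasia cells carry organ codes only. Order and duplicates are
#' preserved (consumers deduplicate by organ where needed).
#'
#' @param cell Character scalar, one raw cell in the findings grammar.
#' @param with_morphology Should each token be split into organ + morphology
#'   (on the last space)? Use `FALSE` for the organ-only columns.
#' @param vocab Optional `"woe_vocabulary"` used to validate every code.
#' @param context Optional string (e.g. a row id) included in error messages.
#' @return A tibble with columns `organ` and `morphology` (the latter `NA`
#'   for organ-only findings); zero rows when the cell is empty.
#' @export
#' @examples
#' parse_finding_list("tes tu; li ad; li ac")
#' parse_finding_list("li; thyr", with_morphology = FALSE)
#' parse_finding_list("-")
parse_finding_list <- function(cell, with_morphology = TRUE, vocab = NULL,
                               context = NULL) {
  stopifnot(length(cell) <= 1)
  empty <- tibble(organ = character(), morphology = character())
  if (length(cell) == 0 || is.na(cell)) return(empty)
  cell <- trimws(cell)
  if (cell %in% c("", "-", "–")) return(empty)
  tokens <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) return(empty)
  if (with_morphology) {
    organ <- sub("\\s+\\S+$", "", tokens)
    morphology <- sub("^.*\\s", "", tokens)
    # a token without any space is an organ-only finding
    bare <- !grepl("\\s", tokens)
    morphology[bare] <- NA_character_
    organ[bare] <- tokens[bare]
  } else {
    organ <- tokens
    morphology <- rep(NA_character_, length(tokens))
  }
  out <- tibble(organ = organ, morphology = morphology)
  if (!is.null(vocab)) {
    .resolve_codes(out$organ, vocab$organs$code, "organ", context)
    morphs <- out$morphology[!is.na(out$morphology)]
    if (length(morphs) > 0) {
      .resolve_codes(morphs, vocab$morphologies$code, "morphology", context)
    }
  }
  out
}

# vectorised helpers over raw cells ------------------------------------------

.has_findings <- function(cells) {
  !is.na(cells) & !(trimws(cells) %in% c("", "-", "–"))
}

# unique organ codes per cell, as a list of character vectors
.finding_organs <- function(cells, with_morphology = TRUE) {
  lapply(cells, function(cell) {
    unique(parse_finding_list(cell, with_morphology = with_morphology)$organ)
  })
}

# all (organ, morphology) pairs of a tumor cell
.tumor_findings <- function(cell) {
  parse_finding_list(cell, with_morphology = TRUE)
}
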