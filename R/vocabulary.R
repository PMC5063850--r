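# Controlled vocabularies and knowledge bases: organ codes, lesion morphology
# codes, human-relevance rules for rat tumor types, pharmacological class
# decisions, single-in-class decisions and final-category overrides.

#' Load the organ and morphology vocabularies
#'
#' Reads the two controlled-vocabulary tables that every finding token must
#' resolve against. Organ codes are short lowercase tokens (`"li"` liver,
#' `"thyr"` thyroid, `"mam"` mammary gland, ...); morphology codes describe
#' the histological appearance of a tumor (`"ad"` adenoma, `"ac"`
#' adenocarcinoma/carcinoma, `"bpha"` benign pheochromocytoma, ...) and carry a
#' `behavior` of `"benign"`, `"malignant"` or `"unspecified"`. Comparison is
#' case-insensitive except for the canonically all-caps morphologies
#' (`SCC`, `SCP`) and the organ token `UGT`.
#'
#' @param organ_path,morphology_path Paths to delimited text files with
#'   headers `code,name,system` (organs) and `code,name,behavior`
#'   (morphologies). Default to the packaged vocabularies.
#' @return A list of class `"woe_vocabulary"` with tibbles `organs` and
#'   `morphologies`.
#' @export
#' @examples
#' vocab <- load_vocabulary()
#' vocab$organs[vocab$organs$code == "li", ]
load_vocabulary <- function(organ_path = .kb_file("organs.csv"),
                            morphology_path = .kb_file("morphologies.csv")) {
  organs <- .read_kb_csv(organ_path, c("code", "name", "system"))
  morphologies <- .read_kb_csv(morphology_path, c("code", "name", "behavior"))
  .assert_unique(.norm_token(organs$code), "organ code", basename(organ_path))
  .assert_unique(.norm_token(morphologies$code), "morphology code",
    basename(morphology_path))
  if (any(!nzchar(organs$code))) {
    abort("empty organ code", class = "woe_schema_error")
  }
  bad <- setdiff(unique(morphologies$behavior),
    c("benign", "malignant", "unspecified"))
  if (nrow(morphologies) > 0 && length(bad) > 0) {
    abort(paste0("invalid morphology behavior: ", paste(bad, collapse = ", ")),
      class = "woe_schema_error"
    )
  }
  structure(
    list(organs = organs, morphologies = morphologies),
    class = "woe_vocabulary"
  )
}

# token normalization: trim, lower-case except all-caps codes, squeeze spaces
.norm_token <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  allcaps <- x == toupper(x) & grepl("[A-Z]", x)
  x[!allcaps] <- tolower(x[!allcaps])
  x
}

.resolve_codes <- function(tokens, codes, kind, context = NULL) {
  miss <- setdiff(unique(.norm_token(tokens)), .norm_token(codes))
  miss <- miss[nzchar(miss)]
  if (length(miss) > 0) {
    ctx <- if (is.null(context)) "" else paste0(" (", context, ")")
    abort(
      paste0("unresolved ", kind, " token(s)", ctx, ": ",
        paste(miss, collapse = ", ")),
      class = "woe_unresolved_token"
    )
  }
  invisible(TRUE)
}

#' Load the full knowledge base
#'
#' Bundles everything the pipeline needs besides the compound table: the organ
#' and morphology vocabularies, the human-relevance rules for rat tumor types,
#' the pharmacological class-decision table (with its class-key map), the
#' single-in-class decisions, and the final-category override rules.
#'
#' @param dir Directory containing the knowledge-base CSV files
#'   (`organs.csv`, `morphologies.csv`, `relevance.csv`, `class_decisions.csv`,
#'   `class_map.csv`, `singles.csv`, `overrides.csv`). Defaults to the
#'   packaged knowledge base.
#' @return A list of class `"woe_kb"`.
#' @export
load_knowledge_base <- function(dir = NULL) {
  p <- function(name) {
    if (is.null(dir)) .kb_file(name) else file.path(dir, name)
  }
  vocab <- load_vocabulary(p("organs.csv"), p("morphologies.csv"))
  relevance <- .read_kb_csv(p("relevance.csv"),
    c("organ", "morphology", "human_relevant", "rationale"))
  relevance$human_relevant <- toupper(relevance$human_relevant) == "TRUE"
  if (any(relevance$organ == "*" & relevance$morphology == "*")) {
    abort("a relevance rule must name at least one of organ or morphology",
      class = "woe_schema_error"
    )
  }
  decisions <- .read_kb_csv(p("class_decisions.csv"),
    c("class_id", "table_of_origin", "decision", "n_compounds",
      "n_with_tumors"))
  decisions$n_compounds <- as.integer(decisions$n_compounds)
  decisions$n_with_tumors <- as.integer(decisions$n_with_tumors)
  .assert_unique(decisions$class_id, "class_id", "class_decisions.csv")
  bad <- setdiff(unique(decisions$decision), .cat_ph_levels)
  if (length(bad) > 0) {
    abort(paste0("invalid class decision value: ", paste(bad, collapse = ", ")),
      class = "woe_schema_error"
    )
  }
  if (any(decisions$n_with_tumors < 0 |
      decisions$n_with_tumors > decisions$n_compounds)) {
    abort("class decision tumor counts must satisfy 0 <= k <= n",
      class = "woe_schema_error"
    )
  }
  class_map <- .read_kb_csv(p("class_map.csv"),
    c("mode_of_action_pattern", "class_id"))
  singles <- .read_kb_csv(p("singles.csv"),
    c("compound_id", "decision", "rationale"))
  singles$compound_id <- as.integer(singles$compound_id)
  overrides <- .read_kb_csv(p("overrides.csv"),
    c("compound_id", "forced_final", "rationale"))
  overrides$compound_id <- as.integer(overrides$compound_id)
  structure(
    list(
      vocabulary = vocab, relevance = relevance,
      class_decisions = decisions, class_map = class_map,
      singles = singles, overrides = overrides
    ),
    class = "woe_kb"
  )
}

#' Decide whether rat tumor findings are relevant for humans
#'
#' Applies the human-relevance rule set to tumor findings. Rules are
#' organ/morphology pairs in which either side may be the wildcard `"*"`; the
#' most specific matching rule decides (exact pair before organ wildcard
#' before morphology wildcard), independent of the order of rules in the
#' file. A finding matched by no rule defaults to human-relevant, the
#' conservative choice for a screening rule set.
#'
#' @param organ,morphology Character vectors of organ and morphology codes
#'   (recycled to a common length).
#' @param rules Tibble of relevance rules with columns
#'   `organ`, `morphology`, `human_relevant`; defaults to the packaged rules.
#' @param vocab Optional `"woe_vocabulary"`; when supplied, unresolvable codes
#'   raise an error identifying the offending token.
#' @return Logical vector: `TRUE` where the tumor type is considered relevant
#'   to humans.
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' is_human_relevant(c("adr", "mam", "kid"), c("bpha", "fad", "ac"),
#'   kb$relevance)
is_human_relevant <- function(organ, morphology, rules = NULL, vocab = NULL) {
  if (is.null(rules)) rules <- load_knowledge_base()$relevance
  n <- max(length(organ), length(morphology))
  organ <- rep_len(.norm_token(organ), n)
  morphology <- rep_len(.norm_token(morphology), n)
  if (!is.null(vocab)) {
    .resolve_codes(organ, vocab$organs$code, "organ")
    .resolve_codes(morphology, vocab$morphologies$code, "morphology")
  }
  ro <- .norm_token(rules$organ)
  rm_ <- .norm_token(rules$morphology)
  ro[rules$organ == "*"] <- "*"
  rm_[rules$morphology == "*"] <- "*"
  vapply(seq_len(n), function(i) {
    hit <- which(ro == organ[i] & rm_ == morphology[i])
    if (length(hit) == 0) hit <- which(ro == organ[i] & rm_ == "*")
    if (length(hit) == 0) hit <- which(ro == "*" & rm_ == morphology[i])
    if (length(hit) == 0) TRUE else rules$human_relevant[hit[1]]
  }, logical(1))
}

# normalize a mode-of-action string to the key used by class_map.csv:
# lower-case, subscript markers removed, whitespace squeezed, trailing
# punctuation stripped
normalize_class_key <- function(x) {
  x <- gsub("_", "", x, fixed = TRUE)
  x <- gsub("\\s+", " ", trimws(tolower(x)))
  x <- sub("[.,]+$", "", x)
  trimws(x)
}
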