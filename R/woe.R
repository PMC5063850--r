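# Final combined categorization: a decisive pharmacological call (TP or TN)
# overrides the histopathological category; an indecisive one (NT or NC)
# falls back to it. Two documented per-compound overrides deviate from the
# closed-form rule, each citing its narrative rationale in the override file.

#' Combine histopathological and pharmacological categories
#'
#' Applies the combination rule per compound: if an override exists for the
#' compound it wins; otherwise `cat_ph` in `{TP, TN}` gives
#' `cat_final = cat_ph`, and `cat_ph` in `{NT, NC}` gives
#' `cat_final = cat_his`.
#'
#' @param data Compound tibble with `cat_his` and `cat_ph` columns.
#' @param overrides Tibble of override rules
#'   (`compound_id`, `forced_final`, `rationale`); defaults to the packaged
#'   two-row file. Use a zero-row tibble to disable.
#' @return `data` with columns `cat_final` and `fired_rule_final` appended.
#' @export
combine_final <- function(data, overrides = NULL) {
  if (is.null(overrides)) overrides <- load_knowledge_base()$overrides
  for (col in c("cat_his", "cat_ph")) {
    if (!col %in% names(data)) {
      abort(paste0("column `", col, "` missing; run the earlier stages first"),
        class = "woe_schema_error"
      )
    }
  }
  bad <- !data$cat_his %in% .cat_his_levels | !data$cat_ph %in% .cat_ph_levels
  if (any(bad)) {
    abort(paste0("invalid category values for compound(s): ",
      paste(data$compound_id[bad], collapse = ", ")),
    class = "woe_schema_error")
  }
  idx <- match(data$compound_id, overrides$compound_id)
  decisive <- data$cat_ph %in% c("TP", "TN")
  data |>
    dplyr::mutate(
      cat_final = dplyr::case_when(
        !is.na(idx) ~ overrides$forced_final[idx],
        decisive ~ .data$cat_ph,
        TRUE ~ .data$cat_his
      ),
      fired_rule_final = dplyr::case_when(
        !is.na(idx) ~ paste0("override: ", overrides$rationale[idx]),
        decisive ~ "pharmacology decisive",
        TRUE ~ "pharmacology indecisive; histopathology retained"
      )
    )
}

#' Partition false negatives by human relevance of their tumors
#'
#' Splits the histopathological false negatives into compounds whose tumor
#' findings are all of types considered not relevant to humans (common
#' spontaneous tumors of aged rats) and compounds bearing at least one
#' human-relevant tumor. Compounds flagged as peroxisome proliferators treat
#' hepatocellular tumors as non-relevant regardless of the liver rules.
#'
#' @param data Compound tibble with a `cat_his` column.
#' @param kb Knowledge base supplying the relevance rules.
#' @return Tibble with one row per false-negative compound: `compound_id`,
#'   `tumor_findings`, `n_relevant` (count of human-relevant tumor findings)
#'   and `bucket` (`"not_human_relevant_tumors"` or
#'   `"human_relevant_tumors"`).
#' @export
#' @examples
#' woe_compounds() |>
#'   categorize_histopathology() |>
#'   refine_false_negatives() |>
#'   dplyr::count(bucket)
refine_false_negatives <- function(data, kb = load_knowledge_base()) {
  if (!"cat_his" %in% names(data)) {
    data <- categorize_histopathology(data)
  }
  fn <- data[data$cat_his == "FN", ]
  rules <- kb$relevance
  n_rel <- vapply(seq_len(nrow(fn)), function(i) {
    f <- .tumor_findings(fn$tumor_findings[i])
    rel <- is_human_relevant(f$organ, f$morphology, rules)
    if (isTRUE(fn$peroxisome_proliferator[i])) {
      rel[.norm_token(f$organ) == "li"] <- FALSE
    }
    sum(rel)
  }, integer(1))
  tibble(
    compound_id = fn$compound_id,
    tumor_findings = fn$tumor_findings,
    n_relevant = n_rel,
    bucket = ifelse(n_rel == 0, "not_human_relevant_tumors",
      "human_relevant_tumors")
  )
}
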