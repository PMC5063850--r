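# Compound table reader/writer and the packaged 289-compound reference
# dataset. One row per pharmaceutical: identifiers, pharmacological class
# annotation, the four findings columns (organ weight, hypertrophy,
# hyperplasia, 2-year tumors) in the findings grammar, and the published
# categories kept as regression ground truth (never read by the pipeline
# stages themselves).

.compound_cols <- c(
  "compound_id", "mode_of_action", "therapeutic_area", "pharm_class_id",
  "single_in_class", "weight_findings", "hypertrophy_findings",
  "hyperplasia_findings", "tumor_findings", "cat_his_published",
  "cat_ph_published", "cat_final_published"
)

# classes whose members are peroxisome proliferators; their hepatocellular
# tumors are treated as not human-relevant irrespective of the liver rules
.pp_classes <- "mb_fibrates"

#' Read a compound table
#'
#' Reads a delimited-text compound table, validates it against the
#' vocabulary (every finding token must resolve to a known organ or
#' morphology code) and derives the `peroxisome_proliferator` flag from the
#' pharmacological class.
#'
#' @param path Path to a CSV file with the columns
#'   `compound_id, mode_of_action, therapeutic_area, pharm_class_id,
#'   single_in_class, weight_findings, hypertrophy_findings,
#'   hyperplasia_findings, tumor_findings, cat_his_published,
#'   cat_ph_published, cat_final_published`.
#' @param kb Knowledge base from [load_knowledge_base()], used for
#'   vocabulary validation.
#' @return A tibble of compound records.
#' @export
read_compounds <- function(path, kb = load_knowledge_base()) {
  raw <- .read_kb_csv(path, .compound_cols)
  if (nrow(raw) == 0) {
    warn("compound table contains no data rows")
  }
  out <- tibble(
    compound_id = as.integer(raw$compound_id),
    mode_of_action = raw$mode_of_action,
    therapeutic_area = raw$therapeutic_area,
    pharm_class_id = raw$pharm_class_id,
    single_in_class = toupper(raw$single_in_class) == "TRUE",
    weight_findings = raw$weight_findings,
    hypertrophy_findings = raw$hypertrophy_findings,
    hyperplasia_findings = raw$hyperplasia_findings,
    tumor_findings = raw$tumor_findings,
    cat_his_published = raw$cat_his_published,
    cat_ph_published = raw$cat_ph_published,
    cat_final_published = raw$cat_final_published
  )
  dup <- unique(out$compound_id[duplicated(out$compound_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate compound_id: ", paste(dup, collapse = ", ")),
      class = "woe_duplicate_id"
    )
  }
  for (col in c("cat_his_published", "cat_ph_published",
    "cat_final_published")) {
    vals <- out[[col]][nzchar(out[[col]])]
    bad <- setdiff(unique(vals), .cat_all_levels)
    if (length(bad) > 0) {
      abort(paste0("invalid category in ", col, ": ",
        paste(bad, collapse = ", ")), class = "woe_schema_error")
    }
  }
  vocab <- kb$vocabulary
  for (i in seq_len(nrow(out))) {
    ctx <- paste0("compound ", out$compound_id[i])
    for (col in c("weight_findings", "hypertrophy_findings",
      "hyperplasia_findings")) {
      parse_finding_list(out[[col]][i], with_morphology = FALSE,
        vocab = vocab, context = ctx)
    }
    parse_finding_list(out$tumor_findings[i], with_morphology = TRUE,
      vocab = vocab, context = ctx)
  }
  out$peroxisome_proliferator <- out$pharm_class_id %in% .pp_classes
  out
}

#' Write a compound table
#'
#' Inverse of [read_compounds()]: writing and re-reading a valid compound
#' table reproduces it exactly. The derived `peroxisome_proliferator` column
#' is not stored.
#'
#' @param data Compound tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(data, path) {
  out <- data[, .compound_cols]
  out$single_in_class <- ifelse(out$single_in_class, "TRUE", "FALSE")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' The packaged 289-compound reference dataset
#'
#' A transcription of the published summary table of paired rat subchronic
#' and 2-year carcinogenicity study outcomes for 289 non-genotoxic
#' pharmaceuticals, with organ-weight, hypertrophy, hyperplasia and tumor
#' findings in the findings grammar plus the published categories of all
#' three categorization stages.
#'
#' @param kb Knowledge base used for validation.
#' @return A tibble with 289 rows.
#' @export
#' @examples
#' compounds <- woe_compounds()
#' dplyr::count(compounds, cat_his_published)
woe_compounds <- function(kb = load_knowledge_base()) {
  read_compounds(.kb_file("compounds.csv"), kb = kb)
}
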