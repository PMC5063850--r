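# Step 2: categorization from pharmacological class knowledge. The tumor
# fraction of each class is computed and called positive (>= 75% of members
# tumor-associated), negative (<= 25%) or mixed, but the compound-level
# category comes from the transcribed class-decision knowledge base, because
# the published class decisions incorporate literature judgment that cannot
# be re-derived from the counts alone (e.g. immunosuppressives called TP
# despite zero rat tumors in the dataset). Both views are emitted so that
# disagreements stay visible.

#' Per-class tumor fractions
#'
#' Counts, per pharmacological class, the members and the members associated
#' with tumor induction (non-empty tumor findings), and the resulting
#' fraction.
#'
#' @param data Compound tibble.
#' @param class_id Optional single class to restrict to; unknown ids raise an
#'   error.
#' @return Tibble with columns `class_id`, `n_members`, `n_with_tumors`,
#'   `fraction`.
#' @export
#' @examples
#' woe_compounds() |> class_tumor_fraction("cns_da2_agonists")
class_tumor_fraction <- function(data, class_id = NULL) {
  out <- data |>
    dplyr::group_by(class_id = .data$pharm_class_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_with_tumors = sum(.has_findings(.data$tumor_findings)),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction = .data$n_with_tumors / .data$n_members)
  if (!is.null(class_id)) {
    if (!class_id %in% out$class_id) {
      abort(paste0("unknown class_id: ", class_id),
        class = "woe_unassigned_class"
      )
    }
    out <- out[out$class_id == class_id, ]
  }
  out
}

#' Call a class outcome from its tumor fraction
#'
#' A class is `"positive"` when at least `positive_threshold` of its members
#' are tumor-associated, `"negative"` when at most `negative_threshold` are,
#' and `"mixed"` in between. The defaults are the 75%/25% convention; the
#' published tables include a 75% class among the positives, fixing the
#' closed boundary.
#'
#' @param fraction Numeric vector of tumor fractions in `[0, 1]`.
#' @param positive_threshold,negative_threshold Decision boundaries with
#'   `0 < negative_threshold < positive_threshold <= 1`.
#' @return Character vector of outcomes.
#' @export
#' @examples
#' class_outcome(c(0.75, 0.17, 0.5))
class_outcome <- function(fraction, positive_threshold = 0.75,
                          negative_threshold = 0.25) {
  if (!(negative_threshold > 0 && negative_threshold < positive_threshold &&
    positive_threshold <= 1)) {
    abort("thresholds must satisfy 0 < negative < positive <= 1",
      class = "woe_invalid_config"
    )
  }
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE)) {
    abort("fraction must lie in [0, 1]", class = "woe_invalid_config")
  }
  dplyr::case_when(
    fraction >= positive_threshold ~ "positive",
    fraction <= negative_threshold ~ "negative",
    TRUE ~ "mixed"
  )
}

#' Assign the pharmacological category
#'
#' Compounds flagged single-in-class take the per-compound expert decision
#' recorded in the singles table; all others take the decision of their
#' pharmacological class from the class-decision knowledge base. Decisions
#' are TP, TN, NT (no mammalian target: antibacterials, antifungals,
#' antivirals) or NC (pharmacology–tumor relationship undecidable).
#'
#' @param data Compound tibble.
#' @param kb Knowledge base from [load_knowledge_base()].
#' @return `data` with columns `cat_ph` and `fired_rule_ph` appended.
#' @export
assign_pharm_category <- function(data, kb = load_knowledge_base()) {
  dec <- kb$class_decisions
  singles <- kb$singles
  idx_class <- match(data$pharm_class_id, dec$class_id)
  idx_single <- match(data$compound_id, singles$compound_id)
  single <- data$single_in_class
  missing_single <- single & is.na(idx_single)
  if (any(missing_single)) {
    abort(
      paste0("no single-in-class decision recorded for compound(s): ",
        paste(data$compound_id[missing_single], collapse = ", ")),
      class = "woe_unassigned_class"
    )
  }
  missing_class <- !single & is.na(idx_class)
  if (any(missing_class)) {
    abort(
      paste0("class(es) absent from the decision table: ",
        paste(unique(data$pharm_class_id[missing_class]), collapse = ", ")),
      class = "woe_unassigned_class"
    )
  }
  data |>
    dplyr::mutate(
      cat_ph = ifelse(single, singles$decision[idx_single],
        dec$decision[idx_class]),
      fired_rule_ph = ifelse(single,
        "single-in-class expert decision",
        paste0("class decision: ", .data$pharm_class_id, " (",
          dec$table_of_origin[idx_class], " class)"))
    )
}
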