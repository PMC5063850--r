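# Step 1: categorization from subchronic histopathology versus the 2-year
# tumor outcome. A compound is subchronic-positive if and only if it induced
# putative preneoplastic lesions, recorded in the hyperplasia column (the
# transcription folds atypical foci of cellular alteration, proliferation and
# dysplasia into that column). Greater organ weights and cellular hypertrophy
# are treated as adaptive and carry no weight: a compound with hypertrophy
# only is scored negative.

#' Categorize compounds from subchronic histopathology
#'
#' Crosses subchronic positivity (non-empty hyperplasia findings) with
#' carcinogenicity positivity (non-empty tumor findings):
#' both positive = TP, subchronic-only = FP, tumor-only = FN,
#' neither = TN.
#'
#' @param data Compound tibble (see [read_compounds()]).
#' @return `data` with columns `cat_his` and `fired_rule_his` appended.
#' @export
#' @examples
#' woe_compounds() |> categorize_histopathology() |> dplyr::count(cat_his)
categorize_histopathology <- function(data) {
  sub_pos <- .has_findings(data$hyperplasia_findings)
  carc_pos <- .has_findings(data$tumor_findings)
  ht_only <- !sub_pos & .has_findings(data$hypertrophy_findings)
  data |>
    dplyr::mutate(
      cat_his = dplyr::case_when(
        sub_pos & carc_pos ~ "TP",
        sub_pos & !carc_pos ~ "FP",
        !sub_pos & carc_pos ~ "FN",
        TRUE ~ "TN"
      ),
      fired_rule_his = dplyr::case_when(
        sub_pos & carc_pos ~ "hyperplasia present; tumors present",
        sub_pos & !carc_pos ~ "hyperplasia present; no tumors",
        !sub_pos & carc_pos & ht_only ~
          "hypertrophy only scored negative; tumors present",
        !sub_pos & carc_pos ~ "no preneoplastic lesion; tumors present",
        ht_only ~ "hypertrophy only scored negative; no tumors",
        TRUE ~ "no preneoplastic lesion; no tumors"
      )
    )
}

#' Compounds of a category without any subchronic finding
#'
#' Selects, within one histopathological category, the compounds whose
#' organ-weight, hypertrophy and hyperplasia columns are all empty — the
#' subset for which the subchronic study was entirely silent.
#'
#' @param data Compound tibble with a `cat_his` column (run
#'   [categorize_histopathology()] first).
#' @param within Category to screen, one of `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @return Tibble of the selected compounds.
#' @export
no_findings_screen <- function(data, within = "TN") {
  if (!within %in% .cat_his_levels) {
    abort(paste0("unknown category: ", within), class = "woe_schema_error")
  }
  if (!"cat_his" %in% names(data)) {
    data <- categorize_histopathology(data)
  }
  data |>
    dplyr::filter(
      .data$cat_his == within,
      !.has_findings(.data$weight_findings),
      !.has_findings(.data$hypertrophy_findings),
      !.has_findings(.data$hyperplasia_findings)
    )
}

#' Organ concordance between hyperplasia and tumors
#'
#' For each compound with both hyperplasia and tumor findings, tests whether
#' the deduplicated organ sets intersect: did the hyperplastic lesion and the
#' tumor develop in the same organ? Compounds lacking either finding type are
#' `"not_applicable"`. Comparison is by organ code only; morphology is
#' ignored.
#'
#' @param data Compound tibble.
#' @return `data` with a `concordance` column
#'   (`"concordant"`, `"discordant"`, `"not_applicable"`).
#' @export
#' @examples
#' woe_compounds() |>
#'   categorize_histopathology() |>
#'   organ_concordance() |>
#'   dplyr::count(cat_his, concordance)
organ_concordance <- function(data) {
  hp <- .finding_organs(data$hyperplasia_findings, with_morphology = FALSE)
  tum <- .finding_organs(data$tumor_findings, with_morphology = TRUE)
  data |>
    dplyr::mutate(
      concordance = purrr::map2_chr(hp, tum, function(h, t) {
        if (length(h) == 0 || length(t) == 0) return("not_applicable")
        if (length(intersect(h, t)) > 0) "concordant" else "discordant"
      })
    )
}
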