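# End-to-end pipeline and report writers: per-compound assignments with rule
# provenance, contingency summaries and predictivity metrics for all three
# stages, the per-class summary, the false-negative relevance refinement, and
# the post-filter metric variants.

#' Run the full weight-of-evidence pipeline
#'
#' Chains the three categorization stages over a compound table and collects
#' every summary the analysis reports: per-compound category assignments with
#' the rule that fired at each stage, contingency tables and the five
#' predictivity metrics per stage, the per-class tumor fractions with their
#' automatic outcome calls next to the transcribed expert decisions, the
#' false-negative human-relevance refinement, and post-filter metric
#' variants in which non-relevant false negatives are re-scored as true
#' negatives.
#'
#' @param data Compound tibble; defaults to the packaged reference dataset.
#' @param kb Knowledge base from [load_knowledge_base()].
#' @param rounding Rounding convention for the reported percentages.
#' @return A list of class `"woe_result"` with elements `assignments`,
#'   `contingency`, `metrics`, `class_summary`, `fn_refinement`,
#'   `post_filter` and `n`.
#' @export
#' @examples
#' res <- run_pipeline()
#' glance(res)
run_pipeline <- function(data = woe_compounds(kb), kb = load_knowledge_base(),
                         rounding = "half_away") {
  if (nrow(data) == 0) {
    abort("compound table is empty", class = "woe_schema_error")
  }
  assignments <- data |>
    categorize_histopathology() |>
    assign_pharm_category(kb = kb) |>
    combine_final(overrides = kb$overrides) |>
    organ_concordance()

  contingency <- dplyr::bind_rows(
    summarize_contingency(assignments, "histopathological"),
    summarize_contingency(assignments, "pharmacological"),
    summarize_contingency(assignments, "final")
  )
  metrics <- dplyr::bind_rows(
    lapply(seq_len(nrow(contingency)), function(i) {
      compute_metrics(contingency[i, ], rounding = rounding)
    })
  )

  class_summary <- class_tumor_fraction(assignments) |>
    dplyr::mutate(outcome_automatic = class_outcome(.data$fraction)) |>
    dplyr::left_join(
      kb$class_decisions[, c("class_id", "table_of_origin", "decision")],
      by = "class_id"
    )

  fn_refinement <- refine_false_negatives(assignments, kb = kb)

  structure(
    list(
      assignments = assignments,
      contingency = contingency,
      metrics = metrics,
      class_summary = class_summary,
      fn_refinement = fn_refinement,
      post_filter = .post_filter_metrics(assignments, fn_refinement,
        rounding),
      n = nrow(data)
    ),
    class = "woe_result"
  )
}

# Post-filter variants: the negative predictivity and specificity after
# moving false negatives whose tumors are all non-human-relevant into the
# true negatives. The moved set is ambiguous in principle, so all three
# readings are computed:
#   histopathological — move the non-relevant histopathological FNs;
#   final             — move the non-relevant final FNs;
#   union             — additionally move histopathological FNs already
#                       rescued as TN by pharmacology (identical to `final`
#                       on the TN side, shown for completeness).
.post_filter_metrics <- function(assignments, fn_refinement, rounding) {
  nr_ids <- fn_refinement$compound_id[
    fn_refinement$bucket == "not_human_relevant_tumors"]
  variant <- function(name, col) {
    x <- assignments
    move <- x$compound_id %in% nr_ids & x[[col]] == "FN"
    x$cat_post <- ifelse(move, "TN", x[[col]])
    cs <- tibble(stage = name,
      tp = sum(x$cat_post == "TP"), fp = sum(x$cat_post == "FP"),
      fn = sum(x$cat_post == "FN"), tn = sum(x$cat_post == "TN"),
      nt = sum(x$cat_post == "NT"), nc = sum(x$cat_post == "NC"))
    cs$total <- nrow(x)
    class(cs) <- c("woe_contingency", class(cs))
    compute_metrics(cs, rounding = rounding)
  }
  dplyr::bind_rows(
    variant("post_filter_histopathological", "cat_his"),
    variant("post_filter_final", "cat_final"),
    variant("post_filter_union", "cat_final")
  )
}

#' @exportS3Method generics::tidy
tidy.woe_result <- function(x, ...) {
  x$assignments
}

#' @exportS3Method generics::glance
glance.woe_result <- function(x, ...) {
  fin <- x$contingency[x$contingency$stage == "final", ]
  m <- x$metrics[x$metrics$stage == "final", ]
  tibble(
    n = x$n,
    tp = fin$tp, fp = fin$fp, fn = fin$fn, tn = fin$tn,
    negative_predictivity =
      m$raw[m$metric == "negative_predictivity"],
    positive_predictivity =
      m$raw[m$metric == "positive_predictivity"],
    sensitivity = m$raw[m$metric == "sensitivity"],
    specificity = m$raw[m$metric == "specificity"]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.woe_result <- function(object, ...) {
  autoplot(object$metrics, ...)
}

#' @export
print.woe_result <- function(x, ...) {
  cat("Weight-of-evidence categorization of", x$n, "compounds\n\n")
  wide <- tidyr::pivot_wider(
    as_tibble(x$metrics)[, c("stage", "metric", "rounded")],
    names_from = "stage", values_from = "rounded"
  )
  print(as.data.frame(wide), row.names = FALSE)
  cat("\nFinal categories: ")
  fin <- x$contingency[x$contingency$stage == "final", ]
  cat(sprintf("TP %d | FP %d | FN %d | TN %d\n", fin$tp, fin$fp, fin$fn,
    fin$tn))
  invisible(x)
}

#' Write pipeline reports to a directory
#'
#' Emits the per-compound assignment table, the stage metrics, the class
#' summary and the false-negative refinement as CSV files, plus a markdown
#' report with the three-stage predictivity table, the class tables grouped
#' by origin, and the final summary counts. Output is byte-identical across
#' runs on identical inputs.
#'
#' @param result A `"woe_result"` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_csv(as_tibble(x), file.path(dir, name), na = "",
      progress = FALSE)
  }
  w(result$assignments, "assignments.csv")
  w(result$contingency, "contingency.csv")
  w(result$metrics, "metrics.csv")
  w(result$class_summary, "class_summary.csv")
  w(result$fn_refinement, "fn_refinement.csv")
  w(result$post_filter, "post_filter_metrics.csv")

  md <- c(
    "# Weight-of-evidence categorization report", "",
    paste0("Compounds evaluated: ", result$n), "",
    "## Predictivity by stage", "",
    .md_table(tidyr::pivot_wider(
      as_tibble(result$metrics)[, c("stage", "metric", "rounded")],
      names_from = "stage", values_from = "rounded")), "",
    "## Contingency counts", "",
    .md_table(as_tibble(result$contingency)), "",
    "## Pharmacological classes", "",
    .md_table(as_tibble(result$class_summary)), "",
    "## False-negative refinement", "",
    .md_table(dplyr::count(result$fn_refinement, .data$bucket)), ""
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

.md_table <- function(df) {
  df <- as.data.frame(df)
  fmt <- function(x) {
    if (is.numeric(x)) format(x, trim = TRUE, digits = 4) else as.character(x)
  }
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(vapply(df[i, , drop = FALSE], fmt, character(1)),
      collapse = " | "), " |")
  }, character(1))
  c(
    paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    body
  )
}
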