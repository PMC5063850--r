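# Contingency summaries and the five predictivity statistics per
# categorization stage. The pharmacological stage has no plain false
# positives or false negatives: its NT calls (no mammalian target) occupy the
# positive-prediction/negative-outcome cell and its NC calls
# (non-categorizable) the negative-prediction/positive-outcome cell, and the
# metrics use those slots.

#' Contingency summary for a categorization stage
#'
#' Tabulates a stage's categories into the 2x2 cells. For
#' `stage = "pharmacological"` the NT and NC counts are kept separately and
#' occupy the FP and FN slots respectively; the other stages use the four
#' plain cells.
#'
#' @param data Compound tibble holding the stage's category column
#'   (`cat_his`, `cat_ph` or `cat_final`).
#' @param stage One of `"histopathological"`, `"pharmacological"`, `"final"`.
#' @return A one-row tibble of class `"woe_contingency"` with columns
#'   `stage, tp, fp, fn, tn, nt, nc, total`.
#' @export
summarize_contingency <- function(data,
                                  stage = c("histopathological",
                                    "pharmacological", "final")) {
  stage <- match.arg(stage)
  col <- switch(stage,
    histopathological = "cat_his",
    pharmacological = "cat_ph",
    final = "cat_final"
  )
  if (!col %in% names(data)) {
    abort(paste0("column `", col, "` missing; compute the ", stage,
      " stage first"), class = "woe_schema_error")
  }
  x <- data[[col]]
  if (any(is.na(x))) {
    abort("missing category assignments", class = "woe_schema_error")
  }
  cnt <- function(v) sum(x == v)
  out <- tibble(
    stage = stage,
    tp = cnt("TP"), fp = cnt("FP"), fn = cnt("FN"), tn = cnt("TN"),
    nt = cnt("NT"), nc = cnt("NC")
  )
  out$total <- with(out, tp + fp + fn + tn + nt + nc)
  class(out) <- c("woe_contingency", class(out))
  out
}

#' Predictivity metrics from a contingency summary
#'
#' Computes the five screening statistics, as percentages:
#' \describe{
#'   \item{fn_fraction}{FN-slot / total}
#'   \item{negative_predictivity}{TN / (TN + FN-slot) — ability to predict
#'     non-carcinogens}
#'   \item{positive_predictivity}{TP / (TP + FP-slot) — ability to predict
#'     rat carcinogens}
#'   \item{sensitivity}{TP / (TP + FN-slot) — ability to detect rat
#'     carcinogens}
#'   \item{specificity}{TN / (TN + FP-slot) — ability to detect
#'     non-carcinogens}
#' }
#' where FP-slot = FP + NT and FN-slot = FN + NC. A zero denominator yields
#' `NA` with `undefined = TRUE`, never an error, so sweeps over degenerate
#' simulated datasets do not abort. Raw and rounded values are both kept;
#' the default rounding is nearest integer with halves away from zero.
#'
#' @param cs A `"woe_contingency"` row from [summarize_contingency()].
#' @param rounding `"half_away"` (default), `"floor"` or `"none"`.
#' @return A tibble of class `"woe_metrics"` with columns
#'   `stage, metric, raw, rounded, undefined`.
#' @export
#' @examples
#' woe_compounds() |>
#'   categorize_histopathology() |>
#'   summarize_contingency("histopathological") |>
#'   compute_metrics()
compute_metrics <- function(cs, rounding = "half_away") {
  stopifnot(nrow(cs) == 1)
  fp_slot <- cs$fp + cs$nt
  fn_slot <- cs$fn + cs$nc
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  raw <- c(
    fn_fraction = pct(fn_slot, cs$total),
    negative_predictivity = pct(cs$tn, cs$tn + fn_slot),
    positive_predictivity = pct(cs$tp, cs$tp + fp_slot),
    sensitivity = pct(cs$tp, cs$tp + fn_slot),
    specificity = pct(cs$tn, cs$tn + fp_slot)
  )
  out <- tibble(
    stage = cs$stage,
    metric = names(raw),
    raw = unname(raw),
    rounded = .round_pct(unname(raw), rounding),
    undefined = is.na(raw)
  )
  class(out) <- c("woe_metrics", class(out))
  out
}

#' @exportS3Method generics::glance
glance.woe_metrics <- function(x, ...) {
  wide <- tidyr::pivot_wider(as_tibble(x)[, c("stage", "metric", "raw")],
    names_from = "metric", values_from = "raw")
  wide
}

#' @exportS3Method ggplot2::autoplot
autoplot.woe_metrics <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$metric, y = .data$raw)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$rounded), vjust = -0.3) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
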