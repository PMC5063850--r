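test_that("contingency summaries place categories in the right cells", {
  a <- test_assignments()
  his <- summarize_contingency(a, "histopathological")
  expect_equal(unlist(his[, c("tp", "fp", "fn", "tn")]),
    c(tp = 31L, fp = 19L, fn = 96L, tn = 143L))
  expect_equal(his$nt + his$nc, 0L)

  ph <- summarize_contingency(a, "pharmacological")
  expect_equal(unlist(ph[, c("tp", "tn", "nt", "nc")]),
    c(tp = 62L, tn = 192L, nt = 21L, nc = 14L))

  fin <- summarize_contingency(a, "final")
  expect_equal(unlist(fin[, c("tp", "fp", "fn", "tn")]),
    c(tp = 67L, fp = 1L, fn = 17L, tn = 204L))
  expect_equal(fin$total, 289L)

  empty <- summarize_contingency(a[0, ], "final")
  expect_equal(empty$total, 0L)
  expect_error(summarize_contingency(test_compounds(), "final"),
    class = "woe_schema_error")
})

test_that("the five predictivity statistics reproduce the printed values", {
  a <- test_assignments()
  m <- compute_metrics(summarize_contingency(a, "histopathological"))
  get <- function(what, col = "rounded") m[[col]][m$metric == what]
  expect_equal(get("negative_predictivity", "raw"), 100 * 143 / 239,
    tolerance = 1e-12)
  expect_equal(get("negative_predictivity"), 60)
  expect_equal(get("positive_predictivity"), 62)
  expect_equal(get("sensitivity"), 24)
  expect_equal(get("specificity"), 88)
  expect_equal(get("fn_fraction"), 33)

  # pharmacological stage: NT in the FP slot, NC in the FN slot
  mp <- compute_metrics(summarize_contingency(a, "pharmacological"))
  getp <- function(what, col = "rounded") mp[[col]][mp$metric == what]
  expect_equal(getp("negative_predictivity"), 93)
  expect_equal(getp("positive_predictivity"), 75)
  expect_equal(getp("sensitivity"), 82)
  expect_equal(getp("specificity"), 90)
  expect_equal(getp("fn_fraction"), 5)
  expect_equal(getp("sensitivity", "raw"), 100 * 62 / 76, tolerance = 1e-12)
})

test_that("zero denominators yield undefined markers, not errors", {
  cs <- tibble::tibble(stage = "final", tp = 0L, fp = 0L, fn = 0L,
    tn = 10L, nt = 0L, nc = 0L, total = 10L)
  class(cs) <- c("woe_contingency", class(cs))
  m <- compute_metrics(cs)
  get <- function(what) m[m$metric == what, ]
  expect_equal(get("negative_predictivity")$raw, 100)
  expect_equal(get("specificity")$raw, 100)
  expect_true(get("sensitivity")$undefined)
  expect_true(get("positive_predictivity")$undefined)
  expect_true(is.na(get("sensitivity")$raw))
})

test_that("metrics are invariant under record permutation", {
  a <- test_assignments()
  base <- compute_metrics(summarize_contingency(a, "final"))
  for (seed in 1:3) {
    set.seed(seed)
    perm <- a[sample.int(nrow(a)), ]
    expect_equal(compute_metrics(summarize_contingency(perm, "final")), base)
  }
})

test_that("rounding mode is configurable and halves round away from zero", {
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  a <- test_assignments()
  fin <- summarize_contingency(a, "final")
  half <- compute_metrics(fin, rounding = "half_away")
  flr <- compute_metrics(fin, rounding = "floor")
  ppv <- function(m) m$rounded[m$metric == "positive_predictivity"]
  spc <- function(m) m$rounded[m$metric == "specificity"]
  # raw 98.53 / 99.51: nearest-integer gives 99/100, floor the printed 98/99
  expect_equal(ppv(half), 99)
  expect_equal(ppv(flr), 98)
  expect_equal(spc(flr), 99)
  raw <- compute_metrics(fin, rounding = "none")
  expect_equal(raw$raw, raw$rounded)
})
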