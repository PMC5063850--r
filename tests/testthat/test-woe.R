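test_that("the combination rule lets decisive pharmacology win", {
  a <- test_assignments()
  pick <- function(id) a$cat_final[a$compound_id == id]
  expect_equal(pick(206), "TN") # FN + TN -> TN
  expect_equal(pick(231), "FN") # FN + NT -> histopathology retained
  expect_equal(pick(144), "TP") # FP + TP -> TP
  expect_equal(pick(184), "TN") # override (would be TP via histopathology)
  expect_equal(pick(161), "TP") # override (would be TN via pharmacology)
  expect_match(a$fired_rule_final[a$compound_id == 184], "override")
})

test_that("the combination rule is total on the category product", {
  grid <- tidyr::expand_grid(
    cat_his = c("TP", "FP", "FN", "TN"),
    cat_ph = c("TP", "TN", "NT", "NC")
  )
  grid$compound_id <- seq_len(nrow(grid))
  no_ovr <- tibble::tibble(compound_id = integer(),
    forced_final = character(), rationale = character())
  out <- combine_final(grid, overrides = no_ovr)
  expect_equal(nrow(out), 16L)
  decisive <- out$cat_ph %in% c("TP", "TN")
  expect_equal(out$cat_final[decisive], out$cat_ph[decisive])
  expect_equal(out$cat_final[!decisive], out$cat_his[!decisive])

  bad <- grid
  bad$cat_ph[1] <- "FP"
  expect_error(combine_final(bad, overrides = no_ovr),
    class = "woe_schema_error")
})

test_that("exactly the two override rows deviate from the closed-form rule", {
  a <- test_assignments()
  plain <- ifelse(a$cat_ph %in% c("TP", "TN"), a$cat_ph, a$cat_his)
  dev <- a$compound_id[plain != a$cat_final]
  expect_equal(sort(dev), c(161L, 184L))
})

test_that("final categories match the published table and counts", {
  a <- test_assignments()
  expect_equal(sum(a$cat_final == a$cat_final_published), 289L)
  counts <- table(a$cat_final)
  expect_equal(counts[["TP"]], 67L)
  expect_equal(counts[["FP"]], 1L)
  expect_equal(counts[["FN"]], 17L)
  expect_equal(counts[["TN"]], 204L)
})

test_that("false negatives partition by tumor human-relevance", {
  ref <- refine_false_negatives(test_assignments(), kb = test_kb())
  expect_equal(nrow(ref), 96L)
  pick <- function(id) ref$bucket[ref$compound_id == id]
  expect_equal(pick(239), "not_human_relevant_tumors") # adr bpha only
  expect_equal(pick(263), "human_relevant_tumors") # kid ac
  expect_equal(sum(ref$bucket == "not_human_relevant_tumors"), 77L)
  # flagged compounds have no relevant tumor findings at all
  nr <- ref[ref$bucket == "not_human_relevant_tumors", ]
  expect_true(all(nr$n_relevant == 0L))
})

test_that("the peroxisome-proliferator flag voids liver-tumor relevance", {
  kb <- test_kb()
  # rule set in which hepatocellular tumors count as relevant
  kb$relevance <- kb$relevance[kb$relevance$organ != "li", ]
  rec <- dplyr::bind_rows(
    make_record(compound_id = 1L, tum = "li ac", pp = TRUE),
    make_record(compound_id = 2L, tum = "li ac", pp = FALSE)
  ) |> categorize_histopathology()
  ref <- refine_false_negatives(rec, kb = kb)
  expect_equal(ref$bucket[ref$compound_id == 1], "not_human_relevant_tumors")
  expect_equal(ref$bucket[ref$compound_id == 2], "human_relevant_tumors")
})

test_that("moving compounds between FN buckets touches no TP or FP count", {
  res <- run_pipeline(test_compounds(), kb = test_kb())
  base <- res$contingency
  # the post-filter variants re-score only FN compounds
  for (variant in unique(res$post_filter$stage)) {
    m <- res$post_filter[res$post_filter$stage == variant, ]
    expect_false(any(m$undefined[m$metric %in%
      c("negative_predictivity", "specificity")]))
  }
  his <- base[base$stage == "histopathological", ]
  expect_equal(his$tp, 31L)
  expect_equal(his$fp, 19L)
})
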