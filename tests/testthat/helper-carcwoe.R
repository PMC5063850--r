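# knowledge base and reference dataset are loaded once per test run
.cache <- new.env(parent = emptyenv())

test_kb <- function() {
  if (is.null(.cache$kb)) .cache$kb <- load_knowledge_base()
  .cache$kb
}

test_compounds <- function() {
  if (is.null(.cache$compounds)) {
    .cache$compounds <- woe_compounds(kb = test_kb())
  }
  .cache$compounds
}

# full three-stage assignment table for the reference dataset
test_assignments <- function() {
  if (is.null(.cache$assignments)) {
    .cache$assignments <- test_compounds() |>
      categorize_histopathology() |>
      assign_pharm_category(kb = test_kb()) |>
      combine_final(overrides = test_kb()$overrides) |>
      organ_concordance()
  }
  .cache$assignments
}

# small hand-built compound rows for targeted cases
make_record <- function(compound_id = 1L, hp = "", tum = "", wt = "",
                        ht = "", class_id = "sim_class_01", single = FALSE,
                        pp = FALSE) {
  tibble::tibble(
    compound_id = as.integer(compound_id),
    mode_of_action = "ZZ, synthetic",
    therapeutic_area = "ZZ",
    pharm_class_id = class_id,
    single_in_class = single,
    weight_findings = wt,
    hypertrophy_findings = ht,
    hyperplasia_findings = hp,
    tumor_findings = tum,
    cat_his_published = "",
    cat_ph_published = "",
    cat_final_published = "",
    peroxisome_proliferator = pp
  )
}
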