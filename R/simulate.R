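# Synthetic compound generator. Emulates the categorical structure of the
# reference dataset — compounds grouped in pharmacological classes, rat
# carcinogenicity drawn per class, subchronic hyperplasia generated
# conditionally on carcinogenicity with configurable sensitivity and
# false-positive rate, tumor types drawn from human-relevant versus
# non-relevant pools — so every pipeline stage is testable without the
# fixture and stage-1 parameter recovery can be demonstrated. It simulates
# no pharmacokinetics, doses or mechanisms.

# token pools default to codes observed in the reference dataset
.sim_nonrelevant_pool <- c(
  "tes ad", "adr bpha", "pit ad", "thyr ad", "pan ad", "mam fad",
  "ut polyp", "li ad", "islet ad", "stom SCP"
)
.sim_relevant_pool <- c(
  "kid ac", "ut ac", "col ac", "skin sar", "zymgl ca", "ln lymph",
  "soft t sar"
)
.sim_organ_pool <- c(
  "li", "kid", "thyr", "adr", "hrt", "spl", "tes", "ova", "pit", "lu",
  "stom", "mam", "pan", "br"
)

#' Simulation configuration
#'
#' Builds and validates the parameter set of the synthetic compound
#' generator. The defaults are the empirical conditions of the reference
#' dataset: 44% of compounds carcinogenic, stage-1 hyperplasia sensitivity
#' 24% and false-positive rate 12%, hyperplasia organ matching a tumor organ
#' with probability 0.42, 80% of tumor draws taken from the non-human-
#' relevant pool, hypertrophy and organ-weight finding rates 23% and 26%.
#'
#' @param n_classes Number of pharmacological classes.
#' @param class_size Integer vector `c(min, max)` of members per class.
#' @param carcinogen_prob Probability that a compound is a rat carcinogen;
#'   either a scalar or one value per class.
#' @param hyperplasia_sensitivity Probability that a carcinogen shows
#'   subchronic hyperplasia.
#' @param hyperplasia_fpr Probability that a non-carcinogen shows subchronic
#'   hyperplasia.
#' @param same_organ_prob Probability that a carcinogen's hyperplasia organ
#'   is drawn from its tumor organs (organ concordance).
#' @param nonrelevant_tumor_fraction Fraction of tumor draws taken from the
#'   non-human-relevant tumor-type pool.
#' @param hypertrophy_rate,weight_finding_rate Per-compound probabilities of
#'   hypertrophy and organ-weight findings.
#' @param seed Integer seed; a fixed seed makes the output fully
#'   reproducible.
#' @return A validated list of class `"woe_sim_config"`.
#' @export
simulation_config <- function(n_classes = 60,
                              class_size = c(1L, 8L),
                              carcinogen_prob = 0.44,
                              hyperplasia_sensitivity = 0.24,
                              hyperplasia_fpr = 0.12,
                              same_organ_prob = 0.42,
                              nonrelevant_tumor_fraction = 0.80,
                              hypertrophy_rate = 0.23,
                              weight_finding_rate = 0.26,
                              seed = 1L) {
  cfg <- list(
    n_classes = as.integer(n_classes), class_size = as.integer(class_size),
    carcinogen_prob = carcinogen_prob,
    hyperplasia_sensitivity = hyperplasia_sensitivity,
    hyperplasia_fpr = hyperplasia_fpr,
    same_organ_prob = same_organ_prob,
    nonrelevant_tumor_fraction = nonrelevant_tumor_fraction,
    hypertrophy_rate = hypertrophy_rate,
    weight_finding_rate = weight_finding_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_classes < 1L) {
    abort("n_classes must be >= 1", class = "woe_invalid_config")
  }
  if (length(cfg$class_size) != 2L || any(cfg$class_size < 1L) ||
    cfg$class_size[1] > cfg$class_size[2]) {
    abort("class_size must be c(min, max) with 1 <= min <= max",
      class = "woe_invalid_config")
  }
  fracs <- c(cfg$carcinogen_prob, cfg$hyperplasia_sensitivity,
    cfg$hyperplasia_fpr, cfg$same_organ_prob,
    cfg$nonrelevant_tumor_fraction, cfg$hypertrophy_rate,
    cfg$weight_finding_rate)
  if (any(!is.finite(fracs)) || any(fracs < 0 | fracs > 1)) {
    abort("all probabilities must lie in [0, 1]",
      class = "woe_invalid_config")
  }
  if (!length(cfg$carcinogen_prob) %in% c(1L, cfg$n_classes)) {
    abort("carcinogen_prob must be a scalar or one value per class",
      class = "woe_invalid_config")
  }
  structure(cfg, class = "woe_sim_config")
}

#' Generate a synthetic compound dataset
#'
#' Draws a compound table with the same schema as the reference dataset.
#' Class sizes are uniform on the configured range; carcinogenicity is
#' Bernoulli per compound (rate per class if a vector was given); carcinogens
#' receive one to three tumor findings from the relevant/non-relevant pools;
#' hyperplasia is present with probability `hyperplasia_sensitivity` for
#' carcinogens and `hyperplasia_fpr` otherwise, its organ matched to a tumor
#' organ with probability `same_organ_prob`. Published-category columns are
#' left empty. All randomness flows from `cfg$seed`; the caller's RNG state
#' is untouched.
#'
#' @param cfg A [simulation_config()].
#' @return A compound tibble accepted by every pipeline stage.
#' @export
#' @examples
#' sim <- simulate_compounds(simulation_config(n_classes = 5, seed = 42))
#' sim |> categorize_histopathology() |> dplyr::count(cat_his)
simulate_compounds <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "woe_sim_config")) {
    cfg <- do.call(simulation_config, as.list(cfg))
  }
  .with_seed(cfg$seed, {
    sizes <- sample(seq(cfg$class_size[1], cfg$class_size[2]),
      cfg$n_classes, replace = TRUE)
    n <- sum(sizes)
    class_idx <- rep(seq_len(cfg$n_classes), sizes)
    p_carc <- rep_len(cfg$carcinogen_prob, cfg$n_classes)[class_idx]
    carcinogen <- stats::runif(n) < p_carc

    draw_tumors <- function(is_carc) {
      if (!is_carc) return("")
      k <- sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
      pool_nr <- stats::runif(k) < cfg$nonrelevant_tumor_fraction
      toks <- ifelse(pool_nr,
        sample(.sim_nonrelevant_pool, k, replace = TRUE),
        sample(.sim_relevant_pool, k, replace = TRUE))
      paste(toks, collapse = "; ")
    }
    tumors <- vapply(carcinogen, draw_tumors, character(1))

    hp_present <- stats::runif(n) <
      ifelse(carcinogen, cfg$hyperplasia_sensitivity, cfg$hyperplasia_fpr)
    hyperplasia <- vapply(seq_len(n), function(i) {
      if (!hp_present[i]) return("")
      tum_org <- unique(parse_finding_list(tumors[i])$organ)
      if (length(tum_org) > 0 && stats::runif(1) < cfg$same_organ_prob) {
        sample(tum_org, 1)
      } else {
        sample(setdiff(.sim_organ_pool, tum_org), 1)
      }
    }, character(1))

    draw_organs <- function(present) {
      vapply(present, function(p) {
        if (!p) return("")
        paste(sample(.sim_organ_pool, sample(1:3, 1)), collapse = "; ")
      }, character(1))
    }
    hypertrophy <- draw_organs(stats::runif(n) < cfg$hypertrophy_rate)
    weights <- draw_organs(stats::runif(n) < cfg$weight_finding_rate)

    tibble(
      compound_id = seq_len(n),
      mode_of_action = sprintf("ZZ, simulated class %02d", class_idx),
      therapeutic_area = "ZZ",
      pharm_class_id = sprintf("sim_class_%02d", class_idx),
      single_in_class = FALSE,
      weight_findings = weights,
      hypertrophy_findings = hypertrophy,
      hyperplasia_findings = hyperplasia,
      tumor_findings = tumors,
      cat_his_published = "",
      cat_ph_published = "",
      cat_final_published = "",
      peroxisome_proliferator = FALSE,
      carcinogen = carcinogen
    )
  })
}
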