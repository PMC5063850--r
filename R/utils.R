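# shared helpers: rounding, seeded evaluation, path to packaged knowledge base

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero (so 0.5 becomes
#' 1 and -0.5 becomes -1), unlike [base::round()] which rounds half to even.
#' This is the convention used for the reported predictivity percentages.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_away(c(59.83, 24.4, 98.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# apply the selected rounding convention to a percentage
.round_pct <- function(x, rounding = c("half_away", "floor", "none")) {
  rounding <- match.arg(rounding)
  switch(rounding,
    half_away = round_half_away(x),
    floor = floor(x),
    none = x
  )
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "woe_invalid_config")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# path to a packaged knowledge-base file
.kb_file <- function(name) {
  path <- system.file("extdata", name, package = "carcwoe")
  if (!nzchar(path)) {
    abort(paste0("packaged knowledge-base file not found: ", name),
      class = "woe_schema_error"
    )
  }
  path
}

.read_kb_csv <- function(path, required) {
  if (!file.exists(path)) {
    abort(paste0("file does not exist: ", path), class = "woe_schema_error")
  }
  out <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
    progress = FALSE, show_col_types = FALSE, na = character())
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(
      paste0("missing required column(s) in ", basename(path), ": ",
        paste(missing, collapse = ", ")),
      class = "woe_schema_error"
    )
  }
  out
}

.assert_unique <- function(x, what, file) {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    abort(
      paste0("duplicate ", what, " in ", file, ": ",
        paste(dup, collapse = ", ")),
      class = "woe_duplicate_code"
    )
  }
  invisible(x)
}
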