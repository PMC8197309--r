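#' trajcvd: trajectory clustering of cardiovascular risk factors
#'
#' Tools to reproduce a longitudinal worker-cohort analysis of cardiovascular
#' risk factors (CVRFs): cohort simulation, trajectory imputation, SCORE risk,
#' smoking-status Markov projection, joint multivariate trajectory k-means and
#' descriptive characterization.
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordered smoking states
#'
#' The three self-reported smoking categories, in the fixed order used by all
#' transition matrices in the package.
#'
#' @return Character vector `c("smoker", "non-smoker", "ex-smoker")`.
#' @export
smoking_states <- function() c("smoker", "non-smoker", "ex-smoker")

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Canonicalize smoking labels; unknown non-missing labels are an error.
normalize_smoking_labels <- function(x) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[_ ]+", "-", y)
  map <- c(
    "smoker" = "smoker", "current-smoker" = "smoker",
    "non-smoker" = "non-smoker", "nonsmoker" = "non-smoker",
    "never-smoker" = "non-smoker",
    "ex-smoker" = "ex-smoker", "exsmoker" = "ex-smoker",
    "former-smoker" = "ex-smoker"
  )
  out <- unname(map[y])
  missing_in <- is.na(x) | y == ""
  bad <- !missing_in & is.na(out)
  if (any(bad)) {
    stop("unknown smoking status label(s): ",
         paste(unique(y[bad]), collapse = ", "))
  }
  out[missing_in] <- NA_character_
  out
}

# Columns of a visit record that hold physiological measurements.
measure_columns <- function() {
  c("age", "sbp", "dbp", "weight", "height", "wc", "bmi",
    "hdl", "total_chol", "glucose", "score")
}

record_columns <- function() {
  c("individual_id", "time_point", "sex", measure_columns(), "smoking")
}
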