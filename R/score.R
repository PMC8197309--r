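# Ten-year SCORE cardiovascular risk (Weibull survival equations) and the
# smoking-status Markov machinery.

.score_coeff_md5 <- "b863a5adc14673fe2e4dc45329c6e12b"

#' SCORE Weibull coefficients
#'
#' Loads the coefficient set of the SCORE ten-year fatal cardiovascular risk
#' equations: per cause (coronary heart disease, non-CHD cardiovascular
#' disease) and sex, a Weibull baseline (`alpha`, `p`) with
#' `S0(a) = exp(-exp(alpha) * (a - 20)^p)`, and log-hazard-ratio coefficients
#' for total cholesterol (per mmol/L above 6), systolic blood pressure (per
#' mmHg above 120) and current smoking. The low-risk European calibration is
#' the default; the high-risk calibration is selectable. Coefficients live in
#' an editable CSV so they can be audited or replaced; the shipped copy is
#' guarded by a checksum.
#'
#' @param region `"low"` (default) or `"high"` risk calibration.
#' @param file Optional path to a replacement coefficient CSV with the same
#'   columns as the shipped file.
#' @return Data frame of class `score_coefficients` with columns `cause`,
#'   `sex`, `alpha`, `p`, `beta_chol`, `beta_sbp`, `beta_smoker`.
#' @export
score_coefficients <- function(region = c("low", "high"), file = NULL) {
  region <- match.arg(region)
  shipped <- is.null(file)
  if (shipped) {
    file <- system.file("extdata", "score_coefficients.csv",
                        package = "trajcvd", mustWork = TRUE)
    if (unname(tools::md5sum(file)) != .score_coeff_md5) {
      warning("shipped SCORE coefficient file does not match its checksum; ",
              "it appears to have been edited")
    }
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("region", "cause", "sex", "alpha", "p",
            "beta_chol", "beta_sbp", "beta_smoker")
  if (!all(need %in% names(tab))) {
    stop("coefficient file must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[tab$region == region, setdiff(need, "region"), drop = FALSE]
  if (!nrow(tab)) stop("no coefficients for region '", region, "'")
  if (any(tab$p <= 0)) stop("Weibull power p must be positive")
  rownames(tab) <- NULL
  structure(tab, class = c("score_coefficients", "data.frame"))
}

#' Conversion constant for total cholesterol
#'
#' mg/dL divided by 38.67 gives mmol/L.
#' @return The constant 38.67.
#' @export
chol_mgdl_per_mmol <- function() 38.67

.weibull_s0 <- function(age, alpha, p) {
  exp(-exp(alpha) * pmax(age - 20, 0)^p)
}

#' Ten-year SCORE cardiovascular risk
#'
#' Evaluates the SCORE equations: for each cause, the baseline survival
#' `S0(a) = exp(-exp(alpha) (a - 20)^p)` is raised to `exp(w)` with
#' `w = beta_chol (chol - 6) + beta_sbp (SBP - 120) + beta_smoker smoker`,
#' the ten-year risk is `1 - S(a + 10)/S(a)`, and the CHD and non-CHD risks
#' are summed, clamped to \[0, 1\] and returned as a percentage.
#'
#' @param age Age in years. The model domain starts at 30; younger ages are
#'   computed anyway with a warning (ages below 20 are floored at 20, where
#'   baseline risk is zero).
#' @param sbp Systolic blood pressure, mmHg.
#' @param total_chol Total cholesterol, in the unit named by `chol_unit`.
#' @param smoker Logical: current smoker.
#' @param coeffs A [score_coefficients()] table.
#' @param sex `"male"` or `"female"` (recycled).
#' @param chol_unit `"mg/dL"` (default; converted by 38.67) or `"mmol/L"`.
#' @return Numeric vector of ten-year risks in percent, in \[0, 100\].
#' @examples
#' score_risk(55, 140, 6.5, smoker = TRUE, chol_unit = "mmol/L")  # ~4.6
#' @export
score_risk <- function(age, sbp, total_chol, smoker,
                       coeffs = score_coefficients(), sex = "male",
                       chol_unit = c("mg/dL", "mmol/L")) {
  chol_unit <- match.arg(chol_unit)
  n <- max(length(age), length(sbp), length(total_chol), length(smoker),
           length(sex))
  age <- rep_len(age, n); sbp <- rep_len(sbp, n)
  total_chol <- rep_len(total_chol, n)
  smoker <- rep_len(as.logical(smoker), n)
  sex <- rep_len(tolower(sex), n)
  if (any(!sex %in% c("male", "female"))) stop("sex must be male or female")
  if (any(!is.na(age) & age < 30)) {
    warning("age(s) below 30 are outside the SCORE model domain; ",
            "computed anyway")
  }
  chol <- if (chol_unit == "mg/dL") total_chol / chol_mgdl_per_mmol() else
    total_chol

  total <- numeric(n)
  miss <- is.na(age) | is.na(sbp) | is.na(chol) | is.na(smoker)
  for (cause in c("chd", "non_chd")) {
    for (sx in unique(sex)) {
      row <- coeffs[coeffs$cause == cause & coeffs$sex == sx, , drop = FALSE]
      if (nrow(row) != 1L) {
        stop(sprintf("missing coefficient entry for cause '%s', sex '%s'",
                     cause, sx))
      }
      i <- which(sex == sx & !miss)
      if (!length(i)) next
      w <- row$beta_chol * (chol[i] - 6) + row$beta_sbp * (sbp[i] - 120) +
        row$beta_smoker * smoker[i]
      s_now <- .weibull_s0(age[i], row$alpha, row$p)^exp(w)
      s_ten <- .weibull_s0(age[i] + 10, row$alpha, row$p)^exp(w)
      total[i] <- total[i] + (1 - s_ten / pmax(s_now, .Machine$double.xmin))
    }
  }
  total[miss] <- NA_real_
  100 * pmin(pmax(total, 0), 1)
}

#' Dichotomized smoking status
#'
#' SCORE distinguishes only current smokers from everyone else: ex-smokers
#' count as non-smokers.
#'
#' @param status Character vector of smoking labels (case and punctuation
#'   variants are normalized); `NA` passes through.
#' @return Logical vector: `TRUE` for current smokers.
#' @export
smoker_binary <- function(status) {
  normalize_smoking_labels(status) == "smoker"
}

#' Estimate the smoking transition matrix
#'
#' Row-stochastic transition probabilities between the three smoking states,
#' estimated from the individuals observed at both of two visits by simple
#' transition counts. An origin state with no observations gets an identity
#' row, with a warning.
#'
#' @param cohort A `cohort_table` with smoking observed at both visits for at
#'   least part of the cohort.
#' @param from_t,to_t The paired time points (defaults 1 and 2).
#' @return Object of class `smoking_transition`: list with the 3x3 matrix
#'   `matrix` (rows = origin states) and `n_from`, the origin-state counts.
#' @export
estimate_transition <- function(cohort, from_t = 1, to_t = 2) {
  stopifnot(inherits(cohort, "cohort_table"))
  rec <- cohort$records
  states <- smoking_states()
  a <- rec[rec$time_point == from_t, c("individual_id", "smoking")]
  b <- rec[rec$time_point == to_t, c("individual_id", "smoking")]
  m <- merge(a, b, by = "individual_id", suffixes = c("_from", "_to"))
  m <- m[!is.na(m$smoking_from) & !is.na(m$smoking_to), , drop = FALSE]
  counts <- table(factor(m$smoking_from, levels = states),
                  factor(m$smoking_to, levels = states))
  n_from <- rowSums(counts)
  P <- matrix(0, 3, 3, dimnames = list(states, states))
  for (i in seq_along(states)) {
    if (n_from[i] == 0) {
      warning(sprintf("no observed transitions from state '%s'; using an identity row",
                      states[i]))
      P[i, i] <- 1
    } else {
      P[i, ] <- counts[i, ] / n_from[i]
    }
  }
  structure(list(matrix = P, n_from = n_from), class = "smoking_transition")
}

#' @export
print.smoking_transition <- function(x, ...) {
  cat("Smoking transition matrix (rows = origin state):\n")
  print(round(x$matrix, 4))
  cat("origin counts:", paste(x$n_from, collapse = ", "), "\n")
  invisible(x)
}

#' Project smoking status forward
#'
#' Draws each individual's status at a later visit from the transition row of
#' their current state, assuming stationary smoking behaviour. Projection is
#' by sampling, not by the modal state, so the projected marginal converges to
#' `marginal x P`. Individuals missing the origin status fall back to the
#' earlier visit's status.
#'
#' @param cohort A `cohort_table` with a complete individual-by-time grid
#'   (run [impute_cohort()] first so target rows exist).
#' @param transition A `smoking_transition` (or bare row-stochastic matrix).
#' @param seed Integer seed for the projection draws.
#' @param from_t Origin time point (default 2).
#' @param to_t Target time point to fill (default 3).
#' @param fallback_t Fallback origin when `from_t` is missing (default 1).
#' @return The cohort with `smoking` at `to_t` filled and flagged in
#'   `smoking_imputed`.
#' @export
project_smoking <- function(cohort, transition, seed = 1, from_t = 2,
                            to_t = 3, fallback_t = 1) {
  stopifnot(inherits(cohort, "cohort_table"))
  P <- if (inherits(transition, "smoking_transition")) transition$matrix else
    transition
  states <- smoking_states()
  stopifnot(all(dim(P) == c(3, 3)), all(abs(rowSums(P) - 1) < 1e-8))
  rec <- cohort$records
  if (is.null(rec$smoking_imputed)) rec$smoking_imputed <- FALSE

  status_at <- function(t) {
    s <- rec$smoking[rec$time_point == t]
    names(s) <- rec$individual_id[rec$time_point == t]
    s
  }
  ids <- sort(unique(rec$individual_id))
  origin <- status_at(from_t)[ids]
  fb <- status_at(fallback_t)[ids]
  use_fb <- is.na(origin) & !is.na(fb)
  origin[use_fb] <- fb[use_fb]
  if (anyNA(origin)) {
    stop("individual(s) with no smoking status at either origin visit: ",
         names(origin)[is.na(origin)][1])
  }

  target_idx <- match(paste(ids, to_t), paste(rec$individual_id, rec$time_point))
  if (anyNA(target_idx)) {
    stop("target time point rows missing; run impute_cohort() first")
  }
  needs <- is.na(rec$smoking[target_idx])
  drawn <- with_seed(seed, {
    u <- stats::runif(length(ids))
    cum <- t(apply(P, 1, cumsum))
    states[sapply(seq_along(ids), function(i) {
      findInterval(u[i], cum[origin[i], ], left.open = TRUE) + 1L
    })]
  })
  rec$smoking[target_idx[needs]] <- drawn[needs]
  rec$smoking_imputed[target_idx[needs]] <- TRUE
  cohort$records <- rec
  cohort
}

#' Carry smoking status across the observed visits
#'
#' Fills a missing smoking status at one of the early visits from the other
#' observed early visit (a worker who missed the first test keeps the status
#' reported at the second, and vice versa). Filled cells are flagged in
#' `smoking_imputed`. The third visit is never touched here: it is projected
#' by [project_smoking()].
#'
#' @param cohort A `cohort_table` with a complete individual-by-time grid.
#' @param times The visits to complete among themselves (default `c(1, 2)`).
#' @return The cohort with smoking carried and flagged.
#' @export
carry_smoking <- function(cohort, times = c(1, 2)) {
  stopifnot(inherits(cohort, "cohort_table"), length(times) >= 2)
  rec <- cohort$records
  if (is.null(rec$smoking_imputed)) rec$smoking_imputed <- FALSE
  for (t in times) {
    idx <- which(rec$time_point == t & is.na(rec$smoking))
    if (!length(idx)) next
    others <- setdiff(times, t)
    for (o in others[order(abs(others - t))]) {
      donor_rows <- rec$time_point == o & !is.na(rec$smoking)
      donor <- stats::setNames(rec$smoking[donor_rows],
                               rec$individual_id[donor_rows])
      fill <- donor[rec$individual_id[idx]]
      ok <- !is.na(fill)
      rec$smoking[idx[ok]] <- fill[ok]
      rec$smoking_imputed[idx[ok]] <- TRUE
      idx <- idx[!ok]
      if (!length(idx)) break
    }
  }
  cohort$records <- rec
  cohort
}

#' Attach the computed SCORE to every visit
#'
#' Evaluates [score_risk()] per record from that visit's age, systolic blood
#' pressure, total cholesterol and (observed or projected) smoking status.
#' A `score` column and, when imputation flags are present, an
#' `imputed_score` flag (true when any SCORE input at that visit was imputed
#' or projected) are added.
#'
#' @param cohort A `cohort_table` with complete age, sbp, total_chol and
#'   smoking.
#' @param coeffs A [score_coefficients()] table.
#' @return The cohort with `score` filled per record.
#' @export
add_score <- function(cohort, coeffs = score_coefficients()) {
  stopifnot(inherits(cohort, "cohort_table"))
  rec <- cohort$records
  sex <- ifelse(is.na(rec$sex), "male", tolower(rec$sex))
  rec$score <- suppressWarnings(score_risk(
    rec$age, rec$sbp, rec$total_chol, smoker_binary(rec$smoking),
    coeffs = coeffs, sex = sex, chol_unit = "mg/dL"
  ))
  flag <- rep(FALSE, nrow(rec))
  for (col in c("imputed_age", "imputed_sbp", "imputed_total_chol",
                "smoking_imputed")) {
    if (!is.null(rec[[col]])) flag <- flag | (rec[[col]] %in% TRUE)
  }
  rec$imputed_score <- flag
  cohort$records <- rec
  cohort
}
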