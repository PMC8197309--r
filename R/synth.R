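# Synthetic cohort generator: two latent risk-profile groups, Gaussian copula
# cross-sectional dependence, random-intercept trajectory persistence,
# three-state smoking Markov chain, attendance-driven missingness.

synth_variables <- function() {
  c("wc", "bmi", "hdl", "glucose", "sbp", "total_chol", "dbp")
}

.default_means <- function() {
  # [cluster, time, variable]; cluster 1 is the leaner/younger profile.
  # sbp and total_chol means are calibrated (analysis/00_calibrate_score.R) so
  # that the SCORE computed from generated age/SBP/cholesterol/smoking lands
  # on the target cluster-wise SCORE means.
  m <- array(NA_real_, c(2, 3, 7),
             dimnames = list(NULL, NULL, synth_variables()))
  m[1, , "wc"] <- c(90.5, 90.6, 91.2);   m[2, , "wc"] <- c(103, 104, 105)
  m[1, , "bmi"] <- c(25.3, 25.4, 25.6);  m[2, , "bmi"] <- c(30.0, 30.2, 30.4)
  m[1, , "hdl"] <- c(55.0, 56.8, 54.1);  m[2, , "hdl"] <- c(49.9, 50.9, 48.9)
  m[1, , "glucose"] <- c(92.9, 91.0, 83.4)
  m[2, , "glucose"] <- c(103.0, 102.0, 96.5)
  m[1, , "sbp"] <- c(123.0, 124.0, 123.2)
  m[2, , "sbp"] <- c(134.1, 133.65, 134.2)
  m[1, , "total_chol"] <- c(205, 199, 182)
  m[2, , "total_chol"] <- c(219, 213, 194)
  m[1, , "dbp"] <- c(81.0, 77.5, 79.0);  m[2, , "dbp"] <- c(86.0, 82.2, 83.9)
  m
}

.default_sds <- function() {
  s <- array(NA_real_, c(2, 3, 7),
             dimnames = list(NULL, NULL, synth_variables()))
  s[1, , "wc"] <- c(6.80, 6.61, 7.31);   s[2, , "wc"] <- c(7.72, 8.06, 8.97)
  s[1, , "bmi"] <- c(2.30, 2.25, 2.41);  s[2, , "bmi"] <- c(3.04, 3.22, 3.49)
  s[1, , "hdl"] <- c(11.3, 11.8, 13.4);  s[2, , "hdl"] <- c(9.94, 9.96, 11.8)
  s[1, , "glucose"] <- c(11.7, 11.5, 11.7)
  s[2, , "glucose"] <- c(22.9, 24.1, 26.7)
  s[1, , "sbp"] <- c(13.5, 13.5, 14.0);  s[2, , "sbp"] <- c(14.0, 14.0, 15.0)
  s[1, , "total_chol"] <- c(36, 33, 31); s[2, , "total_chol"] <- c(36, 33, 31)
  s[1, , "dbp"] <- c(9.5, 9.1, 9.4);     s[2, , "dbp"] <- c(9.5, 9.2, 9.4)
  s
}

.default_corr_within <- function() {
  v <- c(synth_variables(), "age")
  C <- diag(length(v)); dimnames(C) <- list(v, v)
  set <- function(a, b, r) {
    C[a, b] <<- r; C[b, a] <<- r
  }
  # wc/bmi/hdl pairs are overwritten at generation time by the mixture solve
  set("wc", "bmi", 0.78)
  set("wc", "hdl", -0.08); set("bmi", "hdl", -0.08)
  set("glucose", "wc", 0.20); set("glucose", "bmi", 0.20)
  set("glucose", "hdl", -0.10)
  set("sbp", "wc", 0.22); set("sbp", "bmi", 0.22)
  set("sbp", "hdl", -0.05); set("sbp", "glucose", 0.15)
  set("total_chol", "wc", 0.10); set("total_chol", "bmi", 0.10)
  set("total_chol", "hdl", 0.15); set("total_chol", "glucose", 0.10)
  set("total_chol", "sbp", 0.12)
  set("dbp", "wc", 0.18); set("dbp", "bmi", 0.18)
  set("dbp", "hdl", -0.03); set("dbp", "glucose", 0.10)
  set("dbp", "sbp", 0.70); set("dbp", "total_chol", 0.10)
  # age enters only through the shared individual intercept; its entries are
  # inflated by 1/sqrt(rho) at build time so cross-sectional correlations hit
  # the stated values.
  set("age", "wc", 0.10); set("age", "bmi", 0.05)
  set("age", "glucose", 0.15); set("age", "sbp", 0.20)
  set("age", "total_chol", 0.20); set("age", "dbp", 0.10)
  C
}

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions the analysis assumes: a cohort of
#' 4147 men split into two latent risk-profile groups of 2099 and 2048, with
#' the cluster-stratified per-visit means/SDs of the six clustered variables
#' (age, WC, BMI, glucose, HDL, and the SCORE drivers SBP/total cholesterol),
#' cohort-level cross-sectional correlations corr(WC,BMI) = 0.87 and
#' corr(HDL,BMI) = corr(WC,HDL) = -0.21, a within-person random-intercept
#' persistence share `rho = 0.8`, a three-state smoking Markov chain whose
#' first-visit marginal is 36.82/26.90/36.28 percent smoker/non-smoker/
#' ex-smoker, attendance-driven visit missingness with every individual
#' keeping at least two visits, and cluster-dependent cardiovascular event
#' rates.
#'
#' @param n Cohort size; the two latent groups keep the default 2099:2048
#'   proportions.
#' @param ... Overrides for any default element (see the returned list).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n = 4147, ...) {
  cfg <- list(
    n = as.integer(n),
    prop_cluster1 = 2099 / 4147,
    variables = synth_variables(),
    means = .default_means(),
    sds = .default_sds(),
    age_mean = c(44.2, 51.7),
    age_sd = c(9.58, 4.59),
    visit_offsets = c(0, 3.45, 6.4),
    rho = 0.8,
    corr_within = .default_corr_within(),
    # cohort-level (mixture) cross-sectional targets at the first visit
    corr_targets = list(
      c("wc", "bmi", 0.87),
      c("bmi", "hdl", -0.21),
      c("wc", "hdl", -0.21)
    ),
    height_mean = 1.719,
    height_sd = 0.065,
    smoking_init = c(smoker = 0.3682, `non-smoker` = 0.2690,
                     `ex-smoker` = 0.3628),
    smoking_P = matrix(c(0.820, 0.000, 0.180,
                         0.030, 0.895, 0.075,
                         0.033, 0.000, 0.967),
                       nrow = 3, byrow = TRUE,
                       dimnames = list(smoking_states(), smoking_states())),
    observe_smoking_t3 = FALSE,
    attendance = c(0.97, 0.80, 0.75),
    allow_dropout = FALSE,
    event_rate = c(13 / 2099, 32 / 2048),
    p_female = 0, p_prior_cvd = 0, p_no_card = 0, p_not_registry = 0,
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown generator_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg$n <- as.integer(cfg$n)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n >= 2, cfg$prop_cluster1 > 0, cfg$prop_cluster1 < 1,
            cfg$rho >= 0, cfg$rho <= 1)
  if (any(cfg$sds < 0) || any(cfg$age_sd < 0)) stop("SDs must be >= 0")
  if (any(cfg$attendance < 0 | cfg$attendance > 1)) {
    stop("attendance probabilities must be in [0, 1]")
  }
  if (any(abs(rowSums(cfg$smoking_P) - 1) > 1e-8) || any(cfg$smoking_P < 0)) {
    stop("smoking transition matrix must be row-stochastic")
  }
  if (abs(sum(cfg$smoking_init) - 1) > 1e-8) {
    stop("smoking initial distribution must sum to 1")
  }
  invisible(cfg)
}

# Within-cluster correlation that makes the two-component mixture hit a
# cohort-level correlation target, using the first-visit decomposition
# cov_mix = sum_c w_c sd_a_c sd_b_c r_within + cov_between(means).
solve_within_corr <- function(target, mu_a, mu_b, sd_a, sd_b, w) {
  mbar_a <- sum(w * mu_a); mbar_b <- sum(w * mu_b)
  cov_between <- sum(w * (mu_a - mbar_a) * (mu_b - mbar_b))
  var_a <- sum(w * (sd_a^2 + (mu_a - mbar_a)^2))
  var_b <- sum(w * (sd_b^2 + (mu_b - mbar_b)^2))
  unit <- sum(w * sd_a * sd_b)
  if (unit <= 0 || var_a <= 0 || var_b <= 0) return(NA_real_)
  r <- (target * sqrt(var_a * var_b) - cov_between) / unit
  if (abs(r) >= 0.995) {
    stop(sprintf("infeasible correlation target %.3f (needs within-cluster r = %.3f)",
                 target, r))
  }
  r
}

build_corr_matrix <- function(cfg) {
  C <- cfg$corr_within
  w <- c(cfg$prop_cluster1, 1 - cfg$prop_cluster1)
  for (tgt in cfg$corr_targets) {
    a <- tgt[1]; b <- tgt[2]; r_t <- as.numeric(tgt[3])
    r <- solve_within_corr(r_t, cfg$means[, 1, a], cfg$means[, 1, b],
                           cfg$sds[, 1, a], cfg$sds[, 1, b], w)
    if (!is.na(r)) {
      C[a, b] <- r; C[b, a] <- r
    }
  }
  # age correlates with the other variables only through the shared intercept
  # (variance share rho), so the within-matrix entry is the cross-sectional
  # target divided by sqrt(rho).
  if (cfg$rho > 0) {
    others <- setdiff(rownames(C), "age")
    C["age", others] <- pmin(pmax(C["age", others] / sqrt(cfg$rho), -0.99), 0.99)
    C[others, "age"] <- C["age", others]
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    stop("infeasible correlation matrix (not positive definite)")
  }
  C
}

sample_states <- function(u, probs) {
  smoking_states()[findInterval(u, cumsum(probs), left.open = TRUE) + 1L]
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the configured two-profile model. Each individual
#' belongs to one latent group; per visit, the seven continuous measurements
#' are drawn from a Gaussian copula with the configured per-group means/SDs
#' and correlations, decomposed into a shared individual intercept (variance
#' share `rho`) plus independent visit noise so trajectories persist. Age
#' advances deterministically along `visit_offsets`; weight is derived from
#' generated BMI and a fixed per-individual height so `bmi = weight/height^2`
#' holds exactly. Smoking evolves by the configured Markov chain (the
#' third-visit status is withheld from the table by default, mirroring a
#' registry where it must be projected). Visits are deleted by the attendance
#' model, keeping at least two per individual unless `allow_dropout` is set.
#' The latent group labels and event indicators live in the companion truth
#' table, never in the cohort itself.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (default from the config); the same seed gives a
#'   byte-identical cohort.
#' @param n Optional override of `config$n`.
#' @return Object of class `synth_cohort`: list with `cohort` (a
#'   [cohort_table()]), `truth` (data frame: `individual_id`, `cluster`,
#'   `event`, true smoking at each visit) and the expanded `config`.
#' @export
generate_cohort <- function(config = generator_config(), seed = NULL,
                            n = NULL) {
  cfg <- config
  if (!is.null(n)) cfg$n <- as.integer(n)
  seed <- seed %||% cfg$seed
  validate_generator_config(cfg)
  C <- build_corr_matrix(cfg)
  vars <- cfg$variables
  nv <- length(vars)
  n_tot <- cfg$n
  n1 <- round(n_tot * cfg$prop_cluster1)
  n2 <- n_tot - n1
  cl <- rep(1:2, c(n1, n2))
  ids <- sprintf("W%05d", seq_len(n_tot))

  with_seed(seed, {
    zero <- rep(0, nv + 1)
    z <- MASS::mvrnorm(n_tot, mu = zero, Sigma = C)      # intercepts (+ age)
    colnames(z) <- colnames(C)
    Csub <- C[vars, vars]
    e <- lapply(1:3, function(t) {
      MASS::mvrnorm(n_tot, mu = rep(0, nv), Sigma = Csub)
    })

    x <- array(NA_real_, c(n_tot, 3, nv), dimnames = list(NULL, NULL, vars))
    a <- sqrt(cfg$rho); b <- sqrt(1 - cfg$rho)
    for (t in 1:3) {
      for (v in vars) {
        x[, t, v] <- cfg$means[cl, t, v] +
          cfg$sds[cl, t, v] * (a * z[, v] + b * e[[t]][, v])
      }
      # physiological floor; Gaussian tails can graze zero at extreme n
      x[, t, ] <- pmax(x[, t, ], 1)
    }
    age1 <- pmax(cfg$age_mean[cl] + cfg$age_sd[cl] * z[, "age"], 18)
    age <- outer(age1, cfg$visit_offsets, `+`)
    height <- pmax(stats::rnorm(n_tot, cfg$height_mean, cfg$height_sd), 1.3)

    u1 <- stats::runif(n_tot); u2 <- stats::runif(n_tot)
    u3 <- stats::runif(n_tot)
    s1 <- sample_states(u1, cfg$smoking_init)
    s2 <- vapply(seq_len(n_tot), function(i) {
      sample_states(u2[i], cfg$smoking_P[s1[i], ])
    }, character(1))
    s3 <- vapply(seq_len(n_tot), function(i) {
      sample_states(u3[i], cfg$smoking_P[s2[i], ])
    }, character(1))

    event <- stats::rbinom(n_tot, 1, cfg$event_rate[cl]) == 1

    att <- matrix(stats::runif(n_tot * 3), n_tot, 3) <=
      matrix(cfg$attendance, n_tot, 3, byrow = TRUE)
    if (!cfg$allow_dropout) {
      bad <- which(rowSums(att) < 2)
      guard <- 0
      while (length(bad) && guard < 1000) {
        att[bad, ] <- matrix(stats::runif(length(bad) * 3), length(bad), 3) <=
          matrix(cfg$attendance, length(bad), 3, byrow = TRUE)
        bad <- bad[rowSums(att[bad, , drop = FALSE]) < 2]
        guard <- guard + 1
      }
      if (length(bad)) stop("attendance probabilities too low to keep 2 of 3 visits")
    }

    sex <- ifelse(stats::runif(n_tot) < cfg$p_female, "female", "male")
    meta <- data.frame(
      individual_id = ids,
      prior_cvd = stats::runif(n_tot) < cfg$p_prior_cvd,
      health_card = stats::runif(n_tot) >= cfg$p_no_card,
      registry_located = stats::runif(n_tot) >= cfg$p_not_registry,
      stringsAsFactors = FALSE
    )

    smoking <- cbind(s1, s2, s3)
    rows <- which(att, arr.ind = TRUE)
    rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
    i <- rows[, 1]; t <- rows[, 2]
    smk <- smoking[cbind(i, t)]
    if (!cfg$observe_smoking_t3) smk[t == 3] <- NA_character_
    rec <- data.frame(
      individual_id = ids[i],
      time_point = as.integer(t),
      sex = sex[i],
      age = age[cbind(i, t)],
      sbp = x[, , "sbp"][cbind(i, t)],
      dbp = x[, , "dbp"][cbind(i, t)],
      height = height[i],
      bmi = x[, , "bmi"][cbind(i, t)],
      wc = x[, , "wc"][cbind(i, t)],
      hdl = x[, , "hdl"][cbind(i, t)],
      total_chol = x[, , "total_chol"][cbind(i, t)],
      glucose = x[, , "glucose"][cbind(i, t)],
      smoking = smk,
      stringsAsFactors = FALSE
    )
    rec$weight <- rec$bmi * rec$height^2

    truth <- data.frame(
      individual_id = ids, cluster = cl, event = event,
      smoking_t1 = s1, smoking_t2 = s2, smoking_t3 = s3,
      stringsAsFactors = FALSE
    )
    structure(
      list(cohort = cohort_table(rec, individuals = meta),
           truth = truth, config = cfg, seed = seed),
      class = "synth_cohort"
    )
  })
}

#' Ground-truth labels of a generated cohort
#'
#' Returns the latent group label and the event indicator per individual,
#' stored alongside (never inside) the cohort table. Intended for tests and
#' recovery checks.
#'
#' @param x A `synth_cohort` from [generate_cohort()].
#' @return Data frame with `individual_id`, `cluster`, `event` and the true
#'   smoking status at each visit.
#' @export
ground_truth <- function(x) {
  stopifnot(inherits(x, "synth_cohort"))
  x$truth
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> n = %d (groups: %d / %d), seed = %d\n",
              nrow(x$truth), sum(x$truth$cluster == 1),
              sum(x$truth$cluster == 2), x$seed))
  print(x$cohort)
  invisible(x)
}
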