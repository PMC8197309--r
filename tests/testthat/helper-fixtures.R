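# In-code fixtures shared across test files.

# minimal long-format records data frame
toy_records <- function(ids, times, ...) {
  df <- data.frame(individual_id = ids, time_point = times,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# a small complete cohort of n individuals with linear-ish trajectories
toy_cohort <- function(n = 6, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("P%02d", seq_len(n))
    rec <- expand.grid(individual_id = ids, time_point = 1:3,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    base <- stats::setNames(stats::runif(n, 24, 32), ids)
    rec$sex <- "male"
    rec$age <- 45 + 3 * (rec$time_point - 1) + as.numeric(factor(rec$individual_id))
    rec$bmi <- base[rec$individual_id] + 0.2 * rec$time_point +
      stats::rnorm(nrow(rec), 0, 0.3)
    rec$wc <- 60 + 1.3 * rec$bmi + stats::rnorm(nrow(rec), 0, 2)
    rec$glucose <- 70 + rec$bmi + stats::rnorm(nrow(rec), 0, 5)
    rec$hdl <- 80 - rec$bmi + stats::rnorm(nrow(rec), 0, 4)
    rec$sbp <- 100 + rec$bmi / 2 + stats::rnorm(nrow(rec), 0, 5)
    rec$total_chol <- 180 + rec$bmi + stats::rnorm(nrow(rec), 0, 10)
    rec$smoking <- rep(c("smoker", "non-smoker", "ex-smoker"), length.out = nrow(rec))
    cohort_table(rec)
  })
}

# two well-separated blobs of trajectories as a trajectory_set
blob_set <- function(n_per = 30, delta = 8, nv = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per
    vars <- paste0("v", seq_len(nv))
    values <- array(stats::rnorm(n * 3 * nv), c(n, 3, nv),
                    dimnames = list(NULL, NULL, vars))
    values[seq_len(n_per), , ] <- values[seq_len(n_per), , ] + delta
    structure(list(ids = sprintf("B%03d", seq_len(n)), values = values,
                   variables = vars, times = 1:3,
                   center = NULL, scale = NULL),
              class = "trajectory_set")
  })
}

blob_labels <- function(n_per = 30) rep(1:2, each = n_per)

# agreement between two 2-cluster labelings, up to relabeling
label_agreement <- function(a, b) {
  max(mean(a == b), mean(a == 3 - b))
}
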