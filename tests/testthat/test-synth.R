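# analytic mixture moments from a generator config
mixture_mean <- function(cfg, v, t) {
  w <- c(cfg$prop_cluster1, 1 - cfg$prop_cluster1)
  sum(w * cfg$means[, t, v])
}
mixture_sd <- function(cfg, v, t) {
  w <- c(cfg$prop_cluster1, 1 - cfg$prop_cluster1)
  mu <- mixture_mean(cfg, v, t)
  sqrt(sum(w * (cfg$sds[, t, v]^2 + (cfg$means[, t, v] - mu)^2)))
}

test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- generator_config(n = 300)
  g1 <- generate_cohort(cfg, seed = 4)
  g2 <- generate_cohort(cfg, seed = 4)
  expect_identical(g1$cohort$records, g2$cohort$records)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_cohort(cfg, seed = 5)
  expect_false(identical(g1$cohort$records, g3$cohort$records))
})

test_that("degenerate noise puts every individual exactly at its group means", {
  cfg <- generator_config(n = 50,
                          sds = trajcvd:::.default_sds() * 0,
                          age_sd = c(0, 0), height_sd = 0,
                          attendance = c(1, 1, 1))
  g <- generate_cohort(cfg, seed = 1)
  rec <- g$cohort$records
  cl <- g$truth$cluster[match(rec$individual_id, g$truth$individual_id)]
  for (v in c("bmi", "wc", "glucose", "hdl")) {
    vi <- match(v, dimnames(cfg$means)[[3]])
    expect_equal(rec[[v]],
                 cfg$means[cbind(cl, rec$time_point, vi)],
                 tolerance = 1e-12)
  }
  expect_equal(rec$age,
               cfg$age_mean[cl] + cfg$visit_offsets[rec$time_point],
               tolerance = 1e-12)
})

test_that("ground truth has the configured group sizes and aligns with ids", {
  g <- generate_cohort(generator_config(n = 4147), seed = 1)
  tr <- ground_truth(g)
  expect_equal(sum(tr$cluster == 1), 2099)
  expect_equal(sum(tr$cluster == 2), 2048)
  expect_setequal(tr$individual_id, g$cohort$individuals$individual_id)
})

test_that("sample mean of BMI at the first visit sits within 3 SE of the analytic mixture mean", {
  cfg <- generator_config(n = 4147)
  g <- generate_cohort(cfg, seed = 2)
  rec <- g$cohort$records
  x <- rec$bmi[rec$time_point == 1]
  se <- mixture_sd(cfg, "bmi", 1) / sqrt(length(x))
  expect_lt(abs(mean(x) - mixture_mean(cfg, "bmi", 1)), 3 * se)
})

test_that("marginal means and SDs land within 1% of the configured mixture at large n", {
  cfg <- generator_config(n = 40000)
  g <- generate_cohort(cfg, seed = 6)
  rec <- g$cohort$records
  for (v in c("bmi", "wc", "glucose", "hdl", "sbp", "total_chol")) {
    for (t in c(1, 3)) {
      x <- rec[[v]][rec$time_point == t]
      expect_lt(abs(mean(x) - mixture_mean(cfg, v, t)) / mixture_mean(cfg, v, t),
                0.01, label = sprintf("mean %s t%d", v, t))
      expect_lt(abs(stats::sd(x) - mixture_sd(cfg, v, t)) / mixture_sd(cfg, v, t),
                0.01, label = sprintf("sd %s t%d", v, t))
    }
  }
})

test_that("the copula reproduces the cohort-level cross-sectional correlations", {
  g <- generate_cohort(generator_config(n = 10000), seed = 8)
  r <- cvrf_correlations(g$cohort, c("wc", "bmi", "hdl"), 1)$r
  expect_lt(abs(r["wc", "bmi"] - 0.87), 0.02)
  expect_lt(abs(r["bmi", "hdl"] - (-0.21)), 0.02)
  expect_lt(abs(r["wc", "hdl"] - (-0.21)), 0.02)
})

test_that("empirical smoking transitions converge to the configured chain", {
  cfg <- generator_config(n = 20000, attendance = c(1, 1, 1),
                          observe_smoking_t3 = TRUE)
  g <- generate_cohort(cfg, seed = 10)
  for (pair in list(c(1, 2), c(2, 3))) {
    tr <- estimate_transition(g$cohort, pair[1], pair[2])
    expect_lt(max(abs(tr$matrix - cfg$smoking_P)), 0.02)
  }
  # first-visit marginal
  rec <- g$cohort$records
  m1 <- prop.table(table(factor(rec$smoking[rec$time_point == 1],
                                levels = smoking_states())))
  expect_lt(max(abs(as.numeric(m1) - cfg$smoking_init)), 0.02)
})

test_that("attendance keeps at least two visits unless dropouts are allowed", {
  g <- generate_cohort(generator_config(n = 2000), seed = 3)
  visits <- table(g$cohort$records$individual_id)
  expect_true(all(visits >= 2))

  g2 <- generate_cohort(generator_config(n = 2000, allow_dropout = TRUE,
                                         attendance = c(0.7, 0.5, 0.5)),
                        seed = 3)
  visits2 <- table(g2$cohort$records$individual_id)
  expect_true(any(visits2 < 2))
})

test_that("event indicators follow the cluster-dependent rates", {
  g0 <- generate_cohort(generator_config(n = 2000, event_rate = c(0, 0)),
                        seed = 2)
  expect_equal(sum(ground_truth(g0)$event), 0)

  g <- generate_cohort(generator_config(n = 20000), seed = 2)
  tr <- ground_truth(g)
  e1 <- sum(tr$event[tr$cluster == 1]); e2 <- sum(tr$event[tr$cluster == 2])
  expect_gt(e2, e1)
})

test_that("derived weight keeps the BMI identity exactly", {
  g <- generate_cohort(generator_config(n = 500), seed = 11)
  rec <- g$cohort$records
  expect_lt(max(abs(rec$bmi - rec$weight / rec$height^2)), 1e-9)
})

test_that("infeasible correlation targets are rejected before sampling", {
  cfg <- generator_config(n = 100)
  cfg$corr_targets <- list(c("wc", "bmi", 0.999))
  expect_error(generate_cohort(cfg, seed = 1), "infeasible")
})

test_that("exclusion knobs feed the eligibility cascade", {
  g <- generate_cohort(generator_config(n = 1000, p_female = 0.1,
                                        p_prior_cvd = 0.05), seed = 12)
  out <- apply_eligibility(g$cohort)
  expect_gt(out$report$removed[1], 0)
  expect_gt(out$report$removed[2], 0)
  expect_equal(attr(out$report, "initial_n"),
               attr(out$report, "final_n") + sum(out$report$removed))
})
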