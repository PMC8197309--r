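test_that("SCORE reproduces the published low-risk chart cell", {
  # age 55, SBP 140, total cholesterol 6.5 mmol/L, male current smoker:
  # hand evaluation of the low-risk Weibull equations gives CHD 3.42% +
  # non-CHD CVD 1.18% = 4.60%; the published chart rounds the cell to ~5%
  risk <- score_risk(55, 140, 6.5, smoker = TRUE, chol_unit = "mmol/L")
  expect_equal(risk, 4.60, tolerance = 0.02)
})

test_that("SCORE is monotone in age, SBP, cholesterol and smoking", {
  base <- list(age = 50, sbp = 130, chol = 5.5)
  r0 <- score_risk(base$age, base$sbp, base$chol, FALSE, chol_unit = "mmol/L")
  for (d in list(c(5, 0, 0), c(0, 15, 0), c(0, 0, 1))) {
    r1 <- score_risk(base$age + d[1], base$sbp + d[2], base$chol + d[3],
                     FALSE, chol_unit = "mmol/L")
    expect_gt(r1, r0)
  }
  expect_gt(score_risk(50, 130, 5.5, TRUE, chol_unit = "mmol/L"), r0)
  # monotone over a grid, both sexes
  ages <- seq(40, 64, by = 4)
  for (sx in c("male", "female")) {
    risks <- score_risk(ages, 140, 6, TRUE, sex = sx, chol_unit = "mmol/L")
    expect_true(all(diff(risks) > 0))
  }
})

test_that("mg/dL and mmol/L input paths agree to 1e-12", {
  chol_mmol <- c(4.8, 5.5, 6.5, 7.2)
  r1 <- score_risk(55, 135, chol_mmol, TRUE, chol_unit = "mmol/L")
  r2 <- score_risk(55, 135, chol_mmol * chol_mgdl_per_mmol(), TRUE,
                   chol_unit = "mg/dL")
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("degenerate coefficients give zero risk and missing entries error", {
  co <- score_coefficients()
  co$alpha <- -Inf
  co$beta_chol <- co$beta_sbp <- co$beta_smoker <- 0
  expect_equal(score_risk(55, 140, 6.5, TRUE, coeffs = co,
                          chol_unit = "mmol/L"), 0)
  co2 <- score_coefficients()
  co2 <- co2[!(co2$cause == "chd" & co2$sex == "male"), ]
  expect_error(score_risk(55, 140, 6.5, TRUE, coeffs = co2,
                          chol_unit = "mmol/L"), "chd.*male")
})

test_that("ages below the model domain warn but compute", {
  expect_warning(r <- score_risk(27, 130, 5.5, FALSE, chol_unit = "mmol/L"),
                 "below 30")
  expect_true(r >= 0 && r < 1)
})

test_that("smoking dichotomization maps the three states and normalizes labels", {
  expect_true(smoker_binary("smoker"))
  expect_false(smoker_binary("non-smoker"))
  expect_false(smoker_binary("ex-smoker"))
  expect_true(smoker_binary("Smoker"))
  expect_false(smoker_binary("Ex_smoker"))
  expect_true(is.na(smoker_binary(NA)))
  expect_error(smoker_binary("vaper"), "unknown")
})

test_that("transition estimation matches direct counts on toy pairs", {
  rec <- toy_records(
    ids = rep(c("a", "b", "c", "d"), each = 2),
    times = rep(1:2, 4),
    smoking = c("smoker", "smoker", "smoker", "ex-smoker",
                "non-smoker", "non-smoker", "ex-smoker", "ex-smoker")
  )
  tr <- estimate_transition(cohort_table(rec))
  expect_equal(tr$matrix["smoker", ], c(smoker = 0.5, `non-smoker` = 0,
                                        `ex-smoker` = 0.5))
  expect_equal(tr$matrix["non-smoker", "non-smoker"], 1)
  expect_equal(tr$matrix["ex-smoker", "ex-smoker"], 1)
  expect_equal(unname(rowSums(tr$matrix)), rep(1, 3), tolerance = 1e-12)
})

test_that("static cohorts give the identity matrix and empty origins warn", {
  rec <- toy_records(ids = rep(c("a", "b"), each = 2), times = rep(1:2, 2),
                     smoking = c("smoker", "smoker", "ex-smoker", "ex-smoker"))
  expect_warning(tr <- estimate_transition(cohort_table(rec)),
                 "non-smoker")
  expect_equal(unname(tr$matrix), diag(3))
})

test_that("transition estimation recovers the generating chain within 0.02", {
  cfg <- generator_config(n = 10000)
  g <- generate_cohort(cfg, seed = 5)
  tr <- estimate_transition(g$cohort, 1, 2)
  expect_lt(max(abs(tr$matrix - cfg$smoking_P)), 0.02)
})

test_that("smoking projection is seeded, respects identity transitions and conserves mass", {
  g <- generate_cohort(generator_config(n = 3000), seed = 9)
  co <- impute_cohort(g$cohort, c("bmi"))
  co <- carry_smoking(co)

  ident <- diag(3); dimnames(ident) <- list(smoking_states(), smoking_states())
  p1 <- project_smoking(co, ident, seed = 4)
  rec <- p1$records
  s2 <- rec$smoking[rec$time_point == 2]
  s3 <- rec$smoking[rec$time_point == 3]
  expect_equal(s3, s2)

  cfg <- generator_config(n = 3000)
  p_a <- project_smoking(co, cfg$smoking_P, seed = 4)
  p_b <- project_smoking(co, cfg$smoking_P, seed = 4)
  expect_identical(p_a$records$smoking, p_b$records$smoking)
  p_c <- project_smoking(co, cfg$smoking_P, seed = 5)
  expect_false(identical(p_c$records$smoking, p_a$records$smoking))
})

test_that("projected marginal converges to the vector-matrix product", {
  cfg <- generator_config(n = 50000)
  g <- generate_cohort(cfg, seed = 13)
  co <- carry_smoking(impute_cohort(g$cohort, "bmi"))
  pr <- project_smoking(co, cfg$smoking_P, seed = 14)
  rec <- pr$records
  m2 <- prop.table(table(factor(rec$smoking[rec$time_point == 2],
                                levels = smoking_states())))
  m3 <- prop.table(table(factor(rec$smoking[rec$time_point == 3],
                                levels = smoking_states())))
  oracle <- as.numeric(m2) %*% cfg$smoking_P
  expect_lt(max(abs(as.numeric(m3) - oracle)), 0.005)
})

test_that("add_score fills a score per record and flags projected inputs", {
  run <- get_default_run()
  rec <- run$cohort$records
  expect_false(anyNA(rec$score))
  expect_true(all(rec$imputed_score[rec$time_point == 3]))
  expect_true(all(rec$score >= 0 & rec$score <= 100))
})

test_that("shipped coefficient file passes its checksum and loads both regions", {
  expect_silent(lo <- score_coefficients("low"))
  hi <- score_coefficients("high")
  expect_setequal(lo$cause, c("chd", "non_chd"))
  # the high-risk calibration gives strictly higher risk, same inputs
  expect_gt(score_risk(55, 140, 6.5, TRUE, coeffs = hi, chol_unit = "mmol/L"),
            score_risk(55, 140, 6.5, TRUE, coeffs = lo, chol_unit = "mmol/L"))
})
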