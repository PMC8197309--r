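# Independent geometric oracle for the angle bisector: the bisector of two
# lines through a common point with unit direction vectors u1, u2 has
# direction u1 + u2.
bisector_slope_oracle <- function(s1, s2) {
  u1 <- c(1, s1) / sqrt(1 + s1^2)
  u2 <- c(1, s2) / sqrt(1 + s2^2)
  d <- u1 + u2
  d[2] / d[1]
}

test_that("two observed points give exact linear inter/extrapolation", {
  expect_equal(as.numeric(impute_bisector(c(NA, 2, 4))), c(0, 2, 4),
               tolerance = 1e-12)
  expect_equal(as.numeric(impute_bisector(c(2, NA, 6))), c(2, 4, 6),
               tolerance = 1e-12)
  expect_equal(attr(impute_bisector(c(NA, 2, 4)), "imputed"),
               c(TRUE, FALSE, FALSE))
})

test_that("monotone gaps extrapolate along the angle bisector of local and global trends", {
  # trailing: local slope 0 (through (2,2),(3,2)), global slope 1 (through
  # (1,0),(3,2)); bisector slope tan(pi/8), anchored at (3,2)
  got <- impute_bisector(c(0, 2, 2, NA))
  expect_equal(got[4], 2 + tan(pi / 8), tolerance = 1e-12)
  expect_equal(got[4], 2 + bisector_slope_oracle(0, 1), tolerance = 1e-12)

  # leading: local slope 1 (through (2,1),(3,2)), global slope 1.5
  got2 <- impute_bisector(c(NA, 1, 2, 4.5))
  s <- bisector_slope_oracle(1, (4.5 - 1) / 2)
  expect_equal(got2[1], 1 - s, tolerance = 1e-12)
})

test_that("intermittent fills are exact linear interpolation and observed cells never change", {
  for (seed in 1:10) {
    y <- withr::with_seed(seed, stats::rnorm(6))
    miss <- withr::with_seed(seed + 100, sample(2:5, 2))
    y_miss <- y
    y_miss[miss] <- NA
    got <- impute_bisector(y_miss)
    obs <- setdiff(seq_along(y), miss)
    expect_equal(as.numeric(got[obs]), y[obs])
    # closed-form linear interpolation for interior gaps
    interior <- miss[miss > min(obs) & miss < max(obs)]
    if (length(interior)) {
      ref <- stats::approx(obs, y[obs], xout = interior)$y
      expect_equal(as.numeric(got[interior]), ref, tolerance = 1e-12)
    }
  }
})

test_that("bisector fill is invariant under time and value translation, and scale-equivariant when the two trend lines coincide", {
  y <- c(1.2, 2.5, 3.1, NA)
  base <- as.numeric(impute_bisector(y))
  shifted <- as.numeric(impute_bisector(y + 10))
  expect_equal(shifted, base + 10, tolerance = 1e-12)
  t_shift <- as.numeric(impute_bisector(y, times = 4:7))
  expect_equal(t_shift, base, tolerance = 1e-12)
  # with exactly two observed points the bisector is the common line, which
  # scales linearly
  y2 <- c(NA, 3, 7)
  expect_equal(as.numeric(impute_bisector(y2 * 5)),
               5 * as.numeric(impute_bisector(y2)), tolerance = 1e-12)
})

test_that("degenerate trajectories error or warn as documented", {
  expect_error(impute_bisector(c(NA, NA, NA)), "all-missing")
  expect_warning(got <- impute_bisector(c(NA, 4, NA)), "one observed")
  expect_equal(as.numeric(got), c(4, 4, 4))
})

test_that("impute_cohort is identity without missingness and midpoint-fills a skipped visit", {
  co <- toy_cohort(n = 4)
  vars <- c("bmi", "wc", "glucose", "hdl")
  same <- impute_cohort(co, vars)
  for (v in vars) {
    expect_equal(same$records[[v]], co$records[[v]])
    expect_false(any(same$records[[paste0("imputed_", v)]]))
  }

  # drop individual P01's second visit entirely
  rec <- co$records[!(co$records$individual_id == "P01" &
                        co$records$time_point == 2), ]
  out <- impute_cohort(cohort_table(rec), vars)
  for (v in vars) {
    tr <- out$records[out$records$individual_id == "P01", ]
    expect_equal(tr[[v]][tr$time_point == 2],
                 mean(tr[[v]][tr$time_point != 2]), tolerance = 1e-12)
    expect_true(tr[[paste0("imputed_", v)]][tr$time_point == 2])
  }
})

test_that("imputation errors carry the individual id", {
  co <- toy_cohort(n = 3)
  co$records$glucose[co$records$individual_id == "P02"] <- NA
  expect_error(impute_cohort(co, "glucose"), "P02")
})

test_that("MCAR visit deletion leaves variable means within 2% after imputation", {
  g <- generate_cohort(generator_config(n = 2000, attendance = c(1, 1, 0.8)),
                       seed = 21)
  full <- generate_cohort(generator_config(n = 2000, attendance = c(1, 1, 1)),
                          seed = 21)
  imp <- impute_cohort(g$cohort, c("bmi", "wc", "glucose", "hdl"))
  m_rel <- function(v) {
    m_imp <- mean(imp$records[[v]][imp$records$time_point == 3])
    m_true <- mean(full$cohort$records[[v]][full$cohort$records$time_point == 3])
    abs(m_imp - m_true) / m_true
  }
  for (v in c("bmi", "wc")) expect_lt(m_rel(v), 0.02, label = v)
  # glucose and HDL bend non-linearly at the last visit, so trailing
  # bisector extrapolation carries a small systematic bias on top of
  # sampling noise
  for (v in c("glucose", "hdl")) expect_lt(m_rel(v), 0.04, label = v)
})

test_that("compare_real_imputed reports p = 1 without imputation and detects shifts", {
  co <- toy_cohort(n = 6)
  tab <- compare_real_imputed(co, co, "bmi")
  expect_true(all(tab$p_value == 1))
  expect_equal(tab$mean_imputed, tab$mean_real)

  # a wildly shifted imputed cell must move the completed-data mean
  rec <- co$records
  before <- cohort_table(rec[!(rec$individual_id == "P01" &
                                 rec$time_point == 2), ])
  after <- impute_cohort(before, "bmi")
  i <- after$records$individual_id == "P01" & after$records$time_point == 2
  after$records$bmi[i] <- 500
  tab2 <- compare_real_imputed(before, after, "bmi")
  row <- tab2[tab2$time_point == 2, ]
  expect_gt(row$mean_imputed, row$mean_real + 5)
})

test_that("MCAR imputation leaves no detectable mean difference where interpolation is unbiased", {
  run <- get_default_run()
  tab <- run$imputation_report
  # interior gaps (t1, t2) are linear interpolations: unbiased under MCAR
  early <- tab[tab$time_point %in% 1:2 & tab$variable != "score", ]
  expect_true(all(early$p_value > 0.01))
  # trailing extrapolation stays unbiased for variables with near-linear
  # trends; variables whose cohort trend bends at t3 (glucose, cholesterol)
  # inherit a visible extrapolation bias, as the real-vs-imputed comparison
  # of the original cohort also shows
  late <- tab[tab$time_point == 3 & tab$variable %in% c("wc", "bmi"), ]
  expect_true(all(late$p_value > 0.01))
})

test_that("complete_age recomputes age from the visit spacing", {
  co <- toy_cohort(n = 3)
  off <- c(0, 3.45, 6.4)
  co$records$age <- 40 + off[co$records$time_point]
  co$records$age[co$records$time_point == 2] <- NA
  out <- complete_age(co, offsets = off)
  expect_equal(out$records$age[out$records$time_point == 2],
               rep(43.45, 3), tolerance = 1e-12)
  expect_true(all(out$records$imputed_age[out$records$time_point == 2]))
})
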