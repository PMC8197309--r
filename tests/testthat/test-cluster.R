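test_that("normalization is translation-invariant, invertible and errors on zero variance", {
  set <- blob_set(n_per = 15)
  norm <- normalize_trajectories(set)
  shifted <- set
  shifted$values[, , 1] <- shifted$values[, , 1] + 100
  norm2 <- normalize_trajectories(shifted)
  expect_equal(norm2$values, norm$values, tolerance = 1e-10)

  back <- denormalize_trajectories(norm)
  expect_equal(back$values, set$values, tolerance = 1e-12)

  flat <- set
  flat$values[, , 2] <- 7
  expect_error(normalize_trajectories(flat), "v2")
})

test_that("trajectory distance equals the flattened Euclidean norm", {
  expect_equal(traj_distance(matrix(1:6, 3), matrix(1:6, 3)), 0)
  a <- matrix(0, 3, 2)
  b <- a; b[, 1] <- 1  # +1 in one variable at all 3 times
  expect_equal(traj_distance(a, b), sqrt(3))
  for (seed in 1:5) {
    m <- withr::with_seed(seed, list(matrix(rnorm(12), 3), matrix(rnorm(12), 3)))
    expect_equal(traj_distance(m[[1]], m[[2]]),
                 sqrt(sum((as.vector(m[[1]]) - as.vector(m[[2]]))^2)),
                 tolerance = 1e-12)
  }
  expect_error(traj_distance(matrix(0, 3, 2), matrix(0, 2, 3)), "shape")
})

test_that("well-separated blobs are recovered exactly and labels order by centroid", {
  set <- blob_set(n_per = 25, delta = 10)
  km <- kmeans_traj(normalize_trajectories(set), 2, restarts = 5, seed = 42)
  expect_equal(label_agreement(unname(km$assignment), blob_labels(25)), 1)
  expect_true(all(km$sizes > 0))
})

test_that("k = n gives singleton clusters with zero inertia; k > n errors", {
  set <- blob_set(n_per = 3)
  km <- kmeans_traj(normalize_trajectories(set), 6, restarts = 3, seed = 1)
  expect_equal(sort(unname(km$assignment)), 1:6)
  expect_equal(km$inertia, 0, tolerance = 1e-12)
  expect_error(kmeans_traj(normalize_trajectories(set), 7), "exceed")
})

test_that("trajectory k-means matches flat k-means under identical initialization", {
  g <- generate_cohort(generator_config(n = 500, attendance = c(1, 1, 1),
                                        observe_smoking_t3 = TRUE), seed = 3)
  co <- add_score(g$cohort)
  set <- normalize_trajectories(trajectory_set(co))
  X <- matrix(set$values, nrow = 500)
  for (k in 2:3) {
    init <- withr::with_seed(50 + k, sample(rep_len(1:k, 500)))
    mine <- kmeans_traj(set, k, init = init, max_iter = 100)
    centers0 <- rowsum(X, init) / as.vector(table(init))
    ref <- suppressWarnings(stats::kmeans(X, centers = centers0,
                                          algorithm = "Lloyd",
                                          iter.max = 100))
    expect_equal(mine$inertia, ref$tot.withinss, tolerance = 1e-8)
    # identical partitions up to label permutation
    expect_equal(length(unique(paste(mine$assignment, ref$cluster))),
                 k)
  }
})

test_that("inertia is non-increasing across Lloyd iterations", {
  set <- blob_set(n_per = 40, delta = 2)  # overlapping, needs iterations
  km <- kmeans_traj(normalize_trajectories(set), 3, restarts = 8, seed = 11)
  expect_true(all(diff(km$inertia_trace) <= 1e-10))
})

test_that("the result is invariant under permutation of the individuals", {
  set <- blob_set(n_per = 20, delta = 6)
  km1 <- kmeans_traj(normalize_trajectories(set), 2, restarts = 5, seed = 7)
  perm <- withr::with_seed(99, sample(40))
  set2 <- set
  set2$values <- set$values[perm, , , drop = FALSE]
  set2$ids <- set$ids[perm]
  km2 <- kmeans_traj(normalize_trajectories(set2), 2, restarts = 5, seed = 7)
  expect_equal(km2$assignment[set$ids], km1$assignment[set$ids])
})

test_that("clusters are relabeled by ascending mean BMI", {
  run <- get_default_run()
  cent <- run$clusters$centroids
  expect_lt(mean(cent[1, , "bmi"]), mean(cent[2, , "bmi"]))
  s <- run$summary$stats
  b1 <- s$mean[s$cluster == 1 & s$variable == "bmi" & s$time_point == 1]
  b2 <- s$mean[s$cluster == 2 & s$variable == "bmi" & s$time_point == 1]
  expect_lt(b1, b2)
})

test_that("Calinski-Harabasz matches the hand-computed toy and flags degeneracy", {
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  labels <- rep(1:2, each = 3)
  # B = 3(1-6)^2 + 3(11-6)^2 = 150; W = 2 + 2 = 4; CH = (150/1)/(4/4) = 150
  expect_equal(calinski_harabasz(x, labels), 150)

  x0 <- matrix(rep(c(0, 5), each = 3), ncol = 1)
  ch <- calinski_harabasz(x0, labels)
  expect_true(is.infinite(ch))
  expect_true(isTRUE(attr(ch, "degenerate")))
})

test_that("true labels score higher CH than random labels on separated blobs", {
  set <- blob_set(n_per = 30, delta = 6)
  truth <- blob_labels(30)
  random <- withr::with_seed(1, sample(truth))
  expect_gt(calinski_harabasz(set, truth), calinski_harabasz(set, random))
})

test_that("quality sweep peaks at the true k, normalizes to max 1, and is deterministic", {
  set <- blob_set(n_per = 40, delta = 8)
  qs <- quality_sweep(normalize_trajectories(set), k_range = 2:6, restarts = 5, seed = 3)
  expect_equal(qs$recommended_k, 2)
  prof <- qs$profile
  for (idx in unique(prof$index)) {
    expect_equal(max(prof$normalized[prof$index == idx]), 1)
    expect_true(all(prof$normalized[prof$index == idx] >= 0 &
                      prof$normalized[prof$index == idx] <= 1))
  }
  qs2 <- quality_sweep(normalize_trajectories(set), k_range = 2:6, restarts = 5, seed = 3)
  expect_equal(qs2$profile, qs$profile)
})

test_that("trajectory sets demand complete data and known variables", {
  co <- toy_cohort(n = 4)
  expect_error(trajectory_set(co, c("bmi", "score")), "score")
  co2 <- co
  co2$records$bmi[2] <- NA
  expect_error(trajectory_set(co2, "bmi"), "impute")
})
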