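# Joint multivariate trajectory k-means: each individual is a time x variable
# matrix; distance is Euclidean over all entries after per-variable grand
# standardization. Lloyd iterations from seeded random partitions, multiple
# restarts, Calinski-Harabasz model selection.

#' Build a trajectory set
#'
#' Stacks the per-individual (time x variable) matrices of the selected
#' variables into an individuals x times x variables array. Every entry must
#' be present: imputation is upstream.
#'
#' @param cohort A `cohort_table` with a complete individual-by-time grid for
#'   `variables`.
#' @param variables Variables to cluster (default: the six joint-trajectory
#'   variables — age, WC, BMI, glucose, HDL and the computed SCORE).
#' @param times Time points (default `1:3`).
#' @return Object of class `trajectory_set`: list with `ids`, `values`
#'   (array), `variables`, `times`, and normalization slots `center`/`scale`
#'   (`NULL` until [normalize_trajectories()] is applied).
#' @export
trajectory_set <- function(cohort,
                           variables = c("age", "wc", "bmi", "glucose",
                                         "hdl", "score"),
                           times = 1:3) {
  stopifnot(inherits(cohort, "cohort_table"))
  rec <- cohort$records
  missing_vars <- setdiff(variables, names(rec))
  if (length(missing_vars) ||
      any(vapply(variables, function(v) all(is.na(rec[[v]])), logical(1)))) {
    stop("variable(s) absent from the cohort: ",
         paste(union(missing_vars,
                     variables[vapply(variables,
                                      function(v) !is.null(rec[[v]]) &&
                                        all(is.na(rec[[v]])), logical(1))]),
               collapse = ", "))
  }
  ids <- sort(unique(rec$individual_id))
  n <- length(ids); nt <- length(times); nv <- length(variables)
  values <- array(NA_real_, c(n, nt, nv), dimnames = list(NULL, NULL, variables))
  idx <- match(paste(rep(ids, each = nt), rep(times, n)),
               paste(rec$individual_id, rec$time_point))
  if (anyNA(idx)) {
    stop("incomplete time grid; impute the cohort before clustering")
  }
  for (v in variables) {
    values[, , v] <- matrix(rec[[v]][idx], n, nt, byrow = TRUE)
  }
  if (anyNA(values)) {
    bad <- which(apply(is.na(values), 1, any))[1]
    stop(sprintf("missing value(s) in trajectories (e.g. individual '%s'); impute first",
                 ids[bad]))
  }
  structure(list(ids = ids, values = values, variables = variables,
                 times = times, center = NULL, scale = NULL),
            class = "trajectory_set")
}

#' Standardize a trajectory set
#'
#' Centers and scales each variable by its grand mean and SD pooled over all
#' individuals and time points, so the joint Euclidean distance weighs
#' mixed-unit variables comparably. Parameters are stored for inversion.
#'
#' @param set A `trajectory_set`.
#' @return The normalized set, with `center` and `scale` filled.
#' @export
normalize_trajectories <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  if (!is.null(set$center)) return(set)
  center <- scale <- stats::setNames(numeric(length(set$variables)),
                                     set$variables)
  for (v in set$variables) {
    vals <- set$values[, , v]
    center[v] <- mean(vals)
    scale[v] <- stats::sd(as.vector(vals))
    if (!is.finite(scale[v]) || scale[v] == 0) {
      stop(sprintf("variable '%s' has zero variance; cannot normalize", v))
    }
    set$values[, , v] <- (vals - center[v]) / scale[v]
  }
  set$center <- center
  set$scale <- scale
  set
}

#' Invert the standardization of a trajectory set
#'
#' @param set A normalized `trajectory_set`.
#' @return The set on the original measurement scales.
#' @export
denormalize_trajectories <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  if (is.null(set$center)) return(set)
  for (v in set$variables) {
    set$values[, , v] <- set$values[, , v] * set$scale[v] + set$center[v]
  }
  set$center <- NULL
  set$scale <- NULL
  set
}

flatten_trajectories <- function(set) {
  n <- dim(set$values)[1]
  matrix(set$values, nrow = n)
}

#' Distance between two individual trajectories
#'
#' Euclidean (Frobenius) distance over all time x variable entries of two
#' same-shaped trajectory matrices.
#'
#' @param a,b Numeric matrices (time x variable) of identical shape.
#' @return A non-negative scalar.
#' @export
traj_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("trajectory matrices differ in shape")
  sqrt(sum((a - b)^2))
}

# squared Euclidean distances between rows of X and rows of centers
.dist2 <- function(X, centers) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) -
    2 * X %*% t(centers) +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  pmax(d2, 0)
}

# Move the point farthest from its centroid into each empty cluster, never
# emptying another cluster in the process.
.fix_empty <- function(assign_vec, d_own, k) {
  empty <- setdiff(seq_len(k), unique(assign_vec))
  for (j in empty) {
    sizes <- tabulate(assign_vec, nbins = k)
    movable <- which(sizes[assign_vec] > 1)
    if (!length(movable)) break
    far <- movable[which.max(d_own[movable])]
    assign_vec[far] <- j
    d_own[far] <- 0
  }
  assign_vec
}

lloyd_once <- function(X, part, max_iter) {
  n <- nrow(X); k <- max(part)
  assign_vec <- part
  centers <- rowsum(X, assign_vec) / tabulate(assign_vec, nbins = k)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    d2 <- .dist2(X, centers)
    new_assign <- max.col(-d2, ties.method = "first")
    d_own <- d2[cbind(seq_len(n), new_assign)]
    new_assign <- .fix_empty(new_assign, d_own, k)
    centers <- rowsum(X, new_assign) / tabulate(new_assign, nbins = k)
    trace <- c(trace, sum((X - centers[new_assign, , drop = FALSE])^2))
    if (identical(new_assign, assign_vec)) {
      converged <- TRUE
      assign_vec <- new_assign
      break
    }
    assign_vec <- new_assign
  }
  list(assignment = assign_vec, centers = centers,
       inertia = trace[length(trace)], iterations = iter,
       converged = converged, trace = trace)
}

#' K-means over joint multivariate trajectories
#'
#' Lloyd iterations on the flattened (time x variable) trajectories: points
#' are assigned to the nearest centroid under [traj_distance()] and centroids
#' recomputed as entrywise means, starting from seeded random partitions and
#' keeping the restart with the lowest within-cluster inertia. Empty clusters
#' are reseeded with the point farthest from its centroid; assignment ties
#' break toward the lowest cluster index. Final labels are ordered by
#' ascending mean BMI (cluster 1 = leaner profile) when BMI is among the
#' variables, so reported cluster numbers are reproducible.
#'
#' @param set A (normalized) `trajectory_set`. Normalize first for
#'   mixed-unit variables; the function warns if the set is raw.
#' @param k Number of clusters, `2 <= k <= n`.
#' @param restarts Number of seeded random-partition restarts (default 20).
#' @param max_iter Iteration cap per restart.
#' @param seed Base seed; restart `r` uses `seed + r - 1`.
#' @param init Optional explicit initial partition (integer vector in
#'   `1:k`), used instead of random restarts.
#' @return Object of class `cluster_result`: `k`, `assignment` (named by
#'   individual id), `centroids` (k x time x variable array), `inertia`,
#'   `restart`, `seed`, `iterations`, `converged`, `inertia_trace`,
#'   `sizes`.
#' @export
kmeans_traj <- function(set, k, restarts = 20, max_iter = 100, seed = 1,
                        init = NULL) {
  stopifnot(inherits(set, "trajectory_set"))
  X <- flatten_trajectories(set)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of individuals")
  if (k < 1) stop("k must be at least 1")
  if (is.null(set$center)) {
    warning("trajectory set is not normalized; distances mix measurement units")
  }

  runs <- if (!is.null(init)) {
    stopifnot(length(init) == n, all(init %in% seq_len(k)))
    list(lloyd_once(X, as.integer(init), max_iter))
  } else {
    lapply(seq_len(restarts), function(r) {
      part <- with_seed(seed + r - 1, sample(rep_len(seq_len(k), n)))
      lloyd_once(X, part, max_iter)
    })
  }
  best_i <- which.min(vapply(runs, `[[`, numeric(1), "inertia"))
  best <- runs[[best_i]]

  # deterministic relabeling: ascending mean BMI when available, otherwise
  # ascending grand centroid mean
  nt <- length(set$times); nv <- length(set$variables)
  cent_arr <- array(best$centers, c(k, nt, nv),
                    dimnames = list(NULL, NULL, set$variables))
  key <- if ("bmi" %in% set$variables) {
    rowMeans(cent_arr[, , "bmi", drop = FALSE])
  } else {
    rowMeans(best$centers)
  }
  ord <- order(key)
  relabel <- match(seq_len(k), ord)
  assignment <- stats::setNames(relabel[best$assignment], set$ids)
  cent_arr <- cent_arr[ord, , , drop = FALSE]

  structure(list(
    k = k, assignment = assignment, centroids = cent_arr,
    inertia = best$inertia, restart = best_i, seed = seed,
    iterations = best$iterations, converged = best$converged,
    inertia_trace = best$trace,
    sizes = tabulate(assignment, nbins = k),
    variables = set$variables, times = set$times
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, inertia = %.4f, sizes: %s\n",
              x$k, x$inertia, paste(x$sizes, collapse = "/")))
  cat(sprintf("  winning restart %d (seed %d), %d iterations%s\n",
              x$restart, x$seed, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion, each scaled by its degrees
#' of freedom: `CH = (B / (k - 1)) / (W / (n - k))` with
#' `B = sum_k n_k ||m_k - m||^2` and `W` the within-cluster sum of squared
#' distances to the centroids. Larger is better. A degenerate clustering with
#' `W = 0` returns `Inf` with attribute `degenerate = TRUE`.
#'
#' @param x A numeric matrix (rows = observations) or a `trajectory_set`
#'   (flattened over time x variable).
#' @param labels Integer cluster labels (or a `cluster_result`, from which
#'   the assignment is taken).
#' @return The CH score.
#' @export
calinski_harabasz <- function(x, labels) {
  if (inherits(x, "trajectory_set")) x <- flatten_trajectories(x)
  x <- as.matrix(x)
  if (inherits(labels, "cluster_result")) labels <- labels$assignment
  labels <- as.integer(labels)
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2) stop("Calinski-Harabasz requires k >= 2")
  if (n <= k) stop("Calinski-Harabasz requires n > k")
  grand <- colMeans(x)
  sizes <- tabulate(labels, nbins = max(labels))
  centers <- rowsum(x, labels) / sizes[sizes > 0]
  B <- sum(sizes[sizes > 0] *
             rowSums(sweep(centers, 2, grand)^2))
  W <- sum((x - centers[match(labels, sort(unique(labels))), , drop = FALSE])^2)
  if (W <= .Machine$double.eps * n) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Davies-Bouldin index (companion criterion)
#'
#' Mean over clusters of the worst ratio of summed within-cluster scatter to
#' centroid separation; smaller is better. Provided as an optional companion
#' to [calinski_harabasz()], which remains the decision criterion.
#'
#' @inheritParams calinski_harabasz
#' @return The DB score.
#' @export
davies_bouldin <- function(x, labels) {
  if (inherits(x, "trajectory_set")) x <- flatten_trajectories(x)
  x <- as.matrix(x)
  if (inherits(labels, "cluster_result")) labels <- labels$assignment
  labels <- as.integer(labels)
  lev <- sort(unique(labels))
  k <- length(lev)
  if (k < 2) stop("Davies-Bouldin requires k >= 2")
  centers <- rowsum(x, labels) / as.vector(table(labels))
  scatter <- vapply(seq_len(k), function(j) {
    rows <- labels == lev[j]
    mean(sqrt(rowSums(sweep(x[rows, , drop = FALSE], 2, centers[j, ])^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(centers))
  R <- outer(scatter, scatter, `+`) / (M + diag(Inf, k))
  mean(apply(R, 1, max))
}

#' Sweep the number of clusters
#'
#' Fits [kmeans_traj()] for each candidate `k`, computes the enabled quality
#' indices, and min-max normalizes each index across `k` for plotting. The
#' recommended `k` is the Calinski-Harabasz argmax.
#'
#' @param set A normalized `trajectory_set`.
#' @param k_range Candidate cluster numbers (default `2:6`).
#' @param restarts,max_iter,seed Passed to [kmeans_traj()].
#' @param indices Quality indices to compute (`"calinski_harabasz"` always;
#'   `"davies_bouldin"` optional).
#' @return Object of class `quality_profile`: `profile` data frame
#'   (`k`, `index`, `value`, `normalized`), the fitted `results` per k, and
#'   `recommended_k`.
#' @export
quality_sweep <- function(set, k_range = 2:6, restarts = 20, max_iter = 100,
                          seed = 1,
                          indices = c("calinski_harabasz", "davies_bouldin")) {
  stopifnot(inherits(set, "trajectory_set"))
  n <- dim(set$values)[1]
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie within [2, n - 1]")
  }
  indices <- match.arg(indices, several.ok = TRUE)
  fits <- lapply(k_range, function(k) {
    kmeans_traj(set, k, restarts = restarts, max_iter = max_iter, seed = seed)
  })
  names(fits) <- k_range
  rows <- list()
  for (idx in indices) {
    fun <- switch(idx, calinski_harabasz = calinski_harabasz,
                  davies_bouldin = davies_bouldin)
    vals <- vapply(fits, function(f) as.numeric(fun(set, f)), numeric(1))
    rng <- range(vals[is.finite(vals)])
    norm <- if (diff(rng) > 0) (vals - rng[1]) / diff(rng) else
      rep(1, length(vals))
    rows[[idx]] <- data.frame(k = k_range, index = idx, value = vals,
                              normalized = norm, stringsAsFactors = FALSE)
  }
  profile <- do.call(rbind, rows)
  rownames(profile) <- NULL
  ch <- rows[["calinski_harabasz"]]
  structure(list(profile = profile, results = fits,
                 recommended_k = ch$k[which.max(ch$value)]),
            class = "quality_profile")
}

#' @export
print.quality_profile <- function(x, ...) {
  cat(sprintf("<quality_profile> recommended k = %d (Calinski-Harabasz argmax)\n",
              x$recommended_k))
  print(x$profile, row.names = FALSE)
  invisible(x)
}
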