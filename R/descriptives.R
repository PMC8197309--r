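# Descriptive tables, correlation analysis, quartile-transition matrices and
# cluster-stratified comparisons.

.cell_values <- function(cohort, variable, t, use_imputed) {
  rec <- cohort$records
  rows <- rec$time_point == t
  if (!use_imputed) {
    flag <- rec[[paste0("imputed_", variable)]]
    if (!is.null(flag)) rows <- rows & !(flag %in% TRUE)
    if (variable == "smoking" && !is.null(rec$smoking_imputed)) {
      rows <- rows & !(rec$smoking_imputed %in% TRUE)
    }
  }
  rec[[variable]][rows]
}

#' Descriptive summary of the cohort
#'
#' Mean (SD) per quantitative variable and time point, and N (percent) for
#' the categorical variables (smoking status and BMI groups). By default the
#' summary uses observed data only (imputed cells excluded via their flags);
#' `use_imputed = TRUE` switches to the completed data.
#'
#' @param cohort A `cohort_table`.
#' @param times Time points to summarize.
#' @param use_imputed Include imputed/projected cells.
#' @return Object of class `cohort_description`: list with data frames
#'   `quantitative` (`variable`, `time_point`, `n`, `mean`, `sd`) and
#'   `categorical` (`variable`, `level`, `time_point`, `n`, `percent`).
#' @export
describe_cohort <- function(cohort, times = 1:3, use_imputed = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  rec <- cohort$records
  qvars <- intersect(measure_columns(), names(rec))
  qvars <- qvars[vapply(qvars, function(v) any(!is.na(rec[[v]])), logical(1))]
  qrows <- list()
  for (v in qvars) {
    for (t in times) {
      vals <- .cell_values(cohort, v, t, use_imputed)
      vals <- vals[!is.na(vals)]
      qrows[[length(qrows) + 1L]] <- data.frame(
        variable = v, time_point = t, n = length(vals),
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) stats::sd(vals) else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  crows <- list()
  add_cat <- function(name, values, t) {
    values <- values[!is.na(values)]
    if (!length(values)) return()
    tab <- table(values)
    crows[[length(crows) + 1L]] <<- data.frame(
      variable = name, level = names(tab), time_point = t,
      n = as.integer(tab), percent = 100 * as.integer(tab) / length(values),
      stringsAsFactors = FALSE
    )
  }
  for (t in times) {
    smk <- .cell_values(cohort, "smoking", t, use_imputed)
    add_cat("smoking", factor(smk, levels = smoking_states()), t)
    bmi <- .cell_values(cohort, "bmi", t, use_imputed)
    add_cat("bmi_group", bmi_group(bmi), t)
  }
  structure(list(quantitative = do.call(rbind, qrows),
                 categorical = do.call(rbind, crows)),
            class = "cohort_description")
}

#' @export
print.cohort_description <- function(x, ...) {
  cat("Quantitative variables, mean (SD):\n")
  q <- x$quantitative
  q$mean <- round(q$mean, 2); q$sd <- round(q$sd, 2)
  print(q, row.names = FALSE)
  cat("\nCategorical variables, N (%):\n")
  c2 <- x$categorical
  c2$percent <- round(c2$percent, 2)
  print(c2, row.names = FALSE)
  invisible(x)
}

#' Cross-sectional correlation analysis
#'
#' Pearson correlations between the selected variables at one time point on
#' pairwise-complete observations, with the standard t-distributed test of
#' zero correlation per pair.
#'
#' @param cohort A `cohort_table`.
#' @param variables Variables to correlate.
#' @param time_point The visit to analyze.
#' @param use_imputed Include imputed cells (default `TRUE`).
#' @return List of class `cvrf_correlations` with matrices `r` (unit
#'   diagonal), `p` and `n` (pairwise complete sample sizes).
#' @export
cvrf_correlations <- function(cohort, variables, time_point = 1,
                              use_imputed = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  dat <- sapply(variables, function(v) {
    .cell_values(cohort, v, time_point, use_imputed)
  })
  dat <- as.matrix(as.data.frame(dat))
  nv <- length(variables)
  r <- diag(nv); p <- matrix(NA_real_, nv, nv); nmat <- matrix(0L, nv, nv)
  dimnames(r) <- dimnames(p) <- dimnames(nmat) <- list(variables, variables)
  diag(p) <- 0
  diag(nmat) <- colSums(!is.na(dat))
  for (i in seq_len(nv - 1)) {
    for (j in seq.int(i + 1, nv)) {
      ok <- stats::complete.cases(dat[, c(i, j)])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3) {
        stop(sprintf("fewer than 3 complete pairs for (%s, %s)",
                     variables[i], variables[j]))
      }
      if (stats::sd(dat[ok, i]) == 0 || stats::sd(dat[ok, j]) == 0) {
        r[i, j] <- r[j, i] <- NA_real_
        next
      }
      ct <- stats::cor.test(dat[ok, i], dat[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = nmat, time_point = time_point),
            class = "cvrf_correlations")
}

#' @export
print.cvrf_correlations <- function(x, ...) {
  cat(sprintf("Pearson correlations at time point %d:\n", x$time_point))
  print(round(x$r, 3))
  invisible(x)
}

#' Quartile transition matrix
#'
#' Cross-tabulates the quartile membership of a variable between two visits.
#' Cutpoints are recomputed independently at each time point with
#' linear-interpolation quantiles; rows of the transition matrix are
#' normalized to percentages, whose diagonal is the quartile stay percentage.
#'
#' @param cohort A `cohort_table` with the variable complete at both visits
#'   for the individuals analyzed (post-imputation data allowed).
#' @param variable The variable to track.
#' @param from_t,to_t The two visits.
#' @param assignment Optional named cluster assignment; when given, one
#'   transition table is returned per cluster.
#' @param use_imputed Include imputed cells (default `TRUE`).
#' @return Object of class `quartile_transition` (or a list of them, one per
#'   cluster): `matrix` (4x4, row percentages), `counts`, `stay`
#'   (per-quartile stay percentage), `cutpoints` per visit.
#' @export
quartile_transitions <- function(cohort, variable, from_t = 1, to_t = 2,
                                 assignment = NULL, use_imputed = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!is.null(assignment)) {
    ks <- sort(unique(assignment))
    out <- lapply(ks, function(kk) {
      ids <- names(assignment)[assignment == kk]
      sub <- cohort
      sub$records <- sub$records[sub$records$individual_id %in% ids, ,
                                 drop = FALSE]
      sub$individuals <- sub$individuals[
        sub$individuals$individual_id %in% ids, , drop = FALSE]
      quartile_transitions(sub, variable, from_t, to_t,
                           use_imputed = use_imputed)
    })
    names(out) <- paste0("cluster_", ks)
    return(out)
  }

  rec <- cohort$records
  get_t <- function(t) {
    v <- .cell_values(cohort, variable, t, use_imputed)
    ids <- rec$individual_id[rec$time_point == t]
    if (!use_imputed) {
      flag <- rec[[paste0("imputed_", variable)]]
      rows <- rec$time_point == t
      if (!is.null(flag)) rows <- rows & !(flag %in% TRUE)
      ids <- rec$individual_id[rows]
    }
    stats::setNames(v, ids)
  }
  a <- get_t(from_t); b <- get_t(to_t)
  common <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (length(common) < 8) {
    stop("fewer than 8 individuals with the variable at both visits; quartiles are meaningless")
  }
  a <- a[common]; b <- b[common]
  qcut <- function(v) {
    q <- stats::quantile(v, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    if (any(diff(q) <= 0)) {
      stop(sprintf("quartile cutpoints for '%s' are not strictly increasing",
                   variable))
    }
    q
  }
  qa <- qcut(a); qb <- qcut(b)
  bin <- function(v, q) cut(v, c(-Inf, q, Inf), labels = paste0("Q", 1:4))
  counts <- table(from = bin(a, qa), to = bin(b, qb))
  pct <- 100 * counts / pmax(rowSums(counts), 1)
  structure(list(variable = variable, from_t = from_t, to_t = to_t,
                 cutpoints = list(from = qa, to = qb),
                 counts = unclass(counts), matrix = unclass(pct),
                 stay = diag(unclass(pct)), n = length(common)),
            class = "quartile_transition")
}

#' @export
print.quartile_transition <- function(x, ...) {
  cat(sprintf("Quartile transitions for '%s', t%d -> t%d (n = %d), row %%:\n",
              x$variable, x$from_t, x$to_t, x$n))
  print(round(x$matrix, 1))
  cat("stay %:", paste(sprintf("%s=%.1f", paste0("Q", 1:4), x$stay),
                       collapse = "  "), "\n")
  invisible(x)
}

#' Cluster-stratified summary
#'
#' Mean (SD) per cluster, variable and time point, cluster sizes, and (for
#' two clusters) the unpaired two-sample Student's t-test per variable and
#' time point. The pooled-variance test is the default; Welch is available.
#'
#' @param cohort A `cohort_table` (typically the completed one).
#' @param assignment Named integer vector of cluster labels covering every
#'   individual in the cohort.
#' @param variables Variables to summarize (default: the clustered six).
#' @param times Time points.
#' @param welch Use the Welch (unequal-variance) t-test.
#' @return Object of class `cluster_summary`: `stats` (cluster, variable,
#'   time_point, n, mean, sd), `p_values` (variable, time_point, p; `NA`
#'   unless exactly two clusters), and `sizes`.
#' @export
cluster_summary <- function(cohort, assignment,
                            variables = c("age", "wc", "bmi", "glucose",
                                          "hdl", "score"),
                            times = 1:3, welch = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  rec <- cohort$records
  ids <- unique(rec$individual_id)
  if (!all(ids %in% names(assignment))) {
    stop("assignment does not cover every individual in the cohort")
  }
  cl <- assignment[rec$individual_id]
  ks <- sort(unique(as.integer(assignment)))
  srows <- list(); prows <- list()
  for (v in variables) {
    for (t in times) {
      sel <- rec$time_point == t & !is.na(rec[[v]])
      vals <- rec[[v]][sel]; g <- cl[sel]
      for (kk in ks) {
        x <- vals[g == kk]
        srows[[length(srows) + 1L]] <- data.frame(
          cluster = kk, variable = v, time_point = t, n = length(x),
          mean = if (length(x)) mean(x) else NA_real_,
          sd = if (length(x) > 1) stats::sd(x) else NA_real_,
          stringsAsFactors = FALSE
        )
      }
      p <- NA_real_
      if (length(ks) == 2) {
        x1 <- vals[g == ks[1]]; x2 <- vals[g == ks[2]]
        if (length(x1) > 1 && length(x2) > 1 &&
            (stats::sd(x1) > 0 || stats::sd(x2) > 0)) {
          p <- stats::t.test(x1, x2, var.equal = !welch)$p.value
        } else if (length(x1) > 1 && length(x2) > 1) {
          p <- 1  # identical constant groups
        }
      }
      prows[[length(prows) + 1L]] <- data.frame(
        variable = v, time_point = t, p = p, stringsAsFactors = FALSE
      )
    }
  }
  sizes <- stats::setNames(
    vapply(ks, function(kk) sum(assignment == kk), integer(1)),
    paste0("cluster_", ks)
  )
  structure(list(stats = do.call(rbind, srows),
                 p_values = do.call(rbind, prows), sizes = sizes,
                 welch = welch),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat("Cluster sizes:", paste(sprintf("%s=%d", names(x$sizes), x$sizes),
                              collapse = "  "), "\n")
  s <- x$stats
  s$mean <- round(s$mean, 2); s$sd <- round(s$sd, 2)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Event counts by cluster
#'
#' @param events Logical (or 0/1) event indicator, named by individual id or
#'   aligned with `assignment`.
#' @param assignment Named integer cluster assignment.
#' @return Data frame with `cluster`, `n`, `events`; total events preserved.
#' @export
events_by_cluster <- function(events, assignment) {
  if (!is.null(names(events))) {
    if (!all(names(assignment) %in% names(events))) {
      stop("events vector does not cover every assigned individual")
    }
    events <- events[names(assignment)]
  } else {
    stopifnot(length(events) == length(assignment))
  }
  events <- as.logical(events)
  ks <- sort(unique(as.integer(assignment)))
  data.frame(
    cluster = ks,
    n = vapply(ks, function(kk) sum(assignment == kk), integer(1)),
    events = vapply(ks, function(kk) sum(events[assignment == kk]),
                    integer(1))
  )
}
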