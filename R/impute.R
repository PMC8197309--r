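# Trajectory completion: linear interpolation for intermittent gaps, angle
# bisector of the local and global trend lines for monotone (leading/trailing)
# gaps.

bisector_slope <- function(s_local, s_global) {
  # Of the two angle bisectors pick the one whose slope lies between the two
  # line slopes: the tangent of the mean angle, since tan is monotone on
  # (-pi/2, pi/2).
  tan((atan(s_local) + atan(s_global)) / 2)
}

#' Complete one trajectory by bisector/linear interpolation
#'
#' Intermittent gaps (missing values flanked by observations) are filled by
#' the straight line joining the surrounding observed values. Monotone gaps
#' (leading or trailing runs of missingness) are extrapolated along the angle
#' bisector of (i) the line through the two observed points nearest the gap
#' and (ii) the line through the first and last observed points, anchored at
#' the observed point nearest the gap. With only two observed points the two
#' lines coincide and the fill is plain linear extrapolation.
#'
#' @param y Numeric vector, one entry per time point, `NA` where missing.
#' @param times Time positions (default equally spaced `1..length(y)`).
#' @return `y` with gaps filled; attribute `imputed` is a logical vector
#'   marking the filled entries. A single observed value gives a constant
#'   fill with a warning; an all-missing trajectory is an error.
#' @examples
#' impute_bisector(c(NA, 2, 4))   # -> 0 2 4
#' impute_bisector(c(2, NA, 6))   # -> 2 4 6
#' @export
impute_bisector <- function(y, times = seq_along(y)) {
  stopifnot(is.numeric(times), length(times) == length(y),
            !is.unsorted(times, strictly = TRUE))
  obs <- which(!is.na(y))
  if (length(obs) == 0L) stop("cannot impute an all-missing trajectory")
  out <- as.numeric(y)
  imputed <- is.na(y)
  if (length(obs) == 1L) {
    warning("only one observed value; filling trajectory with a constant")
    out[imputed] <- y[obs]
    attr(out, "imputed") <- imputed
    return(out)
  }

  first <- obs[1L]
  last <- obs[length(obs)]
  # intermittent gaps: exact linear interpolation between flanking points
  mid <- which(imputed & seq_along(y) > first & seq_along(y) < last)
  if (length(mid)) {
    out[mid] <- stats::approx(times[obs], y[obs], xout = times[mid])$y
  }
  s_global <- (y[last] - y[first]) / (times[last] - times[first])
  if (first > 1L) {
    a <- obs[1L]; b <- obs[2L]
    s_local <- (y[b] - y[a]) / (times[b] - times[a])
    s <- bisector_slope(s_local, s_global)
    lead <- seq_len(first - 1L)
    out[lead] <- y[a] + s * (times[lead] - times[a])
  }
  if (last < length(y)) {
    a <- obs[length(obs) - 1L]; b <- obs[length(obs)]
    s_local <- (y[b] - y[a]) / (times[b] - times[a])
    s <- bisector_slope(s_local, s_global)
    trail <- seq.int(last + 1L, length(y))
    out[trail] <- y[b] + s * (times[trail] - times[b])
  }
  attr(out, "imputed") <- imputed
  out
}

#' Complete selected variables for every individual in a cohort
#'
#' Applies [impute_bisector()] to each listed variable of each individual over
#' the time grid `times`. Rows for missed visits are created first (carrying
#' `individual_id`, `time_point` and `sex`), so the result has a complete
#' individual-by-time grid. Imputed cells are flagged in logical columns
#' `imputed_<variable>`; observed cells are never altered and unlisted
#' variables are untouched.
#'
#' Extrapolated fills are floored at a small positive value (1) so completed
#' physiological measurements respect the positivity invariant even on
#' extreme trajectories.
#'
#' @param cohort A `cohort_table` whose individuals all attended at least two
#'   visits (the eligibility cascade guarantees this).
#' @param variables Character vector of measurement columns to complete.
#' @param times Integer time grid (default `1:3`).
#' @return The completed `cohort_table`.
#' @export
impute_cohort <- function(cohort, variables, times = 1:3) {
  stopifnot(inherits(cohort, "cohort_table"))
  bad <- setdiff(variables, measure_columns())
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  rec <- cohort$records
  ids <- unique(rec$individual_id)

  # expand to the full individual x time grid
  grid <- expand.grid(individual_id = ids, time_point = as.integer(times),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full <- merge(grid, rec, by = c("individual_id", "time_point"),
                all.x = TRUE, sort = FALSE)
  sex_of <- tapply(rec$sex, rec$individual_id, function(s) {
    s <- s[!is.na(s)]
    if (length(s)) s[1] else NA_character_
  })
  created <- !paste(full$individual_id, full$time_point) %in%
    paste(rec$individual_id, rec$time_point)
  full$sex[created] <- sex_of[full$individual_id[created]]
  full <- full[order(full$individual_id, full$time_point), , drop = FALSE]
  rownames(full) <- NULL

  tvec <- as.numeric(times)
  for (v in variables) {
    m <- matrix(full[[v]], nrow = length(times))  # time x individual
    flags <- is.na(m)
    filled <- vapply(seq_len(ncol(m)), function(j) {
      col <- m[, j]
      if (!anyNA(col)) return(col)
      tryCatch(
        as.numeric(impute_bisector(col, tvec)),
        error = function(e) {
          stop(sprintf("individual '%s', variable '%s': %s",
                       ids[j], v, conditionMessage(e)), call. = FALSE)
        }
      )
    }, numeric(length(times)))
    filled[flags] <- pmax(filled[flags], 1)  # physiological floor for fills
    full[[v]] <- as.vector(filled)
    full[[paste0("imputed_", v)]] <- as.vector(flags)
  }

  out <- cohort
  out$records <- full
  out
}

#' Deterministic completion of age
#'
#' Age advances with the calendar, so missing ages are recomputed from any
#' observed age and the configured spacing between visits rather than
#' interpolated: `age(t) = age(t0) - offset(t0) + offset(t)`.
#'
#' @param cohort A `cohort_table` (typically after [impute_cohort()], so that
#'   every individual has a row per time point).
#' @param offsets Years elapsed at each visit since the first (default
#'   `c(0, 3.45, 6.4)`, the generator's spacing).
#' @param times Integer time grid.
#' @return The cohort with `age` complete and `imputed_age` flags.
#' @export
complete_age <- function(cohort, offsets = c(0, 3.45, 6.4), times = 1:3) {
  stopifnot(inherits(cohort, "cohort_table"), length(offsets) == length(times))
  rec <- cohort$records
  off <- stats::setNames(offsets, times)
  flags <- is.na(rec$age)
  base <- tapply(seq_len(nrow(rec)), rec$individual_id, function(i) {
    ok <- i[!is.na(rec$age[i])]
    if (!length(ok)) return(NA_real_)
    rec$age[ok[1]] - off[as.character(rec$time_point[ok[1]])]
  })
  if (anyNA(base)) {
    stop("individual(s) with no observed age: ",
         paste(names(base)[is.na(base)][1], collapse = ", "))
  }
  fill <- flags
  rec$age[fill] <- base[rec$individual_id[fill]] +
    off[as.character(rec$time_point[fill])]
  rec$imputed_age <- flags
  cohort$records <- rec
  cohort
}

#' Compare observed and completed data
#'
#' For each variable and time point, tabulates the mean (SD) of the observed
#' values against the mean (SD) of the completed data (observed plus imputed),
#' with an unpaired two-sample Student's t-test between the two sets. With no
#' imputed cells the columns are identical and `p = 1` by convention.
#'
#' @param before Cohort prior to imputation.
#' @param after Cohort returned by [impute_cohort()] (and, for `score`-like
#'   derived columns, any cohort carrying `imputed_<var>` flags).
#' @param variables Variables to compare.
#' @param times Time points.
#' @return Data frame with one row per variable and time point: observed and
#'   completed mean/SD, number of imputed cells, and the t-test p-value.
#' @export
compare_real_imputed <- function(before, after, variables, times = 1:3) {
  stopifnot(inherits(before, "cohort_table"), inherits(after, "cohort_table"))
  rows <- list()
  for (v in variables) {
    for (t in times) {
      real <- before$records[[v]][before$records$time_point == t]
      real <- real[!is.na(real)]
      all_vals <- after$records[[v]][after$records$time_point == t]
      all_vals <- all_vals[!is.na(all_vals)]
      n_imp <- length(all_vals) - length(real)
      p <- 1
      if (n_imp > 0 && length(real) > 1 && length(all_vals) > 1 &&
          (stats::sd(real) > 0 || stats::sd(all_vals) > 0)) {
        p <- stats::t.test(all_vals, real, var.equal = TRUE)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, time_point = t,
        mean_imputed = mean(all_vals), sd_imputed = stats::sd(all_vals),
        mean_real = mean(real), sd_real = stats::sd(real),
        n_imputed_cells = n_imp, p_value = p,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
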