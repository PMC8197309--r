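# End-to-end orchestration: (generate | read) -> eligibility -> impute ->
# score -> project smoking -> cluster -> characterize.

#' Pipeline configuration
#'
#' @param input Either a [generator_config()] (the cohort is simulated) or a
#'   `cohort_table` (an existing cohort is analyzed).
#' @param cluster_vars Variables for the joint trajectory clustering
#'   (default: age, WC, BMI, glucose, HDL and the computed SCORE).
#' @param impute_vars Measured variables completed by [impute_cohort()]
#'   before scoring and clustering.
#' @param quartile_vars Variables for the quartile transition tables.
#' @param k Number of clusters for the main fit.
#' @param sweep Optional range of candidate `k` for [quality_sweep()].
#' @param restarts,max_iter K-means restarts and iteration cap.
#' @param seeds Named list of integer seeds: `synth` (generation), `project`
#'   (smoking projection), `cluster` (k-means restarts).
#' @param region SCORE calibration region, `"low"` or `"high"`.
#' @param welch Use Welch t-tests in the cluster summary.
#' @param out_dir Optional directory; when set, every table is persisted as
#'   CSV together with a `manifest.json` of seeds and settings.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = generator_config(),
                            cluster_vars = c("age", "wc", "bmi", "glucose",
                                             "hdl", "score"),
                            impute_vars = c("wc", "bmi", "glucose", "hdl",
                                            "sbp", "total_chol"),
                            quartile_vars = c("bmi", "wc", "glucose", "hdl",
                                              "score"),
                            k = 2, sweep = NULL, restarts = 20,
                            max_iter = 100,
                            seeds = list(synth = 101, project = 202,
                                         cluster = 303),
                            region = "low", welch = FALSE, out_dir = NULL) {
  cfg <- list(input = input, cluster_vars = cluster_vars,
              impute_vars = impute_vars, quartile_vars = quartile_vars,
              k = k, sweep = sweep, restarts = restarts,
              max_iter = max_iter, seeds = seeds, region = region,
              welch = welch, out_dir = out_dir)
  known <- c(measure_columns(), "smoking")
  bad <- setdiff(c(cluster_vars, impute_vars, quartile_vars), known)
  if (length(bad)) {
    stop("unknown variable(s) requested: ", paste(bad, collapse = ", "))
  }
  for (s in c("synth", "project", "cluster")) {
    if (is.null(seeds[[s]])) stop("seeds$", s, " must be set explicitly")
  }
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow with a single configuration: obtain the
#' cohort (simulate or take as given), apply the eligibility cascade,
#' complete the trajectories, estimate the smoking transition matrix from
#' visits 1-2 and project visit-3 status, compute the per-visit SCORE,
#' cluster the joint trajectories, and produce the characterization tables.
#' Deterministic given the configured seeds.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `trajcvd_run`: a list with `cohort` (completed),
#'   `truth` (if simulated), `eligibility`, `imputation_report`,
#'   `transition`, `descriptives`, `correlations`, `quality` (if swept),
#'   `clusters`, `summary`, `quartiles`, `events` (if truth available) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config

  truth <- NULL
  offsets <- c(0, 3.45, 6.4)
  cohort <- .stage("input", {
    if (inherits(cfg$input, "generator_config")) {
      g <- generate_cohort(cfg$input, seed = cfg$seeds$synth)
      truth <- ground_truth(g)
      offsets <- cfg$input$visit_offsets
      g$cohort
    } else if (inherits(cfg$input, "cohort_table")) {
      cfg$input
    } else {
      stop("input must be a generator_config or a cohort_table")
    }
  })

  elig <- .stage("eligibility", apply_eligibility(cohort))
  cohort <- elig$cohort
  before <- .stage("score_observed",
                   suppressWarnings(add_score(
                     cohort, score_coefficients(cfg$region))))

  cohort <- .stage("impute", {
    out <- impute_cohort(cohort, cfg$impute_vars)
    complete_age(out, offsets = offsets)
  })
  transition <- .stage("transition", estimate_transition(cohort, 1, 2))
  cohort <- .stage("carry_smoking", carry_smoking(cohort, times = c(1, 2)))
  cohort <- .stage("project_smoking",
                   project_smoking(cohort, transition,
                                   seed = cfg$seeds$project))
  cohort <- .stage("score",
                   add_score(cohort, score_coefficients(cfg$region)))

  imputation_report <- .stage("imputation_report",
                              compare_real_imputed(
                                before, cohort,
                                c(cfg$impute_vars, "score")))

  set <- .stage("trajectories", {
    normalize_trajectories(trajectory_set(cohort, cfg$cluster_vars))
  })
  quality <- NULL
  if (!is.null(cfg$sweep)) {
    quality <- .stage("quality_sweep",
                      quality_sweep(set, cfg$sweep, restarts = cfg$restarts,
                                    max_iter = cfg$max_iter,
                                    seed = cfg$seeds$cluster))
  }
  clusters <- .stage("cluster",
                     kmeans_traj(set, cfg$k, restarts = cfg$restarts,
                                 max_iter = cfg$max_iter,
                                 seed = cfg$seeds$cluster))

  summary_tab <- .stage("cluster_summary",
                        cluster_summary(cohort, clusters$assignment,
                                        variables = cfg$cluster_vars,
                                        welch = cfg$welch))
  descr <- .stage("descriptives", describe_cohort(cohort))
  corr <- .stage("correlations", lapply(1:3, function(t) {
    cvrf_correlations(cohort, cfg$cluster_vars, t)
  }))
  quart <- .stage("quartiles", {
    out <- list()
    for (v in cfg$quartile_vars) {
      for (tt in list(c(1, 2), c(2, 3))) {
        out[[sprintf("%s_t%d_t%d", v, tt[1], tt[2])]] <-
          quartile_transitions(cohort, v, tt[1], tt[2])
      }
    }
    out
  })
  events <- NULL
  if (!is.null(truth)) {
    ev <- stats::setNames(truth$event, truth$individual_id)
    keep <- names(clusters$assignment)
    events <- events_by_cluster(ev[keep], clusters$assignment)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("trajcvd")),
    seeds = cfg$seeds, k = cfg$k, restarts = cfg$restarts,
    cluster_vars = cfg$cluster_vars, impute_vars = cfg$impute_vars,
    region = cfg$region,
    n_individuals = nrow(cohort$individuals),
    n_records = nrow(cohort$records),
    simulated = !is.null(truth)
  )

  run <- structure(list(
    cohort = cohort, truth = truth, eligibility = elig$report,
    imputation_report = imputation_report, transition = transition,
    descriptives = descr, correlations = corr, quality = quality,
    clusters = clusters, summary = summary_tab, quartiles = quart,
    events = events, manifest = manifest, trajectories = set
  ), class = "trajcvd_run")

  if (!is.null(cfg$out_dir)) write_bundle(run, cfg$out_dir)
  run
}

#' Persist a pipeline run as CSV tables
#'
#' Writes the eligibility report, imputation comparison, descriptives,
#' quality profile, cluster assignments and summary, quartile transition
#' tables and a JSON manifest into a directory. Output content is fully
#' determined by the run, so re-writing the same run is byte-identical.
#'
#' @param run A `trajcvd_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(run, dir) {
  stopifnot(inherits(run, "trajcvd_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  }
  elig <- as.data.frame(run$eligibility)
  elig$initial_n <- attr(run$eligibility, "initial_n")
  elig$final_n <- attr(run$eligibility, "final_n")
  w(elig, "eligibility.csv")
  w(run$imputation_report, "imputation_report.csv")
  w(run$descriptives$quantitative, "descriptives_quantitative.csv")
  w(run$descriptives$categorical, "descriptives_categorical.csv")
  tr <- as.data.frame(as.table(run$transition$matrix))
  names(tr) <- c("from", "to", "probability")
  w(tr, "smoking_transition.csv")
  if (!is.null(run$quality)) w(run$quality$profile, "quality_profile.csv")
  w(data.frame(individual_id = names(run$clusters$assignment),
               cluster = as.integer(run$clusters$assignment)),
    "cluster_assignments.csv")
  w(run$summary$stats, "cluster_summary.csv")
  w(run$summary$p_values, "cluster_summary_tests.csv")
  qt <- do.call(rbind, lapply(names(run$quartiles), function(nm) {
    q <- run$quartiles[[nm]]
    df <- as.data.frame(as.table(q$matrix))
    names(df) <- c("from", "to", "percent")
    cbind(table = nm, variable = q$variable, df)
  }))
  w(qt, "quartile_transitions.csv")
  if (!is.null(run$events)) w(run$events, "events_by_cluster.csv")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.trajcvd_run <- function(x, ...) {
  cat("<trajcvd_run>\n")
  print(x$eligibility)
  cat("\n")
  print(x$clusters)
  if (!is.null(x$events)) {
    cat("\nEvents by cluster:\n")
    print(x$events, row.names = FALSE)
  }
  invisible(x)
}
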