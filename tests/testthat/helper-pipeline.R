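# The default-conditions pipeline run (n = 4147, fixed seeds) is expensive
# enough to share across test files.

.default_run_cache <- new.env(parent = emptyenv())

get_default_run <- function() {
  if (is.null(.default_run_cache$run)) {
    .default_run_cache$run <- run_pipeline(pipeline_config())
  }
  .default_run_cache$run
}

cluster_mean <- function(run, cluster, variable, time_point) {
  s <- run$summary$stats
  s$mean[s$cluster == cluster & s$variable == variable &
           s$time_point == time_point]
}
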