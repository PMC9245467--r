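# Benchmark scenario runner shared by the acceptance tests. Each scenario
# (covariance, signal, n) is computed once over a fixed seed set and
# cached for the remaining test blocks.

.scenario_cache <- new.env(parent = emptyenv())

scenario_paucs <- function(cov_kind = "ar1", signal = "weak", n = 500,
                           seeds = 1:10,
                           methods = c("ige", "j_lasso")) {
  key <- paste(cov_kind, signal, n, paste(range(seeds), collapse = "-"),
               sep = "_")
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  res <- NULL
  for (s in seeds) {
    cfg <- sim_config(n = n, cov_kind = cov_kind, signal = signal, seed = s)
    r <- run_replicate(cfg, methods = methods)
    r$seed <- s
    res <- rbind(res, r)
  }
  .scenario_cache[[key]] <- res
  res
}

mean_pauc <- function(res, method, family) {
  mean(res$pauc[res$method == method & res$family == family])
}
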