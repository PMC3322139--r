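# One shared Monte-Carlo study reused by the acceptance-level tests:
# 2,000 replicate statistic-level panels at the default scaled genome,
# every method under prioritization scenarios (i) (six 2-Mb decoys) and
# (viii) (all six loci covered). Computed once per test run.

study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (!is.null(study_cache$study)) return(study_cache$study)
  cfg <- stat_panel_config()
  scen <- list(
    i = list(n_regions = 6, region_size_bp = 2e6, covered = "i"),
    viii = list(n_regions = 6, region_size_bp = 2e6, covered = "viii"))
  meth <- list(
    wga = list(method = "wga"),
    wei2 = list(method = "wei", r = 2),
    wei5 = list(method = "wei", r = 5),
    wei10 = list(method = "wei", r = 10),
    psa = list(method = "psa"),
    psa_adj = list(method = "psa", q = 0.044))
  study_cache$study <- run_scenario_study(cfg, scen, meth,
                                          n_replicates = 2000L, seed = 20260928L,
                                          q = 0.05)
  study_cache$study
}

study_row <- function(study, scenario, method) {
  which(study$combos$scenario == scenario & study$combos$method == method)
}

fdr_mean_se <- function(study, scenario, method) {
  k <- study_row(study, scenario, method)
  x <- study$fdp[, k]
  c(mean = mean(x), se = sd(x) / sqrt(length(x)))
}
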