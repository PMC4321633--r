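# small in-code fixtures shared across test files

# cohort with fully specified genotypes (alt copies) and covariates
tiny_cohort <- function(genotypes, phenotype,
                        sex = rep(0L, length(phenotype)),
                        age = seq_along(phenotype) + 40,
                        pos = NULL) {
  g <- as.matrix(genotypes)
  m <- ncol(g)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  map <- data.frame(variant_id = sprintf("v%02d", seq_len(m)),
                    pos = as.integer(pos),
                    ref = rep("A", m), alt = rep("G", m),
                    stringsAsFactors = FALSE)
  new_cohort(g, phenotype, sex, age, map)
}

# a small but complete simulated study configuration (minutes -> seconds)
mini_experiment_config <- function(seed = 5L, marker_panel_size = 5L, ...) {
  experiment_config(
    sim = sim_config(n_founders = 10L, n_population_haplotypes = 400L,
                     region_length_bp = 500000L, n_variants = 60L,
                     n_cases = 60L, n_controls = 60L,
                     panel_n_control = 10L, panel_n_case = 10L,
                     panel_n_external = 10L, rng_seed = seed),
    window_bp = 200000L, marker_panel_size = marker_panel_size,
    n_risk_minor = 4L, n_risk_major = 4L, ...)
}

# memoised full-scale study shared by the phenomenon-reproduction tests;
# computed once per test run
acceptance_study <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      cfg <- experiment_config(sim = sim_config(rng_seed = seed))
      cache[[key]] <- run_experiment(cfg, verbose = FALSE)
    }
    cache[[key]]
  }
})
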