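# End-to-end experiment: simulate -> QC -> split -> GWAS -> marker panels ->
# mask-and-impute under three reference conditions -> bias and deflation
# reports. Every stage draws from a named stream derived from the master
# seed, so the whole run is reproducible and stages can be re-run alone.

#' Experiment configuration
#'
#' @param sim a [sim_config()]
#' @param hmm an [hmm_params()]
#' @param window_bp imputation window width in bp (default 1 Mb, centered)
#' @param tol call tolerance `T` for integer calls (default 0.5)
#' @param marker_panel_size DAM and NAM panel sizes (default 100 each)
#' @param n_risk_minor,n_risk_major causal variants whose risk allele is
#'   the minor / major allele
#' @param causal_or per-copy odds ratio of every causal risk allele
#' @param prevalence target disease prevalence used to calibrate the
#'   disease-model intercept
#' @return list of class `experiment_config`
#' @export
experiment_config <- function(sim = sim_config(),
                              hmm = hmm_params(),
                              window_bp = 1000000L,
                              tol = 0.5,
                              marker_panel_size = 100L,
                              n_risk_minor = 55L,
                              n_risk_major = 55L,
                              causal_or = 2,
                              prevalence = 0.1) {
  stopifnot(inherits(sim, "sim_config"), inherits(hmm, "hmm_params"))
  structure(list(sim = sim, hmm = hmm,
                 window_bp = as.integer(window_bp), tol = tol,
                 marker_panel_size = as.integer(marker_panel_size),
                 n_risk_minor = as.integer(n_risk_minor),
                 n_risk_major = as.integer(n_risk_major),
                 causal_or = causal_or, prevalence = prevalence),
            class = "experiment_config")
}

config_hash <- function(cfg) {
  s <- paste(deparse(unclass_all(cfg)), collapse = "")
  # small rolling hash; stable across sessions, only used as a provenance tag
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else x
}

#' Simulate the full study inputs
#'
#' Founders, mosaic population pool, disease model (with its intercept
#' calibrated to the target prevalence), the case/control cohort, and an
#' independent phenotype-agnostic external haplotype pool.
#'
#' @param cfg an [experiment_config()]
#' @return list: `cohort`, `map`, `model`, `external_pool`, `seeds`
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  sim <- cfg$sim
  seeds <- stage_seeds(sim$rng_seed,
                       c("founders", "mosaic", "external", "model",
                         "phenotypes", "split", "panels"))
  founders <- generate_founder_haplotypes(sim, seed = seeds[["founders"]])
  pool <- generate_mosaic_haplotypes(founders$haplotypes, founders$map,
                                     sim$n_population_haplotypes,
                                     sim$switch_rate, sim$mutation_rate,
                                     seed = seeds[["mosaic"]])
  external_pool <- generate_mosaic_haplotypes(
    founders$haplotypes, founders$map,
    max(2L * sim$panel_n_external, 2L), sim$switch_rate, sim$mutation_rate,
    seed = seeds[["external"]])

  model <- make_disease_model(founders$map, cfg$n_risk_minor,
                              cfg$n_risk_major, or = cfg$causal_or,
                              seed = seeds[["model"]])
  model$baseline_logit <- calibrate_baseline(pool, founders$map, model,
                                             cfg$prevalence)
  cohort <- assign_phenotypes(pool, founders$map, model,
                              sim$n_cases, sim$n_controls,
                              seed = seeds[["phenotypes"]])
  list(cohort = cohort, map = founders$map, model = model,
       external_pool = external_pool, seeds = seeds)
}

# mask one marker and impute it under one panel, returning aligned truth /
# calls / dosages (alt-copy coding) for the masked samples
mask_impute_one <- function(cohort, variant_id, samples, panel, cfg) {
  masked <- mask_variant(cohort, variant_id, samples)
  imp <- impute_masked_panel(masked, variant_id, panel,
                             params = cfg$hmm, window_bp = cfg$window_bp,
                             tol = cfg$tol)
  truth <- masked_truth(masked, variant_id)[imp$samples]
  list(truth = truth, called = imp$called, dosage = imp$dosage,
       samples = imp$samples)
}

#' Run the full mask-and-impute bias experiment
#'
#' Executes, in order: simulation; QC filtering; stratified split; logistic
#' GWAS on split A; DAM/NAM selection; per-marker mask-and-impute of split-A
#' cases against the split-B control panel and the split-B case panel, and
#' of the full cohort against the external panel; discordance/bias
#' assessment under all three conditions; and odds-ratio deflation against
#' the external panel. With `out_dir` set, every stage writes its VCF/TSV
#' outputs and a manifest there.
#'
#' @param cfg an [experiment_config()]
#' @param out_dir optional output directory (created if missing)
#' @param verbose print stage progress
#' @return list of class `experiment_result`: `config`, `sim`, `qc`,
#'   `split`, `gwas_A`, `markers`, `panels`, `bias` (per variant x panel
#'   condition), `summaries`, `comparisons`, `deflation`, `deflation_nam`,
#'   `manifest`
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = NULL,
                           verbose = interactive()) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- proc.time()[["elapsed"]]
  hash <- config_hash(cfg)
  manifest <- list()
  note <- function(stage, started, outputs = "") {
    manifest[[stage]] <<- data.frame(
      stage = stage, elapsed_s = round(proc.time()[["elapsed"]] - started, 2),
      outputs = outputs, stringsAsFactors = FALSE)
    if (verbose) message(sprintf("[%s] done (%.1fs)", stage,
                                 proc.time()[["elapsed"]] - started))
  }
  if (!is.null(out_dir)) {
    for (d in c("", "cohort", "panels", "gwas", "imputed", "reports"))
      dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }

  ## 1. simulate ------------------------------------------------------------
  ts <- proc.time()[["elapsed"]]
  sim <- simulate_study(cfg)
  cohort <- sim$cohort
  if (!is.null(out_dir)) {
    write_cohort_vcf(cohort, file.path(out_dir, "cohort", "cohort.vcf"),
                     seed = cfg$sim$rng_seed, config_hash = hash)
    write_sample_metadata(cohort, file.path(out_dir, "cohort", "samples.tsv"),
                          seed = cfg$sim$rng_seed)
  }
  note("simulate", ts, "cohort/cohort.vcf cohort/samples.tsv")

  ## 2. qc ------------------------------------------------------------------
  ts <- proc.time()[["elapsed"]]
  qc <- qc_filter(cohort)
  cohort <- qc$cohort
  orientation <- determine_minor_allele(cohort)
  if (!is.null(out_dir))
    write_report_tsv(qc$report, file.path(out_dir, "reports", "qc.tsv"),
                     seed = cfg$sim$rng_seed)
  note("qc", ts, "reports/qc.tsv")

  ## 3. split ---------------------------------------------------------------
  ts <- proc.time()[["elapsed"]]
  sp <- stratified_split(cohort, seed = sim$seeds[["split"]])
  if (!is.null(out_dir)) {
    write_sample_metadata(sp$A, file.path(out_dir, "cohort", "splitA.tsv"))
    write_sample_metadata(sp$B, file.path(out_dir, "cohort", "splitB.tsv"))
  }
  note("split", ts, "cohort/splitA.tsv cohort/splitB.tsv")

  ## 4. gwas on split A -----------------------------------------------------
  ts <- proc.time()[["elapsed"]]
  gwas_A <- logistic_gwas(sp$A, orientation = orientation)
  if (!is.null(out_dir))
    write_report_tsv(cbind(gwas_A,
                           qc_pass = TRUE)[, c("variant_id", "pos", "maf", "b",
                                               "or_minor", "or_magnitude",
                                               "p_additive", "p_genotypic",
                                               "risk_allele", "qc_pass")],
                     file.path(out_dir, "gwas", "association.tsv"),
                     seed = cfg$sim$rng_seed)
  note("gwas", ts, "gwas/association.tsv")

  ## 5. marker selection ----------------------------------------------------
  ts <- proc.time()[["elapsed"]]
  markers <- select_dam_nam(gwas_A, panel_size = cfg$marker_panel_size)
  if (!is.null(out_dir)) {
    write_report_tsv(rbind(cbind(markers$dam, set = "DAM"),
                           cbind(markers$nam, set = "NAM")),
                     file.path(out_dir, "gwas", "markers.tsv"))
  }
  note("select", ts, "gwas/markers.tsv")

  ## 6. panels + mask-and-impute -------------------------------------------
  ts <- proc.time()[["elapsed"]]
  ext_pool <- sim$external_pool[, match(cohort$map$variant_id,
                                        sim$map$variant_id), drop = FALSE]
  panels <- build_reference_panels(sp$B, ext_pool,
                                   n_control = cfg$sim$panel_n_control,
                                   n_case = cfg$sim$panel_n_control,
                                   n_external = cfg$sim$panel_n_external,
                                   seed = sim$seeds[["panels"]])
  if (!is.null(out_dir)) {
    write_panel_vcf(panels$control_ref, cohort$map,
                    file.path(out_dir, "panels", "control_ref.vcf"))
    write_panel_vcf(panels$case_ref, cohort$map,
                    file.path(out_dir, "panels", "case_ref.vcf"))
    write_panel_vcf(panels$external_ref, cohort$map,
                    file.path(out_dir, "panels", "external_ref.vcf"))
  }

  marker_ids <- c(markers$dam$variant_id, markers$nam$variant_id)
  group_of <- c(setNames(ifelse(markers$dam$risk_allele == "major",
                                "DAM_major", "DAM_minor"),
                         markers$dam$variant_id),
                setNames(rep("NAM", nrow(markers$nam)),
                         markers$nam$variant_id))

  case_rows_A <- which(sp$A$phenotype == 1L)
  n_all <- nrow(cohort$genotypes)
  bias_rows <- vector("list", 3L * length(marker_ids))
  ext_calls <- matrix(NA_integer_, n_all, length(marker_ids),
                      dimnames = list(rownames(cohort$genotypes), marker_ids))
  ext_dosages <- matrix(NA_real_, n_all, length(marker_ids),
                        dimnames = list(rownames(cohort$genotypes), marker_ids))
  k <- 0L
  long_rows <- if (!is.null(out_dir)) vector("list", 2L * length(marker_ids))
  for (v in marker_ids) {
    ov <- orientation[orientation$variant_id == v, , drop = FALSE]
    grp <- group_of[[v]]
    # (a) split-A cases, split-B control reference
    ra <- mask_impute_one(sp$A, v, case_rows_A, panels$control_ref, cfg)
    # (b) split-A cases, split-B case reference
    rb <- mask_impute_one(sp$A, v, case_rows_A, panels$case_ref, cfg)
    # (c) full cohort, external reference
    rc <- mask_impute_one(cohort, v, seq_len(n_all), panels$external_ref, cfg)
    ext_calls[rc$samples, v] <- rc$called
    ext_dosages[rc$samples, v] <- rc$dosage
    bias_rows[[k + 1L]] <- bias_report_row(ra$truth, ra$called, ra$dosage,
                                           ov, v, "control", grp)
    bias_rows[[k + 2L]] <- bias_report_row(rb$truth, rb$called, rb$dosage,
                                           ov, v, "case", grp)
    bias_rows[[k + 3L]] <- bias_report_row(rc$truth, rc$called, rc$dosage,
                                           ov, v, "external", grp)
    k <- k + 3L
    if (!is.null(out_dir)) {
      sid <- rownames(sp$A$genotypes)[ra$samples]
      long_rows[[k / 3L * 2L - 1L]] <- data.frame(
        variant_id = v, panel = "control", sample_id = sid,
        truth = ra$truth, called = ra$called, dosage = ra$dosage,
        stringsAsFactors = FALSE)
      long_rows[[k / 3L * 2L]] <- data.frame(
        variant_id = v, panel = "case", sample_id = sid,
        truth = rb$truth, called = rb$called, dosage = rb$dosage,
        stringsAsFactors = FALSE)
    }
  }
  bias <- do.call(rbind, bias_rows)
  if (!is.null(out_dir))
    write_report_tsv(do.call(rbind, long_rows),
                     file.path(out_dir, "imputed", "splitA_imputed.tsv"),
                     seed = cfg$sim$rng_seed)
  if (!is.null(out_dir)) {
    midx <- sort(match(marker_ids, cohort$map$variant_id))
    ids_sorted <- cohort$map$variant_id[midx]
    write_dosage_vcf(ext_dosages[, ids_sorted, drop = FALSE],
                     cohort$map[midx, , drop = FALSE],
                     file.path(out_dir, "imputed", "external_dosages.vcf"),
                     calls = ext_calls[, ids_sorted, drop = FALSE],
                     seed = cfg$sim$rng_seed, config_hash = hash)
    write_report_tsv(bias, file.path(out_dir, "reports", "bias.tsv"),
                     seed = cfg$sim$rng_seed)
  }
  note("impute", ts,
       "panels/*.vcf imputed/external_dosages.vcf reports/bias.tsv")

  ## 7. assessment ----------------------------------------------------------
  ts <- proc.time()[["elapsed"]]
  summaries <- bias_group_summaries(bias)
  comparisons <- bias_group_comparisons(bias)

  midx <- sort(match(marker_ids, cohort$map$variant_id))
  ids_sorted <- cohort$map$variant_id[midx]
  # sub-cohort keeps the pre-mask truth: masking happened on copies
  sub <- subset_cohort(cohort, variants = midx)
  orient_sub <- orientation[midx, , drop = FALSE]
  true_fit <- logistic_gwas(sub, orientation = orient_sub)
  int_fit <- logistic_gwas(sub, orientation = orient_sub,
                           genotypes = ext_calls[, ids_sorted, drop = FALSE])
  frac_fit <- logistic_gwas(sub, orientation = orient_sub,
                            genotypes = ext_dosages[, ids_sorted, drop = FALSE])
  deflation <- or_deflation(true_fit, int_fit, frac_fit,
                            markers$dam$variant_id)
  deflation_nam <- or_deflation(true_fit, int_fit, frac_fit,
                                markers$nam$variant_id)
  if (!is.null(out_dir)) {
    write_report_tsv(deflation, file.path(out_dir, "reports", "deflation.tsv"),
                     seed = cfg$sim$rng_seed)
    write_report_tsv(summaries, file.path(out_dir, "reports", "summary.tsv"),
                     seed = cfg$sim$rng_seed)
  }
  note("assess", ts, "reports/deflation.tsv reports/summary.tsv")

  manifest <- do.call(rbind, manifest)
  manifest$config_hash <- hash
  manifest$seed <- cfg$sim$rng_seed
  if (!is.null(out_dir))
    write_report_tsv(manifest, file.path(out_dir, "manifest"))
  if (verbose)
    message(sprintf("experiment complete in %.1fs",
                    proc.time()[["elapsed"]] - t0))

  structure(list(config = cfg, sim = sim, qc = qc$report, split = sp,
                 gwas_A = gwas_A, markers = markers, panels = panels,
                 bias = bias, summaries = summaries,
                 comparisons = comparisons, deflation = deflation,
                 deflation_nam = deflation_nam, manifest = manifest),
            class = "experiment_result")
}

#' Group summaries of a bias report
#'
#' Mean and 2-SE interval of each metric per marker group x reference
#' condition.
#'
#' @param bias bias report data.frame (see [run_experiment()])
#' @return data.frame with one row per group x panel x metric
#' @export
bias_group_summaries <- function(bias) {
  out <- list()
  for (panel in unique(bias$panel)) {
    for (grp in unique(bias$group)) {
      sel <- bias$panel == panel & bias$group == grp
      if (!any(sel)) next
      for (metric in c("D_int", "B_int", "D_frac", "B_frac")) {
        s <- group_summary(bias[[metric]][sel],
                           label = paste(grp, panel, sep = "|"))
        s$metric <- metric
        out[[length(out) + 1L]] <- s
      }
    }
  }
  do.call(rbind, out)
}

#' Headline statistical comparisons of a bias report
#'
#' DAM vs NAM discordance (unpaired), control- vs case-reference
#' discordance and |bias| on the same markers (paired), and per-group sign
#' tests of the fractional bias direction under the control reference.
#'
#' @param bias bias report data.frame
#' @return named list of test results
#' @export
bias_group_comparisons <- function(bias) {
  ctrl <- bias[bias$panel == "control", ]
  case <- bias[bias$panel == "case", ]
  case <- case[match(ctrl$variant_id, case$variant_id), ]
  is_dam <- ctrl$group != "NAM"
  list(
    dam_vs_nam_dint_control = compare_groups_unpaired(
      ctrl$D_int[is_dam], ctrl$D_int[!is_dam]),
    control_vs_case_dint_dam = compare_groups_paired(
      ctrl$D_int[is_dam], case$D_int[is_dam]),
    control_vs_case_absbias_dam = compare_groups_paired(
      abs(ctrl$B_frac[is_dam]), abs(case$B_frac[is_dam])),
    sign_bfrac_dam_minor_control = sign_test(
      ctrl$B_frac[ctrl$group == "DAM_minor"], "greater"),
    sign_bfrac_dam_major_control = sign_test(
      ctrl$B_frac[ctrl$group == "DAM_major"], "less")
  )
}
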