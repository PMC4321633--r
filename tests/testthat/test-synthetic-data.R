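test_that("founder generation respects shape, ordering and seeding", {
  cfg <- sim_config(n_founders = 10L, n_variants = 50L,
                    region_length_bp = 100000L, rng_seed = 7L)
  f1 <- generate_founder_haplotypes(cfg)
  expect_equal(dim(f1$haplotypes), c(10L, 50L))
  expect_true(all(f1$haplotypes %in% c(0L, 1L)))
  expect_true(all(diff(f1$map$pos) > 0))
  expect_true(all(f1$map$pos <= cfg$region_length_bp))
  expect_false(anyDuplicated(f1$map$variant_id) > 0)

  f2 <- generate_founder_haplotypes(cfg)
  expect_identical(f1$haplotypes, f2$haplotypes)
  expect_identical(f1$map, f2$map)
})

test_that("degenerate maf range pins every founder frequency", {
  cfg <- sim_config(n_founders = 12L, n_variants = 30L,
                    region_length_bp = 50000L,
                    maf_range = c(0.5, 0.5), rng_seed = 3L)
  f <- generate_founder_haplotypes(cfg)
  # frequencies are draws at p = 0.5; check they are centred there
  freqs <- colMeans(f$haplotypes)
  expect_true(abs(mean(freqs) - 0.5) < 0.1)
})

test_that("more variants than positions is rejected", {
  expect_error(sim_config(n_variants = 100L, region_length_bp = 50L),
               "cannot place")
})

test_that("mosaic limits: exact copies, forced complement, perfect LD", {
  cfg <- sim_config(n_founders = 4L, n_variants = 40L,
                    region_length_bp = 200000L, rng_seed = 2L)
  f <- generate_founder_haplotypes(cfg)

  out <- generate_mosaic_haplotypes(f$haplotypes, f$map, 20L,
                                    switch_rate = 0, mutation_rate = 0,
                                    seed = 9L)
  matches <- apply(out, 1L, function(h)
    any(apply(f$haplotypes, 1L, function(fh) all(fh == h))))
  expect_true(all(matches))

  flipped <- generate_mosaic_haplotypes(f$haplotypes, f$map, 20L,
                                        switch_rate = 0, mutation_rate = 1,
                                        seed = 9L)
  expect_identical(flipped, 1L - out)

  # two founders differing at every site, no switching or mutation:
  # all segregating pairs have r^2 = 1
  fd <- rbind(rep(0L, 10), rep(1L, 10))
  map2 <- data.frame(variant_id = sprintf("v%02d", 1:10),
                     pos = (1:10) * 100L, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  h <- generate_mosaic_haplotypes(fd, map2, 50L, 0, 0, seed = 4L)
  r2 <- suppressWarnings(cor(h))^2
  seg <- apply(h, 2, function(x) length(unique(x)) > 1)
  expect_true(all(abs(r2[seg, seg] - 1) < 1e-12))

  expect_error(generate_mosaic_haplotypes(matrix(0L, 0, 5), map2, 3L, 0, 0, 1L),
               "empty")
})

test_that("LD decays with distance under mosaic switching", {
  cfg <- sim_config(n_founders = 20L, n_variants = 80L,
                    region_length_bp = 1000000L, rng_seed = 13L)
  bins <- c(0, 5e4, 2e5, 1e6)
  acc <- matrix(0, 10, length(bins) - 1)
  for (r in 1:10) {
    f <- generate_founder_haplotypes(cfg, seed = 100 + r)
    h <- generate_mosaic_haplotypes(f$haplotypes, f$map, 200L,
                                    switch_rate = 1e-5, mutation_rate = 0.005,
                                    seed = 200 + r)
    keep <- apply(h, 2, function(x) length(unique(x)) > 1)
    r2 <- suppressWarnings(cor(h[, keep]))^2
    d <- abs(outer(f$map$pos[keep], f$map$pos[keep], "-"))
    ut <- upper.tri(d)
    bin <- cut(d[ut], bins, labels = FALSE)
    acc[r, ] <- tapply(r2[ut], bin, mean, na.rm = TRUE)
  }
  avg <- colMeans(acc)
  expect_true(all(diff(avg) < 0))
})

test_that("phenotype assignment keeps genotype-haplotype consistency", {
  cfg <- sim_config(n_founders = 8L, n_population_haplotypes = 300L,
                    n_variants = 40L, region_length_bp = 200000L,
                    rng_seed = 21L)
  f <- generate_founder_haplotypes(cfg)
  pool <- generate_mosaic_haplotypes(f$haplotypes, f$map, 300L, 1e-5, 0.005,
                                     seed = 22L)
  model <- make_disease_model(f$map, 2L, 2L, or = 2, baseline_logit = -2,
                              seed = 23L)
  coh <- assign_phenotypes(pool, f$map, model, 50L, 50L, seed = 24L)
  expect_equal(sum(coh$phenotype == 1L), 50L)
  expect_equal(sum(coh$phenotype == 0L), 50L)
  n <- nrow(coh$genotypes)
  sums <- coh$truth_haplotypes[2 * seq_len(n) - 1L, ] +
    coh$truth_haplotypes[2 * seq_len(n), ]
  expect_identical(unname(coh$genotypes), sums)
})

test_that("null disease model leaves case/control frequencies exchangeable", {
  cfg <- sim_config(n_founders = 12L, n_variants = 100L,
                    region_length_bp = 500000L, rng_seed = 31L)
  f <- generate_founder_haplotypes(cfg)
  pool <- generate_mosaic_haplotypes(f$haplotypes, f$map, 2000L, 1e-5, 0.005,
                                     seed = 32L)
  null_model <- make_disease_model(f$map, 1L, 1L, or = 1,
                                   baseline_logit = qlogis(0.3), seed = 33L)
  null_model$effect[] <- 0
  coh <- assign_phenotypes(pool, f$map, null_model, 300L, 300L, seed = 34L)
  g_case <- coh$genotypes[coh$phenotype == 1L, ]
  g_ctrl <- coh$genotypes[coh$phenotype == 0L, ]
  f1 <- colMeans(g_case) / 2
  f0 <- colMeans(g_ctrl) / 2
  pbar <- (f1 + f0) / 2
  se <- sqrt(pbar * (1 - pbar) * (1 / (2 * 300) + 1 / (2 * 300)))
  poly <- pbar > 0 & pbar < 1
  z <- abs(f1 - f0)[poly] / se[poly]
  expect_gte(mean(z < 3), 0.95)
  expect_lt(mean(z > 1.96), 0.12)  # approx 5% under the null
})

test_that("a planted odds ratio of 2 is recovered by logistic refit", {
  cfg <- sim_config(n_founders = 12L, n_variants = 50L,
                    region_length_bp = 300000L, rng_seed = 41L)
  f <- generate_founder_haplotypes(cfg)
  pool <- generate_mosaic_haplotypes(f$haplotypes, f$map, 3000L, 1e-5, 0.005,
                                     seed = 42L)
  model <- list(variant_id = f$map$variant_id[25], effect = log(2),
                baseline_logit = 0)
  class(model) <- "disease_model"
  model$baseline_logit <- calibrate_baseline(pool, f$map, model, 0.1)
  coh <- assign_phenotypes(pool, f$map, model, 2000L, 2000L, seed = 43L)
  y <- coh$phenotype
  x <- coh$genotypes[, 25]
  fit <- glm(y ~ x, family = binomial())
  expect_gt(exp(coef(fit)[["x"]]), 1.7)
  expect_lt(exp(coef(fit)[["x"]]), 2.3)
})

test_that("empty case arm yields a control-only cohort", {
  cfg <- sim_config(n_founders = 6L, n_variants = 20L,
                    region_length_bp = 50000L, rng_seed = 51L)
  f <- generate_founder_haplotypes(cfg)
  pool <- generate_mosaic_haplotypes(f$haplotypes, f$map, 100L, 0, 0, seed = 52L)
  model <- make_disease_model(f$map, 1L, 0L, or = 1.5, baseline_logit = -2,
                              seed = 53L)
  coh <- assign_phenotypes(pool, f$map, model, 0L, 20L, seed = 54L)
  expect_equal(sum(coh$phenotype == 1L), 0L)
  expect_equal(nrow(coh$genotypes), 20L)
})

test_that("unattainable case counts fail with a clear error", {
  cfg <- sim_config(n_founders = 6L, n_variants = 20L,
                    region_length_bp = 50000L, rng_seed = 61L)
  f <- generate_founder_haplotypes(cfg)
  pool <- generate_mosaic_haplotypes(f$haplotypes, f$map, 100L, 0, 0, seed = 62L)
  model <- make_disease_model(f$map, 1L, 0L, or = 1, baseline_logit = -30,
                              seed = 63L)
  expect_error(assign_phenotypes(pool, f$map, model, 50L, 10L, seed = 64L,
                                 max_attempts = 500L),
               "could not reach")
})

test_that("reference panels are sized, disjoint and reproducible", {
  cfg <- mini_experiment_config(seed = 71L)
  sim <- simulate_study(cfg)
  coh <- sim$cohort
  p1 <- build_reference_panels(coh, sim$external_pool,
                               n_control = 10L, n_external = 8L, seed = 72L)
  expect_equal(nrow(p1$control_ref), 20L)
  expect_equal(nrow(p1$case_ref), 20L)
  expect_equal(nrow(p1$external_ref), 16L)
  p2 <- build_reference_panels(coh, sim$external_pool,
                               n_control = 10L, n_external = 8L, seed = 72L)
  expect_identical(p1, p2)
  expect_error(build_reference_panels(coh, sim$external_pool,
                                      n_control = 10L, n_case = 12L,
                                      n_external = 5L, seed = 1L),
               "equal number")
  expect_error(build_reference_panels(coh, matrix(0L, 0, 60),
                                      n_control = 5L, n_external = 5L,
                                      seed = 1L),
               "external pool")
  expect_error(build_reference_panels(coh, sim$external_pool,
                                      n_control = 1000L, n_external = 5L,
                                      seed = 1L),
               "only .* available")
})
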