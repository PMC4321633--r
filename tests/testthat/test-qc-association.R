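test_that("QC removes low-MAF, HWE-failing and low-call-rate variants", {
  set.seed(5)
  n <- 200
  # v1: maf 0.04 (fails MAF); v2: extreme HWE violation in controls;
  # v3: call rate exactly 0.95 (fails strict inequality); v4: clean
  v1 <- c(rep(1L, 14), rep(0L, n - 14))   # maf 0.035
  v2 <- rep(c(0L, 2L), n / 2)           # no heterozygotes at freq 0.5
  v3 <- rbinom(n, 2, 0.3); v3[seq_len(n * 0.05)] <- NA
  v4 <- rbinom(n, 2, 0.3)
  coh <- tiny_cohort(cbind(v1, v2, v3, v4),
                     phenotype = rep(c(1L, 0L), each = n / 2))
  out <- qc_filter(coh)
  expect_equal(out$report$pass, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(ncol(out$cohort$genotypes), 1L)
  expect_equal(out$cohort$map$variant_id, "v04")
})

test_that("QC leaves an all-passing cohort untouched and needs controls", {
  set.seed(6)
  g <- matrix(rbinom(300, 2, 0.3), 100, 3)
  coh <- tiny_cohort(g, phenotype = rep(c(1L, 0L), 50))
  out <- qc_filter(coh)
  expect_true(all(out$report$pass))
  expect_identical(out$cohort$genotypes, coh$genotypes)

  all_cases <- tiny_cohort(g, phenotype = rep(1L, 100))
  expect_error(qc_filter(all_cases), "no controls")
})

test_that("stratified split halves every stratum and is seeded", {
  set.seed(7)
  n <- 800
  coh <- tiny_cohort(matrix(rbinom(n * 2, 2, 0.3), n, 2),
                     phenotype = rep(c(1L, 0L), each = n / 2),
                     sex = rep(c(0L, 1L), n / 2),
                     age = rnorm(n, 60, 10))
  sp <- stratified_split(coh, seed = 99L)
  expect_lte(abs(sum(sp$A$phenotype == 1L) - 200L), 1L)
  expect_lte(abs(sum(sp$A$phenotype == 0L) - 200L), 1L)
  expect_lte(abs(sum(sp$A$sex) - sum(sp$B$sex)), 8L)
  expect_length(intersect(sp$idx_A, sp$idx_B), 0L)
  expect_equal(sort(c(sp$idx_A, sp$idx_B)), seq_len(n))

  sp2 <- stratified_split(coh, seed = 99L)
  expect_identical(sp$idx_A, sp2$idx_A)
})

test_that("splitting works with degenerate strata", {
  coh <- tiny_cohort(matrix(rbinom(40, 2, 0.3), 20, 2),
                     phenotype = rep(c(1L, 0L), each = 10),
                     sex = rep(0L, 20), age = rep(50, 20))
  sp <- stratified_split(coh, seed = 1L)
  expect_equal(sum(sp$A$phenotype == 1L), 5L)
  expect_equal(sum(sp$A$phenotype == 0L), 5L)
})

test_that("logistic fit on a binary predictor equals the cross-product OR", {
  # dominant-coded 2x2 table: exposed cases 30, unexposed cases 70,
  # exposed controls 10, unexposed controls 90 -> OR = 27/7
  y <- c(rep(1L, 100), rep(0L, 100))
  x <- c(rep(1L, 30), rep(0L, 70), rep(1L, 10), rep(0L, 90))
  coh <- tiny_cohort(cbind(x), phenotype = y)
  res <- logistic_gwas(coh)
  expect_equal(res$or_minor, 27 / 7, tolerance = 1e-6)
  expect_equal(res$risk_allele, "minor")

  # property over seeded random 2x2 tables
  set.seed(11)
  for (i in 1:25) {
    tab <- rbinom(4, 40, runif(4, 0.2, 0.8)) + 1L
    y <- rep(c(1L, 1L, 0L, 0L), tab)
    x <- rep(c(1L, 0L, 1L, 0L), tab)
    if (mean(x) >= 0.5) x <- 1L - x  # keep exposure the minor allele
    coh <- tiny_cohort(cbind(x), phenotype = y)
    res <- logistic_gwas(coh)
    or_cp <- (sum(y & x) * sum(!y & !x)) / (sum(!y & x) * sum(y & !x))
    expect_equal(res$or_minor, or_cp, tolerance = 1e-6)
  }
})

test_that("null genotypes give approximately uniform additive p-values", {
  set.seed(12)
  n <- 300; m <- 2000
  g <- matrix(rbinom(n * m, 2, 0.3), n, m)
  coh <- tiny_cohort(g, phenotype = rep(c(1L, 0L), each = n / 2),
                     pos = seq_len(m) * 100L)
  res <- logistic_gwas(coh)
  p <- res$p_additive[!is.na(res$p_additive)]
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(res$or_minor, na.rm = TRUE) - 1), 0.05)
})

test_that("constant and separated predictors are flagged and excluded", {
  y <- rep(c(1L, 0L), each = 20)
  g <- cbind(rep(1L, 40),              # constant
             c(rep(1L, 20), rep(0L, 20)),  # perfect separation
             rbinom(40, 2, 0.4))
  coh <- tiny_cohort(g, phenotype = y)
  res <- logistic_gwas(coh)
  expect_equal(res$flag[1], "monomorphic")
  expect_equal(res$flag[2], "separation")
  expect_true(is.na(res$b[1]) && is.na(res$b[2]))
  expect_equal(res$flag[3], "")
})

test_that("DAM/NAM selection ranks by OR magnitude with documented ties", {
  mk <- function(id, orm, p) data.frame(variant_id = id, pos = 1L, maf = 0.2,
                                        b = log(orm), or_minor = orm,
                                        or_magnitude = orm, p_additive = p,
                                        p_genotypic = p, risk_allele = "minor",
                                        flag = "", stringsAsFactors = FALSE)
  res <- do.call(rbind, Map(mk, c("a", "b", "c", "d", "e", "f"),
                            c(3.0, 2.0, 1.5, 1.0005, 1.0001, 1.0),
                            c(0.01, 0.01, 0.1, 0.5, 0.6, 0.9)))
  panel <- select_dam_nam(res, panel_size = 2L)
  expect_setequal(panel$dam$variant_id, c("a", "b"))
  expect_setequal(panel$nam$variant_id, c("e", "f"))
  expect_equal(panel$dam_or_threshold, 2.0)

  # tie at the DAM boundary: broken by smaller p, then variant id
  res2 <- do.call(rbind, Map(mk, c("a", "b", "c", "d"),
                             c(2.0, 2.0, 2.0, 1.0),
                             c(0.5, 0.01, 0.5, 0.9)))
  panel2 <- select_dam_nam(res2, panel_size = 1L)
  expect_equal(panel2$dam$variant_id, "b")

  expect_error(select_dam_nam(res, panel_size = 4L), "at least 8")
})
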