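make_map <- function(pos) {
  data.frame(variant_id = sprintf("v%02d", seq_along(pos)),
             pos = as.integer(pos), ref = "A", alt = "G",
             stringsAsFactors = FALSE)
}

test_that("window selection is positional, centered and excludes the query", {
  map <- make_map(c(10000, 499000, 500000, 501000, 999000, 1100000))
  idx <- select_window(map, "v03", window_bp = 1000000L)
  expect_equal(map$pos[idx], c(10000, 499000, 501000, 999000))

  # window larger than the region: everything else
  idx2 <- select_window(map, "v03", window_bp = 10000000L)
  expect_equal(length(idx2), 5L)

  map2 <- make_map(c(100, 2000000))
  expect_error(select_window(map2, "v01", 1000000L), "cannot impute")
  expect_error(select_window(map, "nope"), "unknown variant")
})

test_that("calling rule reproduces the tolerance intervals exactly", {
  expect_equal(call_integer_genotype(0.4, 0.5), 0L)
  expect_true(is.na(call_integer_genotype(0.4, 0.3)))
  expect_equal(call_integer_genotype(1.5, 0.5), 2L)
  expect_equal(call_integer_genotype(0.5, 0.5), 1L)
  expect_error(call_integer_genotype(2.4), "\\[0, 2\\]")
  expect_error(call_integer_genotype(1, 0.6), "tol")
  expect_true(is.na(call_integer_genotype(NA_real_)))
})

test_that("calling at T = 0.5 is total and rounds to nearest genotype", {
  d <- seq(0, 2, by = 1e-3)
  calls <- call_integer_genotype(d, 0.5)
  expect_false(anyNA(calls))
  expect_equal(calls, ifelse(d < 0.5, 0L, ifelse(d < 1.5, 1L, 2L)))
})

test_that("a degenerate panel of identical haplotypes forces the genotype", {
  panel <- matrix(0L, 6, 4)
  post <- impute_sample(c(0L, 0L, NA, 0L), panel, c(1, 2, 3, 4) * 1000, 3,
                        hmm_params(1e-6, 0))
  expect_equal(post, c(1, 0, 0))
})

test_that("a perfect proxy with no copying error recovers exact dosages", {
  # panel alleles at masked site equal those at the proxy site (r^2 = 1)
  set.seed(14)
  a <- rbinom(12, 1, 0.5)
  panel <- cbind(a, rbinom(12, 1, 0.5), a)
  pos <- c(1000, 5000, 1200)  # proxy adjacent to the masked site
  pos <- sort(pos)
  panel <- panel[, order(c(1000, 5000, 1200))]
  for (g in c(0L, 2L)) {
    post <- impute_sample(c(g, NA, NA), panel, pos, 2,
                          hmm_params(1e-9, 0))
    expect_equal(post[g + 1L], 1, tolerance = 1e-6)
  }
})

test_that("forward-backward equals exhaustive path enumeration", {
  for (s in 1:40) {
    inst <- random_ls_instance(s)
    fb <- impute_sample(inst$obs, inst$panel, inst$pos, inst$masked,
                        hmm_params(inst$rho, inst$eps))
    en <- ls_posterior_enum(inst$panel, inst$obs, inst$pos, inst$masked,
                            inst$rho, inst$eps)
    expect_equal(fb, en, tolerance = 1e-8, label = paste("instance", s))
    expect_equal(sum(fb), 1, tolerance = 1e-12)
  }
})

test_that("uninformative flanking sites leave the dosage unchanged", {
  set.seed(15)
  a <- rbinom(10, 1, 0.5)
  panel <- cbind(a, a)                      # proxy + masked site
  pos <- c(1000, 1100)
  p_base <- impute_sample(c(2L, NA), panel, pos, 2, hmm_params(1e-6, 0))
  # add flanking sites where every panel haplotype is identical and the
  # query matches: they carry no information about the copied template
  panel2 <- cbind(1L, a, a, 0L)
  pos2 <- c(500, 1000, 1100, 2000)
  p_aug <- impute_sample(c(2L, 2L, NA, 0L), panel2, pos2, 3,
                         hmm_params(1e-6, 0))
  expect_equal(p_aug, p_base, tolerance = 1e-12)
})

test_that("the engine is numerically stable on large panels and windows", {
  set.seed(16)
  H <- 200; L <- 500
  panel <- matrix(rbinom(H * L, 1, 0.3), H, L)
  pos <- sort(sample.int(3000000L, L))
  obs <- rbinom(L, 2, 0.3); obs[250] <- NA
  post <- impute_sample(obs, panel, pos, 250, hmm_params())
  expect_equal(sum(post), 1, tolerance = 1e-12)
  expect_true(all(post >= 0))
})

test_that("degenerate inputs are rejected", {
  panel <- matrix(c(0L, 1L), 1, 2)
  expect_error(impute_sample(c(0L, NA), panel, c(1, 2), 2),
               "at least 2 haplotypes")
  panel2 <- rbind(c(0L, 1L), c(1L, 0L))
  expect_error(impute_sample(c(NA, NA), panel2, c(1, 2), 2),
               "all flanking")
  panel3 <- rbind(c(0L, NA), c(1L, 0L))
  expect_error(impute_sample(c(0L, NA), panel3, c(1, 2), 2),
               "complete")
})

test_that("batch imputation is deterministic and handles failed samples", {
  set.seed(17)
  m <- 12
  g <- matrix(rbinom(8 * m, 2, 0.4), 8, m)
  g[3, ] <- NA  # this sample has no flanking information at all
  coh <- tiny_cohort(g, phenotype = rep(c(1L, 0L), 4),
                     pos = seq_len(m) * 5000L)
  panel <- matrix(rbinom(10 * m, 1, 0.4), 10, m)
  masked <- mask_variant(coh, "v06")
  r1 <- impute_masked_panel(masked, "v06", panel, window_bp = 100000L)
  r2 <- impute_masked_panel(masked, "v06", panel, window_bp = 100000L)
  expect_identical(r1, r2)
  expect_true(is.na(r1$dosage[3]))
  expect_true(all(r1$dosage[-3] >= 0 & r1$dosage[-3] <= 2))
  expect_equal(rowSums(r1$posterior[-3, ]), rep(1, 7), tolerance = 1e-12)

  expect_error(impute_masked_panel(coh, "v06", panel), "not been masked")
  panel_na <- panel; panel_na[1, 2] <- NA
  expect_error(impute_masked_panel(masked, "v06", panel_na), "complete")
})
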