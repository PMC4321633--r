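test_that("integer discordance decomposes into major and minor errors", {
  # minor-copy coding: sample 2 under-calls the minor allele (D_M event),
  # sample 4 over-calls it (D_m event)
  r <- integer_discordance_bias(c(0L, 1L, 2L, 1L), c(0L, 0L, 2L, 2L))
  expect_equal(r$D_M, 25)
  expect_equal(r$D_m, 25)
  expect_equal(r$D_int, 50)
  expect_equal(r$B_int, 0)
  expect_equal(r$n_evaluated, 4L)

  expect_equal(integer_discordance_bias(c(1L, 1L), c(1L, 1L)),
               list(D_M = 0, D_m = 0, D_int = 0, B_int = 0, n_evaluated = 2L))

  r2 <- integer_discordance_bias(c(1L, 1L), c(0L, 0L))
  expect_equal(r2$D_M, 100)
  expect_equal(r2$B_int, 100)
})

test_that("missing calls drop out of numerator and denominator alike", {
  r <- integer_discordance_bias(c(0L, 1L, NA, 2L), c(0L, NA, 1L, 0L))
  expect_equal(r$n_evaluated, 2L)
  expect_equal(r$D_M, 50)
  expect_error(integer_discordance_bias(c(NA_integer_), c(1L)), "no evaluable")
  expect_error(integer_discordance_bias(c(1L, 2L), c(1L)), "aligned")
})

test_that("fractional discordance and bias match hand computation", {
  r <- fractional_discordance_bias(c(0L, 2L), c(0.5, 1.5))
  expect_equal(r$D_frac, 0.5)
  expect_equal(r$B_frac, 0)

  expect_equal(fractional_discordance_bias(c(1L, 1L), c(1, 1))$D_frac, 0)

  # minor copies under-called by one on average: major over-predicted
  r2 <- fractional_discordance_bias(c(2L, 2L), c(1.0, 1.0))
  expect_equal(r2$D_frac, 1)
  expect_equal(r2$B_frac, 1)
})

test_that("bias never exceeds discordance over random columns", {
  set.seed(18)
  for (i in 1:500) {
    n <- sample(2:50, 1)
    truth <- sample(0:2, n, TRUE)
    called <- sample(c(0:2, NA), n, TRUE)
    if (all(is.na(called))) next
    dosage <- pmin(2, pmax(0, truth + rnorm(n, 0, 0.7)))
    ri <- tryCatch(integer_discordance_bias(truth, called),
                   error = function(e) NULL)
    if (!is.null(ri)) {
      expect_identical(ri$D_int, ri$D_M + ri$D_m)
      expect_lte(abs(ri$B_int), ri$D_int)
      expect_true(all(c(ri$D_M, ri$D_m, ri$D_int) >= 0 &
                        c(ri$D_M, ri$D_m, ri$D_int) <= 100))
    }
    rf <- fractional_discordance_bias(truth, dosage)
    expect_lte(abs(rf$B_frac), rf$D_frac + 1e-12)
  }
})

test_that("swapping allele labels negates bias and preserves discordance", {
  set.seed(19)
  for (i in 1:50) {
    truth <- sample(0:2, 30, TRUE)
    called <- sample(0:2, 30, TRUE)
    dosage <- runif(30, 0, 2)
    a_i <- integer_discordance_bias(truth, called)
    b_i <- integer_discordance_bias(2L - truth, 2L - called)
    expect_equal(b_i$D_M, a_i$D_m)
    expect_equal(b_i$D_m, a_i$D_M)
    expect_equal(b_i$D_int, a_i$D_int)
    expect_equal(b_i$B_int, -a_i$B_int)
    a_f <- fractional_discordance_bias(truth, dosage)
    b_f <- fractional_discordance_bias(2L - truth, 2 - dosage)
    expect_equal(b_f$D_frac, a_f$D_frac)
    expect_equal(b_f$B_frac, -a_f$B_frac)
  }
})

test_that("report rows convert alt coding through the orientation", {
  ori <- data.frame(variant_id = "v01", minor_is_alt = FALSE, maf = 0.3)
  # alt copies; minor = ref, so minor copies are 2 - alt
  row <- bias_report_row(truth_alt = c(2L, 2L, 0L),
                         called_alt = c(2L, 1L, 0L),
                         dosage_alt = c(2, 1.5, 0.25),
                         orientation = ori, panel = "control", group = "NAM")
  # minor-coded truth (0,0,2) vs calls (0,1,2): one minor over-call
  expect_equal(row$D_m, 100 / 3, tolerance = 1e-12)
  expect_equal(row$D_M, 0)
  expect_equal(row$B_int, -100 / 3, tolerance = 1e-12)
  expect_equal(row$B_frac, mean(c(0, -0.5, 0.25)), tolerance = 1e-12)
})

test_that("group summaries report mean with symmetric 2-SE bounds", {
  x <- c(1, 2, 3, 4, 5)
  s <- group_summary(x, "demo")
  expect_equal(s$mean, 3)
  expect_equal(s$ci_hi - s$mean, s$mean - s$ci_lo)
  expect_equal(s$ci_hi, 3 + 2 * sd(x) / sqrt(5))
  expect_error(group_summary(numeric(0)), "no values")
})
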