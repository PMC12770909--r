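test_that("the WHR statistic depends only on angle differences", {
  withr::with_seed(1, {
    th <- runif(20, 0, 2 * pi)
    w <- runif(20)
  })
  t0 <- whr_statistic(th, w)
  for (rot in c(0.3, pi, 5.9)) {
    expect_equal(whr_statistic((th + rot) %% (2 * pi), w), t0,
                 tolerance = 1e-9)
  }
  # simultaneous permutation of angles and weights
  withr::with_seed(2, perm <- sample.int(20))
  expect_equal(whr_statistic(th[perm], w[perm]), t0)

  # hand evaluation of the kernel for two antipodal unit-weight angles
  k0 <- pi / 2 - 2.895 * 2 / pi
  kpi <- abs(pi - pi) - pi / 2 + 2.895 * (abs(sin(pi)) - 2 / pi)
  expect_equal(whr_statistic(c(0, pi), c(1, 1)), 2 * k0 + 2 * kpi)

  expect_error(whr_statistic(1, 1), "at least 2")
  expect_error(whr_statistic(c(1, 2), 1), "length mismatch")
})

make_null_records <- function(n_ind, seed, lags = default_phase_lags()) {
  withr::with_seed(seed, {
    tibble::tibble(
      individual_id = rep(sprintf("i%02d", seq_len(n_ind)),
                          each = length(lags)),
      phase_lag = rep(lags, n_ind),
      value = rnorm(n_ind * length(lags))
    )
  })
}

test_that("the permutation test statistic matches the direct double sum", {
  rec <- make_null_records(5, 33)
  tst <- phase_modulation_test(rec, n_perm = 199, seed = 4)
  w <- (rec$value - min(rec$value)) / diff(range(rec$value))
  expect_equal(tst$statistic, whr_statistic(rec$phase_lag, w),
               tolerance = 1e-9)
  expect_gte(tst$p_raw, 1 / 200)
})

test_that("the permutation test is seeded, reproducible and valid at the
           degenerate extremes", {
  rec <- make_null_records(6, 7)
  a <- phase_modulation_test(rec, n_perm = 299, seed = 11)
  b <- phase_modulation_test(rec, n_perm = 299, seed = 11)
  expect_identical(a$p_raw, b$p_raw)
  c <- phase_modulation_test(rec, n_perm = 299, seed = 12)
  expect_true(is.numeric(c$p_raw)) # different stream still valid

  # identical values at all lags: every permutation reproduces T_obs
  flat <- rec
  flat$value <- 1
  expect_equal(phase_modulation_test(flat, n_perm = 199, seed = 1)$p_raw, 1)

  # strongly sinusoidal modulation: minimum attainable p
  strong <- rec
  strong$value <- 10 + 10 * cos(strong$phase_lag) +
    0.01 * seq_len(nrow(strong))
  expect_equal(
    phase_modulation_test(strong, n_perm = 999, seed = 2)$p_raw,
    1 / 1000
  )

  # incomplete designs are rejected
  expect_error(
    suppressWarnings(phase_modulation_test(rec[-1, ], n_perm = 199)),
    "every individual"
  )
  expect_warning(phase_modulation_test(rec, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("Holm correction follows the step-down recipe", {
  expect_equal(holm_correct(0.03), 0.03)
  expect_equal(holm_correct(c(0.01, 0.04)), c(0.02, 0.04))
  withr::with_seed(10, p <- runif(12, 0.001, 1))
  h <- holm_correct(p)
  expect_true(all(h >= p))
  expect_true(all(h <= 1))
  # never fewer rejections than Bonferroni, never more than raw
  bonf <- pmin(1, p * length(p))
  for (alpha in c(0.01, 0.05, 0.2)) {
    expect_gte(sum(h < alpha), sum(bonf < alpha))
    expect_lte(sum(h < alpha), sum(p < alpha))
  }
  expect_error(holm_correct(c(0.5, 0)), "p-values")
})

test_that("coefficient of variation uses the sample SD in percent", {
  expect_equal(coefficient_of_variation(c(1, 1, 1)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 100 * sqrt(2) / 2)
  withr::with_seed(4, v <- rlnorm(20))
  expect_equal(coefficient_of_variation(5 * v),
               coefficient_of_variation(v))
  expect_error(coefficient_of_variation(c(-1, 1)), "mean is zero")
})

test_that("null permutation p-values are calibrated at small scale", {
  # quick super-uniformity check; the full calibration lives in the
  # acceptance suite
  reps <- 400
  p <- vapply(seq_len(reps), function(i) {
    phase_modulation_test(make_null_records(6, 1000 + i),
                          n_perm = 199, seed = 2000 + i)$p_raw
  }, numeric(1))
  rate <- mean(p <= 0.05)
  expect_lt(abs(rate - 0.05), 0.025)
})

test_that("grouped testing adjusts across montages within metric/region", {
  lags <- default_phase_lags()
  withr::with_seed(55, {
    rec <- tidyr::expand_grid(
      individual_id = sprintf("i%d", 1:5),
      montage_id = c("a", "b", "c"),
      phase_lag = lags,
      region_set = "M1s",
      metric = c("rdm", "dotp")
    )
    rec$value <- rnorm(nrow(rec))
    rec$value[rec$metric == "rdm" & rec$montage_id == "a"] <-
      cos(rec$phase_lag[rec$metric == "rdm" & rec$montage_id == "a"]) +
      rnorm(sum(rec$metric == "rdm" & rec$montage_id == "a"), 0, 0.01)
  })
  res <- test_phase_modulation(rec, n_perm = 499, seed = 9)
  tab <- tidy(res)
  expect_equal(nrow(tab), 6) # 2 metrics x 3 montages x 1 region
  expect_true(all(tab$p_adjusted >= tab$p_raw))
  # the modulated cell is detected
  hit <- tab[tab$metric == "rdm" & tab$montage_id == "a", ]
  expect_lt(hit$p_adjusted, 0.05)
  g <- glance(res)
  expect_equal(g$n_tests, 6)
  expect_gte(g$n_significant, 1)
  # reruns with the same seed are identical
  res2 <- test_phase_modulation(rec, n_perm = 499, seed = 9)
  expect_identical(tidy(res2)$p_raw, tab$p_raw)
})

test_that("metric_cv averages per-lag CVs and skips trivial zero rows", {
  lags <- c(0, pi / 2, pi)
  rec <- tidyr::expand_grid(
    individual_id = c("i1", "i2"), montage_id = "m", region_set = "M1s",
    metric = "rdm", phase_lag = lags
  )
  rec$value <- ifelse(rec$phase_lag == 0, 0,
                      ifelse(rec$individual_id == "i1", 1, 3))
  out <- metric_cv(rec)
  expect_equal(out$cv, 100 * sqrt(2) / 2) # lag-0 rows are skipped
})
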