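test_that("the sphere sheet is a closed labelled manifold", {
  sh <- make_sphere_sheet(radius = 80, subdivisions = 3)
  # every edge is shared by exactly two triangles
  tri <- sh$triangles
  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  # total area within 1% of the analytic sphere
  expect_equal(sum(sh$areas), 4 * pi * 80^2, tolerance = 1e-2)
  # label sets disjoint and non-empty
  m1l <- region_nodes(sh, "M1_left")
  m1r <- region_nodes(sh, "M1_right")
  surr <- region_nodes(sh, "surrounding")
  expect_gt(length(m1l), 0)
  expect_gt(length(m1r), 0)
  expect_gt(length(surr), 0)
  expect_length(intersect(m1l, m1r), 0)
  expect_length(intersect(union(m1l, m1r), surr), 0)
})

test_that("antipodal site centres give caps of equal area", {
  spec <- synthetic_montage_spec(site_centres = rbind(c(0, 0, 1),
                                                     c(0, 0, -1)))
  sh <- make_sphere_sheet(subdivisions = 3, spec = spec)
  a_r <- sum(sh$areas[region_nodes(sh, "M1_right")])
  a_l <- sum(sh$areas[region_nodes(sh, "M1_left")])
  expect_equal(a_r, a_l, tolerance = 1e-6)
})

test_that("overlapping caps are rejected", {
  spec <- synthetic_montage_spec(
    site_centres = rbind(c(0.1, 0, 1), c(-0.1, 0, 1)),
    target_radius = 0.3
  )
  expect_error(make_sphere_sheet(spec = spec), "too close")
})

test_that("basis fields are deterministic and structured by mode", {
  sh <- small_sheet()
  spec <- synthetic_montage_spec()
  b1 <- make_basis_fields(sh, spec, seed = 5)
  b2 <- make_basis_fields(sh, spec, seed = 5)
  expect_identical(b1$er1, b2$er1)
  expect_identical(b1$er2, b2$er2)

  # separated mode: the two sites' supports share no node
  bsep <- make_basis_fields(sh, synthetic_montage_spec(mode = "separated"),
                            seed = 5)
  s1 <- rowSums((bsep$er1 - bsep$ec1)^2) > 0
  s2 <- rowSums(bsep$er2^2) > 0
  expect_false(any(s1 & s2))

  # site-2 / site-1 power ratio honours amplitude_ratio
  br <- make_basis_fields(sh, synthetic_montage_spec(amplitude_ratio = 2),
                          seed = 5)
  expect_equal(sum(br$er2^2) / sum((br$er1 - br$ec1)^2), 2,
               tolerance = 1e-9)
})

test_that("site overlap increases the field redistribution across lags", {
  sh <- std_sheet()
  rdm_at <- function(ov, phi, rs) {
    bs <- make_basis_fields(sh, synthetic_montage_spec(overlap = ov),
                            seed = 1)
    m <- compute_metrics(sh, bs, phase_lags = phi)
    m$value[m$metric == "rdm" & m$region_set == rs]
  }
  # at the half-cycle lag the two drives are in antiphase: without
  # overlap the spatial pattern is unchanged, with overlap the shared
  # nodes flip and the distribution shifts
  expect_gt(rdm_at(0.3, pi, "M1s"), rdm_at(0, pi, "M1s"))
  expect_gt(rdm_at(0.3, pi, "surrounding"), rdm_at(0, pi, "surrounding"))
  expect_gt(rdm_at(0.3, pi / 2, "M1s"), rdm_at(0, pi / 2, "M1s"))
})

test_that("cohorts are reproducible and degenerate without jitter", {
  mont <- default_montages()[c(2, 6), ]
  c1 <- make_cohort(n_individuals = 3, seed = 42, montages = mont)
  c2 <- make_cohort(n_individuals = 3, seed = 42, montages = mont)
  expect_identical(c1[[2]]$basis[[1]]$er2, c2[[2]]$basis[[1]]$er2)
  expect_equal(length(c1), 3)
  expect_false(identical(c1[[1]]$basis[[1]]$er2, c1[[2]]$basis[[1]]$er2))

  # zero jitter: all individuals identical, zero CV everywhere
  c0 <- make_cohort(n_individuals = 3, seed = 7, site_jitter_sd = 0,
                    amp_sdlog = 0, montages = mont[1, ])
  expect_identical(c0[[1]]$basis[[1]]$er1, c0[[3]]$basis[[1]]$er1)
  met0 <- cohort_metrics(c0)
  cv0 <- metric_cv(met0)
  expect_true(all(cv0$cv == 0 | is.nan(cv0$cv)))

  # jitter produces inter-individual variability in delta_dotp
  cj <- make_cohort(n_individuals = 4, seed = 7, site_jitter_sd = 0.06,
                    amp_sdlog = 0.3, montages = mont)
  metj <- cohort_metrics(cj)
  cvj <- metric_cv(metj)
  expect_true(all(cvj$cv[cvj$metric == "delta_dotp"] > 0))
})
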