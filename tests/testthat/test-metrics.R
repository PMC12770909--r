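test_that("peak magnitude is the max norm over kept nodes and steps", {
  one <- basis_fields(matrix(c(3, 4, 0), 1, 3), matrix(0, 1, 3),
                      matrix(0, 1, 3), io = 1, f = 1)
  # single node, single step at the sine peak
  fld <- superpose(one, 0, times = 0.25)
  expect_equal(peak_magnitude(fld), 5)

  sh <- small_sheet()
  bs <- rand_basis(sh, 13)
  tg <- make_time_grid(24, bs$f)
  f0 <- superpose(bs, 0, tg)
  # zero-lag factoring: peak = Io * max_k |sin| * max_p ||combined||
  comb_norm <- sqrt(rowSums((bs$er1 - bs$ec1 + bs$er2)^2))
  expect_equal(peak_magnitude(f0),
               bs$io * max(abs(sin(2 * pi * bs$f * tg))) * max(comb_norm))
  # invariant under time-step permutation
  shuf <- f0
  withr::with_seed(8, ks <- sample.int(24))
  shuf$vectors <- f0$vectors[, , ks, drop = FALSE]
  expect_equal(peak_magnitude(shuf), peak_magnitude(f0))
  # homogeneous of degree 1 in Io
  bs2 <- basis_fields(bs$er1, bs$ec1, bs$er2, io = 3 * bs$io, f = bs$f)
  expect_equal(peak_magnitude(superpose(bs2, 0.3, tg)),
               3 * peak_magnitude(superpose(bs, 0.3, tg)))
})

test_that("peak normal component handles sign and tangential fields", {
  sh <- small_sheet()
  # field aligned with the outward normals, magnitude 2
  aligned <- basis_fields(2 * sh$normals, matrix(0, nrow(sh$nodes), 3),
                          matrix(0, nrow(sh$nodes), 3), io = 1, f = 1)
  fld <- superpose(aligned, 0, times = 0.25)
  pk <- peak_normal_component(fld, sh$normals)
  expect_equal(unname(pk["absolute"]), 2)

  # purely tangential field: component 0
  tang <- cbind(-sh$nodes[, 2], sh$nodes[, 1], 0)
  tang <- tang - sh$normals * rowSums(tang * sh$normals)
  ft <- superpose(basis_fields(tang, 0 * tang, 0 * tang, io = 1, f = 1),
                  0, times = 0.25)
  expect_equal(unname(peak_normal_component(ft, sh$normals)["absolute"]),
               0, tolerance = 1e-12)

  # two-node toy with components +1.5 and -2.0
  nrm <- rbind(c(0, 0, 1), c(0, 0, 1))
  two <- basis_fields(rbind(c(0, 0, 1.5), c(0, 0, -2)), matrix(0, 2, 3),
                      matrix(0, 2, 3), io = 1, f = 1)
  f2 <- superpose(two, 0, times = 0.25)
  pk2 <- peak_normal_component(f2, nrm)
  expect_equal(unname(pk2["absolute"]), 2.0)
  expect_equal(unname(pk2["inward"]), 2.0)
})

test_that("rdm has the stated fixed points and invariances", {
  withr::with_seed(101, s <- matrix(rnorm(50 * 24), 50))
  expect_equal(rdm(s, s), 0)
  expect_equal(rdm(s, s, mode = "envelope"), 0)

  # disjoint supports: two orthogonal nonnegative unit vectors -> sqrt(2)
  withr::with_seed(102, {
    a <- rbind(matrix(abs(rnorm(25 * 24)), 25), matrix(0, 25, 24))
    b <- rbind(matrix(0, 25, 24), matrix(abs(rnorm(25 * 24)), 25))
  })
  expect_equal(rdm(a, b), sqrt(2), tolerance = 1e-12)

  # normalization: per-step positive rescaling changes nothing
  withr::with_seed(5, s2 <- matrix(rnorm(50 * 24), 50))
  expect_equal(rdm(3.7 * s, 0.01 * s2), rdm(s, s2), tolerance = 1e-12)

  expect_error(rdm(s, s2[, 1:12]), "share")
  expect_error(rdm(matrix(0, 5, 3), matrix(0, 5, 3)), "degenerate")
})

test_that("dotp is the averaged cosine with the stated limits", {
  withr::with_seed(202, s <- matrix(rnorm(40 * 24), 40))
  expect_equal(dotp(s, s), 1)
  expect_equal(dotp(s, -s), -1)
  # disjoint supports are orthogonal
  withr::with_seed(203, {
    a <- rbind(matrix(rnorm(20 * 8), 20), matrix(0, 20, 8))
    b <- rbind(matrix(0, 20, 8), matrix(rnorm(20 * 8), 20))
    noise <- matrix(rnorm(40 * 24), 40)
  })
  expect_equal(dotp(a, b), 0)
  expect_true(abs(dotp(s, s + 0.5 * noise)) <= 1)
})

test_that("ideal dotp matches its closed-form per-step cosine", {
  # independent oracle: direct trigonometric evaluation of the two-site
  # cosine, never touching superpose()
  oracle <- function(p1, p2, phi, f = 20, tg = make_time_grid(24, f)) {
    s <- sin(2 * pi * f * tg)
    sp <- sin(2 * pi * f * tg + phi)
    num <- p1 * s^2 + p2 * s * sp
    den <- sqrt((p1 + p2) * s^2) * sqrt(p1 * s^2 + p2 * sp^2)
    mean(num / den)
  }
  for (case in list(c(1, 1), c(2, 0.5), c(0.2, 3))) {
    for (phi in c(0, pi / 4, pi / 2, 3 * pi / 4, pi)) {
      expect_equal(ideal_dotp(case[1], case[2], phi),
                   oracle(case[1], case[2], phi), tolerance = 1e-12)
    }
  }
  expect_equal(ideal_dotp(5, 2, 0), 1, tolerance = 1e-12)
  expect_equal(ideal_dotp(1, 1, pi), 0, tolerance = 1e-12)
  # time-reversal symmetry over the full-cycle grid
  for (phi in c(pi / 4, pi / 2, 1.234)) {
    expect_equal(ideal_dotp(2, 1, phi), ideal_dotp(2, 1, 2 * pi - phi),
                 tolerance = 1e-12)
  }
  expect_error(ideal_dotp(0, 0, 1), "zero total power")
})

test_that("delta dotp is the absolute deviation", {
  expect_equal(delta_dotp(0.7, 0.5), 0.2)
  expect_equal(delta_dotp(0.5, 0.5), 0)
  expect_equal(delta_dotp(-1, 1), 2)
  expect_error(delta_dotp(1.5, 0), "\\[-1, 1\\]")
})

test_that("effective area counts target area above the reference peak", {
  # 3-node toy: areas 1,1,1; components 1.0, 0.6, 0.4; frac 0.5 -> 2 mm2
  s <- matrix(c(1, 0.6, 0.4), 3, 1)
  expect_equal(effective_area(s, 1:3, rep(1, 3)), 2)

  # uniform component: the whole target is at peak at every step
  su <- matrix(1, 10, 5)
  withr::with_seed(78, ar <- runif(10, 0.5, 2))
  expect_equal(effective_area(su, 3:7, ar), sum(ar[3:7]))

  # all target components below the cut at every step
  sb <- rbind(matrix(1, 2, 4), matrix(0.2, 5, 4))
  expect_equal(effective_area(sb, 3:7, rep(1, 7)), 0)

  # monotone non-increasing in frac, bounded by total target area
  withr::with_seed(77, sr <- matrix(abs(rnorm(30 * 6)), 30))
  areas <- rep(1.5, 30)
  vals <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(fr) {
    effective_area(sr, 1:12, areas, frac = fr)
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals <= sum(areas[1:12])))
  expect_error(effective_area(matrix(0, 0, 3), 1, numeric(0)), "empty")
})
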