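test_that("vertex normals are unit, outward, and radial on a sphere", {
  ico <- icosphere(3, 1)
  sh <- cortical_sheet(ico$nodes, ico$triangles)
  expect_equal(sqrt(rowSums(sh$normals^2)), rep(1, nrow(sh$nodes)),
               tolerance = 1e-9)
  # radial symmetry: normal of a unit sphere node is the node itself
  expect_lt(max(sqrt(rowSums((sh$normals - ico$nodes)^2))), 1e-2)
  # outward: positive dot with the position vector everywhere
  expect_true(all(rowSums(sh$normals * ico$nodes) > 0))
})

test_that("a flat CCW triangle gets +z normals and one-third areas", {
  sh <- flat_patch()
  expect_equal(sh$normals, matrix(rep(c(0, 0, 1), each = 3), ncol = 3))
  expect_equal(sh$areas, rep(0.5 / 3, 3))
})

test_that("node areas conserve the total surface area", {
  ico <- icosphere(4, 10)
  sh <- cortical_sheet(ico$nodes, ico$triangles)
  # analytic sphere area, up to the subdivision deficit
  expect_equal(sum(sh$areas), 4 * pi * 100, tolerance = 1e-2)
  # exact conservation against independently computed triangle areas
  tri_area <- function(a, b, c) {
    u <- b - a; v <- c - a
    0.5 * sqrt(sum(crossprod_vec(u, v)^2))
  }
  crossprod_vec <- function(u, v) {
    c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
  }
  tot <- sum(vapply(seq_len(nrow(sh$triangles)), function(i) {
    idx <- sh$triangles[i, ]
    tri_area(sh$nodes[idx[1], ], sh$nodes[idx[2], ], sh$nodes[idx[3], ])
  }, numeric(1)))
  expect_equal(sum(sh$areas), tot, tolerance = 1e-9)
})

test_that("normal_component is the signed projection and is linear", {
  sh <- small_sheet()
  n <- nrow(sh$nodes)
  expect_equal(normal_component(3 * sh$normals, sh$normals), rep(3, n))
  # tangential field has zero component
  tang <- cbind(-sh$nodes[, 2], sh$nodes[, 1], 0)
  tang <- tang - sh$normals * rowSums(tang * sh$normals)
  expect_equal(normal_component(tang, sh$normals), rep(0, n),
               tolerance = 1e-12)
  # sign convention: outward positive
  expect_equal(normal_component(matrix(c(0, 0, 2), 1, 3),
                                matrix(c(0, 0, -1), 1, 3)), -2)
  # linearity
  withr::with_seed(7, {
    f1 <- matrix(rnorm(n * 3), n)
    f2 <- matrix(rnorm(n * 3), n)
  })
  expect_equal(normal_component(2 * f1 + 3 * f2, sh$normals),
               2 * normal_component(f1, sh$normals) +
                 3 * normal_component(f2, sh$normals))
})

test_that("areas and normals follow a node permutation", {
  ico <- icosphere(2, 5)
  sh <- cortical_sheet(ico$nodes, ico$triangles)
  withr::with_seed(3, perm <- sample.int(nrow(ico$nodes)))
  inv <- order(perm)
  tri2 <- matrix(inv[ico$triangles], ncol = 3)
  sh2 <- cortical_sheet(ico$nodes[perm, ], tri2)
  expect_equal(sh2$areas, sh$areas[perm])
  expect_equal(sh2$normals, sh$normals[perm, ])
})

test_that("degenerate geometry is flagged", {
  # a zero-area triangle (repeated index) warns but contributes nothing
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  tris <- rbind(c(1L, 2L, 3L), c(2L, 4L, 3L), c(2L, 2L, 4L))
  expect_warning(sh <- cortical_sheet(nodes, tris), "degenerate")
  expect_equal(sum(sh$areas), 1) # only the two valid triangles count
  # isolated node errors
  expect_error(
    cortical_sheet(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5)),
                   matrix(c(1L, 2L, 3L), nrow = 1)),
    "isolated"
  )
  # invalid triangle index errors
  expect_error(
    cortical_sheet(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   matrix(c(1L, 2L, 4L), nrow = 1)),
    "indices"
  )
})

test_that("region label sets must be disjoint and are retrievable", {
  ico <- icosphere(2, 1)
  labels <- rep_len(c(1L, 2L, 3L, 0L), nrow(ico$nodes))
  expect_error(
    cortical_sheet(ico$nodes, ico$triangles, labels,
                   region_sets = list(M1_left = 1L, M1_right = 1:2,
                                      surrounding = 3L)),
    "disjoint"
  )
  sh <- cortical_sheet(ico$nodes, ico$triangles, labels,
                       region_sets = list(M1_left = 1L, M1_right = 2L,
                                          surrounding = 3L))
  expect_setequal(region_nodes(sh, "M1_left"), which(labels == 1L))
  expect_setequal(region_nodes(sh, c("M1_left", "M1_right")),
                  which(labels %in% 1:2))
  expect_error(region_nodes(sh, "nope"), "unknown region set")
})
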