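test_that("curvature calibration: plane zero, sphere -1/R, cylinder half", {
  plane <- gridSheetMesh(function(x, y) rep(0, length(x)), c(0, 10), c(0, 8),
                         nx = 20, ny = 16)
  cv <- vertexCurvature(plane)@values
  V <- vertices(plane)
  interior <- V[, 1] > 1 & V[, 1] < 9 & V[, 2] > 1 & V[, 2] < 7
  expect_lt(max(abs(cv[interior])), 1e-6)

  sph <- icosphereMesh(10, 3)
  cs <- vertexCurvature(sph)@values
  expect_true(all(cs < 0))
  expect_lt(abs(mean(cs) / (-1 / 10) - 1), 0.05)

  # near-isotropic sampling (axial spacing = angular spacing): the uniform
  # umbrella weights average the principal curvatures evenly
  cyl <- cylinderMesh(5, 20, nu = 64, nv = 42)
  cc <- vertexCurvature(cyl)@values
  mid <- abs(vertices(cyl)[, 3] - 10) < 6
  expect_true(all(cc[mid] < 0))
  # one principal direction flat: half the equal-radius sphere value
  expect_lt(abs(mean(cc[mid]) / (-1 / (2 * 5)) - 1), 0.05)

  # larger support keeps the same calibration (exact chord identity)
  cs3 <- vertexCurvature(sph, rings = 3)@values
  expect_lt(abs(mean(cs3) / (-1 / 10) - 1), 0.05)
})

test_that("curvature rejects meshes with isolated vertices", {
  m <- icosphereMesh(1, 1)
  m2 <- TriangleMesh(rbind(vertices(m), c(9, 9, 9)), triangles(m))
  expect_error(vertexCurvature(m2), "isolated")
})

test_that("a sphere is a near fixed point of inflation", {
  s <- icosphereMesh(10, 3)
  infl <- inflateSurface(s)
  # no net motion: summed convexity stays near zero...
  expect_lt(abs(mean(infl@sulc)), 0.005 * 10)
  # ...and pointwise displacement stays at the uniform-weight equilibrium
  # floor, well under the fold-scale signals the map is read against
  expect_lt(max(abs(infl@sulc)), 0.03 * 10)
  expect_lt(abs(infl@areaDrift), 0.01)
})

test_that("sulc separates the waist and crowns of a two-lobe peanut", {
  p <- peanutMesh(5, subdivisions = 3)
  infl <- inflateSurface(p)
  z <- vertices(p)[, 3]
  waist <- abs(z) < 2
  crown <- abs(z) > 6.5
  expect_gt(mean(infl@sulc[waist]), 0)
  expect_lt(mean(infl@sulc[crown]), 0)
  # separation beats the fixed-point noise floor measured on a sphere of
  # the same radius by 5x or more
  floor <- sd(inflateSurface(icosphereMesh(5, 3))@sulc)
  expect_gte(mean(infl@sulc[waist]) - mean(infl@sulc[crown]), 5 * floor)
  expect_lt(abs(infl@areaDrift), 0.01)
})

test_that("mean-centering sulc is available and exact", {
  p <- peanutMesh(4, subdivisions = 2)
  infl <- inflateSurface(p, center = TRUE)
  expect_lt(abs(mean(infl@sulc)), 1e-12)
})

test_that("mesh area matches closed forms, a brute-force loop, and exclusions", {
  # icosahedron with circumradius R has edge a = 4R/sqrt(10+2*sqrt(5))
  R <- 3
  ico <- icosphereMesh(R, 0)
  a <- 4 * R / sqrt(10 + 2 * sqrt(5))
  expect_equal(meshArea(ico), 5 * sqrt(3) * a^2, tolerance = 1e-9)

  set.seed(5)
  m <- peanutMesh(4, subdivisions = 2)
  brute <- 0
  V <- vertices(m); tr <- triangles(m)
  for (i in seq_len(nrow(tr))) {
    u <- V[tr[i, 2], ] - V[tr[i, 1], ]
    v <- V[tr[i, 3], ] - V[tr[i, 1], ]
    brute <- brute + 0.5 * sqrt(sum(crossprod(matrix(c(
      u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])))))
  }
  expect_equal(meshArea(m), brute, tolerance = 1e-9)

  slab <- gridSheetMesh(function(x, y) rep(0, length(x)), c(0, 10), c(0, 10),
                        nx = 11, ny = 11)
  half <- vertices(slab)[, 1] <= 5
  expect_equal(meshArea(slab, exclude = half), 50, tolerance = 1e-9)
})

test_that("mesh area is rigid-invariant and scales quadratically", {
  set.seed(8)
  m <- peanutMesh(4, subdivisions = 2)
  a0 <- meshArea(m)
  for (i in 1:5) {
    R <- rotationMatrix3(runif(3, 0, 2 * pi))
    t <- runif(3, -10, 10)
    s <- runif(1, 0.2, 5)
    moved <- TriangleMesh(sweep(vertices(m) %*% t(R), 2, t, `+`),
                          triangles(m))
    expect_equal(meshArea(moved), a0, tolerance = 1e-9)
    scaled <- TriangleMesh(s * vertices(m), triangles(m))
    expect_equal(meshArea(scaled), s^2 * a0, tolerance = 1e-9)
  }
})

test_that("shrinkage correction implements the isotropic-volume closed form", {
  expect_identical(correctShrinkage(123.4, ShrinkageModel(0)), 123.4)
  expect_equal(correctShrinkage(1, ShrinkageModel(0.03)), (1 / 0.97)^(2 / 3),
               tolerance = 1e-12)
  expect_equal(correctShrinkage(1, ShrinkageModel(0.271)),
               exp(-(2 / 3) * log(0.729)), tolerance = 1e-12)
  expect_error(ShrinkageModel(1), "fraction")
  expect_error(correctShrinkage(-1, ShrinkageModel(0.03)))
})
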