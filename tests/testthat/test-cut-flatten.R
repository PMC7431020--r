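test_that("cutting changes topology by the book", {
  # sphere + meridian pole to pole: still one piece, now a disk
  s <- icosphereMesh(5, 2)
  V <- vertices(s)
  A <- vertexAdjacency(s)
  path <- which.max(V[, 3])
  repeat {
    nb <- setdiff(which(A[path[length(path)], ] > 0), path)
    nxt <- nb[which.min(V[nb, 3])]
    path <- c(path, nxt)
    if (V[nxt, 3] <= min(V[, 3]) + 1e-9) break
  }
  pieces <- applyCuts(s, CutSpec(paths = list(path)))
  expect_length(pieces, 1L)
  expect_identical(eulerCharacteristic(pieces[[1]]$mesh), 1L)
  # provenance covers the duplicated vertices
  expect_identical(nrow(vertices(pieces[[1]]$mesh)),
                   length(pieces[[1]]$origVertices))

  # open tube + axial path: developable sheet
  tube <- cylinderMesh(5, 20, nu = 32, nv = 20)
  expect_identical(eulerCharacteristic(tube), 0L)
  axial <- seq(1, by = 32, length.out = 20)
  tp <- applyCuts(tube, CutSpec(paths = list(axial)))
  expect_length(tp, 1L)
  expect_identical(eulerCharacteristic(tp[[1]]$mesh), 1L)

  # torus + the two canonical loops through a shared vertex: disk
  nu <- 24; nv <- 12
  tor <- torusMesh(10, 3, nu = nu, nv = nv)
  expect_identical(eulerCharacteristic(tor), 0L)
  loop1 <- c(1:nu, 1)
  loop2 <- c(seq(1, by = nu, length.out = nv), 1)
  tps <- applyCuts(tor, CutSpec(paths = list(loop1, loop2)))
  expect_length(tps, 1L)
  expect_identical(eulerCharacteristic(tps[[1]]$mesh), 1L)
})

test_that("cut paths must follow mesh edges", {
  s <- icosphereMesh(5, 1)
  far <- order(rowSums(sweep(vertices(s), 2, vertices(s)[1, ])^2),
               decreasing = TRUE)[1]
  expect_error(applyCuts(s, CutSpec(paths = list(c(1, far)))), "non-edges")
})

test_that("piece labels split a mesh with provenance", {
  slab <- gridSheetMesh(function(x, y) rep(0, length(x)), c(0, 10), c(0, 6),
                        nx = 11, ny = 7)
  labs <- ifelse(vertices(slab)[, 1] <= 5, 1L, 2L)
  pieces <- applyCuts(slab, CutSpec(pieceLabels = labs))
  expect_length(pieces, 2L)
  areas <- vapply(pieces, function(p) meshArea(p$mesh), numeric(1))
  expect_equal(sum(areas), 60, tolerance = 1e-9)
  for (p in pieces)
    expect_equal(vertices(p$mesh),
                 vertices(slab)[p$origVertices, , drop = FALSE])
})

test_that("a cut cylinder flattens to its developable rectangle", {
  tube <- cylinderMesh(5, 20, nu = 48, nv = 30)
  piece <- applyCuts(tube, CutSpec(paths = list(seq(1, by = 48,
                                                    length.out = 30))))[[1]]
  fm <- flattenPiece(piece$mesh)
  ad <- arealDistortion(piece$mesh, fm)
  expect_identical(fm@flippedCount, 0L)
  expect_lt(ad$medianAbsLog, 0.01)
  expect_lt(abs(ad$totalAreaRatio - 1), 0.01)
  expect_equal(sort(fm@bbox), sort(c(2 * pi * 5, 20)), tolerance = 0.02)
})

test_that("a planar piece is recovered rigidly", {
  plane <- gridSheetMesh(function(x, y) 0.3 * x - 0.1 * y, c(0, 8), c(0, 6),
                         nx = 12, ny = 9)
  fm <- flattenPiece(plane)
  expect_lt(max(abs(fm@distortion)), 1e-6)
  expect_identical(fm@flippedCount, 0L)
  # rigid recovery: all pairwise 3D distances preserved in 2D (checked on a
  # random sample of vertex pairs)
  set.seed(2)
  i <- sample(nVertices(plane), 40, replace = TRUE)
  j <- sample(nVertices(plane), 40, replace = TRUE)
  d3 <- sqrt(rowSums((vertices(plane)[i, ] - vertices(plane)[j, ])^2))
  d2 <- sqrt(rowSums((fm@coords2d[i, ] - fm@coords2d[j, ])^2))
  expect_equal(d2, d3, tolerance = 1e-6)
})

test_that("intrinsic curvature forces distortion that grows with cap angle", {
  meds <- vapply(c(20, 40, 60), function(ang) {
    cap <- capMesh(ang)
    fm <- flattenPiece(cap)
    arealDistortion(cap, fm)$medianAbsLog
  }, numeric(1))
  expect_gt(meds[1], 0)
  expect_true(all(diff(meds) > 0))
})

test_that("the relaxed cap matches an independent energy minimization", {
  cap <- capMesh(40, nr = 9, na = 26)  # ~240 vertices
  fm <- flattenPiece(cap)
  # oracle: minimize the same edge-spring energy by generic BFGS from a
  # different (flat projection) start, no ARAP, no Tutte
  V <- vertices(cap); tr <- triangles(cap)
  e <- foliaflat:::meshEdgeTable(cap)$edges
  L3 <- sqrt(rowSums((V[e[, 1], ] - V[e[, 2], ])^2))
  n <- nrow(V)
  en <- function(x) {
    q <- matrix(x, n, 2)
    d <- q[e[, 1], ] - q[e[, 2], ]
    sum((sqrt(rowSums(d^2)) - L3)^2)
  }
  gr <- function(x) {
    q <- matrix(x, n, 2)
    d <- q[e[, 1], ] - q[e[, 2], ]
    len <- pmax(sqrt(rowSums(d^2)), 1e-12)
    f <- d * (2 * (len - L3) / len)
    g <- matrix(0, n, 2)
    for (c in 1:2) {
      acc <- rowsum(c(f[, c], -f[, c]), c(e[, 1], e[, 2]), reorder = FALSE)
      g[as.integer(rownames(acc)), c] <- acc[, 1]
    }
    as.numeric(g)
  }
  init <- V[, 1:2] * 1.02  # flat projection of the shallow cap
  o <- optim(as.numeric(init), en, gr, method = "L-BFGS-B",
             control = list(maxit = 3000, factr = 1e4))
  # the two routes minimize the same functional from unrelated starts; the
  # package's solution must reach at least the oracle's energy level
  expect_lte(fm@energy, 1.05 * o$value + 1e-8)
  # and both agree that the cap cannot flatten without distortion
  q <- matrix(o$par, n, 2)
  a2 <- abs(foliaflat:::area2d(q, tr))
  a3 <- triangleAreas(cap)
  ring2 <- foliaflat:::vertexRingAreas(tr, a2, n)
  ring3 <- foliaflat:::vertexRingAreas(tr, a3, n)
  medOracle <- median(abs(log(ring2 / ring3)))
  expect_gt(medOracle, 0.01)
  expect_gt(arealDistortion(cap, fm)$medianAbsLog, 0.01)
})

test_that("areal distortion statistics behave on constructed cases", {
  cap <- capMesh(30, nr = 6, na = 18)
  fm <- flattenPiece(cap)
  # identical geometry: a fake flat map equal to a planar piece gives zeros
  plane <- gridSheetMesh(function(x, y) rep(0, length(x)), c(0, 5), c(0, 4),
                         nx = 6, ny = 5)
  idFlat <- new("FlatMap", coords2d = vertices(plane)[, 1:2],
                triangles = triangles(plane),
                distortion = numeric(nVertices(plane)),
                flippedCount = 0L, bbox = c(5, 4), converged = TRUE,
                energy = 0)
  ad <- arealDistortion(plane, idFlat)
  expect_lt(max(abs(ad$distortion@values)), 1e-12)
  expect_equal(ad$totalAreaRatio, 1, tolerance = 1e-12)
  # uniform 2x linear scale: log ratio is log 4 everywhere
  sc <- new("FlatMap", coords2d = 2 * vertices(plane)[, 1:2],
            triangles = triangles(plane),
            distortion = numeric(nVertices(plane)),
            flippedCount = 0L, bbox = c(10, 8), converged = TRUE, energy = 0)
  ads <- arealDistortion(plane, sc)
  expect_equal(unique(round(ads$distortion@values, 10)), round(log(4), 10))
  # mismatched triangle count is rejected
  expect_error(arealDistortion(plane, fm), "disagree")
})

test_that("non-disk pieces are rejected with advice to cut further", {
  s <- icosphereMesh(5, 1)
  expect_error(flattenPiece(s), "add more cuts")
})

test_that("an anisotropic folded strip unrolls to the designed aspect ratio", {
  spec <- PhantomSpec(extent = c(30, 8, 14), lobuleWavelength = 10,
                      lobuleAmplitude = 2.5, foliumWavelength = 3,
                      foliumAmplitude = 0, sheetThickness = 0.8,
                      voxelWidth = 0.25)
  f <- sheetHeightFunctions(spec)
  m <- gridSheetMesh(function(x, y) f$S(x, y), c(0, 30), c(0, 8),
                     nx = 120, ny = 26)
  fm <- flattenPiece(m)
  xs <- seq(0, 30, length.out = 2000)
  arc <- sum(sqrt(1 + f$Sx(xs, rep(4, 2000))^2)) * 30 / 2000
  designed <- arc / 8
  got <- max(fm@bbox) / min(fm@bbox)
  expect_lt(abs(got / designed - 1), 0.1)
  expect_lt(abs(arealDistortion(m, fm)$totalAreaRatio - 1), 0.01)
})
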