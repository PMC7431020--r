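test_that("explicit-threshold segmentation reproduces a clean two-class label", {
  spec <- smallSphereSpec(noise = 0)
  ph <- generatePhantom(spec)
  lab <- voxelValues(ph@labels)
  v <- array(0.1, dim(lab))
  v[lab == 1L] <- 0.9
  mask <- segmentWhite(Volume(v, voxelWidth(ph@labels), worldOrigin(ph@labels)),
                       threshold = 0.5)
  expect_identical(voxelValues(mask), lab == 1L)
})

test_that("interior cavities are filled", {
  m <- array(FALSE, c(12, 12, 12))
  m[3:10, 3:10, 3:10] <- TRUE
  m[6:7, 6:7, 6:7] <- FALSE  # cavity
  v <- array(0, c(12, 12, 12)); v[m] <- 1
  mask <- segmentWhite(Volume(v, 1), threshold = 0.5)
  got <- voxelValues(mask)
  expect_true(all(got[3:10, 3:10, 3:10]))
  # background is a single component again
  bg <- array(foliaflat:::cpp_label6(!got, dim(got)), dim(got))
  expect_identical(max(bg), 1L)
})

test_that("Otsu segmentation of a noisy two-class volume is near-exact", {
  spec <- smallSphereSpec(noise = 0)
  ph <- generatePhantom(spec)
  lab <- voxelValues(ph@labels)
  set.seed(21)
  v <- array(0.1, dim(lab))
  v[lab == 1L] <- 0.9
  v <- v + array(rnorm(length(v), sd = 0.08), dim(v))  # sigma = 10% of gap
  mask <- segmentWhite(Volume(v, voxelWidth(ph@labels)), threshold = "otsu")
  expect_lt(mean(voxelValues(mask) != (lab == 1L)), 0.01)
})

test_that("voxel-face tessellation has exact counts, areas and Euler number", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  m1 <- tessellate(SegmentationMask(one, 0.7))
  expect_identical(nVertices(m1), 8L)
  expect_identical(nTriangles(m1), 12L)
  expect_identical(eulerCharacteristic(m1), 2L)
  expect_equal(meshArea(m1), 6 * 0.7^2, tolerance = 1e-12)
  st <- manifoldStatus(m1)
  expect_true(st$closed && st$consistentWinding)
  # outward normals
  ctr <- colMeans(vertices(m1))
  tri <- triangles(m1)
  cent <- (vertices(m1)[tri[, 1], ] + vertices(m1)[tri[, 2], ] +
           vertices(m1)[tri[, 3], ]) / 3
  expect_true(all(rowSums(triangleNormals(m1) * sweep(cent, 2, ctr)) > 0))

  cube <- array(FALSE, c(8, 8, 8)); cube[2:6, 2:6, 2:6] <- TRUE
  m5 <- tessellate(SegmentationMask(cube, 0.5))
  expect_equal(meshArea(m5), 6 * 25 * 0.25, tolerance = 1e-12)
  expect_identical(eulerCharacteristic(m5), 2L)
})

test_that("a digitized sphere tessellates with the known Manhattan inflation", {
  mask <- digitizedBallMask(15)
  mesh <- tessellate(mask)
  ratio <- meshArea(mesh) / (4 * pi * 15^2)
  expect_gte(ratio, 1.45)
  expect_lte(ratio, 1.55)
  # face-count oracle: boundary faces counted directly from the mask
  m <- voxelValues(mask)
  faces <- 0L
  for (axis in 1:3) for (d in c(-1, 1))
    faces <- faces + sum(m & !foliaflat:::shiftArray(m, axis, d))
  expect_identical(nTriangles(mesh), 2L * faces)
  expect_identical(eulerCharacteristic(mesh), 2L)
})

test_that("edge- and corner-touching voxels are thickened to a manifold", {
  edge <- array(FALSE, c(6, 6, 6))
  edge[2, 2, 2] <- TRUE; edge[3, 3, 2] <- TRUE   # share an edge only
  me <- tessellate(SegmentationMask(edge, 1))
  ste <- manifoldStatus(me)
  expect_true(ste$closed && ste$consistentWinding)

  corner <- array(FALSE, c(6, 6, 6))
  corner[2, 2, 2] <- TRUE; corner[3, 3, 3] <- TRUE  # share a corner only
  mc <- tessellate(SegmentationMask(corner, 1))
  stc <- manifoldStatus(mc)
  expect_true(stc$closed && stc$consistentWinding)
})

test_that("refinement recovers shell surfaces and preserves topology", {
  spec <- smallSphereSpec()
  ph <- generatePhantom(spec)
  rec <- reconstructSurfaces(synthesizeEchoes(ph))
  expect_lt(abs(meshArea(rec$gw) / (4 * pi * 81) - 1), 0.02)
  expect_lt(abs(meshArea(rec$pial) / (4 * pi * 100) - 1), 0.02)
  expect_identical(eulerCharacteristic(rec$init), 2L)
  expect_identical(eulerCharacteristic(rec$gw), 2L)
  expect_identical(eulerCharacteristic(rec$pial), 2L)
  expect_identical(selfIntersectionCount(rec$pial), 0L)
})

test_that("refined slab surfaces are planar to a fraction of a voxel", {
  spec <- PhantomSpec(shapeKind = "slab", extent = c(16, 14, 12),
                      sheetThickness = 1.2, voxelWidth = 0.4,
                      noiseSigma = 0.01, seed = 13)
  ph <- generatePhantom(spec)
  rec <- reconstructSurfaces(synthesizeEchoes(ph))
  V <- vertices(rec$gw)
  nrm <- vertexNormals(rec$gw)
  top <- V[, 1] > 3 & V[, 1] < 13 & V[, 2] > 3 & V[, 2] < 11 & nrm[, 3] > 0.9
  expect_gt(sum(top), 200)
  expect_lt(sd(V[top, 3]) / 0.4, 0.2)
})

test_that("refinement in a constant volume reduces to smoothing", {
  mesh <- tessellate(digitizedBallMask(8, w = 1))
  flat <- Volume(array(0.5, c(24, 24, 24)), 1)
  areas <- numeric(0)
  cur <- mesh
  for (rep in 1:3) {
    out <- foliaflat:::refineOne(cur, flat, iso = 0.5, contrast = 1,
                                 maxIter = 10L, stepClamp = 0.25,
                                 lambdaT = 0.3, tol = 0, lambdaN = 0.1)
    areas <- c(areas, meshArea(out$mesh))
    cur <- out$mesh
  }
  expect_true(all(diff(c(meshArea(mesh), areas)) < 0))
})
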