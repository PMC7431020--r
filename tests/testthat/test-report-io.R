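test_that("headline area ratios reproduce the printed percentages", {
  # the published areas are already shrinkage-corrected, so they enter the
  # report as given
  rep <- buildAreaReport(
    c(cerebellum = 1590, neocortex = 2038, macaqueCb = 90, macaqueNeo = 269,
      dentate = 18.6),
    applyShrinkage = FALSE,
    ratios = list(c("cerebellum", "neocortex"),
                  c("macaqueCb", "macaqueNeo"),
                  c("cerebellum", "dentate")))
  expect_equal(unname(rep@ratios["cerebellum/neocortex"]), 1590 / 2038,
               tolerance = 1e-12)
  expect_identical(unname(rep@percents["cerebellum/neocortex"]), 78)
  expect_identical(unname(rep@percents["macaqueCb/macaqueNeo"]), 33)
  expect_gte(unname(rep@ratios["cerebellum/dentate"]), 80)
  expect_equal(unname(rep@ratios["cerebellum/dentate"]), 85.48387,
               tolerance = 1e-5)
})

test_that("the report applies shrinkage and gray/white factors per entry", {
  rep <- buildAreaReport(c(exvivo = 100, invivo = 100),
                         shrinkage = ShrinkageModel(0.03),
                         applyShrinkage = c(exvivo = TRUE),
                         applyGwFactor = c(invivo = TRUE),
                         gwToPialFactor = 1.2,
                         ratios = list(c("exvivo", "invivo")))
  a <- rep@areas
  expect_equal(a$corrected_mm2[a$label == "exvivo"], 100 * (1 / 0.97)^(2 / 3),
               tolerance = 1e-12)
  expect_equal(a$corrected_mm2[a$label == "invivo"], 120, tolerance = 1e-12)
  expect_equal(unname(rep@ratios[1]),
               a$corrected_mm2[1] / a$corrected_mm2[2], tolerance = 1e-12)
  expect_error(buildAreaReport(c(a = 1), ratios = list(c("a", "nope"))),
               "unknown label")
  # percentages round half away from zero
  r2 <- buildAreaReport(c(x = 335, y = 1000), applyShrinkage = FALSE,
                        ratios = list(c("x", "y")))
  expect_identical(unname(r2@percents[1]), 34)
})

test_that("FreeSurfer surface files round-trip", {
  m <- icosphereMesh(7, 2)
  path <- tempfile(fileext = ".surf")
  writeFreeSurferSurface(m, path)
  m2 <- readFreeSurferSurface(path)
  expect_identical(triangles(m2), triangles(m))
  expect_lt(max(abs(vertices(m2) - vertices(m))), 1e-5)
  # malformed magic is named
  bad <- tempfile()
  writeBin(as.raw(c(1, 2, 3, 4)), bad)
  expect_error(readFreeSurferSurface(bad), "magic")
})

test_that("FreeSurfer curv files round-trip", {
  set.seed(6)
  vals <- rnorm(200)
  path <- tempfile(fileext = ".curv")
  writeFreeSurferCurv(vals, path, nFaces = 396L)
  got <- readFreeSurferCurv(path)
  expect_equal(got, vals, tolerance = 1e-6)
  bad <- tempfile()
  writeBin(as.raw(c(0, 0, 0)), bad)
  expect_error(readFreeSurferCurv(bad), "magic")
})

test_that("PLY files round-trip and agree with an independent parser", {
  m <- icosphereMesh(7, 2)
  path <- tempfile(fileext = ".ply")
  writePly(m, path)
  m2 <- readPly(path)
  expect_identical(triangles(m2), triangles(m))
  expect_lt(max(abs(vertices(m2) - vertices(m))), 1e-6)
  # cross-parser check: trimesh reads our PLY and reports the same area
  out <- suppressWarnings(tryCatch(
    system2("python", c("-c",
      shQuote(sprintf("import trimesh; print(trimesh.load(%s).area)",
                      deparse(path)))),
      stdout = TRUE, stderr = FALSE),
    error = function(e) character(0)))
  expect_gt(length(out), 0)
  expect_equal(as.numeric(out[length(out)]), meshArea(m), tolerance = 1e-5)
})

test_that("NIfTI volumes round-trip with grid geometry", {
  set.seed(9)
  vol <- Volume(array(rnorm(10 * 9 * 8), c(10, 9, 8)), 0.19,
                origin = c(-2, 1, 0.5))
  path <- tempfile(fileext = ".nii.gz")
  writeVolumeNifti(vol, path)
  v2 <- readVolumeNifti(path)
  expect_equal(voxelValues(v2), voxelValues(vol), tolerance = 1e-12)
  expect_equal(voxelWidth(v2), 0.19, tolerance = 1e-6)
  expect_equal(worldOrigin(v2), c(-2, 1, 0.5), tolerance = 1e-5)
})

test_that("the end-to-end driver writes a consistent bundle", {
  outDir <- tempfile("run")
  spec <- PhantomSpec(extent = c(14, 12, 10), lobuleWavelength = 10,
                      lobuleAmplitude = 1.5, foliumWavelength = 3,
                      foliumAmplitude = 0.4, sheetThickness = 0.8,
                      voxelWidth = 0.3, seed = 4)
  res <- runPipeline(spec, outDir, margin = 2, verbose = FALSE)
  expect_true(file.exists(file.path(outDir, "manifest.json")))
  man <- jsonlite::read_json(file.path(outDir, "manifest.json"))
  expect_equal(man$recoveredFraction, res$manifest$recoveredFraction,
               tolerance = 1e-9)
  expect_gt(man$recoveredFraction, 0.9)
  expect_lt(man$recoveredFraction, 1.1)
  for (f in c("pd.nii.gz", "t2star.nii.gz", "surf.gw", "surf.pial",
              "pial.curv", "pial.sulc"))
    expect_true(file.exists(file.path(outDir, f)))
  # the written pial surface re-reads to the in-memory one
  back <- readFreeSurferSurface(file.path(outDir, "surf.pial"))
  expect_equal(meshArea(back), meshArea(res$reconstruction$pial),
               tolerance = 1e-4)
})
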