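#' Full image-to-surfaces reconstruction
#'
#' Runs the prepared-image chain (echo combination, bias flattening and
#' contrast inversion, oriented anisotropic filtering), segments the
#' white-matter interior, tessellates the initial surface, and refines it
#' into gray/white and pial surfaces with data-driven isovalues.
#'
#' @param pair a [TwoEchoPair-class].
#' @param cfg a [PrepConfig-class].
#' @param threshold segmentation threshold mode (see [segmentWhite()]).
#' @param maxIter refinement iteration cap per surface.
#' @return list with `combined`, `prepared` (filtered), `mask`, `init`,
#'   `gw`, `pial`, `iso`, and refinement convergence info.
#' @export
reconstructSurfaces <- function(pair, cfg = PrepConfig(), threshold = "otsu2",
                                maxIter = 100L) {
  combined <- combineEchoes(pair, cfg)
  fg <- pair@pd@values > otsuThreshold(pair@pd@values)
  prepared <- flattenAndInvert(combined, cfg, fg)
  filtered <- orientedSmooth(prepared, cfg)
  mask <- segmentWhite(filtered, threshold)
  init <- tessellate(mask)
  iso <- estimateIsovalues(filtered, mask)
  ref <- refineSurfaces(init, filtered, iso$gw, iso$pial, maxIter = maxIter)
  list(combined = combined, prepared = filtered, mask = mask, init = init,
       gw = ref$gw, pial = ref$pial, iso = iso,
       gwInfo = ref$gwInfo, pialInfo = ref$pialInfo)
}

#' Extract the folded top-sheet patch of a reconstructed sheet phantom
#'
#' Selects the triangles of the folded top surface inside the
#' margin-trimmed sheet window — the block's bottom face and side walls are
#' excluded by the window and a height floor, so the patch keeps no
#' punctures from locally steep wall triangles — keeps the largest
#' connected patch, and returns it as a piece ready for flattening.
#'
#' @param mesh reconstructed surface.
#' @param spec the sheet [PhantomSpec-class].
#' @param margin window trim (mm).
#' @param zFloor minimum centroid height (mm) separating the top sheet from
#'   the block's bottom face.
#' @return list with `mesh` (the patch) and `origVertices`.
#' @export
extractSheetPiece <- function(mesh, spec, margin = 3, zFloor = 1) {
  tr <- mesh@triangles
  cent <- (mesh@vertices[tr[, 1], , drop = FALSE] +
           mesh@vertices[tr[, 2], , drop = FALSE] +
           mesh@vertices[tr[, 3], , drop = FALSE]) / 3
  keep <- which(cent[, 1] >= margin & cent[, 1] <= spec@extent[1] - margin &
                cent[, 2] >= margin & cent[, 2] <= spec@extent[2] - margin &
                cent[, 3] > zFloor)
  if (!length(keep)) stop("no top-sheet triangles inside the window")
  sub <- extractSubmesh(mesh, keep)
  comps <- meshComponents(sub$mesh)
  if (length(comps) > 1L) {
    sizes <- vapply(comps, function(cp) nrow(cp$mesh@triangles), numeric(1))
    best <- comps[[which.max(sizes)]]
    list(mesh = best$mesh, origVertices = sub$vertexMap[best$vertexMap])
  } else {
    list(mesh = sub$mesh, origVertices = sub$vertexMap)
  }
}

#' End-to-end phantom pipeline driver
#'
#' Generates a phantom, synthesizes the echoes, reconstructs the surfaces,
#' computes curv/sulc, measures areas (with shrinkage correction), flattens
#' the top sheet patch, optionally runs the resolution-loss curve, and
#' writes all products (NIfTI volumes, FreeSurfer/PLY surfaces, curv maps,
#' CSV/JSON tables and a manifest) under one directory.
#'
#' @param spec a [PhantomSpec-class].
#' @param outDir output directory (created if needed).
#' @param cfg a [PrepConfig-class].
#' @param widths optional voxel widths for the resolution curve.
#' @param margin sheet-window trim (mm) for area measurement/flattening.
#' @param maxIter refinement iteration cap.
#' @param verbose print per-stage progress.
#' @return (invisibly) list with all intermediate objects and the report.
#' @export
runPipeline <- function(spec, outDir, cfg = PrepConfig(), widths = NULL,
                        margin = 3, maxIter = 100L, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  say("phantom: generating (%s)", spec@shapeKind)
  phantom <- generatePhantom(spec)
  pair <- synthesizeEchoes(phantom)
  writeVolumeNifti(pair@pd, file.path(outDir, "pd.nii.gz"))
  writeVolumeNifti(pair@t2star, file.path(outDir, "t2star.nii.gz"))
  writeVolumeNifti(phantom@labels, file.path(outDir, "labels.nii.gz"))
  say("reconstruct: prep + segment + tessellate + refine")
  rec <- reconstructSurfaces(pair, cfg, maxIter = maxIter)
  writeFreeSurferSurface(rec$gw, file.path(outDir, "surf.gw"))
  writeFreeSurferSurface(rec$pial, file.path(outDir, "surf.pial"))
  writePly(rec$pial, file.path(outDir, "surf.pial.ply"))
  say("metrics: curv + inflation (sulc)")
  curv <- vertexCurvature(rec$pial)
  infl <- inflateSurface(rec$pial)
  writeFreeSurferCurv(curv, file.path(outDir, "pial.curv"),
                      nFaces = nrow(rec$pial@triangles))
  writeFreeSurferCurv(infl@sulc, file.path(outDir, "pial.sulc"),
                      nFaces = nrow(rec$pial@triangles))
  say("flatten: top-sheet patch")
  flat <- NULL
  if (spec@shapeKind %in% c("slab", "folded_sheet")) {
    piece <- extractSheetPiece(rec$pial, spec, margin = margin)
    flat <- tryCatch(flattenPiece(piece$mesh), error = function(e) {
      say("flatten skipped: %s", conditionMessage(e))
      NULL
    })
    if (!is.null(flat)) {
      utils::write.csv(data.frame(x = flat@coords2d[, 1],
                                  y = flat@coords2d[, 2],
                                  logArealDistortion = flat@distortion),
                       file.path(outDir, "flat.csv"), row.names = FALSE)
    }
  }
  curve <- NULL
  if (!is.null(widths)) {
    say("resolution: %d widths", length(widths))
    curve <- areaRecoveryCurve(phantom, widths, cfg, margin = margin,
                               maxIter = maxIter)
    utils::write.csv(curve@entries, file.path(outDir, "resolution.csv"),
                     row.names = FALSE)
  }
  recovered <- measurePhantomArea(rec$pial, spec, margin = margin)
  truth <- if (spec@shapeKind %in% c("slab", "folded_sheet")) {
    sheetReferenceArea(spec, c(margin, spec@extent[1] - margin),
                       c(margin, spec@extent[2] - margin))
  } else phantom@pialArea
  report <- buildAreaReport(
    c(pial_recovered = recovered, pial_truth = truth),
    ratios = list(c("pial_recovered", "pial_truth")))
  manifest <- list(
    shapeKind = spec@shapeKind, voxelWidth = spec@voxelWidth,
    seed = spec@seed,
    nVerticesPial = nrow(rec$pial@vertices),
    recoveredAreaMm2 = recovered, referenceAreaMm2 = truth,
    recoveredFraction = recovered / truth,
    inflationAreaDrift = infl@areaDrift,
    flattenMedianAbsLogDistortion =
      if (!is.null(flat)) median(abs(flat@distortion)) else NA,
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = list.files(outDir))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1f s; recovered %.4g mm^2 vs reference %.4g mm^2 (%.2f%%)",
      manifest$elapsedSec, recovered, truth, 100 * recovered / truth)
  invisible(list(phantom = phantom, pair = pair, reconstruction = rec,
                 curv = curv, inflation = infl, flat = flat, curve = curve,
                 report = report, manifest = manifest))
}
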