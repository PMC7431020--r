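#' @rdname Volume-class
#' @param object,x an object.
#' @export
setGeneric("voxelWidth", function(x) standardGeneric("voxelWidth"))

#' @rdname Volume-class
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))

#' @rdname Volume-class
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("nTriangles", function(x) standardGeneric("nTriangles"))

#' @export
#' @rdname meshArea
setGeneric("meshArea", function(mesh, exclude = NULL) standardGeneric("meshArea"))

setMethod("voxelWidth", "Volume", function(x) x@voxelWidth)
setMethod("voxelWidth", "SegmentationMask", function(x) x@voxelWidth)
setMethod("voxelWidth", "TwoEchoPair", function(x) x@pd@voxelWidth)
setMethod("worldOrigin", "Volume", function(x) x@origin)
setMethod("worldOrigin", "SegmentationMask", function(x) x@origin)
setMethod("voxelValues", "Volume", function(x) x@values)
setMethod("voxelValues", "SegmentationMask", function(x) x@values)

setMethod("vertices", "TriangleMesh", function(x) x@vertices)
setMethod("triangles", "TriangleMesh", function(x) x@triangles)
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))
setMethod("nTriangles", "TriangleMesh", function(x) nrow(x@triangles))

setMethod("show", "Volume", function(object) {
  d <- dim(object@values)
  cat(sprintf("Volume: %d x %d x %d voxels, width %.4g mm\n",
              d[1], d[2], d[3], object@voxelWidth))
  cat(sprintf("  origin (mm): %.3f %.3f %.3f  range: [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@values), max(object@values)))
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("SegmentationMask: %d x %d x %d voxels, width %.4g mm, %d foreground\n",
              d[1], d[2], d[3], object@voxelWidth, sum(object@values)))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d triangles, area %.4g mm^2\n",
              nrow(object@vertices), nrow(object@triangles),
              sum(triangleAreas(object))))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec (%s): extent %s mm, voxel %.3g mm, seed %d\n",
              object@shapeKind, paste(object@extent, collapse = " x "),
              object@voxelWidth, object@seed))
  if (object@shapeKind == "folded_sheet")
    cat(sprintf("  lobules: lambda %.3g mm amp %.3g mm; folia: lambda %.3g mm amp %.3g mm; thickness %.3g mm\n",
                object@lobuleWavelength, object@lobuleAmplitude,
                object@foliumWavelength, object@foliumAmplitude,
                object@sheetThickness))
})

setMethod("show", "GroundTruthPhantom", function(object) {
  cat(sprintf("GroundTruthPhantom (%s): pial %.4g mm^2, gw %.4g mm^2\n",
              object@spec@shapeKind, object@pialArea, object@gwArea))
})

setMethod("show", "InflationResult", function(object) {
  cat(sprintf("InflationResult: %d iterations, area drift %.3g%%, sulc range [%.3g, %.3g] mm\n",
              object@iterations, 100 * object@areaDrift,
              min(object@sulc), max(object@sulc)))
})

setMethod("show", "FlatMap", function(object) {
  cat(sprintf("FlatMap: %d vertices, bbox %.4g x %.4g mm, %d flipped, median |log distortion| %.3g\n",
              nrow(object@coords2d), object@bbox[1], object@bbox[2],
              object@flippedCount, median(abs(object@distortion))))
})

setMethod("show", "ResolutionCurve", function(object) {
  cat(sprintf("ResolutionCurve: reference %.4g mm^2 at %.3g mm\n",
              object@referenceArea, object@referenceWidth))
  print(object@entries, row.names = FALSE)
})

setMethod("show", "AreaReport", function(object) {
  cat("AreaReport\n")
  print(object@areas, row.names = FALSE)
  if (length(object@ratios)) {
    for (nm in names(object@ratios))
      cat(sprintf("  %s = %.5g (%d%%)\n", nm, object@ratios[[nm]],
                  object@percents[[nm]]))
  }
})
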