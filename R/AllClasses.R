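#' @import methods
#' @importFrom stats median optim cor kmeans quantile rnorm runif sd .lm.fit setNames
#' @importFrom utils head tail
#' @useDynLib foliaflat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Volume: a 3D scalar image on an isotropic voxel grid
#'
#' Carrier of all image-domain data: echo images, prepared (combined,
#' flattened, inverted, filtered) images, and integer tissue-label maps.
#' World coordinates are in mm; the voxel with array index `(1,1,1)` has its
#' CENTER at `origin`, and voxel centers advance by `voxelWidth` per index.
#'
#' @slot values 3D numeric array (intensities or integer class labels).
#' @slot voxelWidth isotropic voxel width in mm (> 0).
#' @slot origin world coordinate (mm) of the center of the first voxel.
#' @export
setClass("Volume", representation(
  values = "array", voxelWidth = "numeric", origin = "numeric"
))

setValidity("Volume", function(object) {
  msg <- NULL
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  else if (any(dim(object@values) < 2L))
    msg <- c(msg, "each dimension must be >= 2 voxels")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(object@voxelWidth) != 1L || object@voxelWidth <= 0)
    msg <- c(msg, "voxelWidth must be a single positive number")
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite 3-vector")
  if (is.null(msg)) TRUE else msg
})

#' Construct a Volume
#'
#' @param values 3D numeric array.
#' @param voxelWidth isotropic voxel width (mm).
#' @param origin world coordinate (mm) of the center of voxel (1,1,1).
#' @return A [Volume-class] object.
#' @export
Volume <- function(values, voxelWidth, origin = c(0, 0, 0)) {
  new("Volume", values = values, voxelWidth = as.numeric(voxelWidth),
      origin = as.numeric(origin))
}

#' Two co-registered echo images (short-TE PD and long-TE T2*)
#'
#' @slot pd short-TE proton-density-weighted [Volume-class].
#' @slot t2star long-TE T2*-weighted [Volume-class] on the identical grid.
#' @export
setClass("TwoEchoPair", representation(pd = "Volume", t2star = "Volume"))

setValidity("TwoEchoPair", function(object) {
  if (!identical(dim(object@pd@values), dim(object@t2star@values)))
    return("pd and t2star grids differ in dimensions")
  if (object@pd@voxelWidth != object@t2star@voxelWidth)
    return("pd and t2star voxel widths differ")
  if (!isTRUE(all.equal(object@pd@origin, object@t2star@origin)))
    return("pd and t2star origins differ")
  TRUE
})

#' @rdname TwoEchoPair-class
#' @param pd,t2star the two echo [Volume-class]s.
#' @export
TwoEchoPair <- function(pd, t2star) new("TwoEchoPair", pd = pd, t2star = t2star)

#' Binary segmentation mask on a voxel grid
#'
#' @slot values 3D logical array.
#' @slot voxelWidth,origin grid geometry as in [Volume-class].
#' @export
setClass("SegmentationMask", representation(
  values = "array", voxelWidth = "numeric", origin = "numeric"
))

setValidity("SegmentationMask", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be a 3D array")
  if (!is.logical(object@values)) return("values must be logical")
  if (object@voxelWidth <= 0) return("voxelWidth must be > 0")
  TRUE
})

#' @rdname SegmentationMask-class
#' @param values,voxelWidth,origin see slots.
#' @export
SegmentationMask <- function(values, voxelWidth, origin = c(0, 0, 0)) {
  new("SegmentationMask", values = values, voxelWidth = as.numeric(voxelWidth),
      origin = as.numeric(origin))
}

#' Oriented triangle mesh in world coordinates
#'
#' Carrier of all surface-domain data. Triangles are 1-based vertex index
#' triples wound so that the right-hand normal points outward for closed
#' surfaces.
#'
#' @slot vertices n x 3 numeric matrix of vertex positions (mm).
#' @slot triangles m x 3 integer matrix of vertex indices.
#' @export
setClass("TriangleMesh", representation(
  vertices = "matrix", triangles = "matrix"
))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; tr <- object@triangles
  if (ncol(v) != 3L) return("vertices must be n x 3")
  if (ncol(tr) != 3L) return("triangles must be m x 3")
  if (!all(is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(tr) > 0L) {
    if (min(tr) < 1L || max(tr) > nrow(v))
      return("triangle indices out of range")
  }
  TRUE
})

#' @rdname TriangleMesh-class
#' @param vertices n x 3 numeric matrix (mm).
#' @param triangles m x 3 integer matrix of 1-based indices.
#' @export
TriangleMesh <- function(vertices, triangles) {
  storage.mode(triangles) <- "integer"
  new("TriangleMesh", vertices = as.matrix(vertices), triangles = triangles)
}

#' Per-vertex scalar field bound to a mesh
#'
#' Holds vertexwise quantities such as the local curvature map ("curv"),
#' the average convexity ("sulc"), or log areal distortion.
#'
#' @slot values numeric vector, one value per mesh vertex.
#' @slot meshLabel free-text identifier of the owning mesh.
#' @export
setClass("VertexScalarMap", representation(
  values = "numeric", meshLabel = "character"
))

setValidity("VertexScalarMap", function(object) {
  if (!all(is.finite(object@values))) return("values must be finite")
  TRUE
})

#' @rdname VertexScalarMap-class
#' @param values,meshLabel see slots.
#' @export
VertexScalarMap <- function(values, meshLabel = "") {
  new("VertexScalarMap", values = as.numeric(values), meshLabel = meshLabel)
}

#' Parametric folded-sheet phantom description
#'
#' Defines a synthetic specimen: a thin gray-matter sheet (inner granule and
#' outer molecular layer) folded at two scales — large "lobules" carrying
#' small "folia" — over a white-matter interior, immersed in a low-signal
#' background, plus the imaging conditions (tissue-class intensities per
#' echo, a shared smooth multiplicative coil bias field, additive Gaussian
#' noise, isotropic voxel width).
#'
#' @slot shapeKind one of "slab", "sphere_shell", "cylinder_shell",
#'   "folded_sheet".
#' @slot extent sheet-domain extent in mm (x, y, z).
#' @slot lobuleWavelength,lobuleAmplitude large folding scale (mm).
#' @slot foliumWavelength,foliumAmplitude small folding scale (mm).
#' @slot sheetThickness cortical gray thickness (mm).
#' @slot classMeans 4 x 2 matrix, rows background/white/granule/molecular,
#'   columns pd/t2star: mean intensity of each tissue class in each echo.
#' @slot biasOrder polynomial order of the shared coil-receive bias field.
#' @slot noiseSigma additive Gaussian noise SD (intensity units).
#' @slot voxelWidth isotropic voxel width (mm).
#' @slot seed integer; identical spec + seed gives bit-identical volumes.
#' @slot radius outer (pial) radius for shell shapes (mm); ignored otherwise.
#' @slot pad background padding around the structure (mm).
#' @export
setClass("PhantomSpec", representation(
  shapeKind = "character", extent = "numeric",
  lobuleWavelength = "numeric", lobuleAmplitude = "numeric",
  foliumWavelength = "numeric", foliumAmplitude = "numeric",
  sheetThickness = "numeric", classMeans = "matrix",
  biasOrder = "integer", noiseSigma = "numeric",
  voxelWidth = "numeric", seed = "integer",
  radius = "numeric", pad = "numeric"
))

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (!object@shapeKind %in%
      c("slab", "sphere_shell", "cylinder_shell", "folded_sheet"))
    msg <- c(msg, "unknown shapeKind")
  lens <- c(object@extent, object@lobuleWavelength, object@foliumWavelength,
            object@sheetThickness, object@voxelWidth, object@pad)
  if (any(lens <= 0)) msg <- c(msg, "all lengths must be > 0")
  if (object@foliumWavelength >= object@lobuleWavelength)
    msg <- c(msg, "foliumWavelength must be < lobuleWavelength")
  if (object@sheetThickness >= object@foliumWavelength)
    msg <- c(msg, "sheetThickness must be < foliumWavelength")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@lobuleAmplitude < 0 || object@foliumAmplitude < 0)
    msg <- c(msg, "amplitudes must be >= 0")
  cm <- object@classMeans
  if (!identical(rownames(cm),
                 c("background", "white", "granule", "molecular")) ||
      !identical(colnames(cm), c("pd", "t2star")))
    msg <- c(msg, paste("classMeans must have rows",
                        "background/white/granule/molecular, columns pd/t2star"))
  if (object@biasOrder < 0L) msg <- c(msg, "biasOrder must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Default tissue-class mean intensities per echo
#'
#' Chosen so that the combined (T2*/PD) and inverted image has white matter
#' brightest, then granule, then molecular layer, then background — the
#' monotone outward-decreasing profile the surface refinement relies on.
#' The background medium is modelled as nearly signal-free in both echoes.
#'
#' @return 4 x 2 matrix of class means.
#' @export
defaultClassMeans <- function() {
  m <- rbind(background = c(0.020, 0.021),
             white      = c(1.00, 0.25),
             granule    = c(0.90, 0.45),
             molecular  = c(0.80, 0.52))
  colnames(m) <- c("pd", "t2star")
  m
}

#' @rdname PhantomSpec-class
#' @param shapeKind,extent,lobuleWavelength,lobuleAmplitude,foliumWavelength,foliumAmplitude,sheetThickness,classMeans,biasOrder,noiseSigma,voxelWidth,seed,radius,pad
#'   see slot documentation.
#' @export
PhantomSpec <- function(shapeKind = "folded_sheet",
                        extent = c(40, 30, 20),
                        lobuleWavelength = 20, lobuleAmplitude = 3.5,
                        foliumWavelength = 4, foliumAmplitude = 0.6,
                        sheetThickness = 1.0,
                        classMeans = defaultClassMeans(),
                        biasOrder = 2L, noiseSigma = 0.01,
                        voxelWidth = 0.25, seed = 1L,
                        radius = NA_real_, pad = 2) {
  if (shapeKind %in% c("sphere_shell", "cylinder_shell") && is.na(radius))
    radius <- min(extent) / 2 - 2 * sheetThickness
  new("PhantomSpec", shapeKind = shapeKind, extent = as.numeric(extent),
      lobuleWavelength = lobuleWavelength, lobuleAmplitude = lobuleAmplitude,
      foliumWavelength = foliumWavelength, foliumAmplitude = foliumAmplitude,
      sheetThickness = sheetThickness, classMeans = classMeans,
      biasOrder = as.integer(biasOrder), noiseSigma = noiseSigma,
      voxelWidth = voxelWidth, seed = as.integer(seed),
      radius = as.numeric(radius), pad = pad)
}

#' Phantom with exactly known reference geometry
#'
#' @slot spec the generating [PhantomSpec-class].
#' @slot midSurface dense reference triangulation of the sheet mid-surface.
#' @slot pialArea,gwArea reference surface areas (mm^2).
#' @slot labels integer tissue-class label [Volume-class]
#'   (0 background, 1 white, 2 granule, 3 molecular).
#' @export
setClass("GroundTruthPhantom", representation(
  spec = "PhantomSpec", midSurface = "TriangleMesh",
  pialArea = "numeric", gwArea = "numeric", labels = "Volume"
))

setValidity("GroundTruthPhantom", function(object) {
  a <- c(object@pialArea, object@gwArea)
  if (any(a <= 0)) return("reference areas must be > 0")
  if (max(a) / min(a) > 2) return("pial and gw areas differ by > 2x")
  TRUE
})

#' Result of geometry-preserving inflation
#'
#' @slot inflated the inflated [TriangleMesh-class].
#' @slot sulc average convexity: per-vertex summed displacement along the
#'   vertex normal accumulated during inflation (mm); positive where the
#'   surface moved outward (fissure depths), negative at crowns.
#' @slot areaDrift relative change of total surface area vs. the input.
#' @slot iterations number of iterations run.
#' @slot converged logical.
#' @export
setClass("InflationResult", representation(
  inflated = "TriangleMesh", sulc = "numeric", areaDrift = "numeric",
  iterations = "integer", converged = "logical"
))

#' Isotropic fixation-shrinkage model
#'
#' @slot fraction volume fraction lost to fixation (default 0.03).
#' @export
setClass("ShrinkageModel", representation(fraction = "numeric"))

setValidity("ShrinkageModel", function(object) {
  f <- object@fraction
  if (length(f) != 1L || f < 0 || f >= 1)
    return("fraction must be in [0, 1)")
  TRUE
})

#' @rdname ShrinkageModel-class
#' @param fraction volume shrinkage fraction in `[0, 1)`.
#' @export
ShrinkageModel <- function(fraction = 0.03) new("ShrinkageModel", fraction = fraction)

#' Cut specification for a surface
#'
#' Either edge paths (vertex-index sequences along mesh edges, duplicated on
#' cutting) or an explicit per-vertex piece labelling.
#'
#' @slot paths list of integer vectors; consecutive entries share a mesh edge.
#' @slot pieceLabels optional integer vector, one label per vertex
#'   (length 0 when unused).
#' @export
setClass("CutSpec", representation(paths = "list", pieceLabels = "integer"))

#' @rdname CutSpec-class
#' @param paths list of integer vertex-index paths.
#' @param pieceLabels optional per-vertex piece labels.
#' @export
CutSpec <- function(paths = list(), pieceLabels = integer(0)) {
  new("CutSpec", paths = lapply(paths, as.integer),
      pieceLabels = as.integer(pieceLabels))
}

#' Planar embedding of a surface piece
#'
#' @slot coords2d n x 2 matrix of flattened vertex positions (mm).
#' @slot triangles as in the source piece.
#' @slot distortion per-vertex log areal ratio (2D over 3D 1-ring area).
#' @slot flippedCount number of 2D triangles with inverted orientation.
#' @slot bbox extents of the flat map's bounding box (mm).
#' @slot converged logical; FALSE flags a partial result.
#' @slot energy final metric (edge-spring) energy.
#' @export
setClass("FlatMap", representation(
  coords2d = "matrix", triangles = "matrix", distortion = "numeric",
  flippedCount = "integer", bbox = "numeric", converged = "logical",
  energy = "numeric"
))

#' Recovered-area-versus-voxel-width curve
#'
#' @slot entries data.frame with columns voxelWidth, areaMm2, fraction, ok.
#' @slot referenceArea pial area at native width (mm^2).
#' @slot referenceWidth native voxel width (mm).
#' @export
setClass("ResolutionCurve", representation(
  entries = "data.frame", referenceArea = "numeric", referenceWidth = "numeric"
))

setValidity("ResolutionCurve", function(object) {
  e <- object@entries
  if (is.unsorted(e$voxelWidth, strictly = TRUE))
    return("voxel widths must be strictly increasing")
  fr <- e$fraction[e$ok]
  if (length(fr) && (any(fr <= 0) || any(fr > 1.2)))
    return("recovered fractions must lie in (0, 1.2]")
  TRUE
})

#' Named area report with shrinkage correction and headline ratios
#'
#' @slot areas data.frame with columns label, raw_mm2, corrected_mm2.
#' @slot ratios named numeric vector of requested area ratios ("a/b").
#' @slot percents named integer vector: the same ratios as integer percent,
#'   rounded half away from zero.
#' @slot gwToPialFactor multiplier taking a gray/white area to a pial
#'   area estimate (default 1.2).
#' @export
setClass("AreaReport", representation(
  areas = "data.frame", ratios = "numeric", percents = "numeric",
  gwToPialFactor = "numeric"
))

setValidity("AreaReport", function(object) {
  a <- object@areas
  if (!all(c("label", "raw_mm2", "corrected_mm2") %in% names(a)))
    return("areas must have columns label, raw_mm2, corrected_mm2")
  if (any(a$raw_mm2 <= 0)) return("areas must be positive")
  TRUE
})
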