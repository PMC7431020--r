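#' Analytic mid-surface of a sheet phantom
#'
#' For `slab` and `folded_sheet` shapes the sheet mid-surface is the graph
#' `z = S(x, y)` over the sheet domain `[0, Lx] x [0, Ly]`:
#' `S = z0 + Al sin(2 pi x / Ll) + Af sin(2 pi y / Lf) env(x)`,
#' where `env(x)` is a smoothstep taper that brings the folium amplitude to
#' zero within one folium wavelength of the sheet's x edges (so the small
#' folds die out before the cut edge, avoiding boundary self-intersection).
#' The gray sheet occupies `S - t/2 <= z < S + t/2` (granule below the
#' mid-surface, molecular above), white matter fills `0 <= z < S - t/2`.
#'
#' @param spec a [PhantomSpec-class] with shapeKind "slab" or "folded_sheet".
#' @return list of vectorized functions `S(x, y)`, `Sx(x, y)`, `Sy(x, y)`
#'   (height and its partial derivatives).
#' @export
sheetHeightFunctions <- function(spec) {
  stopifnot(spec@shapeKind %in% c("slab", "folded_sheet"))
  z0 <- spec@extent[3] / 2
  if (spec@shapeKind == "slab") {
    return(list(S = function(x, y) rep(z0, length(x)),
                Sx = function(x, y) rep(0, length(x)),
                Sy = function(x, y) rep(0, length(x))))
  }
  Al <- spec@lobuleAmplitude; Ll <- spec@lobuleWavelength
  Af <- spec@foliumAmplitude; Lf <- spec@foliumWavelength
  Lx <- spec@extent[1]
  m <- Lf  # taper width
  ss <- function(t) {
    t <- pmin(pmax(t, 0), 1)
    3 * t^2 - 2 * t^3
  }
  dss <- function(t) ifelse(t > 0 & t < 1, 6 * t - 6 * t^2, 0)
  env <- function(x) ss(x / m) * ss((Lx - x) / m)
  denv <- function(x) dss(x / m) / m * ss((Lx - x) / m) -
    ss(x / m) * dss((Lx - x) / m) / m
  list(
    S = function(x, y) z0 + Al * sin(2 * pi * x / Ll) +
      Af * sin(2 * pi * y / Lf) * env(x),
    Sx = function(x, y) Al * (2 * pi / Ll) * cos(2 * pi * x / Ll) +
      Af * sin(2 * pi * y / Lf) * denv(x),
    Sy = function(x, y) Af * (2 * pi / Lf) * cos(2 * pi * y / Lf) * env(x)
  )
}

#' Reference mid-surface area of a sheet phantom by dense quadrature
#'
#' Midpoint-rule quadrature of `sqrt(1 + Sx^2 + Sy^2)` using the analytic
#' height gradient, sampled far denser than the folium frequency.
#'
#' @param spec a sheet-shaped [PhantomSpec-class].
#' @param xlim,ylim integration window (mm); default the full sheet domain.
#' @param spacing quadrature spacing (mm); default `foliumWavelength / 40`.
#' @return area in mm^2.
#' @export
sheetReferenceArea <- function(spec, xlim = c(0, spec@extent[1]),
                               ylim = c(0, spec@extent[2]),
                               spacing = spec@foliumWavelength / 40) {
  f <- sheetHeightFunctions(spec)
  nx <- max(8L, ceiling(diff(xlim) / spacing))
  ny <- max(8L, ceiling(diff(ylim) / spacing))
  hx <- diff(xlim) / nx; hy <- diff(ylim) / ny
  xs <- xlim[1] + (seq_len(nx) - 0.5) * hx
  ys <- ylim[1] + (seq_len(ny) - 0.5) * hy
  g <- expand.grid(x = xs, y = ys)
  sum(sqrt(1 + f$Sx(g$x, g$y)^2 + f$Sy(g$x, g$y)^2)) * hx * hy
}

#' Generate a phantom with exactly known surface area
#'
#' Builds the tissue-class label volume (0 background, 1 white, 2 granule,
#' 3 molecular), the dense reference mid-surface mesh, and the reference
#' gray/white and pial areas. For `slab`, `sphere_shell` and
#' `cylinder_shell` the stored areas are closed forms; for `folded_sheet`
#' they come from dense analytic quadrature. A folded sheet whose
#' half-thickness exceeds the mid-surface's minimum radius of curvature is
#' rejected (the offset layers would self-intersect).
#'
#' @param spec a [PhantomSpec-class].
#' @return a [GroundTruthPhantom-class].
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  w <- spec@voxelWidth; t <- spec@sheetThickness; pad <- spec@pad
  if (spec@shapeKind %in% c("slab", "folded_sheet")) {
    # a slab ignores the fold parameters entirely
    Al <- if (spec@shapeKind == "slab") 0 else spec@lobuleAmplitude
    Af <- if (spec@shapeKind == "slab") 0 else spec@foliumAmplitude
    kmax <- Al * (2 * pi / spec@lobuleWavelength)^2 +
      Af * (2 * pi / spec@foliumWavelength)^2
    if (spec@shapeKind == "folded_sheet" && (t / 2) * kmax >= 1)
      stop(sprintf(paste("sheet self-intersection: half-thickness %.3g mm",
                         "exceeds minimum curvature radius %.3g mm;",
                         "reduce amplitudes or increase wavelengths"),
                   t / 2, 1 / kmax))
    f <- sheetHeightFunctions(spec)
    z0 <- spec@extent[3] / 2
    zmaxS <- z0 + Al + Af
    if (z0 - Al - Af - t / 2 <= 0.5)
      stop("fold amplitudes too large for the z extent: no white interior left")
    boxMin <- c(-pad, -pad, -pad)
    boxMax <- c(spec@extent[1] + pad, spec@extent[2] + pad,
                min(spec@extent[3], zmaxS + t / 2 + 1) + pad)
    dims <- pmax(8L, as.integer(round((boxMax - boxMin) / w)))
    origin <- boxMin + w / 2
    xs <- origin[1] + (seq_len(dims[1]) - 1) * w
    ys <- origin[2] + (seq_len(dims[2]) - 1) * w
    zs <- origin[3] + (seq_len(dims[3]) - 1) * w
    g <- expand.grid(x = xs, y = ys)
    Sxy <- matrix(f$S(g$x, g$y), dims[1], dims[2])
    inDom <- outer(xs >= 0 & xs <= spec@extent[1],
                   ys >= 0 & ys <= spec@extent[2], "&")
    lab <- array(0L, dims)
    for (k in seq_len(dims[3])) {
      z <- zs[k]
      sl <- matrix(0L, dims[1], dims[2])
      sl[inDom & z >= 0 & z < Sxy - t / 2] <- 1L
      sl[inDom & z >= Sxy - t / 2 & z < Sxy] <- 2L
      sl[inDom & z >= Sxy & z < Sxy + t / 2] <- 3L
      lab[, , k] <- sl
    }
    if (spec@shapeKind == "slab") {
      areaMid <- spec@extent[1] * spec@extent[2]
    } else {
      areaMid <- sheetReferenceArea(spec)
    }
    step <- max(spec@foliumWavelength / 12, w)
    mid <- gridSheetMesh(function(x, y) f$S(x, y),
                         c(0, spec@extent[1]), c(0, spec@extent[2]),
                         nx = max(16L, ceiling(spec@extent[1] / step)),
                         ny = max(16L, ceiling(spec@extent[2] / step)))
    # offsetting the graph vertically by +/- t/2 leaves its area unchanged,
    # so gw, mid and pial reference areas coincide exactly
    return(new("GroundTruthPhantom", spec = spec, midSurface = mid,
               pialArea = areaMid, gwArea = areaMid,
               labels = Volume(lab, w, origin)))
  }
  R <- spec@radius
  if (!is.finite(R) || R <= t)
    stop("shell shapes need a finite radius > sheetThickness")
  if (spec@shapeKind == "sphere_shell") {
    boxMin <- rep(-R - pad, 3); boxMax <- rep(R + pad, 3)
    dims <- pmax(8L, as.integer(round((boxMax - boxMin) / w)))
    origin <- boxMin + w / 2
    ax <- lapply(1:3, function(d) origin[d] + (seq_len(dims[d]) - 1) * w)
    r2 <- outer(ax[[1]]^2, ax[[2]]^2, "+")
    lab <- array(0L, dims)
    for (k in seq_len(dims[3])) {
      r <- sqrt(r2 + ax[[3]][k]^2)
      sl <- matrix(0L, dims[1], dims[2])
      sl[r < R - t] <- 1L
      sl[r >= R - t & r < R - t / 2] <- 2L
      sl[r >= R - t / 2 & r < R] <- 3L
      lab[, , k] <- sl
    }
    mid <- icosphereMesh(R - t / 2, subdivisions = 4)
    return(new("GroundTruthPhantom", spec = spec, midSurface = mid,
               pialArea = 4 * pi * R^2, gwArea = 4 * pi * (R - t)^2,
               labels = Volume(lab, w, origin)))
  }
  # cylinder_shell: axis along z, length = extent[3]; reference areas are
  # the lateral (side-wall) areas, the flat cut ends are excluded
  L <- spec@extent[3]
  boxMin <- c(-R - pad, -R - pad, -pad)
  boxMax <- c(R + pad, R + pad, L + pad)
  dims <- pmax(8L, as.integer(round((boxMax - boxMin) / w)))
  origin <- boxMin + w / 2
  ax <- lapply(1:3, function(d) origin[d] + (seq_len(dims[d]) - 1) * w)
  rxy <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, "+"))
  lab <- array(0L, dims)
  sl <- matrix(0L, dims[1], dims[2])
  sl[rxy < R - t] <- 1L
  sl[rxy >= R - t & rxy < R - t / 2] <- 2L
  sl[rxy >= R - t / 2 & rxy < R] <- 3L
  for (k in seq_len(dims[3]))
    if (ax[[3]][k] >= 0 && ax[[3]][k] < L) lab[, , k] <- sl
  mid <- cylinderMesh(R - t / 2, L, nu = 96, nv = 48)
  new("GroundTruthPhantom", spec = spec, midSurface = mid,
      pialArea = 2 * pi * R * L, gwArea = 2 * pi * (R - t) * L,
      labels = Volume(lab, w, origin))
}

# run code with a private, seeded RNG stream, restoring the global state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# smooth multiplicative coil-receive bias field shared by both echoes:
# a random polynomial over normalized coordinates, affinely mapped into
# [0.6, 1.6] (order 0 gives the flat field 1)
makeBiasField <- function(dims, order, coeffs) {
  if (order == 0L) return(array(1, dims))
  u <- lapply(dims, function(n) seq(-1, 1, length.out = n))
  raw <- array(0, dims)
  idx <- 0L
  for (px in 0:order) for (py in 0:(order - px)) for (pz in 0:(order - px - py)) {
    idx <- idx + 1L
    term <- outer(outer(u[[1]]^px, u[[2]]^py), u[[3]]^pz)
    raw <- raw + coeffs[idx] * term
  }
  rng <- range(raw)
  if (diff(rng) < 1e-12) return(array(1, dims))
  0.6 + (raw - rng[1]) / (rng[2] - rng[1])
}

nPolyCoeffs <- function(order) {
  n <- 0L
  for (px in 0:order) for (py in 0:(order - px)) n <- n + (order - px - py + 1L)
  n
}

#' Synthesize the two echo images of a phantom
#'
#' Each echo is the tissue-class mean intensity of the label map, multiplied
#' by a smooth random polynomial bias field (the same field for both echoes,
#' emulating the shared coil receive profile), plus additive Gaussian noise.
#' All randomness flows from the single seed in the spec; identical spec and
#' seed give bit-identical volumes.
#'
#' @param phantom a [GroundTruthPhantom-class].
#' @param returnBias also return the bias field used.
#' @return a [TwoEchoPair-class], or (with `returnBias`) a list with
#'   elements `pair` and `bias`.
#' @export
synthesizeEchoes <- function(phantom, returnBias = FALSE) {
  spec <- phantom@spec
  lab <- phantom@labels@values
  dims <- dim(lab)
  cm <- spec@classMeans
  withSeed(spec@seed, {
    coeffs <- rnorm(nPolyCoeffs(max(1L, spec@biasOrder)))
    bias <- makeBiasField(dims, spec@biasOrder, coeffs)
    nvox <- prod(dims)
    pd <- array(cm[lab + 1L, "pd"], dims) * bias
    t2s <- array(cm[lab + 1L, "t2star"], dims) * bias
    if (spec@noiseSigma > 0) {
      pd <- pd + array(rnorm(nvox, sd = spec@noiseSigma), dims)
      t2s <- t2s + array(rnorm(nvox, sd = spec@noiseSigma), dims)
    }
  })
  pair <- TwoEchoPair(Volume(pd, spec@voxelWidth, phantom@labels@origin),
                      Volume(t2s, spec@voxelWidth, phantom@labels@origin))
  if (returnBias) list(pair = pair, bias = bias) else pair
}

#' Measure the recovered sheet area of a reconstructed surface
#'
#' For sheet phantoms, sums the areas of triangles belonging to the folded
#' top surface: centroid inside the margin-trimmed sheet window and normal
#' pointing upward (excludes the flat bottom and the vertical side walls of
#' the voxelized specimen block). Compare against
#' [sheetReferenceArea()] over the same window. For shell phantoms the
#' total mesh area is returned.
#'
#' @param mesh reconstructed surface ([TriangleMesh-class]).
#' @param spec the generating [PhantomSpec-class].
#' @param margin window trim (mm) applied to the sheet x/y domain.
#' @param nzMin minimum upward normal z-component for a sheet triangle.
#' @return area in mm^2.
#' @export
measurePhantomArea <- function(mesh, spec, margin = 3, nzMin = 0.2) {
  if (spec@shapeKind %in% c("sphere_shell", "cylinder_shell"))
    return(sum(triangleAreas(mesh)))
  tr <- mesh@triangles
  cent <- (mesh@vertices[tr[, 1], , drop = FALSE] +
           mesh@vertices[tr[, 2], , drop = FALSE] +
           mesh@vertices[tr[, 3], , drop = FALSE]) / 3
  nrm <- triangleNormals(mesh)
  keep <- cent[, 1] >= margin & cent[, 1] <= spec@extent[1] - margin &
    cent[, 2] >= margin & cent[, 2] <= spec@extent[2] - margin &
    nrm[, 3] > nzMin
  sum(triangleAreas(mesh)[keep])
}
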