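#' Preparation parameters for the image pipeline
#'
#' @slot ratioEpsilon denominator guard for the echo ratio; `NA` means
#'   auto (1e-3 times the median PD intensity over the foreground).
#' @slot biasPolyOrder polynomial order for residual bias flattening.
#' @slot fwhmVoxels in-plane Gaussian FWHM of the oriented filter, in
#'   voxels (default 2.5).
#' @slot filterWindow odd window width of the oriented filter (default 7).
#' @slot tensorSigma structure-tensor integration scale in voxels.
#' @slot isoRatio eigenvalue ratio below which the tensor is treated as
#'   isotropic and a 3D Gaussian of the same FWHM is used instead.
#' @slot passes number of filter passes.
#' @export
setClass("PrepConfig", representation(
  ratioEpsilon = "numeric", biasPolyOrder = "integer", fwhmVoxels = "numeric",
  filterWindow = "integer", tensorSigma = "numeric", isoRatio = "numeric",
  passes = "integer"
))

setValidity("PrepConfig", function(object) {
  msg <- NULL
  if (!is.na(object@ratioEpsilon) && object@ratioEpsilon <= 0)
    msg <- c(msg, "ratioEpsilon must be > 0 (or NA for auto)")
  if (object@filterWindow < 3L || object@filterWindow %% 2L == 0L)
    msg <- c(msg, "filterWindow must be odd and >= 3")
  if (object@fwhmVoxels <= 0) msg <- c(msg, "fwhmVoxels must be > 0")
  if (object@tensorSigma <= 0) msg <- c(msg, "tensorSigma must be > 0")
  if (object@passes < 1L) msg <- c(msg, "passes must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @rdname PrepConfig-class
#' @param ratioEpsilon,biasPolyOrder,fwhmVoxels,filterWindow,tensorSigma,isoRatio,passes
#'   see slots.
#' @export
PrepConfig <- function(ratioEpsilon = NA_real_, biasPolyOrder = 2L,
                       fwhmVoxels = 2.5, filterWindow = 7L,
                       tensorSigma = 1.5, isoRatio = 1.2, passes = 1L) {
  new("PrepConfig", ratioEpsilon = ratioEpsilon,
      biasPolyOrder = as.integer(biasPolyOrder), fwhmVoxels = fwhmVoxels,
      filterWindow = as.integer(filterWindow), tensorSigma = tensorSigma,
      isoRatio = isoRatio, passes = as.integer(passes))
}

#' Global Otsu threshold
#'
#' Maximizes between-class variance of the intensity histogram.
#'
#' @param x numeric vector or array.
#' @param nbins number of histogram bins.
#' @return threshold value.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  # clip the far tails so histogram binning is not destroyed by the heavy
  # tailed noise of near-zero denominators in ratio images
  r <- as.numeric(quantile(x, c(0.002, 0.998), names = FALSE))
  if (diff(r) == 0) return(r[1])
  x <- pmin(pmax(x, r[1]), r[2])
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  denom <- omega * (1 - omega)
  sigmaB <- ifelse(denom > 0, (muT * omega - mu)^2 / denom, 0)
  mids[which.max(sigmaB)]
}

#' Combine the two echoes to cancel the coil receive field
#'
#' Divides the long-TE (T2*-weighted) image by the short-TE (PD-weighted)
#' image voxel-by-voxel. Any multiplicative field shared by the two echoes
#' cancels exactly; `ratioEpsilon` guards the denominator against the
#' near-zero background.
#'
#' @param pair a [TwoEchoPair-class].
#' @param cfg a [PrepConfig-class].
#' @return combined ratio image as a [Volume-class].
#' @export
combineEchoes <- function(pair, cfg = PrepConfig()) {
  pd <- pair@pd@values; t2s <- pair@t2star@values
  if (!identical(dim(pd), dim(t2s)))
    stop(sprintf("echo grids differ: pd %s vs t2star %s",
                 paste(dim(pd), collapse = "x"),
                 paste(dim(t2s), collapse = "x")))
  eps <- cfg@ratioEpsilon
  if (is.na(eps)) {
    fg <- pd > otsuThreshold(pd)
    eps <- 1e-3 * median(pd[fg])
    if (!is.finite(eps) || eps <= 0) eps <- 1e-6
  }
  out <- t2s / (pd + eps)
  out[!is.finite(out)] <- 0
  Volume(out, pair@pd@voxelWidth, pair@pd@origin)
}

# design matrix of 3D monomials up to total degree `order` over normalized
# voxel coordinates
polyDesign <- function(dims, order, subset = NULL) {
  u <- lapply(dims, function(n) seq(-1, 1, length.out = n))
  idx <- if (is.null(subset)) seq_len(prod(dims)) else subset
  ii <- (idx - 1L) %% dims[1] + 1L
  jj <- ((idx - 1L) %/% dims[1]) %% dims[2] + 1L
  kk <- (idx - 1L) %/% (dims[1] * dims[2]) + 1L
  x <- u[[1]][ii]; y <- u[[2]][jj]; z <- u[[3]][kk]
  cols <- list()
  for (px in 0:order) for (py in 0:(order - px)) for (pz in 0:(order - px - py))
    cols[[length(cols) + 1L]] <- x^px * y^py * z^pz
  do.call(cbind, cols)
}

#' Flatten residual intensity bias and invert contrast
#'
#' Fits a low-order 3D polynomial to the log-intensity over the foreground
#' by least squares, divides it out (preserving the mean foreground level),
#' then inverts the contrast so that white matter becomes the brightest
#' tissue: `out = max_fg + min_fg - v`.
#'
#' @param vol input [Volume-class] (positive over the foreground).
#' @param cfg a [PrepConfig-class]; `biasPolyOrder` sets the fit order.
#' @param foregroundMask logical array (or [SegmentationMask-class]) of
#'   tissue voxels used for the fit and the inversion anchors.
#' @return flattened, inverted [Volume-class].
#' @export
flattenAndInvert <- function(vol, cfg = PrepConfig(), foregroundMask) {
  fg <- if (is(foregroundMask, "SegmentationMask")) foregroundMask@values
        else foregroundMask
  if (!any(fg)) stop("foreground mask is empty")
  v <- vol@values
  dims <- dim(v)
  idx <- which(fg)
  if (length(idx) > 2e5) {
    sub <- idx[seq(1L, length(idx), length.out = 2e5)]
  } else sub <- idx
  floorv <- 1e-6 * median(abs(v[sub]))
  X <- polyDesign(dims, cfg@biasPolyOrder, sub)
  yv <- log(pmax(v[sub], floorv))
  # segmentation-coupled fit: the log image is (class offset) + (smooth
  # bias); alternating a 1-D clustering of the residuals (the tissue-class
  # offsets) with a least-squares refit on offset-corrected data recovers
  # the bias field whether or not the classes are spatially correlated
  # with the polynomial basis — a plain fit would soak up the anatomy
  beta <- c(median(yv), rep(0, ncol(X) - 1L))
  for (pass in 1:10) {
    r <- yv - as.numeric(X %*% beta)
    if (1.4826 * median(abs(r - median(r))) < 1e-9) break
    init <- quantile(r, c(0.1, 0.5, 0.9), names = FALSE)
    init <- init + c(0, 1, 2) * 1e-7 * max(diff(range(r)), 1e-6)
    km <- suppressWarnings(kmeans(matrix(r, ncol = 1),
                                  centers = matrix(init, ncol = 1)))
    offs <- km$centers[km$cluster, 1] - mean(km$centers[km$cluster, 1])
    fit <- .lm.fit(X, yv - offs)
    if (fit$rank < ncol(X))
      stop("singular polynomial fit: degenerate foreground mask")
    betaNew <- fit$coefficients
    done <- max(abs(betaNew - beta)) < 1e-10
    beta <- betaNew
    if (done) break
  }
  Xall <- polyDesign(dims, cfg@biasPolyOrder)
  logbias <- as.numeric(Xall %*% beta)
  level <- mean(logbias[idx])
  flat <- array(as.numeric(v) / exp(logbias - level), dims)
  # inversion anchors: extreme quantiles rather than the absolute min/max,
  # which noise tails would otherwise control (identical for clean images)
  qs <- quantile(flat[idx], c(0.001, 0.999), names = FALSE)
  out <- qs[1] + qs[2] - flat
  # clamp to the observed tissue range (plus a quarter contrast span of
  # slack): intensities far outside it are ratio-noise in the near-zero
  # background and carry no boundary information, but would otherwise
  # dominate histograms and leak through the smoothing filter
  slack <- 0.25 * (qs[2] - qs[1])
  out <- pmin(pmax(out, qs[1] - slack), qs[2] + slack)
  # outside the foreground the echo ratio is noise over noise; pin those
  # voxels to the dark floor so the pial boundary is driven by the tissue
  # partial-volume profile, not by background ratio noise
  out[!fg] <- qs[1] - slack
  Volume(out, vol@voxelWidth, vol@origin)
}

#' Oriented anisotropic smoothing in the plane of least brightness variation
#'
#' At each voxel the structure tensor (Gaussian-integrated outer product of
#' intensity gradients) defines the local sheet orientation; the image is
#' smoothed with a 2D Gaussian of the configured FWHM restricted to the
#' plane of the two smallest-eigenvalue eigenvectors, sampled on the
#' `filterWindow`^3 neighborhood with trilinear interpolation, weights
#' normalized to one. Near-isotropic tensors (eigenvalue ratio below
#' `isoRatio`) fall back to an isotropic 3D Gaussian of the same FWHM. This
#' suppresses noise within the cortical sheet without blurring across it.
#'
#' @param vol input [Volume-class].
#' @param cfg a [PrepConfig-class].
#' @return filtered [Volume-class].
#' @export
orientedSmooth <- function(vol, cfg = PrepConfig()) {
  dims <- dim(vol@values)
  if (any(dims < cfg@filterWindow))
    stop("volume smaller than the filter window in at least one axis")
  out <- as.numeric(vol@values)
  for (p in seq_len(cfg@passes))
    out <- cpp_oriented_smooth(out, dims, cfg@filterWindow, cfg@fwhmVoxels,
                               cfg@tensorSigma, cfg@isoRatio)
  Volume(array(out, dims), vol@voxelWidth, vol@origin)
}

#' Sample a volume at world coordinates by trilinear interpolation
#'
#' @param vol a [Volume-class].
#' @param points n x 3 matrix of world coordinates (mm); coordinates are
#'   clamped to the grid.
#' @return numeric vector of sampled values.
#' @export
sampleVolume <- function(vol, points) {
  pts <- sweep(points, 2, vol@origin) / vol@voxelWidth
  cpp_trilinear(as.numeric(vol@values), dim(vol@values), pts)
}
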