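# shift a 3D logical/numeric array by one voxel along an axis, padding with
# `fill`; d = +1 brings in the previous neighbor (result[i] = x[i - 1])
shiftArray <- function(x, axis, d, fill = FALSE) {
  dims <- dim(x)
  out <- array(fill, dims)
  n <- dims[axis]
  src <- if (d > 0) seq_len(n - 1) else 2:n
  dst <- if (d > 0) 2:n else seq_len(n - 1)
  ix <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  sx <- ix; sx[[axis]] <- src
  dx <- ix; dx[[axis]] <- dst
  out[dx[[1]], dx[[2]], dx[[3]]] <- x[sx[[1]], sx[[2]], sx[[3]]]
  out
}

#' Segment the white-matter interior
#'
#' Thresholds the prepared (inverted, white-brightest) image, keeps the
#' largest 6-connected component, and fills interior cavities. Deterministic.
#'
#' @param vol prepared [Volume-class].
#' @param threshold `"otsu"` (global Otsu), `"otsu2"` (two-stage Otsu:
#'   background vs. tissue, then gray vs. white within tissue — the default
#'   for the four-class pipeline), or an explicit numeric threshold.
#' @return a [SegmentationMask-class].
#' @export
segmentWhite <- function(vol, threshold = "otsu2") {
  v <- vol@values
  th <- if (is.numeric(threshold)) {
    threshold
  } else if (identical(threshold, "otsu")) {
    otsuThreshold(v)
  } else if (identical(threshold, "otsu2")) {
    t1 <- otsuThreshold(v)
    otsuThreshold(v[v > t1])
  } else stop("threshold must be 'otsu', 'otsu2' or a number")
  m <- v > th
  if (!any(m)) stop("empty foreground after thresholding")
  lab <- array(cpp_label6(as.logical(m), dim(m)), dim(m))
  keep <- which.max(tabulate(lab[lab > 0L]))
  m <- lab == keep
  m <- array(cpp_fill_cavities(as.logical(m), dim(m)), dim(m))
  SegmentationMask(m, vol@voxelWidth, vol@origin)
}

# resolve voxel configurations that would tessellate to a non-manifold
# surface: two foreground voxels sharing only an edge (diagonal pattern in
# the 2x2 cross-section around the edge) or only a corner (body-diagonal
# pattern in a 2x2x2 block). The documented thickening rule fills the
# lexicographically first empty voxel of the offending pair; repeated until
# clean.
thickenNonManifold <- function(m) {
  for (pass in 1:25) {
    changed <- FALSE
    for (axis in 1:3) {
      oth <- setdiff(1:3, axis)
      a1 <- oth[1]; a2 <- oth[2]
      A <- m
      B <- shiftArray(m, a1, -1)   # neighbor at +1 along a1
      C <- shiftArray(m, a2, -1)   # neighbor at +1 along a2
      D <- shiftArray(B, a2, -1)   # diagonal neighbor
      # pattern 1: A and D set, B and C empty -> fill B (at +1 along a1)
      p <- A & D & !B & !C
      if (any(p)) {
        fill <- shiftArray(p, a1, 1)
        m[fill] <- TRUE
        changed <- TRUE
      }
      # pattern 2: B and C set, A and D empty -> fill A
      p <- !m & !D & B & C
      if (any(p)) {
        m[p] <- TRUE
        changed <- TRUE
      }
    }
    # corner-only contact: exactly the two body-diagonal voxels of a 2x2x2
    # block are set
    s <- function(dx, dy, dz) {
      out <- m
      if (dx) out <- shiftArray(out, 1, -1)
      if (dy) out <- shiftArray(out, 2, -1)
      if (dz) out <- shiftArray(out, 3, -1)
      out
    }
    blocks <- list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                   c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
    occ <- lapply(blocks, function(b) s(b[1], b[2], b[3]))
    total <- Reduce(`+`, lapply(occ, function(x) x + 0L))
    for (dpair in list(c(1, 8), c(2, 7), c(3, 6), c(4, 5))) {
      p <- total == 2L & occ[[dpair[1]]] & occ[[dpair[2]]]
      if (any(p)) {
        # fill the (0,0,0)-corner-adjacent voxel offset (1,0,0)
        fill <- shiftArray(p, 1, 1)
        m[fill] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Tessellate a segmentation mask into a closed triangle mesh
#'
#' Emits every boundary face between an in- and an out-voxel as a quad
#' split into two triangles, with vertices at voxel-corner world
#' coordinates, wound so normals point outward. Voxel configurations that
#' touch only along an edge or corner are first resolved by a thickening
#' rule so the output is always a closed 2-manifold.
#'
#' @param mask a [SegmentationMask-class].
#' @return a [TriangleMesh-class].
#' @export
tessellate <- function(mask) {
  m <- thickenNonManifold(mask@values)
  dims <- dim(m)
  w <- mask@voxelWidth
  corner0 <- mask@origin - w / 2  # world position of corner (0,0,0)
  nxc <- dims[1] + 1L; nyc <- dims[2] + 1L
  cornerId <- function(ci, cj, ck) 1 + ci + nxc * (cj + nyc * ck)
  tris <- vector("list", 6)
  dirIdx <- 0L
  for (axis in 1:3) for (sgn in c(1L, -1L)) {
    dirIdx <- dirIdx + 1L
    nb <- shiftArray(m, axis, -sgn)  # neighbor one step along sgn*axis
    face <- which(m & !nb, arr.ind = TRUE)
    if (nrow(face) == 0L) next
    i0 <- face[, 1] - 1L; j0 <- face[, 2] - 1L; k0 <- face[, 3] - 1L
    if (axis == 1L) {
      ci <- if (sgn > 0) i0 + 1L else i0
      c1 <- cornerId(ci, j0, k0); c2 <- cornerId(ci, j0 + 1L, k0)
      c3 <- cornerId(ci, j0 + 1L, k0 + 1L); c4 <- cornerId(ci, j0, k0 + 1L)
    } else if (axis == 2L) {
      cj <- if (sgn > 0) j0 + 1L else j0
      c1 <- cornerId(i0, cj, k0); c2 <- cornerId(i0, cj, k0 + 1L)
      c3 <- cornerId(i0 + 1L, cj, k0 + 1L); c4 <- cornerId(i0 + 1L, cj, k0)
    } else {
      ck <- if (sgn > 0) k0 + 1L else k0
      c1 <- cornerId(i0, j0, ck); c2 <- cornerId(i0 + 1L, j0, ck)
      c3 <- cornerId(i0 + 1L, j0 + 1L, ck); c4 <- cornerId(i0, j0 + 1L, ck)
    }
    if (sgn > 0) {
      t1 <- cbind(c1, c2, c3); t2 <- cbind(c1, c3, c4)
    } else {
      t1 <- cbind(c1, c3, c2); t2 <- cbind(c1, c4, c3)
    }
    tris[[dirIdx]] <- rbind(t1, t2)
  }
  tri <- do.call(rbind, tris)
  if (is.null(tri) || nrow(tri) == 0L) stop("mask has no boundary faces")
  used <- sort(unique(as.vector(tri)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  u0 <- used - 1L
  ci <- u0 %% nxc
  cj <- (u0 %/% nxc) %% nyc
  ck <- u0 %/% (nxc * nyc)
  verts <- cbind(corner0[1] + ci * w, corner0[2] + cj * w, corner0[3] + ck * w)
  TriangleMesh(verts, matrix(remap[tri], ncol = 3))
}

# binary erosion by one voxel (6-neighborhood)
erodeMask <- function(m) {
  out <- m
  for (axis in 1:3) for (d in c(-1, 1))
    out <- out & shiftArray(m, axis, d, fill = FALSE)
  out
}

# binary dilation by `steps` voxels (6-neighborhood)
dilateMask <- function(m, steps = 1L) {
  for (s in seq_len(steps)) {
    out <- m
    for (axis in 1:3) for (d in c(-1, 1))
      out <- out | shiftArray(m, axis, d, fill = FALSE)
    m <- out
  }
  m
}

#' Estimate refinement isovalues from the data
#'
#' White-side level: median intensity over the eroded white mask. The
#' flanking gray and background levels come from k-means (k = 3,
#' deterministic quantile initialization) on intensities outside the mask:
#' sorted centers give the granule, molecular and background levels. The
#' gray/white isovalue is the midpoint of the white median and the granule
#' center; the pial isovalue is the midpoint of the molecular and
#' background centers.
#'
#' @param vol prepared [Volume-class].
#' @param mask white-matter [SegmentationMask-class].
#' @return list with `gw`, `pial`, and the class levels.
#' @export
estimateIsovalues <- function(vol, mask) {
  v <- vol@values
  m <- mask@values
  inside <- erodeMask(m)
  if (!any(inside)) inside <- m
  whiteMed <- median(v[inside])
  # sample the shell just outside the mask: deep enough to reach background
  # whatever the gray thickness in voxels, shallow enough that the three
  # classes stay balanced for clustering
  shell <- dilateMask(m, 6L) & !m
  outsideVals <- v[shell]
  if (length(outsideVals) > 2e5)
    outsideVals <- outsideVals[seq(1L, length(outsideVals), length.out = 2e5)]
  # clip heavy noise tails so the cluster centers stay at the class levels
  qs <- quantile(outsideVals, c(0.005, 0.995), names = FALSE)
  outsideVals <- pmin(pmax(outsideVals, qs[1]), qs[2])
  init <- quantile(outsideVals, c(0.95, 0.5, 0.05), names = FALSE)
  # keep the deterministic initial centers distinct even when the shell is
  # dominated by a single (pinned background) level
  init <- init + c(2, 1, 0) * 1e-7 * max(diff(range(outsideVals)), 1e-6)
  km <- kmeans(matrix(outsideVals, ncol = 1), centers = matrix(init, ncol = 1))
  cen <- sort(km$centers[, 1], decreasing = TRUE)
  list(gw = (whiteMed + cen[1]) / 2, pial = (cen[2] + cen[3]) / 2,
       white = whiteMed, granule = cen[1], molecular = cen[2],
       background = cen[3])
}

# one deformable-surface refinement run; returns mesh + convergence info
refineOne <- function(mesh, vol, iso, contrast, maxIter, stepClamp, lambdaT,
                      tol, avoidSelf = FALSE, lambdaN = 0) {
  V <- mesh@vertices
  w <- vol@voxelWidth
  n <- nrow(V)
  ops <- meshOperators(mesh)
  W <- ops$W
  ring2 <- NULL
  if (avoidSelf) {
    # 2-ring neighbor lists (CSC of a symmetric pattern = per-vertex rows)
    P <- methods::as(ops$A + ops$A %*% ops$A, "CsparseMatrix")
    ring2 <- list(xp = P@p, xi = P@i)
  }
  converged <- FALSE
  it <- 0L
  meanResid <- NA_real_
  s0 <- 0.25 * contrast
  for (it in seq_len(maxIter)) {
    nrm <- fastVertexNormals(V, mesh@triangles, ops$Tinc)
    I <- sampleVolume(vol, V)
    err <- I - iso
    stepN <- stepClamp * w * tanh(err / s0)
    Lap <- as.matrix(W %*% V) - V
    lapN <- rowSums(Lap * nrm)
    LapT <- Lap - nrm * lapN
    moveN <- stepN + lambdaN * lapN
    if (avoidSelf) {
      # spatial-hash proximity to facing (normal-opposed) non-2-ring
      # surface: freeze outward motion near contact, back off when the gap
      # falls below a voxel
      d <- cpp_nonlocal_min_dist(V, nrm, ring2$xp, ring2$xi, cutoff = 2 * w)
      moveN[d < 1.0 * w & moveN > 0] <- 0
      moveN[d < 0.6 * w] <- -0.5 * stepClamp * w
    }
    V <- V + nrm * moveN + lambdaT * LapT
    meanResid <- mean(abs(stepN)) / w
    if (meanResid < tol) {
      converged <- TRUE
      break
    }
  }
  list(mesh = TriangleMesh(V, mesh@triangles), converged = converged,
       iterations = it, meanStepVoxels = meanResid)
}

# remove residual local fold-overs (adjacent triangles crossing after a
# noisy deformation) by repeatedly Laplacian-relaxing the vertices of
# intersecting triangle pairs; returns the mesh and the leftover count
untangleSelfIntersections <- function(mesh, maxRounds = 15L) {
  tr <- mesh@triangles
  V <- mesh@vertices
  A <- vertexAdjacency(mesh)
  W <- A / Matrix::rowSums(A)
  pairs <- cpp_self_intersection_pairs(V, tr)
  rounds <- 0L
  while (nrow(pairs) > 0L && rounds < maxRounds) {
    rounds <- rounds + 1L
    bad <- unique(as.vector(tr[as.vector(pairs), ]))
    sm <- as.matrix(W %*% V)
    V[bad, ] <- sm[bad, , drop = FALSE]
    pairs <- cpp_self_intersection_pairs(V, tr)
  }
  list(mesh = TriangleMesh(V, tr), remaining = nrow(pairs), rounds = rounds)
}

#' Refine an initial tessellation into gray/white and pial surfaces
#'
#' Iterative per-vertex deformation: a displacement along the vertex normal
#' toward the target intensity isovalue (the prepared image decreases
#' monotonically from white matter outward, so positive intensity error
#' drives the vertex outward), plus tangential Laplacian smoothing, with the
#' normal step clamped to a quarter voxel. The gray/white surface targets
#' the white/granule isovalue; the pial surface starts from the gray/white
#' result, targets the molecular/background isovalue, and truncates outward
#' steps of vertices that approach non-neighboring surface (spatial-hash
#' proximity check). Self-intersection of the pial output can be verified
#' exactly with [selfIntersectionCount()].
#'
#' @param init closed manifold [TriangleMesh-class] from [tessellate()].
#' @param vol prepared, filtered [Volume-class].
#' @param gwIso,pialIso target isovalues (see [estimateIsovalues()]).
#' @param maxIter iteration cap per surface.
#' @param stepClamp normal step clamp in voxels (default 0.25).
#' @param lambdaT tangential smoothing weight.
#' @param lambdaN normal (curvature-spring) smoothing weight that damps
#'   noise-driven wrinkling.
#' @param tol convergence: mean |normal step| below `tol` voxels.
#' @return list with `gw`, `pial` ([TriangleMesh-class]), and per-surface
#'   convergence info (`gwInfo`, `pialInfo`: flag, iterations, residual).
#' @export
refineSurfaces <- function(init, vol, gwIso, pialIso, maxIter = 100L,
                           stepClamp = 0.25, lambdaT = 0.3, lambdaN = 0.1,
                           tol = 0.02) {
  contrast <- abs(gwIso - pialIso)
  if (contrast <= 0) stop("gwIso and pialIso must differ")
  gw <- refineOne(init, vol, gwIso, contrast, maxIter, stepClamp, lambdaT,
                  tol, lambdaN = lambdaN)
  pial <- refineOne(gw$mesh, vol, pialIso, contrast, maxIter, stepClamp,
                    lambdaT, tol, avoidSelf = TRUE, lambdaN = lambdaN)
  fix <- untangleSelfIntersections(pial$mesh)
  if (fix$remaining > 0L)
    warning(sprintf("pial surface kept %d self-intersecting triangle pairs after %d untangling rounds",
                    fix$remaining, fix$rounds))
  list(gw = gw$mesh, pial = fix$mesh,
       gwInfo = gw[c("converged", "iterations", "meanStepVoxels")],
       pialInfo = c(pial[c("converged", "iterations", "meanStepVoxels")],
                    list(untangleRounds = fix$rounds,
                         selfIntersections = fix$remaining)))
}
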