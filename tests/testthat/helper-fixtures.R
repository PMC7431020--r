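# Shared fixtures, all generated in code.

# spherical cap of the given opening angle, consistently wound (+z apex)
capMesh <- function(alphaDeg, R = 10, nr = 12, na = 36) {
  alpha <- alphaDeg * pi / 180
  verts <- matrix(c(0, 0, R), 1)
  start <- 1L
  for (i in 1:nr) {
    th <- alpha * i / nr
    ph <- seq(0, 2 * pi, length.out = na + 1)[-(na + 1)]
    verts <- rbind(verts, cbind(R * sin(th) * cos(ph), R * sin(th) * sin(ph),
                                R * cos(th)))
    start <- c(start, nrow(verts) - na + 1L)
  }
  idx <- function(i, k) start[i + 1] + (k - 1L) %% na
  f <- NULL
  for (k in 1:na) f <- rbind(f, c(1L, idx(1, k + 1), idx(1, k)))
  for (i in 1:(nr - 1)) for (k in 1:na) {
    a <- idx(i, k); b <- idx(i, k + 1); cc <- idx(i + 1, k + 1); d <- idx(i + 1, k)
    f <- rbind(f, c(a, b, cc), c(a, cc, d))
  }
  TriangleMesh(verts, f)
}

# small sphere-shell phantom spec used across module tests
smallSphereSpec <- function(seed = 7, noise = 0.01, w = 0.5) {
  PhantomSpec(shapeKind = "sphere_shell", extent = c(26, 26, 26), radius = 10,
              sheetThickness = 1, voxelWidth = w, noiseSigma = noise,
              seed = seed)
}

# small folia-scale folded sheet for resolution tests
foliaSpec <- function(seed = 5) {
  PhantomSpec(extent = c(20, 16, 12), lobuleWavelength = 12,
              lobuleAmplitude = 2, foliumWavelength = 3,
              foliumAmplitude = 0.45, sheetThickness = 0.7,
              voxelWidth = 0.2, seed = seed)
}

# digitize a solid ball into a SegmentationMask, radius in voxels
digitizedBallMask <- function(rVox, w = 1) {
  n <- as.integer(2 * rVox + 5)
  c0 <- (n + 1) / 2
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  m <- array((g$i - c0)^2 + (g$j - c0)^2 + (g$k - c0)^2 <= rVox^2, c(n, n, n))
  SegmentationMask(m, w)
}

rotationMatrix3 <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
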