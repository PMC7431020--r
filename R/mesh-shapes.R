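#' Reference meshes: icosphere, cylinder tube, torus, graph sheet, peanut
#'
#' Small parametric meshes used for calibration and testing: the icosphere
#' calibrates the discrete curvature scale; tube/torus/sheet exercise the
#' cutting and flattening machinery; the peanut is a two-lobe closed shape
#' whose waist/crown geometry probes the sign convention of sulc.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions icosahedron subdivision level (4 -> 2562 vertices).
#' @return a [TriangleMesh-class] with outward-pointing normals.
#' @export
icosphereMesh <- function(radius = 1, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    key <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      got <- key[[k]]
      if (!is.null(got)) return(got)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      key[[k]] <- nv
      nv
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(4 * i - 3):(4 * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    v <- v / sqrt(rowSums(v^2))
    f <- nf
  }
  TriangleMesh(v * radius, f)
}

#' @rdname icosphereMesh
#' @param height tube height (mm); the tube axis is z.
#' @param nu,nv angular and axial sample counts.
#' @param caps close the tube with end caps (fan to a pole vertex).
#' @export
cylinderMesh <- function(radius = 5, height = 20, nu = 48, nv = 30,
                         caps = FALSE) {
  th <- seq(0, 2 * pi, length.out = nu + 1)[-(nu + 1)]
  z <- seq(0, height, length.out = nv)
  v <- cbind(radius * cos(rep(th, nv)), radius * sin(rep(th, nv)),
             rep(z, each = nu))
  idx <- function(i, j) (j - 1L) * nu + ((i - 1L) %% nu) + 1L
  f <- list()
  for (j in seq_len(nv - 1)) for (i in seq_len(nu)) {
    a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    f[[length(f) + 1L]] <- rbind(c(a, b, cc), c(a, cc, d))
  }
  f <- do.call(rbind, f)
  if (caps) {
    p1 <- nrow(v) + 1L; p2 <- nrow(v) + 2L
    v <- rbind(v, c(0, 0, 0), c(0, 0, height))
    for (i in seq_len(nu)) {
      f <- rbind(f,
                 c(p1, idx(i + 1, 1L), idx(i, 1L)),
                 c(p2, idx(i, nv), idx(i + 1, nv)))
    }
  }
  TriangleMesh(v, f)
}

#' @rdname icosphereMesh
#' @param R,r major and minor torus radii (mm).
#' @export
torusMesh <- function(R = 10, r = 3, nu = 36, nv = 18) {
  u <- seq(0, 2 * pi, length.out = nu + 1)[-(nu + 1)]
  w <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  g <- expand.grid(iu = seq_len(nu), iv = seq_len(nv))
  uu <- u[g$iu]; ww <- w[g$iv]
  v <- cbind((R + r * cos(ww)) * cos(uu), (R + r * cos(ww)) * sin(uu),
             r * sin(ww))
  idx <- function(i, j) ((j - 1L) %% nv) * nu + ((i - 1L) %% nu) + 1L
  f <- matrix(0L, 2 * nu * nv, 3)
  k <- 0L
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    f[k + 1L, ] <- c(a, b, cc); f[k + 2L, ] <- c(a, cc, d); k <- k + 2L
  }
  TriangleMesh(v, f)
}

#' @rdname icosphereMesh
#' @param fz function of (x, y) returning sheet height z (mm); vectorized.
#' @param xlim,ylim sheet domain (mm).
#' @param nx,ny sample counts along x and y.
#' @export
gridSheetMesh <- function(fz, xlim, ylim, nx = 80, ny = 60) {
  xs <- seq(xlim[1], xlim[2], length.out = nx)
  ys <- seq(ylim[1], ylim[2], length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  v <- cbind(g$x, g$y, fz(g$x, g$y))
  idx <- function(i, j) (j - 1L) * nx + i
  f <- matrix(0L, 2 * (nx - 1) * (ny - 1), 3)
  k <- 0L
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    # winding gives +z normals
    f[k + 1L, ] <- c(a, b, cc); f[k + 2L, ] <- c(a, cc, d); k <- k + 2L
  }
  TriangleMesh(v, f)
}

#' @rdname icosphereMesh
#' @param waist fractional radius reduction at the waist (0..1).
#' @param elongation scale factor applied along z.
#' @export
peanutMesh <- function(radius = 5, waist = 0.45, elongation = 1.8,
                       subdivisions = 3) {
  m <- icosphereMesh(radius, subdivisions)
  v <- m@vertices
  z <- v[, 3] * elongation
  pinch <- 1 - waist * exp(-(z / (0.45 * radius * elongation))^2)
  TriangleMesh(cbind(v[, 1] * pinch, v[, 2] * pinch, z), m@triangles)
}
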