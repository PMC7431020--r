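#' Cut a surface along edge paths or a piece labelling
#'
#' Path cutting duplicates the vertices along each path so the surface
#' separates there: around every path vertex the incident triangle fan is
#' partitioned into the groups still connected through non-cut edges, and
#' each group beyond the first receives its own copy of the vertex. Open
#' path endpoints are not duplicated (the cut ends in a slit), and paths may
#' touch mesh boundary or each other. With `pieceLabels`, triangles are
#' assigned to the majority label of their vertices and pieces are split
#' directly. The result is split into connected pieces, each a
#' manifold-with-boundary, with a vertex provenance map so per-vertex
#' scalar maps transfer.
#'
#' @param mesh a [TriangleMesh-class].
#' @param cuts a [CutSpec-class].
#' @return list of pieces; each element has `mesh` and `origVertices`
#'   (index into the vertices of the input mesh).
#' @export
applyCuts <- function(mesh, cuts) {
  if (length(cuts@pieceLabels)) {
    if (length(cuts@pieceLabels) != nrow(mesh@vertices))
      stop("pieceLabels must have one label per vertex")
    tr <- mesh@triangles
    lab <- matrix(cuts@pieceLabels[tr], ncol = 3)
    triLab <- apply(lab, 1, function(r) {
      tb <- table(r)
      as.integer(names(tb)[which.max(tb)])
    })
    out <- list()
    for (l in sort(unique(triLab))) {
      sub <- extractSubmesh(mesh, which(triLab == l))
      out[[length(out) + 1L]] <- list(mesh = sub$mesh,
                                      origVertices = sub$vertexMap)
    }
    return(out)
  }
  V <- mesh@vertices
  tr <- mesh@triangles
  # cut edge set
  cutKey <- character(0)
  for (p in cuts@paths) {
    if (length(p) < 2L) stop("each cut path needs at least 2 vertices")
    a <- p[-length(p)]; b <- p[-1]
    cutKey <- c(cutKey, paste(pmin(a, b), pmax(a, b)))
  }
  et <- meshEdgeTable(mesh)
  allKey <- paste(et$edges[, 1], et$edges[, 2])
  bad <- setdiff(cutKey, allKey)
  if (length(bad))
    stop("cut path uses non-edges: ", paste(head(bad, 3), collapse = "; "))
  cutSet <- new.env(hash = TRUE)
  for (k in cutKey) assign(k, TRUE, envir = cutSet)
  # vertex -> incident triangles
  n <- nrow(V)
  vt <- vector("list", n)
  for (corner in 1:3) {
    sp <- split(seq_len(nrow(tr)), tr[, corner])
    for (nm in names(sp))
      vt[[as.integer(nm)]] <- c(vt[[as.integer(nm)]], sp[[nm]])
  }
  pathVerts <- sort(unique(unlist(cuts@paths)))
  newV <- list()
  origOfNew <- integer(0)
  for (v in pathVerts) {
    tris <- vt[[v]]
    if (is.null(tris)) stop("cut path vertex ", v, " not on the mesh")
    # union-find over incident triangles: connect through non-cut edges at v
    parent <- seq_along(tris)
    findp <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    others <- lapply(tris, function(t) setdiff(tr[t, ], v))
    # group triangles by shared neighbor u with (v,u) not cut
    us <- unique(unlist(others))
    for (u in us) {
      k <- paste(min(v, u), max(v, u))
      if (!is.null(cutSet[[k]])) next
      members <- which(vapply(others, function(o) u %in% o, logical(1)))
      if (length(members) > 1) {
        r <- findp(members[1])
        for (mm in members[-1]) parent[findp(mm)] <- r
      }
    }
    roots <- vapply(seq_along(tris), findp, integer(1))
    groups <- split(seq_along(tris), roots)
    if (length(groups) > 1) {
      for (gi in seq_along(groups)[-1]) {
        newIdx <- n + length(origOfNew) + 1L
        origOfNew <- c(origOfNew, v)
        for (t in tris[groups[[gi]]]) tr[t, tr[t, ] == v] <- newIdx
      }
    }
  }
  if (length(origOfNew)) V <- rbind(V, V[origOfNew, , drop = FALSE])
  provenance <- c(seq_len(n), origOfNew)
  cutMesh <- TriangleMesh(V, tr)
  comps <- meshComponents(cutMesh)
  lapply(comps, function(cp) list(mesh = cp$mesh,
                                  origVertices = provenance[cp$vertexMap]))
}

# sum `val` into bins given by `idx` over 1..n
tabulateSum <- function(idx, val, n) {
  out <- numeric(n)
  acc <- rowsum(val, idx, reorder = FALSE)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

# per-vertex 1-ring triangle-area sums
vertexRingAreas <- function(triangleMat, areas, n) {
  out <- numeric(n)
  for (k in 1:3) {
    acc <- rowsum(areas, triangleMat[, k], reorder = FALSE)
    idx <- as.integer(rownames(acc))
    out[idx] <- out[idx] + acc[, 1]
  }
  out
}

area2d <- function(p, tr) {
  a <- p[tr[, 2], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  b <- p[tr[, 3], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  0.5 * (a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Flatten a disk-topology surface piece with minimal metric distortion
#'
#' The piece must be a topological disk (Euler characteristic 1): surfaces
#' with leftover intrinsic curvature "bubbles" cannot be flattened without
#' severe distortion and are rejected with advice to cut further. The map
#' is initialized by a boundary-fixed convex (Tutte) embedding — boundary on
#' a circle, interior by a uniform-weight Laplace solve, which is flip-free —
#' and then relaxed with free boundary by as-rigid-as-possible local/global
#' iteration: each triangle's target is the best-fitting rotation of its
#' isometric 2D rest shape, and a single prefactored sparse least-squares
#' solve updates all positions. This minimizes metric distortion while
#' strongly preserving orientation, which lets multiply folded (accordion)
#' sheets unroll without fold-overs. A final quasi-Newton polish of the
#' edge-spring energy `sum_e (|e_2D| - |e_3D|)^2` sharpens edge lengths;
#' residual flipped triangles are repaired by local untangling, and a
#' nonzero leftover count is flagged rather than hidden.
#'
#' @param piece a [TriangleMesh-class] disk (e.g., from [applyCuts()]).
#' @param maxIter iteration cap for the local/global relaxation.
#' @param polishIter iteration cap for the spring-energy polish.
#' @param flipRepairRounds local untangling rounds if flips remain.
#' @return a [FlatMap-class].
#' @export
flattenPiece <- function(piece, maxIter = 300L, polishIter = 500L,
                         flipRepairRounds = 10L) {
  chi <- eulerCharacteristic(piece)
  if (chi != 1L)
    stop(sprintf(paste("piece is not a topological disk (Euler characteristic",
                       "%d, need 1): add more cuts before flattening"), chi))
  V <- piece@vertices
  tr <- piece@triangles
  n <- nrow(V)
  m <- nrow(tr)
  loops <- boundaryLoops(piece)
  if (!length(loops)) stop("piece has no boundary; cut it open first")
  loop <- loops[[which.max(lengths(loops))]]
  area3 <- triangleAreas(piece)
  totalArea3 <- sum(area3)
  # boundary on a circle, spaced by boundary arc length
  bl <- V[loop, , drop = FALSE]
  seg <- sqrt(rowSums((bl - bl[c(2:nrow(bl), 1), , drop = FALSE])^2))
  theta <- 2 * pi * cumsum(c(0, seg[-length(seg)])) / sum(seg)
  r <- sqrt(totalArea3 / pi)
  p <- matrix(0, n, 2)
  p[loop, ] <- r * cbind(cos(theta), sin(theta))
  interior <- setdiff(seq_len(n), loop)
  A <- vertexAdjacency(piece)
  deg <- Matrix::rowSums(A)
  if (length(interior)) {
    L <- Matrix::Diagonal(x = deg) - A
    Lii <- L[interior, interior, drop = FALSE]
    Lib <- L[interior, loop, drop = FALSE]
    p[interior, ] <- as.matrix(Matrix::solve(Lii, -Lib %*% p[loop, ]))
  }
  # isometric 2D rest shape of every triangle
  q1 <- V[tr[, 1], , drop = FALSE]
  e1 <- V[tr[, 2], , drop = FALSE] - q1
  e2 <- V[tr[, 3], , drop = FALSE] - q1
  l1 <- sqrt(rowSums(e1^2)); l1[l1 < 1e-12] <- 1e-12
  u <- e1 / l1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nl <- sqrt(rowSums(nrm^2)); nl[nl < 1e-12] <- 1e-12
  nrm <- nrm / nl
  vax <- cbind(nrm[, 2] * u[, 3] - nrm[, 3] * u[, 2],
               nrm[, 3] * u[, 1] - nrm[, 1] * u[, 3],
               nrm[, 1] * u[, 2] - nrm[, 2] * u[, 1])
  # rest edge vectors (2->1 is implied); r2 = B - A, r3 = C - A in 2D
  r2 <- cbind(l1, 0)
  r3 <- cbind(rowSums(e2 * u), rowSums(e2 * vax))
  # global-step operator: uniform-weight least squares over the three
  # directed edges of every triangle; soft-pin vertex 1 to fix translation
  ei <- c(tr[, 1], tr[, 2], tr[, 3])
  ej <- c(tr[, 2], tr[, 3], tr[, 1])
  Lg <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = -1,
                             dims = c(n, n)) +
    Matrix::Diagonal(x = tabulate(c(ei, ej), n))
  Lg[1, 1] <- Lg[1, 1] + 1
  ch <- Matrix::Cholesky(methods::as(Lg, "symmetricMatrix"), LDL = FALSE)
  restE <- list(r2, r3 - r2, -r3)  # edge vectors A->B, B->C, C->A
  # signed incidence of the three directed edges per triangle, prebuilt so
  # the per-iteration right-hand side is a single sparse matvec
  Minc <- do.call(cbind, lapply(1:3, function(k) {
    a <- tr[, k]; b <- tr[, c(2, 3, 1)[k]]
    Matrix::sparseMatrix(i = c(b, a), j = rep(seq_len(m), 2),
                         x = rep(c(1, -1), each = m), dims = c(n, m))
  }))
  pinTarget <- p[1, ]
  prev <- p
  for (iter in seq_len(maxIter)) {
    # local step: best rotation per triangle (closed-form 2x2 polar factor)
    d2 <- p[tr[, 2], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
    d3 <- p[tr[, 3], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
    # covariance S = sum_k cur_k rest_k^T over the two independent edges
    s11 <- d2[, 1] * r2[, 1] + d3[, 1] * r3[, 1]
    s12 <- d2[, 1] * r2[, 2] + d3[, 1] * r3[, 2]
    s21 <- d2[, 2] * r2[, 1] + d3[, 2] * r3[, 1]
    s22 <- d2[, 2] * r2[, 2] + d3[, 2] * r3[, 2]
    x1 <- s11 + s22
    x2 <- s21 - s12
    rr <- sqrt(x1^2 + x2^2); rr[rr < 1e-12] <- 1
    ct <- x1 / rr; st <- x2 / rr
    # right-hand side: every directed edge (a->b) contributes R_t * rest
    # edge to b and its negative to a
    tx <- unlist(lapply(restE, function(re) ct * re[, 1] - st * re[, 2]),
                 use.names = FALSE)
    ty <- unlist(lapply(restE, function(re) st * re[, 1] + ct * re[, 2]),
                 use.names = FALSE)
    bx <- as.numeric(Minc %*% tx)
    by <- as.numeric(Minc %*% ty)
    bx[1] <- bx[1] + pinTarget[1]
    by[1] <- by[1] + pinTarget[2]
    p <- cbind(as.numeric(Matrix::solve(ch, bx)),
               as.numeric(Matrix::solve(ch, by)))
    move <- sqrt(mean(rowSums((p - prev)^2)))
    prev <- p
    if (move < 1e-7 * sqrt(totalArea3)) break
  }
  # polish: free-boundary quasi-Newton descent of the edge-spring energy
  et <- meshEdgeTable(piece)
  e <- et$edges
  L3 <- sqrt(rowSums((V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE])^2))
  energyFn <- function(x) {
    q <- matrix(x, n, 2)
    d <- q[e[, 1], , drop = FALSE] - q[e[, 2], , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    sum((len - L3)^2)
  }
  gradFn <- function(x) {
    q <- matrix(x, n, 2)
    d <- q[e[, 1], , drop = FALSE] - q[e[, 2], , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    len[len < 1e-12] <- 1e-12
    f <- d * (2 * (len - L3) / len)
    g <- matrix(0, n, 2)
    for (c in 1:2) {
      acc <- rowsum(c(f[, c], -f[, c]), c(e[, 1], e[, 2]), reorder = FALSE)
      g[as.integer(rownames(acc)), c] <- acc[, 1]
    }
    as.numeric(g)
  }
  opt <- NULL
  if (polishIter > 0L) {
    opt <- optim(as.numeric(p), energyFn, gradFn, method = "L-BFGS-B",
                 control = list(maxit = polishIter, factr = 1e4))
    # second basin: relax from the principal-plane projection, which is the
    # better start for gently curved (cap-like) pieces, while the ARAP
    # route wins for multiply folded ones; keep whichever relaxes lower
    ctrV <- sweep(V, 2, colMeans(V))
    axes <- eigen(crossprod(ctrV) / n, symmetric = TRUE)$vectors[, 1:2]
    proj <- ctrV %*% axes
    pa <- abs(sum(area2d(proj, tr)))
    if (pa > 1e-9) proj <- proj * sqrt(totalArea3 / pa)
    opt2 <- optim(as.numeric(proj), energyFn, gradFn, method = "L-BFGS-B",
                  control = list(maxit = polishIter, factr = 1e4))
    if (opt2$value < opt$value) opt <- opt2
    p <- matrix(opt$par, n, 2)
  }
  signedA <- area2d(p, tr)
  orient <- sign(sum(signedA))
  flipped <- which(signedA * orient <= 0)
  rounds <- 0L
  W <- A / deg
  while (length(flipped) && rounds < flipRepairRounds) {
    rounds <- rounds + 1L
    bad <- unique(as.vector(tr[flipped, ]))
    sm <- as.matrix(W %*% p)
    p[bad, ] <- sm[bad, , drop = FALSE]
    opt <- optim(as.numeric(p), energyFn, gradFn, method = "L-BFGS-B",
                 control = list(maxit = 100L, factr = 1e7))
    p <- matrix(opt$par, n, 2)
    signedA <- area2d(p, tr)
    flipped <- which(signedA * orient <= 0)
  }
  ring3 <- vertexRingAreas(tr, area3, n)
  ring2 <- vertexRingAreas(tr, abs(signedA), n)
  distortion <- log(pmax(ring2, 1e-300) / pmax(ring3, 1e-300))
  # bounding-box extents along the principal axes (the flat map's in-plane
  # orientation is arbitrary)
  pc <- sweep(p, 2, colMeans(p))
  ev <- eigen(crossprod(pc) / n, symmetric = TRUE)$vectors
  pr <- pc %*% ev
  new("FlatMap", coords2d = p, triangles = tr, distortion = distortion,
      flippedCount = length(flipped),
      bbox = c(diff(range(pr[, 1])), diff(range(pr[, 2]))),
      converged = (is.null(opt) || opt$convergence == 0) &&
        length(flipped) == 0L,
      energy = energyFn(as.numeric(p)))
}

#' Areal distortion statistics of a flat map
#'
#' Per-vertex log ratio of flattened to original 1-ring area, summarized as
#' the median and 95th percentile of its absolute value plus the total-area
#' ratio.
#'
#' @param piece the source [TriangleMesh-class].
#' @param flat its [FlatMap-class].
#' @return list with `medianAbsLog`, `p95AbsLog`, `totalAreaRatio`, and the
#'   per-vertex `distortion` as a [VertexScalarMap-class].
#' @export
arealDistortion <- function(piece, flat) {
  if (!identical(dim(piece@triangles), dim(flat@triangles)))
    stop("piece and flat map disagree in triangle count")
  a3 <- triangleAreas(piece)
  a2 <- abs(area2d(flat@coords2d, flat@triangles))
  n <- nrow(piece@vertices)
  ring3 <- vertexRingAreas(piece@triangles, a3, n)
  ring2 <- vertexRingAreas(flat@triangles, a2, n)
  d <- log(pmax(ring2, 1e-300) / pmax(ring3, 1e-300))
  list(medianAbsLog = median(abs(d)),
       p95AbsLog = as.numeric(quantile(abs(d), 0.95)),
       totalAreaRatio = sum(a2) / sum(a3),
       distortion = VertexScalarMap(d))
}
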