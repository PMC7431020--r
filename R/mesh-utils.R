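#' Per-triangle areas
#'
#' Half the cross-product magnitude of two triangle edge vectors.
#'
#' @param mesh a [TriangleMesh-class].
#' @return numeric vector of triangle areas (mm^2).
#' @export
triangleAreas <- function(mesh) {
  v <- mesh@vertices; tr <- mesh@triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-triangle unit normals (right-hand rule)
#' @inheritParams triangleAreas
#' @return m x 3 matrix of unit normals.
#' @export
triangleNormals <- function(mesh) {
  v <- mesh@vertices; tr <- mesh@triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Area-weighted outward vertex normals
#' @inheritParams triangleAreas
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertexNormals <- function(mesh) {
  tr <- mesh@triangles
  fn <- triangleNormals(mesh) * triangleAreas(mesh)
  n <- matrix(0, nrow(mesh@vertices), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- rowsum(fn[, c], tr[, k], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      n[idx, c] <- n[idx, c] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Precomputed sparse operators for iterative mesh deformation: row-normalized
# adjacency W, triangle->vertex incidence Tinc, signed edge incidence Einc
# (vertex x edge: +1 at the first endpoint, -1 at the second), edge list and
# vertex degrees. Computing these once makes each deformation iteration a
# handful of sparse matvecs.
meshOperators <- function(mesh) {
  n <- nrow(mesh@vertices)
  m <- nrow(mesh@triangles)
  et <- meshEdgeTable(mesh)
  e <- et$edges
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  tr <- mesh@triangles
  Tinc <- Matrix::sparseMatrix(i = as.vector(tr), j = rep(seq_len(m), 3),
                               x = 1, dims = c(n, m))
  Einc <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]),
                               j = rep(seq_len(nrow(e)), 2),
                               x = rep(c(1, -1), each = nrow(e)),
                               dims = c(n, nrow(e)))
  list(W = A / deg, A = A, deg = deg, Tinc = Tinc, Einc = Einc, edges = e)
}

# area-weighted vertex normals from precomputed operators
fastVertexNormals <- function(V, tr, Tinc) {
  a <- V[tr[, 2], , drop = FALSE] - V[tr[, 1], , drop = FALSE]
  b <- V[tr[, 3], , drop = FALSE] - V[tr[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- as.matrix(Tinc %*% fn)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Unique undirected edges as a 2-column matrix (i < j), plus the per-edge
# triangle incidence count.
meshEdgeTable <- function(mesh) {
  tr <- mesh@triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  first <- !duplicated(key)
  edges <- cbind(pmin(e[first, 1], e[first, 2]), pmax(e[first, 1], e[first, 2]))
  counts <- as.integer(tab[key[first]])
  list(edges = edges, counts = counts)
}

#' Euler characteristic V - E + F
#' @inheritParams triangleAreas
#' @return integer.
#' @export
eulerCharacteristic <- function(mesh) {
  et <- meshEdgeTable(mesh)
  nrow(mesh@vertices) - nrow(et$edges) + nrow(mesh@triangles)
}

#' Closed-manifold and winding checks
#'
#' A mesh is a closed manifold when every edge is shared by exactly two
#' triangles; winding is consistent when the two triangles traverse their
#' shared edge in opposite directions.
#'
#' @inheritParams triangleAreas
#' @return list with logical `closed`, `consistentWinding`, and the number
#'   of boundary edges.
#' @export
manifoldStatus <- function(mesh) {
  tr <- mesh@triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  closed <- all(cnt == 2L)
  boundary <- sum(cnt == 1L)
  # directed-edge multiset: consistent winding <=> no directed edge repeats
  dkey <- paste(e[, 1], e[, 2])
  consistent <- !any(duplicated(dkey)) && all(cnt <= 2L)
  list(closed = closed, consistentWinding = consistent,
       boundaryEdges = as.integer(boundary))
}

#' Sparse vertex adjacency matrix
#' @inheritParams triangleAreas
#' @return symmetric sparse pattern matrix from \pkg{Matrix}.
#' @export
vertexAdjacency <- function(mesh) {
  et <- meshEdgeTable(mesh)
  n <- nrow(mesh@vertices)
  e <- et$edges
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}

#' Boundary loops of a mesh with boundary
#'
#' @inheritParams triangleAreas
#' @return list of integer vertex cycles (each loop closed, first != last).
#' @export
boundaryLoops <- function(mesh) {
  tr <- mesh@triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bdir <- e[cnt[key] == 1L, , drop = FALSE]  # directed boundary edges
  if (nrow(bdir) == 0L) return(list())
  # boundary edges are traversed once; follow successor map v -> next
  nxt <- new.env(hash = TRUE)
  for (i in seq_len(nrow(bdir)))
    assign(as.character(bdir[i, 2]), bdir[i, 1], envir = nxt)
  # note: directed boundary edge (a,b) of triangle winding means boundary
  # loop runs b -> a to keep the surface on its left
  seen <- new.env(hash = TRUE)
  loops <- list()
  for (i in seq_len(nrow(bdir))) {
    start <- bdir[i, 2]
    if (!is.null(seen[[as.character(start)]])) next
    loop <- integer(0)
    v <- start
    repeat {
      loop <- c(loop, v)
      assign(as.character(v), TRUE, envir = seen)
      v <- get(as.character(v), envir = nxt)
      if (v == start) break
      if (length(loop) > nrow(bdir)) stop("boundary is not a union of simple loops")
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Connected components of a mesh
#'
#' Splits a mesh into its triangle-connected pieces (shared-edge
#' connectivity), dropping unreferenced vertices.
#'
#' @inheritParams triangleAreas
#' @return list of lists: `mesh` ([TriangleMesh-class]) and `vertexMap`
#'   (original index of each piece vertex).
#' @export
meshComponents <- function(mesh) {
  n <- nrow(mesh@vertices)
  et <- meshEdgeTable(mesh)
  g <- igraph::graph_from_edgelist(et$edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  out <- list()
  for (cid in sort(unique(comp[mesh@triangles[, 1]]))) {
    keep <- comp[mesh@triangles[, 1]] == cid
    out[[length(out) + 1L]] <- extractSubmesh(mesh, which(keep))
  }
  out
}

# Extract a submesh from triangle indices; returns mesh + vertexMap.
extractSubmesh <- function(mesh, triIdx) {
  tr <- mesh@triangles[triIdx, , drop = FALSE]
  vid <- sort(unique(as.vector(tr)))
  remap <- integer(nrow(mesh@vertices))
  remap[vid] <- seq_along(vid)
  list(mesh = TriangleMesh(mesh@vertices[vid, , drop = FALSE],
                           matrix(remap[tr], ncol = 3)),
       vertexMap = vid)
}

#' Count of intersecting non-adjacent triangle pairs
#'
#' Exact triangle-triangle intersection test over candidate pairs found by
#' a uniform spatial hash; pairs sharing a vertex are skipped.
#'
#' @inheritParams triangleAreas
#' @return integer count (0 means the surface is free of self-intersections).
#' @export
selfIntersectionCount <- function(mesh) {
  cpp_self_intersections(mesh@vertices, mesh@triangles)
}
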