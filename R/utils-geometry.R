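# Small vector-geometry helpers shared across modules. All coordinates are in
# millimetres; 3D point sets are n x 3 matrices, 2D sets n x 2.

vec_norm <- function(v) sqrt(sum(v^2))

unitize <- function(v, tol = 1e-12) {
  n <- vec_norm(v)
  if (n < tol) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product for n x 3 matrices.
cross3_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

rad2deg <- function(x) x * 180 / pi
deg2rad <- function(x) x * pi / 180

as_point_matrix <- function(x, d) {
  if (is.null(dim(x))) {
    if (length(x) != d) stop(sprintf("expected a %d-vector or n x %d matrix", d, d),
                             call. = FALSE)
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != d) stop(sprintf("expected %d columns, got %d", d, ncol(x)), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# Areas of triangles given an n x 3 vertex matrix and an m x 3 index matrix.
triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  cc <- vertices[triangles[, 3L], , drop = FALSE]
  cr <- cross3_rows(b - a, cc - a)
  0.5 * sqrt(rowSums(cr^2))
}

triangle_centroids <- function(vertices, triangles) {
  (vertices[triangles[, 1L], , drop = FALSE] +
     vertices[triangles[, 2L], , drop = FALSE] +
     vertices[triangles[, 3L], , drop = FALSE]) / 3
}

# Connected components of a facet set under shared-edge adjacency.
# Returns an integer component label per facet (1-based, 1 = largest).
facet_components <- function(triangles) {
  nf <- nrow(triangles)
  if (nf == 0L) return(integer(0))
  edges <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)], triangles[, c(3L, 1L)])
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  key <- paste(edges[, 1L], edges[, 2L], sep = "-")
  face_of_edge <- rep.int(seq_len(nf), 3L)
  by_key <- split(face_of_edge, key)
  # union-find over facets sharing an edge
  parent <- seq_len(nf)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (faces in by_key) {
    if (length(faces) > 1L) {
      r <- find(faces[1L])
      for (f in faces[-1L]) {
        rf <- find(f)
        if (rf != r) parent[rf] <- r
      }
    }
  }
  roots <- vapply(seq_len(nf), find, integer(1))
  labels <- match(roots, unique(roots))
  sizes <- tabulate(labels)
  order_by_size <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes))
  relabel[order_by_size] <- seq_along(sizes)
  relabel[labels]
}

# Boundary edges (edges used by exactly one facet) of a triangle subset,
# chained into ordered polylines. Returns a list of integer vertex-index paths
# (closed loops repeat the first vertex at the end).
boundary_loops <- function(triangles) {
  if (nrow(triangles) == 0L) return(list())
  edges <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)], triangles[, c(3L, 1L)])
  ukey <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]), sep = "-")
  cnt <- table(ukey)
  boundary <- edges[cnt[ukey] == 1L, , drop = FALSE]
  if (nrow(boundary) == 0L) return(list())
  # adjacency: follow directed boundary edges head-to-tail
  nxt <- split(boundary[, 2L], boundary[, 1L])
  used <- rep(FALSE, nrow(boundary))
  starts <- boundary[, 1L]
  loops <- list()
  remaining <- boundary
  while (nrow(remaining) > 0L) {
    path <- c(remaining[1L, 1L], remaining[1L, 2L])
    remaining <- remaining[-1L, , drop = FALSE]
    repeat {
      k <- which(remaining[, 1L] == path[length(path)])
      if (length(k) == 0L) break
      k <- k[1L]
      path <- c(path, remaining[k, 2L])
      remaining <- remaining[-k, , drop = FALSE]
      if (path[length(path)] == path[1L]) break
    }
    loops[[length(loops) + 1L]] <- path
  }
  loops
}

# Closed-form eigenvalues of many symmetric 3x3 tensors, vectorized.
# `s` is an n x 6 matrix with columns (xx, yy, zz, xy, yz, zx).
# Returns an n x 3 matrix of eigenvalues sorted descending per row.
symmetric3_eigenvalues <- function(s) {
  s <- as_point_matrix(s, 6L)
  sxx <- s[, 1L]; syy <- s[, 2L]; szz <- s[, 3L]
  sxy <- s[, 4L]; syz <- s[, 5L]; szx <- s[, 6L]
  p1 <- sxy^2 + syz^2 + szx^2
  q <- (sxx + syy + szz) / 3
  p2 <- (sxx - q)^2 + (syy - q)^2 + (szz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  out <- matrix(0, nrow(s), 3L)
  near_diag <- p < 1e-300
  # determinant of (S - qI)/p via explicit cofactors
  bxx <- sxx - q; byy <- syy - q; bzz <- szz - q
  detb <- bxx * (byy * bzz - syz^2) -
    sxy * (sxy * bzz - syz * szx) +
    szx * (sxy * syz - byy * szx)
  r <- ifelse(near_diag, 0, detb / (2 * pmax(p, 1e-300)^3))
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  out[, 1L] <- e1; out[, 2L] <- e2; out[, 3L] <- e3
  out[near_diag, 1L] <- q[near_diag]
  out[near_diag, 2L] <- q[near_diag]
  out[near_diag, 3L] <- q[near_diag]
  # enforce descending order (guaranteed analytically, but guard roundoff)
  mx <- pmax(out[, 1L], out[, 2L], out[, 3L])
  mn <- pmin(out[, 1L], out[, 2L], out[, 3L])
  cbind(mx, out[, 1L] + out[, 2L] + out[, 3L] - mx - mn, mn, deparse.level = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
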