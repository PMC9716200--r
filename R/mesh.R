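#' Triangle surface mesh
#'
#' Minimal triangle-mesh container used throughout the package: an `n x 3`
#' matrix of vertex coordinates in millimetres and an `m x 3` integer matrix
#' of 1-based vertex indices per face.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns", call. = FALSE)
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates", call. = FALSE)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Area-weighted outward vertex normals.
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  # rowsum-based accumulation (vectorized, handles repeated indices)
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    acc <- rowsum(fn, f[, k])
    rows <- as.integer(rownames(acc))
    n[rows, ] <- n[rows, ] + acc
  }
  len <- row_norms(n)
  len[len < 1e-12] <- 1
  n / len
}

transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  triangle_mesh(sweep(mesh$vertices %*% t(R), 2, t, "+"), mesh$faces)
}

# Squared-distance matrix between two point sets (rows are points).
pairwise_dist2 <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  d2
}

# Rigid alignment (rotation + translation, no scaling) of X onto Y by
# minimizing ||R x_i + t - y_i||^2 (Kabsch).
kabsch <- function(X, Y) {
  xb <- colMeans(X); yb <- colMeans(Y)
  H <- t(sweep(X, 2, xb)) %*% sweep(Y, 2, yb)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(yb - R %*% xb))
}

# Minimal distances from points `p` (k x 3) to the surface of `mesh`
# (closest point on any triangle, not just vertices).
points_to_surface_dist <- function(p, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  E0 <- v[f[, 2], , drop = FALSE] - A
  E1 <- v[f[, 3], , drop = FALSE] - A
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); c <- rowSums(E1 * E1)
  det <- pmax(a * c - b * b, 1e-30)
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    D <- sweep(A, 2, p[i, ])
    d <- rowSums(E0 * D); e <- rowSums(E1 * D)
    s <- b * e - c * d
    t <- b * d - a * e
    # clamp barycentric solution to the triangle (Eberly-style, vectorized)
    s1 <- s / det; t1 <- t / det
    s1 <- pmin(pmax(s1, 0), 1)
    t1 <- pmin(pmax(t1, 0), 1)
    over <- s1 + t1 > 1
    if (any(over)) {
      sc <- s1[over]; tc <- t1[over]
      tot <- sc + tc
      s1[over] <- sc / tot
      t1[over] <- tc / tot
    }
    # refine: project onto the three edges and take the best candidate
    cand2 <- function(ss, tt) {
      q <- A + E0 * ss + E1 * tt
      rowSums(sweep(q, 2, p[i, ])^2)
    }
    # edge t = 0: minimize over s
    s_e0 <- pmin(pmax(-d / pmax(a, 1e-30), 0), 1)
    # edge s = 0: minimize over t
    t_e1 <- pmin(pmax(-e / pmax(c, 1e-30), 0), 1)
    # edge s + t = 1: parametrize s = u, t = 1 - u
    num <- (c + e) - (b + d)
    den <- pmax(a - 2 * b + c, 1e-30)
    u_e2 <- pmin(pmax(num / den, 0), 1)
    d2 <- pmin(cand2(s1, t1),
               pmin(cand2(s_e0, 0), pmin(cand2(0, t_e1), cand2(u_e2, 1 - u_e2))))
    out[i] <- sqrt(min(d2))
  }
  out
}

# Minimal vertex-to-surface gap between two meshes, restricted to vertex ids.
mesh_min_gap <- function(mesh_a, mesh_b, ids_a = NULL) {
  p <- mesh_a$vertices
  if (!is.null(ids_a)) p <- p[ids_a, , drop = FALSE]
  min(points_to_surface_dist(p, mesh_b))
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a mesh as ASCII STL
#'
#' @inheritParams write_mesh_ply
#' @export
write_mesh_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid kneewear", con)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    n <- tryCatch(unit_vector(crossprod3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])),
                  error = function(e) c(0, 0, 1))
    writeLines(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]), con)
    writeLines("    outer loop", con)
    writeLines(sprintf("      vertex %g %g %g", tri[, 1], tri[, 2], tri[, 3]), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid kneewear", con)
  invisible(path)
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}
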