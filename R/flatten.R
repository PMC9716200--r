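# Conformal-style flattening of the articular surface patch: a discrete
# harmonic map with cotangent weights and the single boundary loop pinned to
# the unit-square perimeter by arc length. With positive weights and a convex
# target domain the discrete harmonic map is injective; per-triangle
# quasi-conformal distortion is reported so test geometries can assert the
# absence of flipped triangles.

# Extract the sub-mesh of `mesh` spanned by vertex ids (faces fully inside).
submesh <- function(mesh, ids) {
  ids <- sort(unique(as.integer(ids)))
  keep <- rowSums(matrix(mesh$faces %in% ids, nrow(mesh$faces))) == 3L
  faces <- mesh$faces[keep, , drop = FALSE]
  remap <- integer(nrow(mesh$vertices))
  remap[ids] <- seq_along(ids)
  structure(list(vertices = mesh$vertices[ids, , drop = FALSE],
                 faces = matrix(remap[faces], ncol = 3),
                 orig_ids = ids),
            class = "triangle_mesh")
}

# Ordered single boundary loop of a patch; error on non-disk topology.
boundary_loop <- function(faces, nv) {
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(key)
  if (any(cnt > 2)) stop("non-manifold patch", call. = FALSE)
  bkey <- names(cnt)[cnt == 1]
  if (length(bkey) == 0) stop("topology error: patch has no boundary", call. = FALSE)
  bedges <- edges[key %in% bkey, , drop = FALSE]
  adj <- split(c(bedges[, 2], bedges[, 1]), c(bedges[, 1], bedges[, 2]))
  start <- bedges[1, 1]
  loop <- c(start)
  prev <- -1L
  cur <- start
  repeat {
    nxt <- setdiff(adj[[as.character(cur)]], prev)
    if (length(nxt) == 0) stop("topology error: open boundary", call. = FALSE)
    nxt <- nxt[1]
    if (nxt == start) break
    loop <- c(loop, nxt)
    prev <- cur; cur <- nxt
    if (length(loop) > 4L * nrow(bedges)) stop("topology error: boundary not a single loop",
                                               call. = FALSE)
  }
  if (length(loop) != nrow(bedges))
    stop("topology error: patch boundary is not a single loop", call. = FALSE)
  loop
}

cotangent_weights <- function(vertices, faces) {
  i <- integer(0); j <- integer(0); w <- numeric(0)
  for (c1 in 1:3) {
    c2 <- c1 %% 3 + 1; c3 <- c2 %% 3 + 1
    a <- vertices[faces[, c2], , drop = FALSE] - vertices[faces[, c1], , drop = FALSE]
    b <- vertices[faces[, c3], , drop = FALSE] - vertices[faces[, c1], , drop = FALSE]
    dotp <- rowSums(a * b)
    crs <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
    cr <- pmax(row_norms(crs), 1e-12)
    cot <- dotp / cr
    i <- c(i, faces[, c2], faces[, c3])
    j <- c(j, faces[, c3], faces[, c2])
    w <- c(w, 0.5 * cot, 0.5 * cot)
  }
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = rep(nrow(vertices), 2))
}

#' Flatten an articular surface patch to the unit square
#'
#' Discrete harmonic parameterization of a topological-disk patch with the
#' boundary loop mapped to the unit-square perimeter by arc length. Corners
#' are picked deterministically (the boundary vertex farthest from the
#' boundary centroid, then the quarter arc-length points). If `orient_axes`
#' is supplied, the chart is flipped/transposed so that `u` increases
#' medial -> lateral and `v` anterior -> posterior.
#'
#' @param patch a [triangle_mesh()] patch (single boundary loop), e.g. from
#'   the femoral articular ROI.
#' @param orient_axes optional list with unit 3-vectors `medial` and
#'   `anterior` fixing the chart orientation.
#' @return a `square_param`: list with `uv` (per-vertex coordinates in
#'   \[0,1\]^2), `boundary` (loop vertex ids), `n_flipped`, `max_qc` and
#'   `mean_qc` (quasi-conformal distortion ratios).
#' @export
conformal_flatten <- function(patch, orient_axes = NULL) {
  v <- patch$vertices; f <- patch$faces
  areas <- triangle_areas(v, f)
  if (any(areas < 1e-12))
    stop("mesh-quality error: degenerate triangles in patch", call. = FALSE)
  loop <- boundary_loop(f, nrow(v))
  bc <- colMeans(v[loop, , drop = FALSE])
  # first corner: boundary vertex farthest from the boundary centroid;
  # near-ties resolved by smallest vertex id so the choice is invariant to
  # rigid motion of the patch
  bd <- row_norms(sweep(v[loop, , drop = FALSE], 2, bc))
  ties <- which(bd > max(bd) - 1e-6 * max(bd))
  start <- min(loop[ties])
  s0 <- match(start, loop)
  loop <- c(loop[s0:length(loop)], loop[seq_len(s0 - 1L)])
  # cumulative arc length around the loop
  pts <- v[c(loop, loop[1]), , drop = FALSE]
  seglen <- row_norms(diff(pts))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  tfrac <- cum[seq_along(loop)] / total
  corner_idx <- vapply(c(0, 0.25, 0.5, 0.75), function(q) which.min(abs(tfrac - q)), 0L)
  if (length(unique(corner_idx)) < 4) stop("boundary too short for four corners", call. = FALSE)
  # piecewise arc-length map of the four boundary segments onto square sides
  corners_uv <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  buv <- matrix(0, length(loop), 2)
  for (side in 1:4) {
    i0 <- corner_idx[side]
    i1 <- if (side < 4) corner_idx[side + 1] else length(loop) + 1L
    seg <- i0:(i1 - 1L)
    t0 <- tfrac[i0]
    t1 <- if (side < 4) tfrac[corner_idx[side + 1]] else 1
    lam <- (tfrac[seg] - t0) / max(t1 - t0, 1e-12)
    a <- corners_uv[side, ]; b <- corners_uv[side %% 4 + 1, ]
    buv[seg, ] <- cbind(a[1] + lam * (b[1] - a[1]), a[2] + lam * (b[2] - a[2]))
  }
  W <- cotangent_weights(v, f)
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  interior <- setdiff(seq_len(nrow(v)), loop)
  uv <- matrix(0, nrow(v), 2)
  uv[loop, ] <- buv
  if (length(interior) > 0) {
    Lii <- L[interior, interior, drop = FALSE]
    Lib <- L[interior, loop, drop = FALSE]
    uv[interior, ] <- as.matrix(Matrix::solve(Lii, -Lib %*% buv))
  }
  uv <- orient_chart(uv, v, orient_axes)
  qc <- chart_distortion(v, f, uv)
  structure(list(uv = uv, boundary = loop, n_flipped = qc$n_flipped,
                 max_qc = qc$max_qc, mean_qc = qc$mean_qc),
            class = "square_param")
}

triangle_areas <- function(v, f) {
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  crs <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * row_norms(crs)
}

# Align the chart with anatomical axes: u medial -> lateral, v anterior ->
# posterior (flips and axis swap only; the square maps to itself).
orient_chart <- function(uv, v, orient_axes) {
  if (is.null(orient_axes)) return(uv)
  med <- as.numeric(v %*% orient_axes$medial)
  ant <- as.numeric(v %*% orient_axes$anterior)
  if (abs(stats::cor(uv[, 1], med)) < abs(stats::cor(uv[, 2], med)))
    uv <- uv[, 2:1]
  if (stats::cor(uv[, 1], med) > 0) uv[, 1] <- 1 - uv[, 1]
  if (stats::cor(uv[, 2], ant) > 0) uv[, 2] <- 1 - uv[, 2]
  uv
}

# Per-triangle singular values of the 3D -> uv Jacobian.
chart_distortion <- function(v, f, uv) {
  n_flipped <- 0L
  qc <- numeric(nrow(f))
  signs <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    q <- uv[f[i, ], , drop = FALSE]
    e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
    # local orthonormal 2D frame of the 3D triangle
    b1 <- unit_vector(e1)
    n <- crossprod3(e1, e2)
    b2 <- unit_vector(crossprod3(n, e1))
    P <- rbind(c(sum(e1 * b1), sum(e2 * b1)), c(0, sum(e2 * b2)))
    Q <- rbind(q[2, ] - q[1, ], q[3, ] - q[1, ])
    J <- t(Q) %*% solve(P)
    sv <- svd(J)$d
    qc[i] <- sv[1] / max(sv[2], 1e-12)
    signs[i] <- sign(det(J))
  }
  maj <- sign(sum(signs))
  if (maj == 0) maj <- 1
  list(n_flipped = sum(signs != maj), max_qc = max(qc), mean_qc = mean(qc))
}

#' Flatten the femoral articular region of a limb
#'
#' Extracts the femoral articular ROI patch of an `articulated_limb` and
#' parameterizes it onto the unit square with the anatomical orientation
#' convention (u medial -> lateral, v anterior -> posterior). Because all
#' limbs share the template correspondence, the chart computed on one limb
#' (or on the model mean) applies to the whole cohort.
#'
#' @param limb an `articulated_limb`.
#' @return list with `patch` (the ROI sub-mesh), `roi_ids` (femoral vertex
#'   ids of the patch) and `param` (the `square_param`).
#' @export
flatten_femoral_roi <- function(limb) {
  tpl <- limb$template
  patch <- submesh(limb$femur, tpl$femur_roi)
  par <- conformal_flatten(patch, orient_axes = list(medial = c(1, 0, 0),
                                                     anterior = c(0, 1, 0)))
  list(patch = patch, roi_ids = patch$orig_ids, param = par)
}
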