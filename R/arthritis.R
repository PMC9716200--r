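# Artificial arthritic degradation of healthy limbs: osteophyte-like outward
# outliers, compartment-wise cartilage erosion, joint-space narrowing and
# rigid coronal misalignment of the tibia. Every applied deformation is
# recorded exactly so it can be subtracted back out and so that twin
# reconstruction can be scored against ground truth.

# Marginal knee-region vertex ids (distal femur / proximal tibia) in
# per-bone indexing: the rings surrounding, but not inside, the articular
# cap — osteophytes form at the joint margins.
knee_region_ids <- function(tpl) {
  ring_ids <- function(j) 1L + (j - 1L) * tpl$n_theta + seq_len(tpl$n_theta)
  rings <- (tpl$n_phi - 5L):(tpl$n_phi - 2L)
  sort(unlist(lapply(rings, ring_ids)))
}

#' Random osteophyte-like outlier map
#'
#' Draws smooth outward bumps on a fraction of knee-region vertices of both
#' bones, to mimic marginal osteophytes. Magnitudes are in millimetres and the
#' maximum equals `magnitude_mm` by construction.
#'
#' @param limb an `articulated_limb`.
#' @param fraction fraction of knee-region vertices seeded with a bump.
#' @param magnitude_mm peak outward displacement (mm).
#' @param seed integer seed.
#' @return list with per-vertex magnitude vectors `femur` and `tibia`.
#' @export
osteophyte_map <- function(limb, fraction = 0.05, magnitude_mm = 3, seed = 1) {
  tpl <- limb$template
  ids <- knee_region_ids(tpl)
  with_seed(seed, {
    mk <- function(mesh) {
      m <- numeric(nrow(mesh$vertices))
      n_seed <- max(1L, round(fraction * length(ids)))
      centers <- sample(ids, n_seed)
      d2 <- pairwise_dist2(mesh$vertices, mesh$vertices[centers, , drop = FALSE])
      sigma <- 0.02 * max(row_norms(sweep(mesh$vertices, 2, colMeans(mesh$vertices))))
      bump <- exp(-d2 / (2 * sigma^2))
      m <- apply(bump, 1, max)
      m[m < 0.05] <- 0
      m * magnitude_mm / max(m)
    }
    list(femur = mk(limb$femur), tibia = mk(limb$tibia))
  })
}

#' Impose arthritic deformation on a healthy limb
#'
#' Applies, in order: outward osteophyte offsets along vertex normals,
#' inward articular erosion offsets, joint-space narrowing (tibia translated
#' towards the femur along the mechanical axis) and an additional rigid varus
#' rotation of the tibia about the knee centre. The returned record contains
#' the exact per-vertex displacements and rigid motion; applying
#' [revert_arthritis()] reproduces the input to machine precision.
#'
#' @param limb healthy `articulated_limb`.
#' @param outlier_map list with non-negative per-vertex magnitudes `femur`
#'   and/or `tibia` (mm), e.g. from [osteophyte_map()]; `NULL` for none.
#' @param narrowing_mm scalar joint-space narrowing (mm, >= 0). An error is
#'   raised if it exceeds the remaining joint gap (non-physical
#'   interpenetration).
#' @param extra_varus_deg additional rigid coronal misalignment of the tibia
#'   (degrees; positive = more varus).
#' @param seed integer seed (reserved for stochastic maps supplied as
#'   functions; deterministic inputs ignore it).
#' @return list with elements `limb` (deformed `articulated_limb`) and
#'   `record` (ground-truth deformation record).
#' @export
impose_arthritis <- function(limb, outlier_map = NULL, narrowing_mm = 0,
                             extra_varus_deg = 0, seed = 1) {
  stopifnot(inherits(limb, "articulated_limb"))
  if (narrowing_mm < 0) stop("`narrowing_mm` must be >= 0", call. = FALSE)
  tpl <- limb$template
  check_map <- function(map, what) {
    if (is.null(map)) return(list(femur = NULL, tibia = NULL))
    for (b in names(map)) {
      if (!is.null(map[[b]])) {
        if (length(map[[b]]) != tpl$nv)
          stop(what, " length must match vertex count", call. = FALSE)
        if (any(map[[b]] < 0)) stop(what, " magnitudes must be >= 0", call. = FALSE)
      }
    }
    map
  }
  outlier_map <- check_map(outlier_map, "outlier_map")

  femur <- limb$femur; tibia <- limb$tibia
  add_offsets <- function(mesh, mags) {
    if (is.null(mags)) return(matrix(0, tpl$nv, 3))
    vertex_normals(mesh) * mags
  }
  disp_f <- add_offsets(femur, outlier_map$femur)
  femur$vertices <- femur$vertices + disp_f
  disp_t <- add_offsets(tibia, outlier_map$tibia)
  tibia$vertices <- tibia$vertices + disp_t

  # narrowing: translate the tibia along the knee->hip mechanical direction
  narrow_vec <- c(0, 0, 0)
  if (narrowing_mm > 0) {
    lm <- landmarks_from_meshes(femur, tibia, tpl)
    gap <- mesh_min_gap(femur, tibia, ids_a = tpl$femur_roi)
    if (narrowing_mm > gap)
      stop(sprintf(
        "narrowing of %.2f mm exceeds the remaining joint gap (%.2f mm): non-physical interpenetration",
        narrowing_mm, gap), call. = FALSE)
    narrow_vec <- unit_vector(lm$hip - lm$knee) * narrowing_mm
    tibia$vertices <- sweep(tibia$vertices, 2, narrow_vec, "+")
  }

  # rigid coronal misalignment of the tibia about the knee centre
  rot <- diag(3); rot_center <- c(0, 0, 0)
  if (abs(extra_varus_deg) > 1e-12) {
    lm <- landmarks_from_meshes(femur, tibia, tpl)
    rot_center <- lm$knee
    u <- lm$hip - lm$knee
    m <- lm$knee_medial - lm$knee
    axis <- crossprod3(u, m)
    if (vnorm(axis) < 1e-9) axis <- c(0, 1, 0)
    hka0 <- hka_from_landmarks(lm)
    apply_rot <- function(angle) {
      R <- rotation_matrix(axis, angle)
      tv <- sweep(sweep(tibia$vertices, 2, rot_center) %*% t(R), 2, rot_center, "+")
      tb <- tibia; tb$vertices <- tv
      list(R = R, tibia = tb,
           hka = hka_from_landmarks(landmarks_from_meshes(femur, tb, tpl)))
    }
    # orient the rotation so that positive extra varus increases HKA
    probe <- apply_rot(1)
    dir <- if (probe$hka >= hka0) 1 else -1
    ang <- stats::uniroot(function(a) apply_rot(dir * a)$hka - (hka0 + extra_varus_deg),
                          c(-45, 45), tol = 1e-10)$root
    res <- apply_rot(dir * ang)
    rot <- res$R
    tibia <- res$tibia
  }

  out <- new_articulated_limb(femur, tibia, tpl, params = limb$params,
                              gap_mm = limb$gap_mm)
  record <- list(femur_offset = disp_f, tibia_offset = disp_t,
                 narrow_vec = narrow_vec, narrowing_mm = narrowing_mm,
                 rot = rot, rot_center = rot_center,
                 extra_varus_deg = extra_varus_deg)
  list(limb = out, record = record)
}

#' Undo a recorded arthritic deformation
#'
#' Inverse of [impose_arthritis()]: applying the record of a deformation to
#' its output reproduces the input limb to machine precision.
#'
#' @param limb deformed `articulated_limb`.
#' @param record deformation record returned by [impose_arthritis()].
#' @return the restored `articulated_limb`.
#' @export
revert_arthritis <- function(limb, record) {
  tpl <- limb$template
  femur <- limb$femur; tibia <- limb$tibia
  tv <- sweep(sweep(tibia$vertices, 2, record$rot_center) %*% record$rot,
              2, record$rot_center, "+")
  tv <- sweep(tv, 2, record$narrow_vec)
  tibia$vertices <- tv - record$tibia_offset
  femur$vertices <- femur$vertices - record$femur_offset
  new_articulated_limb(femur, tibia, tpl, params = limb$params, gap_mm = limb$gap_mm)
}
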