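#' Femorotibial joint-space-width distance map
#'
#' Computes, for each femoral articular ROI vertex, the minimal Euclidean
#' distance to the tibial surface (closest point on any tibial triangle).
#' Both meshes must be posed in the same frame. Distances are deterministic
#' and non-negative; a warning is emitted if surfaces touch or interpenetrate
#' (distance numerically zero).
#'
#' @param femur,tibia [triangle_mesh()] objects in a common frame.
#' @param roi integer vertex ids into the femoral mesh defining the articular
#'   region of interest.
#' @return a `distance_map`: list with `roi_vertex_ids` and `jsw_mm`.
#' @export
compute_jsw <- function(femur, tibia, roi) {
  stopifnot(inherits(femur, "triangle_mesh"), inherits(tibia, "triangle_mesh"))
  roi <- as.integer(roi)
  if (length(roi) == 0) stop("ROI must be non-empty", call. = FALSE)
  if (min(roi) < 1 || max(roi) > nrow(femur$vertices))
    stop("ROI vertex ids out of range", call. = FALSE)
  d <- points_to_surface_dist(femur$vertices[roi, , drop = FALSE], tibia)
  if (any(d < 1e-9)) {
    warning("surfaces touch or interpenetrate; distances clamped at 0")
    d[d < 0] <- 0
  }
  structure(list(roi_vertex_ids = roi, jsw_mm = d), class = "distance_map")
}

#' Normalize and invert a joint-space distance map
#'
#' Maps joint-space width to a wear value via `w = clamp(1 - jsw / ref, 0, 1)`
#' against a fixed cohort-level reference width, so that 1 corresponds to
#' complete cartilage erosion (0 mm joint space) and 0 to a fully preserved
#' joint space of `reference_mm` or more.
#'
#' @param dmap a `distance_map` from [compute_jsw()], or a numeric vector of
#'   joint-space widths in mm.
#' @param reference_mm cohort-level reference joint-space width (> 0).
#' @return numeric vector of normalized, inverted wear values in \[0, 1\].
#' @export
normalize_invert <- function(dmap, reference_mm = 8) {
  if (reference_mm <= 0) stop("`reference_mm` must be > 0", call. = FALSE)
  jsw <- if (inherits(dmap, "distance_map")) dmap$jsw_mm else as.numeric(dmap)
  if (any(jsw < 0)) stop("negative joint-space width violates the distance-map invariant",
                         call. = FALSE)
  clip01(1 - jsw / reference_mm)
}
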