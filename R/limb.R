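#' Limb geometry parameters
#'
#' Parameter set controlling a synthetic lower limb. The hip-knee-ankle (HKA)
#' angle follows the radiographic convention: 180 deg is neutral, values at or
#' below 177 deg are valgus, values at or above 183 deg are varus. Native
#' coronal alignment is encoded *intrinsically* (a metaphyseal bend of femur
#' and tibia, i.e. joint-line obliquity), so that alignment survives per-bone
#' rigid registration and remains recoverable from bone shape alone.
#'
#' @param hka_deg hip-knee-ankle angle in degrees; must lie in \[160, 200\].
#' @param femoral_torsion_deg axial twist of the femur (degrees).
#' @param tibial_torsion_deg axial twist of the tibia (degrees).
#' @param tibial_slope_deg posterior inclination of the tibial plateau (degrees).
#' @param femoral_bowing_deg coronal bowing of the femoral shaft (degrees).
#' @param scale_mm overall limb length in millimetres (> 0).
#' @return an object of class `limb_params`.
#' @export
limb_params <- function(hka_deg = 180, femoral_torsion_deg = 0,
                        tibial_torsion_deg = 0, tibial_slope_deg = 0,
                        femoral_bowing_deg = 0, scale_mm = 800) {
  p <- list(hka_deg = hka_deg, femoral_torsion_deg = femoral_torsion_deg,
            tibial_torsion_deg = tibial_torsion_deg,
            tibial_slope_deg = tibial_slope_deg,
            femoral_bowing_deg = femoral_bowing_deg, scale_mm = scale_mm)
  bad <- !vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), TRUE)
  if (any(bad))
    stop("non-finite or non-scalar limb parameter(s): ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  if (p$scale_mm <= 0) stop("`scale_mm` must be > 0", call. = FALSE)
  if (p$hka_deg < 160 || p$hka_deg > 200)
    stop("`hka_deg` must lie in [160, 200]", call. = FALSE)
  structure(p, class = "limb_params")
}

# ---- template topology ------------------------------------------------------

# Pole-capped theta x phi grid; vertex 1 = far pole, last vertex = knee pole.
bone_grid <- function(n_theta, n_phi) {
  nv <- n_theta * n_phi + 2L
  ring <- function(j, i) 1L + (j - 1L) * n_theta + i
  faces <- matrix(0L, 0, 3)
  i2 <- c(2:n_theta, 1L)
  # far-pole fan (wound consistently with the quad strips)
  faces <- rbind(faces, cbind(1L, ring(1L, i2), ring(1L, seq_len(n_theta))))
  for (j in seq_len(n_phi - 1L)) {
    a <- ring(j, seq_len(n_theta)); b <- ring(j, i2)
    c_ <- ring(j + 1L, i2); d <- ring(j + 1L, seq_len(n_theta))
    faces <- rbind(faces, cbind(a, b, c_), cbind(a, c_, d))
  }
  faces <- rbind(faces, cbind(nv, ring(n_phi, seq_len(n_theta)), ring(n_phi, i2)))
  faces <- faces[, c(1L, 3L, 2L)] # outward orientation
  list(nv = nv, faces = faces, n_theta = n_theta, n_phi = n_phi)
}

# Template bookkeeping shared by every generated limb: vertex ids of caps,
# landmarks and the femoral articular ROI, all in per-bone local indexing.
limb_template <- function(resolution) {
  if (resolution < 200) stop("`resolution` must be at least 200 vertices per bone",
                             call. = FALSE)
  n_phi <- max(8L, as.integer(ceiling(sqrt(resolution - 2))))
  n_theta <- max(8L, as.integer(ceiling((resolution - 2) / n_phi)))
  g <- bone_grid(n_theta, n_phi)
  ring_ids <- function(j) 1L + (j - 1L) * n_theta + seq_len(n_theta)
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  far_cap <- c(1L, ring_ids(1L))
  knee_cap <- c(g$nv, ring_ids(n_phi))
  # medial (+x) vertices of the two distal-most femoral rings: sign reference
  med <- which(cos(theta) > 0.5)
  medial_ids <- c(ring_ids(n_phi)[med], ring_ids(n_phi - 1L)[med])
  # femoral articular region: the flattened distal cap facing the tibia
  n_roi_rings <- 2L
  roi <- c(g$nv, unlist(lapply((n_phi - n_roi_rings + 1L):n_phi, ring_ids)))
  list(n_theta = n_theta, n_phi = n_phi, nv = g$nv, faces = g$faces,
       theta = theta, far_cap = far_cap, knee_cap = knee_cap,
       medial_ids = medial_ids, femur_roi = roi)
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Smooth pseudo-random surface offset field (sum of cosine waves of the
# template coordinates); deterministic in `seed`.
smooth_noise_field <- function(base_xyz, amplitude, seed) {
  if (amplitude <= 0) return(numeric(nrow(base_xyz)))
  with_seed(seed, {
    k <- 6L
    dirs <- matrix(stats::rnorm(3 * k), k, 3)
    dirs <- dirs / row_norms(dirs)
    freq <- stats::runif(k, 0.5, 2.0)
    phase <- stats::runif(k, 0, 2 * pi)
    amp <- stats::rnorm(k)
    scale <- max(row_norms(sweep(base_xyz, 2, colMeans(base_xyz))))
    z <- base_xyz %*% t(dirs) / scale
    f <- sweep(cos(sweep(z, 2, freq, "*") * pi + matrix(phase, nrow(base_xyz), k, byrow = TRUE)),
               2, amp, "*")
    amplitude * rowSums(f) / sqrt(k)
  })
}

# Solve the metaphyseal bend angle (radians) that places the far landmark at
# `target_deg` from the mechanical (z) axis, as seen from the knee center.
solve_bend <- function(target_deg, L, hinge, gap_half) {
  f <- function(alpha) {
    x <- (L - hinge) * sin(alpha)
    z <- gap_half + hinge + (L - hinge) * cos(alpha)
    atan2(x, z) * 180 / pi - target_deg
  }
  if (abs(target_deg) < 1e-12) return(0)
  stats::uniroot(f, c(-0.6, 0.6), tol = 1e-12)$root
}

generate_bone <- function(type = c("femur", "tibia"), params, tpl, gap_mm,
                          seed, shape_noise_mm) {
  type <- match.arg(type)
  n_theta <- tpl$n_theta; n_phi <- tpl$n_phi
  theta <- rep(tpl$theta, times = n_phi)
  phi <- rep(pi * seq_len(n_phi) / (n_phi + 1), each = n_theta)
  # s: 1 at the far end (hip / ankle), 0 at the knee end
  s_ring <- (1 + cos(phi)) / 2
  s <- c(1, s_ring, 0)
  th <- c(0, theta, 0)
  sphi <- c(0, sin(phi), 0)

  L <- if (type == "femur") 0.45 * params$scale_mm else 0.42 * params$scale_mm
  if (type == "femur") {
    r0 <- 0.085 * L
    prof <- 1 - 0.45 * sin(pi * s)^1.5
    condyle <- 1 + 0.45 * exp(-(s / 0.12)^2) * (0.6 + 0.4 * cos(2 * th))
    head <- 1 + 0.25 * exp(-((1 - s) / 0.10)^2)
  } else {
    r0 <- 0.075 * L
    prof <- 1 - 0.40 * sin(pi * s)^1.5
    # broad, nearly circular plateau so the femoral articular cap projects
    # onto plateau interior across the joint gap
    condyle <- 1 + 0.85 * exp(-(s / 0.14)^2) * (0.85 + 0.15 * cos(2 * th))
    head <- 1 + 0.10 * exp(-((1 - s) / 0.10)^2)
  }
  rad <- sphi * r0 * prof * condyle * head
  zdir <- if (type == "femur") 1 else -1
  # flatten the joint-facing cap (condylar surface / tibial plateau) so the
  # articular region directly opposes the other bone across the joint gap
  zflat <- if (type == "femur") s * (1 - 0.8 * exp(-(s / 0.08)^2)) else
    s * (1 - 0.88 * exp(-(s / 0.11)^2))
  v <- cbind(rad * cos(th), rad * sin(th), zdir * L * zflat)

  # 1) axial torsion: twist increases towards the far end
  tor <- if (type == "femur") params$femoral_torsion_deg else params$tibial_torsion_deg
  if (abs(tor) > 1e-12) {
    ang <- tor * pi / 180 * s
    x <- v[, 1] * cos(ang) - v[, 2] * sin(ang)
    y <- v[, 1] * sin(ang) + v[, 2] * cos(ang)
    v[, 1] <- x; v[, 2] <- y
  }
  # 2) tibial slope: tilt the plateau about its own centroid (medio-lateral axis)
  if (type == "tibia" && abs(params$tibial_slope_deg) > 1e-12) {
    w <- smoothstep((0.22 - s) / 0.14)
    cap <- c(tpl$nv, 1L + (n_phi - 1L) * n_theta + seq_len(n_theta))
    ctr <- colMeans(v[cap, , drop = FALSE])
    R <- rotation_matrix(c(1, 0, 0), params$tibial_slope_deg)
    vc <- sweep(v, 2, ctr)
    vr <- vc %*% t(R)
    v <- sweep(vc * (1 - w) + vr * w, 2, ctr, "+")
  }
  # 3) femoral coronal bowing: mid-shaft arc, endpoints fixed
  if (type == "femur" && abs(params$femoral_bowing_deg) > 1e-12) {
    A <- L * tan(params$femoral_bowing_deg * pi / 180) / pi
    v[, 1] <- v[, 1] + A * sin(pi * s)
  }
  # 4) intrinsic coronal angulation carrying half the HKA deviation per bone
  dev <- params$hka_deg - 180
  hinge <- 0.35 * L
  alpha <- solve_bend(dev / 2, L, hinge, gap_mm / 2)
  if (abs(alpha) > 0) {
    w <- smoothstep((s - 0.35) / 0.5)
    if (type == "femur") {
      ca <- cos(alpha * w); sa <- sin(alpha * w)
      dz <- v[, 3] - hinge
      x <- v[, 1] * ca + dz * sa
      z <- -v[, 1] * sa + dz * ca + hinge
      v[, 1] <- x; v[, 3] <- z
    } else {
      # mirror-symmetric bend towards +x for the downward axis
      ca <- cos(alpha * w); sa <- sin(alpha * w)
      dz <- v[, 3] + hinge
      x <- v[, 1] * ca - dz * sa
      z <- v[, 1] * sa + dz * ca - hinge
      v[, 1] <- x; v[, 3] <- z
    }
  }
  # 5) smooth individual shape noise along the surface normal direction
  if (shape_noise_mm > 0) {
    mesh0 <- triangle_mesh(v, tpl$faces)
    nrm <- vertex_normals(mesh0)
    off <- smooth_noise_field(v, shape_noise_mm, seed)
    v <- v + nrm * off
  }
  v[, 3] <- v[, 3] + zdir * gap_mm / 2
  triangle_mesh(v, tpl$faces)
}

landmarks_from_meshes <- function(femur, tibia, tpl) {
  list(hip = colMeans(femur$vertices[tpl$far_cap, , drop = FALSE]),
       ankle = colMeans(tibia$vertices[tpl$far_cap, , drop = FALSE]),
       knee = colMeans(rbind(femur$vertices[tpl$knee_cap, , drop = FALSE],
                             tibia$vertices[tpl$knee_cap, , drop = FALSE])),
       knee_medial = colMeans(femur$vertices[tpl$medial_ids, , drop = FALSE]))
}

new_articulated_limb <- function(femur, tibia, tpl, params = NULL, gap_mm = NA_real_) {
  structure(list(femur = femur, tibia = tibia,
                 landmarks = landmarks_from_meshes(femur, tibia, tpl),
                 template = tpl, params = params, gap_mm = gap_mm),
            class = "articulated_limb")
}

#' Generate a synthetic articulated lower limb
#'
#' Builds corresponded femur and tibia surface meshes (identical vertex count
#' and ordering for every limb generated at the same `resolution`) from a
#' parametric condyle-bearing bone template, together with hip, knee and ankle
#' centre landmarks. The measured HKA angle of the output matches
#' `params$hka_deg` to within 0.1 degrees.
#'
#' @param params a [limb_params()] object.
#' @param resolution target vertex count per bone (>= 200).
#' @param seed integer seed driving the individual smooth shape noise.
#' @param shape_noise_mm amplitude (mm) of smooth per-limb shape variation.
#' @param joint_gap_mm femorotibial joint gap of the healthy limb (mm).
#' @return an `articulated_limb`: femur and tibia [triangle_mesh()] objects,
#'   landmark list (`hip`, `knee`, `ankle`, `knee_medial`), template metadata
#'   and the generating parameters.
#' @export
generate_limb <- function(params, resolution = 240, seed = 1,
                          shape_noise_mm = 0.3, joint_gap_mm = 6) {
  if (!inherits(params, "limb_params")) params <- do.call(limb_params, as.list(params))
  tpl <- limb_template(resolution)
  femur <- generate_bone("femur", params, tpl, joint_gap_mm,
                         derive_seed(seed, 1), shape_noise_mm)
  tibia <- generate_bone("tibia", params, tpl, joint_gap_mm,
                         derive_seed(seed, 2), shape_noise_mm)
  new_articulated_limb(femur, tibia, tpl, params, joint_gap_mm)
}

#' @export
print.articulated_limb <- function(x, ...) {
  cat(sprintf("articulated_limb: %d + %d vertices, HKA %.2f deg\n",
              nrow(x$femur$vertices), nrow(x$tibia$vertices),
              hka_from_landmarks(x$landmarks)))
  invisible(x)
}

# ---- alignment measurement --------------------------------------------------

hka_from_landmarks <- function(lm) {
  u <- lm$hip - lm$knee
  v <- lm$ankle - lm$knee
  if (vnorm(u) < 1e-9 || vnorm(v) < 1e-9)
    stop("coincident landmarks: HKA undefined", call. = FALSE)
  gamma <- angle_deg(u, v)
  dev <- 180 - gamma
  b <- u / vnorm(u) + v / vnorm(v)
  if (vnorm(b) < 1e-9) return(180)
  m <- lm$knee_medial - lm$knee
  side <- sign(sum(b * m))
  if (side == 0) side <- 1
  180 + side * dev
}

#' Classify coronal alignment from the HKA angle
#'
#' Varus if HKA >= 183 deg, valgus if HKA <= 177 deg, neutral otherwise
#' (boundaries inclusive).
#'
#' @param hka_deg hip-knee-ankle angle in degrees.
#' @return `"varus"`, `"neutral"` or `"valgus"`.
#' @export
classify_alignment <- function(hka_deg) {
  ifelse(hka_deg >= 183, "varus", ifelse(hka_deg <= 177, "valgus", "neutral"))
}

#' Measure the coronal alignment profile of a limb
#'
#' The HKA angle is the angle subtended at the knee centre by the rays towards
#' the hip and ankle centres, signed by the side (medial reference landmark)
#' on which the mechanical axis passes. The measurement depends only on
#' relative landmark positions and is therefore invariant to rigid motion of
#' the whole limb.
#'
#' @param limb an `articulated_limb` (landmarks present).
#' @return an `alignment_profile` with `hka_deg`, `varus_valgus_class` and,
#'   where the generating parameters are known, torsion/slope/bowing values.
#' @export
measure_alignment <- function(limb) {
  lm <- limb$landmarks
  hka <- hka_from_landmarks(lm)
  p <- limb$params
  structure(list(hka_deg = hka,
                 femoral_torsion_deg = p$femoral_torsion_deg %||% NA_real_,
                 tibial_torsion_deg = p$tibial_torsion_deg %||% NA_real_,
                 tibial_slope_deg = p$tibial_slope_deg %||% NA_real_,
                 bowing_deg = p$femoral_bowing_deg %||% NA_real_,
                 varus_valgus_class = classify_alignment(hka)),
            class = "alignment_profile")
}

#' @export
print.alignment_profile <- function(x, ...) {
  cat(sprintf("HKA %.2f deg (%s)\n", x$hka_deg, x$varus_valgus_class))
  invisible(x)
}
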