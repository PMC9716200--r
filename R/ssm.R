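# Statistical shape modelling of corresponded limb meshes: generalized
# Procrustes alignment (translation + rotation, no scaling, keeping
# millimetres interpretable) followed by eigen-decomposition of the
# vertex-coordinate covariance.

limb_stack <- function(limb) rbind(limb$femur$vertices, limb$tibia$vertices)

# Generalized Procrustes alignment of a list of V x 3 point sets.
gpa_align <- function(shapes, max_iter = 5) {
  shapes <- lapply(shapes, function(s) sweep(s, 2, colMeans(s)))
  ref <- shapes[[1]]
  for (it in seq_len(max_iter)) {
    shapes <- lapply(shapes, function(s) {
      k <- kabsch(s, ref)
      sweep(s %*% t(k$R), 2, k$t, "+")
    })
    new_ref <- Reduce(`+`, shapes) / length(shapes)
    if (max(abs(new_ref - ref)) < 1e-10) { ref <- new_ref; break }
    ref <- new_ref
  }
  list(shapes = shapes, mean = ref)
}

#' Build a statistical shape model
#'
#' Aligns corresponded training limbs by generalized Procrustes analysis
#' (translation and rotation only) and extracts orthonormal variation modes
#' from the singular value decomposition of the centred coordinate matrix.
#' Per-bone models (`part = "femur"` / `"tibia"`) are built in the *same*
#' whole-limb alignment frame as the articulated model and share its
#' `frame_id`, which makes twin reassembly a plain orthonormal projection.
#'
#' @param limbs list of `articulated_limb` objects with identical templates,
#'   or a list of corresponded `V x 3` vertex matrices.
#' @param variance_kept fraction of total variance the retained modes must
#'   explain (modes with numerically zero variance are always dropped).
#' @param part `"articulated"` (femur + tibia jointly), `"femur"` or `"tibia"`.
#' @return a `shape_model` with fields `mean` (V x 3), `modes` (3V x k,
#'   orthonormal columns), `variances` (descending, mm^2), `n_training`,
#'   `template`, `part` and `frame_id`.
#' @export
build_ssm <- function(limbs, variance_kept = 0.98, part = c("articulated", "femur", "tibia")) {
  part <- match.arg(part)
  if (length(limbs) < 3) stop("need at least 3 training shapes", call. = FALSE)
  is_limb <- inherits(limbs[[1]], "articulated_limb")
  if (is_limb) {
    tpl <- limbs[[1]]$template
    mats <- lapply(limbs, limb_stack)
  } else {
    tpl <- NULL
    mats <- lapply(limbs, as.matrix)
  }
  nv <- vapply(mats, nrow, 0L)
  if (length(unique(nv)) != 1L)
    stop("correspondence error: training shapes have mismatched vertex counts",
         call. = FALSE)
  g <- gpa_align(mats)
  frame_id <- config_hash(round(g$mean, 6))
  vf <- if (is_limb) tpl$nv else nrow(g$mean)
  rows <- switch(part,
                 articulated = seq_len(nrow(g$mean)),
                 femur = seq_len(vf),
                 tibia = vf + seq_len(nrow(g$mean) - vf))
  if (!is_limb && part != "articulated")
    stop("per-bone parts require articulated_limb training input", call. = FALSE)
  sub <- lapply(g$shapes, function(s) s[rows, , drop = FALSE])
  X <- do.call(rbind, lapply(sub, as.vector))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  n <- length(sub)
  vars <- sv$d^2 / (n - 1)
  keep <- vars > pmax(1e-9 * sum(vars), 1e-12)
  vars <- vars[keep]
  modes <- sv$v[, keep, drop = FALSE]
  if (variance_kept < 1) {
    cum <- cumsum(vars) / sum(vars)
    k <- max(1L, which(cum >= variance_kept)[1])
    if (is.na(k)) k <- length(vars)
    vars <- vars[seq_len(k)]
    modes <- modes[, seq_len(k), drop = FALSE]
  }
  structure(list(mean = matrix(mu, ncol = 3), modes = modes, variances = vars,
                 n_training = n, template = tpl, part = part,
                 frame_id = frame_id, n_vertices = length(rows),
                 vf = if (is_limb) tpl$nv else NA_integer_),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model (%s): %d vertices, %d modes from %d training shapes\n",
              x$part, x$n_vertices, length(x$variances), x$n_training))
  invisible(x)
}

# Shape instance (V x 3) for a coefficient vector.
model_instance <- function(model, coef = NULL) {
  v <- as.vector(model$mean)
  if (!is.null(coef) && length(coef) > 0)
    v <- v + as.vector(model$modes[, seq_along(coef), drop = FALSE] %*% coef)
  matrix(v, ncol = 3)
}

#' Sample shape coefficients from a model
#'
#' Draws mode loadings from independent normals with the model's per-mode
#' variances, truncated at `sd_trunc` standard deviations.
#'
#' @param model a `shape_model`.
#' @param n number of samples.
#' @param seed integer seed.
#' @param sd_trunc truncation in per-mode standard deviations.
#' @return an `n x k` coefficient matrix.
#' @export
sample_shape_coefficients <- function(model, n, seed = 1, sd_trunc = 2.5) {
  k <- length(model$variances)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * k), n, k)
    z[z > sd_trunc] <- sd_trunc; z[z < -sd_trunc] <- -sd_trunc
    sweep(z, 2, sqrt(model$variances), "*")
  })
}

#' Reconstruct an articulated limb from model coefficients
#'
#' @param model articulated `shape_model` built from `articulated_limb`s.
#' @param coef coefficient vector (length <= number of modes).
#' @return an `articulated_limb` with landmarks recomputed from the template.
#' @export
limb_from_coefficients <- function(model, coef) {
  if (model$part != "articulated" || is.null(model$template))
    stop("an articulated shape_model with template metadata is required", call. = FALSE)
  inst <- model_instance(model, coef)
  tpl <- model$template
  femur <- triangle_mesh(inst[seq_len(tpl$nv), , drop = FALSE], tpl$faces)
  tibia <- triangle_mesh(inst[tpl$nv + seq_len(tpl$nv), , drop = FALSE], tpl$faces)
  new_articulated_limb(femur, tibia, tpl, params = NULL, gap_mm = NA_real_)
}

#' Build articulated and per-bone models in one shared frame
#'
#' @inheritParams build_ssm
#' @return list with `articulated`, `femur`, `tibia` shape models sharing one
#'   GPA frame.
#' @export
build_limb_models <- function(limbs, variance_kept = 0.98) {
  list(articulated = build_ssm(limbs, variance_kept, "articulated"),
       femur = build_ssm(limbs, variance_kept, "femur"),
       tibia = build_ssm(limbs, variance_kept, "tibia"))
}

#' Mahalanobis normalization of shape loadings
#'
#' Divides each mode loading by the model's per-mode standard deviation so
#' that features are unit-variance under the model and dominant unrelated
#' variance (such as size) no longer dominates distances.
#'
#' @param scores `n x k` matrix of per-case mode loadings.
#' @param model the `shape_model` the loadings refer to.
#' @return matrix of normalized scores.
#' @export
mahalanobis_normalize <- function(scores, model) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k > length(model$variances)) stop("more score columns than model modes", call. = FALSE)
  v <- model$variances[seq_len(k)]
  if (any(v <= 0)) stop("zero-variance mode requested in Mahalanobis normalization",
                        call. = FALSE)
  sweep(scores, 2, sqrt(v), "/")
}

# Direct projection of a corresponded limb onto an articulated model
# (rigid alignment to the model mean, then orthonormal projection).
project_limb <- function(model, limb, align_iter = 2) {
  X <- limb_stack(limb)
  Xc <- sweep(X, 2, colMeans(X))
  target <- model$mean
  for (i in seq_len(align_iter)) {
    k <- kabsch(Xc, target)
    Xa <- sweep(Xc %*% t(k$R), 2, k$t, "+")
    co <- as.numeric(t(model$modes) %*% (as.vector(Xa) - as.vector(model$mean)))
    target <- model_instance(model, co)
    Xc <- Xa
  }
  co
}
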