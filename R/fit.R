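# Robust fitting of a statistical shape model to a (possibly arthritic)
# target mesh: closest-point correspondences, one-sided outlier flagging on
# the residual distribution, rigid pose and least-squares coefficient updates
# interleaved until convergence. Outlier regions (osteophyte-like
# protrusions) are excluded from the coefficient update, so the fitted shape
# stays within the healthy model span.

# Row indices of vertex v in the column-major (x | y | z) stacked layout.
coord_rows <- function(v_idx, nv) c(v_idx, nv + v_idx, 2L * nv + v_idx)

# Rotation vector (axis * angle, radians) of a rotation matrix.
rotation_vec <- function(R) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (vnorm(ax) < 1e-12) return(c(0, 0, 0))
  ang * ax / vnorm(ax)
}

#' Robustly fit a shape model to a target mesh
#'
#' Iterates (1) nearest-neighbour correspondence from the posed model
#' instance to the target vertices, (2) one-sided outlier flagging of
#' correspondences whose residual exceeds `mean + outlier_sd * SD` of the
#' residual distribution, (3) rigid pose (Kabsch) and least-squares mode
#' coefficient updates on the inlier set, until the relative coefficient
#' change drops below `tol` or `max_iter` is reached.
#'
#' @param model a `shape_model` (articulated or per-bone).
#' @param target a [triangle_mesh()] in any rigid pose.
#' @param outlier_sd one-sided outlier threshold in residual standard
#'   deviations (default 2); `Inf` disables outlier rejection, making the fit
#'   a plain rigid + least-squares projection.
#' @param max_iter maximum number of interleaved iterations.
#' @param tol relative coefficient-change convergence tolerance.
#' @param coef_prior optional weight of a Mahalanobis prior on the mode
#'   coefficients (0 disables it; useful for heavily contaminated targets).
#'
#' @details The rigid pose and the shape modes of a single bone are nearly
#'   degenerate: modes trained on whole-limb-aligned data can mimic small
#'   rotations of one bone. The fit resolves this flat direction towards the
#'   minimal-rotation pose via a weak penalty on the accumulated rotation,
#'   matching the convention under which training coefficients are defined;
#'   genuinely rigid motion of the target (e.g. disease misalignment of the
#'   tibia) is residual-driven and unaffected by the weak penalty.
#' @return a `fit_result`: `coefficients`, `correspondence` (target vertex
#'   index per model vertex), `outlier_mask`, `residuals` (mm),
#'   `n_iterations`, `converged`, the rigid pose (`R`, `t`) mapping the model
#'   frame onto the target, the inlier RMS per iteration (`rms_history`) and
#'   the model `part`/`frame_id`.
#' @export
robust_fit <- function(model, target, outlier_sd = 2, max_iter = 50, tol = 1e-4,
                       coef_prior = 0) {
  stopifnot(inherits(model, "shape_model"), inherits(target, "triangle_mesh"))
  if (outlier_sd <= 0) stop("`outlier_sd` must be > 0", call. = FALSE)
  if (nrow(target$vertices) == 0) stop("empty target mesh", call. = FALSE)
  nv <- model$n_vertices
  k <- length(model$variances)
  Phi <- model$modes
  co <- rep(0, k)
  R <- diag(3)
  tt <- colMeans(target$vertices) - colMeans(model$mean)
  tv <- target$vertices
  # rigid-only ICP warm start: brings the pose near its basin before shape
  # coefficients and pose are optimized jointly
  for (it0 in 1:8) {
    posed <- sweep(model$mean %*% t(R), 2, tt, "+")
    nn0 <- max.col(-pairwise_dist2(posed, tv), ties.method = "first")
    kb <- kabsch(model$mean, tv[nn0, , drop = FALSE])
    if (max(abs(kb$R - R)) < 1e-8) { R <- kb$R; tt <- kb$t; break }
    R <- kb$R; tt <- kb$t
  }
  rms_history <- numeric(0)
  converged <- FALSE
  nn <- rep(1L, nv); res <- numeric(nv); inl <- rep(TRUE, nv)
  n_it <- 0L
  for (it in seq_len(max_iter)) {
    n_it <- it
    X <- model_instance(model, co)
    posed <- sweep(X %*% t(R), 2, tt, "+")
    nn <- max.col(-pairwise_dist2(posed, tv), ties.method = "first")
    Y <- tv[nn, , drop = FALSE]
    res <- row_norms(posed - Y)
    if (is.finite(outlier_sd)) {
      thr <- mean(res) + outlier_sd * stats::sd(res)
      out <- (res > thr) & (res > 1e-6)
    } else out <- rep(FALSE, nv)
    inl <- !out
    if (!any(inl)) stop("fit failure: all vertices flagged as outliers", call. = FALSE)
    # joint Gauss-Newton step: mode coefficients and a linearized rigid
    # increment solved in one least squares on the inlier set (avoids the
    # slow ping-pong of alternating Kabsch and coefficient updates).
    widx <- which(inl)
    ni <- length(widx)
    P <- posed[widx, , drop = FALSE]
    modes_rot <- vapply(seq_len(k), function(j)
      as.vector((matrix(Phi[, j], nv, 3) %*% t(R))[widx, , drop = FALSE]),
      numeric(3 * ni))
    z0 <- numeric(ni)
    rot_cols <- cbind(c(z0, -P[, 3], P[, 2]),
                      c(P[, 3], z0, -P[, 1]),
                      c(-P[, 2], P[, 1], z0))
    trans_cols <- cbind(c(rep(1, ni), z0, z0), c(z0, rep(1, ni), z0),
                        c(z0, z0, rep(1, ni)))
    A <- cbind(modes_rot, rot_cols, trans_cols)
    b <- as.vector(Y[widx, , drop = FALSE] - P)
    w <- NULL
    if (coef_prior > 0) {
      w <- sqrt(coef_prior * 3 * ni / k) / sqrt(model$variances)
      A <- rbind(A, cbind(diag(w, k), matrix(0, k, 6)))
      b <- c(b, -w * co)
    }
    # weak minimal-rotation penalty: resolves the rotation/mode flat
    # direction towards the canonical (least-rotated) pose
    wr <- 0.1 * sqrt(3 * ni)
    omega <- rotation_vec(R)
    A <- rbind(A, cbind(matrix(0, 3, k), diag(wr, 3), matrix(0, 3, 3)))
    b <- c(b, -wr * omega)
    # Levenberg damping keeps the step finite along near-degenerate
    # rotation/mode directions
    A <- rbind(A, diag(1e-4, k + 6))
    b <- c(b, numeric(k + 6))
    step <- qr.solve(A, b)
    objective <- function(co2, R2, tt2) {
      posed2 <- sweep(model_instance(model, co2) %*% t(R2), 2, tt2, "+")
      obj <- sum((posed2 - Y)[widx, , drop = FALSE]^2) +
        sum((wr * rotation_vec(R2))^2)
      if (!is.null(w)) obj <- obj + sum((w * co2)^2)
      list(obj = obj,
           rms = sqrt(mean(rowSums((posed2 - Y)[widx, , drop = FALSE]^2))))
    }
    obj0 <- objective(co, R, tt)
    # trust region on the rotation increment: early correspondences are
    # unreliable, large one-shot rotations jump into spurious basins
    lam <- min(1, 0.15 / max(vnorm(step[k + 1:3]), 1e-12))
    # backtracking line search: never accept an objective increase
    for (bt in 1:8) {
      dc <- lam * step[seq_len(k)]
      dw <- lam * step[k + 1:3]
      dt <- lam * step[k + 4:6]
      wn <- vnorm(dw)
      if (wn > 1e-12) {
        Rw <- rotation_matrix(dw / wn, wn * 180 / pi)
        R2 <- Rw %*% R
        tt2 <- as.numeric(Rw %*% tt) + dt
      } else { R2 <- R; tt2 <- tt + dt }
      cand <- objective(co + dc, R2, tt2)
      if (cand$obj <= obj0$obj + 1e-12 * (1 + obj0$obj)) break
      lam <- lam / 2
    }
    co <- co + dc
    R <- R2
    tt <- tt2
    rms_history <- c(rms_history, cand$rms)
    delta <- vnorm(dc) / (vnorm(co) + 1e-8)
    if (delta < tol && vnorm(dw) < 10 * tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("robust_fit did not converge within %d iterations", max_iter))
  # final residual bookkeeping at the converged coefficients
  posed <- sweep(model_instance(model, co) %*% t(R), 2, tt, "+")
  nn <- max.col(-pairwise_dist2(posed, tv), ties.method = "first")
  res <- row_norms(posed - tv[nn, , drop = FALSE])
  if (is.finite(outlier_sd)) {
    thr <- mean(res) + outlier_sd * stats::sd(res)
    out <- (res > thr) & (res > 1e-6)
  } else out <- rep(FALSE, nv)
  structure(list(coefficients = co, correspondence = nn, outlier_mask = out,
                 residuals = res, n_iterations = n_it, converged = converged,
                 R = R, t = tt, rms_history = rms_history,
                 part = model$part, frame_id = model$frame_id),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): %d modes, %d iterations (%s), RMS %.3f mm, %d outliers\n",
              x$part, length(x$coefficients), x$n_iterations,
              if (x$converged) "converged" else "not converged",
              sqrt(mean(x$residuals[!x$outlier_mask]^2)), sum(x$outlier_mask)))
  invisible(x)
}

#' Reassemble a virtual healthy twin from per-bone fits
#'
#' Combines the healthy femur and tibia reconstructions into the articulated
#' configuration whose per-bone components best match them in least squares;
#' the relative pose of the bones comes from the articulated model, not from
#' the (misaligned) diseased input. Articulated coefficients and one free
#' rigid transform per bone are solved jointly by Gauss-Newton: because the
#' articulated modes are learned from whole-limb Procrustes-aligned training
#' data they are nearly orthogonal to global rotations, which makes the
#' coefficient / pose decomposition well identified at the articulated level
#' (unlike for a single bone).
#'
#' @param femur_fit,tibia_fit `fit_result`s from [robust_fit()] with per-bone
#'   models.
#' @param articulated_model articulated `shape_model`.
#' @param femur_model,tibia_model the per-bone models used for the fits
#'   (needed to materialize the fitted shapes).
#' @param coef_prior Mahalanobis prior weight on the articulated
#'   coefficients (see [robust_fit()]).
#' @return an `articulated_limb` with attribute `coefficients` (articulated
#'   mode loadings).
#' @export
reconstruct_twin <- function(femur_fit, tibia_fit, articulated_model,
                             femur_model, tibia_model, coef_prior = 0) {
  stopifnot(inherits(femur_fit, "fit_result"), inherits(tibia_fit, "fit_result"))
  if (!femur_fit$converged || !tibia_fit$converged)
    warning("twin reconstruction from non-converged fits")
  tpl <- articulated_model$template
  if (is.null(tpl)) stop("articulated model lacks template metadata", call. = FALSE)
  vf <- tpl$nv
  if (femur_model$n_vertices != vf || tibia_model$n_vertices != vf ||
      articulated_model$n_vertices != 2L * vf)
    stop("inconsistent model dimensions", call. = FALSE)
  yf <- model_instance(femur_model, femur_fit$coefficients)
  yt <- model_instance(tibia_model, tibia_fit$coefficients)
  Phi <- articulated_model$modes
  k <- length(articulated_model$variances)
  mu <- articulated_model$mean
  rows_f <- seq_len(vf); rows_t <- vf + seq_len(vf)
  # initial per-bone poses: rigid alignment onto the articulated mean blocks
  kf <- kabsch(yf, mu[rows_f, , drop = FALSE])
  kt <- kabsch(yt, mu[rows_t, , drop = FALSE])
  Rf <- kf$R; tf_ <- kf$t; Rt <- kt$R; tt_ <- kt$t
  co <- rep(0, k)
  n2 <- 2L * vf
  z0 <- numeric(vf)
  for (it in 1:20) {
    pf <- sweep(yf %*% t(Rf), 2, tf_, "+")
    pt <- sweep(yt %*% t(Rt), 2, tt_, "+")
    P <- rbind(pf, pt)
    inst <- model_instance(articulated_model, co)
    # residual: instance - posed bones; unknowns dc and per-bone (dw, dt)
    rot_block <- function(P1) cbind(c(numeric(nrow(P1)), -P1[, 3], P1[, 2]),
                                    c(P1[, 3], numeric(nrow(P1)), -P1[, 1]),
                                    c(-P1[, 2], P1[, 1], numeric(nrow(P1))))
    idx_f <- coord_rows(rows_f, n2); idx_t <- coord_rows(rows_t, n2)
    Af <- matrix(0, 3 * n2, 3); Af[idx_f, ] <- rot_block(pf)
    At <- matrix(0, 3 * n2, 3); At[idx_t, ] <- rot_block(pt)
    Tf <- matrix(0, 3 * n2, 3); Tf[cbind(idx_f, rep(1:3, each = vf))] <- 1
    Tt <- matrix(0, 3 * n2, 3); Tt[cbind(idx_t, rep(1:3, each = vf))] <- 1
    A <- cbind(-Phi, Af, Tf, At, Tt)
    b <- as.vector(inst - P)
    if (coef_prior > 0) {
      w <- sqrt(coef_prior * 3 * n2 / k) / sqrt(articulated_model$variances)
      A <- rbind(A, cbind(diag(-w, k), matrix(0, k, 12)))
      b <- c(b, w * co)
    }
    A <- rbind(A, diag(1e-4, k + 12)) # Levenberg damping
    b <- c(b, numeric(k + 12))
    step <- qr.solve(A, b)
    dc <- step[seq_len(k)]
    co <- co + dc
    upd <- function(R, t, dw, dt) {
      wn <- vnorm(dw)
      if (wn > 1e-14) {
        Rw <- rotation_matrix(dw / wn, wn * 180 / pi)
        list(R = Rw %*% R, t = as.numeric(Rw %*% t) + dt)
      } else list(R = R, t = t + dt)
    }
    uf <- upd(Rf, tf_, step[k + 1:3], step[k + 4:6])
    ut <- upd(Rt, tt_, step[k + 7:9], step[k + 10:12])
    Rf <- uf$R; tf_ <- uf$t; Rt <- ut$R; tt_ <- ut$t
    if (vnorm(dc) / (vnorm(co) + 1e-8) < 1e-6) break
  }
  twin <- limb_from_coefficients(articulated_model, co)
  attr(twin, "coefficients") <- co
  twin
}
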