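# Principal polynomial autoencoder (PPAE): a fully-connected autoencoder
# whose bottleneck is replaced, after training, by a low-rank SVD of the
# latent activations and sequential polynomial residualization of the SVD
# scores. The result is an ordered set of decorrelated, non-linear wear
# components with per-component variance attribution over the latent space.

#' Mirror augmentation of wear images
#'
#' Expands the training set with left-right, antero-posterior and double
#' mirrorings: output = originals U horizontal flips U vertical flips U
#' double flips, emitted per case in contiguous groups of four
#' (original, LR, AP, LR+AP), quadrupling the sample count.
#'
#' @param images list of [wear_image()]s sharing one size.
#' @return list of `4 * length(images)` wear images.
#' @export
augment <- function(images) {
  sizes <- vapply(images, function(im) im$size, 0L)
  if (length(unique(sizes)) > 1) stop("images must share one size", call. = FALSE)
  out <- vector("list", 4L * length(images))
  for (i in seq_along(images)) {
    im <- images[[i]]
    out[[4L * i - 3L]] <- im
    out[[4L * i - 2L]] <- flip_lr(im)
    out[[4L * i - 1L]] <- flip_ap(im)
    out[[4L * i]] <- flip_ap(flip_lr(im))
  }
  out
}

images_to_matrix <- function(images, mask = NULL) {
  s <- images[[1]]$size
  if (is.null(mask)) mask <- images[[1]]$mask
  t(vapply(images, function(im) as.numeric(im$pixels[mask]),
           numeric(sum(mask))))
}

act_fun <- function(x, activation) if (activation == "tanh") tanh(x) else x
act_grad <- function(a, activation) if (activation == "tanh") 1 - a^2 else 1

ppae_forward <- function(w, X, activation) {
  H1 <- act_fun(sweep(X %*% w$W1, 2, w$b1, "+"), activation)
  Z <- sweep(H1 %*% w$W2, 2, w$b2, "+")
  H2 <- act_fun(sweep(Z %*% w$W3, 2, w$b3, "+"), activation)
  Xh <- sweep(H2 %*% w$W4, 2, w$b4, "+")
  list(H1 = H1, Z = Z, H2 = H2, Xh = Xh)
}

#' Train the autoencoder backbone of a PPAE
#'
#' Two fully-connected encoder layers compress each wear image into a latent
#' space (15 dimensions by default), mirrored by the decoder. The loss is the
#' masked-pixel mean squared error with L2 weight decay and an optional
#' sparsity penalty (KL divergence between a target activation rate and the
#' mean hidden activation, the classic sparse-autoencoder form). Training is
#' full-batch Adam and fully reproducible from `seed`.
#'
#' @param images list of [wear_image()]s (training set, typically augmented).
#' @param latent_dim latent dimensionality (default 15).
#' @param hidden_dim width of the hidden layers (default 512).
#' @param activation `"tanh"` (default) or `"linear"`.
#' @param l2_weight L2 regularization weight.
#' @param sparsity_weight weight of the sparsity penalty; 0 disables it.
#' @param sparsity_target target mean activation rate of the penalty.
#' @param epochs number of full-batch Adam steps.
#' @param learning_rate Adam step size.
#' @param seed integer seed for weight initialization.
#' @return a `ppae_model` holding the weights, training configuration,
#'   pixel mask and loss history. The polynomial bottleneck is added by
#'   [fit_polynomial_bottleneck()].
#' @export
train_ppae <- function(images, latent_dim = 15, hidden_dim = 512,
                       activation = c("tanh", "linear"), l2_weight = 1e-5,
                       sparsity_weight = 0, sparsity_target = 0.1,
                       epochs = 400, learning_rate = 2e-3, seed = 1) {
  activation <- match.arg(activation)
  if (length(images) < 2 * latent_dim)
    stop("need at least 2 * latent_dim training images", call. = FALSE)
  if (latent_dim > length(images))
    stop("latent_dim exceeds the sample count", call. = FALSE)
  mask <- images[[1]]$mask
  X <- images_to_matrix(images, mask)
  n <- nrow(X); p <- ncol(X); h <- hidden_dim; m <- latent_dim
  w <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(p * h, 0, 1 / sqrt(p)), p, h), b1 = numeric(h),
    W2 = matrix(stats::rnorm(h * m, 0, 1 / sqrt(h)), h, m), b2 = numeric(m),
    W3 = matrix(stats::rnorm(m * h, 0, 1 / sqrt(m)), m, h), b3 = numeric(h),
    W4 = matrix(stats::rnorm(h * p, 0, 1 / sqrt(h)), h, p), b4 = numeric(p)))
  adam_m <- lapply(w, function(x) x * 0)
  adam_v <- lapply(w, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- ppae_forward(w, X, activation)
    E <- fw$Xh - X
    mse <- mean(E^2)
    l2 <- l2_weight * (sum(w$W1^2) + sum(w$W2^2) + sum(w$W3^2) + sum(w$W4^2))
    spars <- 0
    if (sparsity_weight > 0 && activation == "tanh") {
      rho_hat <- pmin(pmax(colMeans((fw$H1 + 1) / 2), 1e-6), 1 - 1e-6)
      rho <- sparsity_target
      spars <- sparsity_weight *
        sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
    }
    loss <- mse + l2 + spars
    if (!is.finite(loss))
      stop(sprintf("NaN/Inf loss at epoch %d (lr %.g); reduce the learning rate",
                   ep, learning_rate), call. = FALSE)
    loss_history[ep] <- loss
    dXh <- 2 * E / (n * p)
    g <- list()
    g$W4 <- t(fw$H2) %*% dXh + 2 * l2_weight * w$W4
    g$b4 <- colSums(dXh)
    dH2 <- dXh %*% t(w$W4) * act_grad(fw$H2, activation)
    g$W3 <- t(fw$Z) %*% dH2 + 2 * l2_weight * w$W3
    g$b3 <- colSums(dH2)
    dZ <- dH2 %*% t(w$W3)
    g$W2 <- t(fw$H1) %*% dZ + 2 * l2_weight * w$W2
    g$b2 <- colSums(dZ)
    dH1 <- dZ %*% t(w$W2)
    if (sparsity_weight > 0 && activation == "tanh") {
      drho <- sparsity_weight * (-rho / rho_hat + (1 - rho) / (1 - rho_hat))
      dH1 <- dH1 + matrix(drho / (2 * n), n, h, byrow = TRUE)
    }
    dH1 <- dH1 * act_grad(fw$H1, activation)
    g$W1 <- t(X) %*% dH1 + 2 * l2_weight * w$W1
    g$b1 <- colSums(dH1)
    for (nm in names(w)) {
      adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g[[nm]]
      adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- adam_m[[nm]] / (1 - beta1^ep)
      vhat <- adam_v[[nm]] / (1 - beta2^ep)
      w[[nm]] <- w[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(weights = w, mask = mask, size = images[[1]]$size,
                 latent_dim = m,
                 training_config = list(latent_dim = m, hidden_dim = h,
                                        activation = activation,
                                        l2_weight = l2_weight,
                                        sparsity_weight = sparsity_weight,
                                        sparsity_target = sparsity_target,
                                        epochs = epochs,
                                        learning_rate = learning_rate,
                                        seed = seed),
                 loss_history = loss_history,
                 final_loss = loss_history[epochs],
                 bottleneck = NULL),
            class = "ppae_model")
}

#' @export
print.ppae_model <- function(x, ...) {
  cat(sprintf("ppae_model: %d px -> %d latent (%s, hidden %d), final loss %.4g%s\n",
              sum(x$mask), x$latent_dim, x$training_config$activation,
              x$training_config$hidden_dim, x$final_loss,
              if (is.null(x$bottleneck)) ", bottleneck not fitted" else
                sprintf(", %d polynomial components", length(x$bottleneck$order))))
  invisible(x)
}

ppae_encode <- function(model, images) {
  X <- images_to_matrix(images, model$mask)
  act <- model$training_config$activation
  H1 <- act_fun(sweep(X %*% model$weights$W1, 2, model$weights$b1, "+"), act)
  sweep(H1 %*% model$weights$W2, 2, model$weights$b2, "+")
}

ppae_decode <- function(model, Z) {
  act <- model$training_config$activation
  H2 <- act_fun(sweep(Z %*% model$weights$W3, 2, model$weights$b3, "+"), act)
  sweep(H2 %*% model$weights$W4, 2, model$weights$b4, "+")
}

# Reconstruct images (list of wear_image) from latent codes.
decode_to_images <- function(model, Z) {
  Xh <- ppae_decode(model, Z)
  lapply(seq_len(nrow(Xh)), function(i) {
    px <- matrix(0, model$size, model$size)
    px[model$mask] <- clip01(Xh[i, ])
    wear_image(px, model$mask)
  })
}

# Per-predictor polynomial design matrix (powers 1..degree of each column).
poly_design <- function(S, degree) {
  S <- as.matrix(S)
  cols <- lapply(seq_len(ncol(S)), function(j)
    matrix(S[, j], nrow(S), degree)^matrix(seq_len(degree), nrow(S), degree,
                                           byrow = TRUE))
  cbind(1, do.call(cbind, cols))
}

#' Fit the polynomial bottleneck of a PPAE
#'
#' Replaces the autoencoder bottleneck by (1) an SVD of the centred latent
#' activations, giving ordered orthogonal directions, and (2) sequential
#' polynomial residualization: the scores of each further component are
#' residualized by a polynomial regression (degree `degree`) on all previous
#' components' final scores, which makes the final scores exactly
#' decorrelated. Components are ordered by descending residual variance;
#' variance fractions are taken over the total latent variance.
#'
#' @param model a trained `ppae_model`.
#' @param images the images whose latent activations define the bottleneck
#'   (typically the training set).
#' @param degree polynomial degree (1-3; degree 1 reduces to plain SVD
#'   scores).
#' @return list with `components` (a `poly_components` object: `scores`,
#'   `variance_fraction`, `cumulative_fraction`, `component_sd`) and `model`
#'   (the updated `ppae_model` with the fitted bottleneck).
#' @export
fit_polynomial_bottleneck <- function(model, images, degree = 2) {
  stopifnot(inherits(model, "ppae_model"))
  if (degree < 1 || degree > 3) stop("`degree` must be 1, 2 or 3", call. = FALSE)
  Z <- ppae_encode(model, images)
  zbar <- colMeans(Z)
  Zc <- sweep(Z, 2, zbar)
  sv <- svd(Zc, nu = 0)
  keep <- sv$d > 1e-9 * sv$d[1]
  if (sum(keep) < length(sv$d))
    warning(sprintf("rank-deficient latent activations: %d of %d components returned",
                    sum(keep), length(sv$d)))
  V <- sv$v[, keep, drop = FALSE]
  TT <- Zc %*% V
  r <- ncol(TT)
  S <- matrix(0, nrow(TT), r)
  S[, 1] <- TT[, 1]
  coeffs <- vector("list", r)
  for (j in seq_len(r)[-1]) {
    D <- poly_design(S[, seq_len(j - 1), drop = FALSE], degree)
    beta <- qr.solve(D, TT[, j])
    S[, j] <- TT[, j] - D %*% beta
    coeffs[[j]] <- beta
  }
  total_var <- sum(sv$d^2) / (nrow(Z) - 1)
  vars <- apply(S, 2, stats::var)
  ord <- order(vars, decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  vf <- vars[ord] / total_var
  comp_sd <- sqrt(vars[ord])
  bottleneck <- list(center = zbar, svd_basis = V, poly_coeffs = coeffs,
                     degree = degree, order = ord, component_sd = comp_sd,
                     training_scores = S)
  model$bottleneck <- bottleneck
  components <- structure(list(scores = S, variance_fraction = vf,
                               cumulative_fraction = cumsum(vf),
                               component_sd = comp_sd),
                          class = "poly_components")
  list(components = components, model = model)
}

#' @export
print.poly_components <- function(x, ...) {
  cat("poly_components:\n")
  k <- min(8, length(x$variance_fraction))
  for (i in seq_len(k))
    cat(sprintf("  comp %d: %5.1f%% of latent variance (cum %5.1f%%)\n",
                i, 100 * x$variance_fraction[i], 100 * x$cumulative_fraction[i]))
  invisible(x)
}

# Raw (un-reordered) sequential scores for latent codes Z.
bottleneck_scores_raw <- function(bn, Z) {
  Zc <- sweep(Z, 2, bn$center)
  TT <- Zc %*% bn$svd_basis
  r <- ncol(TT)
  S <- matrix(0, nrow(TT), r)
  S[, 1] <- TT[, 1]
  for (j in seq_len(r)[-1]) {
    D <- poly_design(S[, seq_len(j - 1), drop = FALSE], bn$degree)
    S[, j] <- TT[, j] - D %*% bn$poly_coeffs[[j]]
  }
  S
}

#' Transform images to polynomial component scores
#'
#' Deterministic map image -> encoder -> SVD projection -> sequential
#' polynomial residualization -> ordered component scores.
#'
#' @param model a `ppae_model` with a fitted bottleneck.
#' @param images a single [wear_image()] or a list of them.
#' @return numeric matrix of component scores (one row per image).
#' @export
ppae_transform <- function(model, images) {
  if (inherits(images, "wear_image")) images <- list(images)
  if (is.null(model$bottleneck)) stop("fit the polynomial bottleneck first", call. = FALSE)
  if (images[[1]]$size != model$size)
    stop(sprintf("image size %d does not match model size %d",
                 images[[1]]$size, model$size), call. = FALSE)
  S <- bottleneck_scores_raw(model$bottleneck, ppae_encode(model, images))
  S[, model$bottleneck$order, drop = FALSE]
}

# Invert the ordered score vector back to a latent code.
scores_to_latent <- function(bn, s_ordered) {
  r <- length(bn$order)
  s_raw <- numeric(r)
  s_raw[bn$order] <- s_ordered
  tt <- numeric(r)
  tt[1] <- s_raw[1]
  for (j in seq_len(r)[-1]) {
    D <- poly_design(matrix(s_raw[seq_len(j - 1)], 1), bn$degree)
    tt[j] <- s_raw[j] + as.numeric(D %*% bn$poly_coeffs[[j]])
  }
  bn$center + as.numeric(bn$svd_basis %*% tt)
}

#' Decode a component excursion for visual interpretation
#'
#' Decodes the images corresponding to scores at +/- `sd_range` standard
#' deviations along one component (all other components at 0), for
#' qualitative labelling of the wear pattern a component encodes.
#'
#' @param model a `ppae_model` with fitted bottleneck.
#' @param component_index which ordered component to excite.
#' @param sd_range excursion in component standard deviations.
#' @return list with wear images `minus` and `plus` (values clipped to
#'   \[0, 1\]).
#' @export
component_wear_interpretation <- function(model, component_index, sd_range = 2) {
  bn <- model$bottleneck
  if (is.null(bn)) stop("fit the polynomial bottleneck first", call. = FALSE)
  r <- length(bn$order)
  if (component_index < 1 || component_index > r)
    stop("`component_index` out of range", call. = FALSE)
  mk <- function(sign) {
    s <- numeric(r)
    s[component_index] <- sign * sd_range * bn$component_sd[component_index]
    z <- scores_to_latent(bn, s)
    decode_to_images(model, matrix(z, 1))[[1]]
  }
  list(minus = mk(-1), plus = mk(+1))
}
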