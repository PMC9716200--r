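# Ground-truth cartilage wear patterns on the flattened articular domain.
# The unit square (u, v) is the anatomically standardized chart of the
# femorotibial articular region: u increases medial -> lateral, v increases
# anterior -> posterior. Pattern templates are smooth bumps placed so that
# medial/lateral form an exact left-right mirror pair and anteromedial/
# posteromedial an exact antero-posterior mirror pair.

WEAR_PATTERNS <- c("medial", "lateral", "anteromedial", "posteromedial", "spine")

gauss2 <- function(u, v, cu, cv, su, sv) {
  exp(-(((u - cu) / su)^2 + ((v - cv) / sv)^2) / 2)
}

#' Wear pattern template
#'
#' Evaluates one of the five canonical wear-pattern templates at (u, v)
#' coordinates of the flattened articular domain.
#'
#' @param u,v numeric vectors in \[0, 1\].
#' @param pattern one of `"medial"`, `"lateral"`, `"anteromedial"`,
#'   `"posteromedial"`, `"spine"`.
#' @return numeric vector of template values in \[0, 1\].
#' @export
wear_template <- function(u, v, pattern = WEAR_PATTERNS) {
  pattern <- match.arg(pattern)
  switch(pattern,
         medial = gauss2(u, v, 0.25, 0.50, 0.16, 0.30),
         lateral = wear_template(1 - u, v, "medial"),
         anteromedial = gauss2(u, v, 0.28, 0.28, 0.13, 0.15),
         posteromedial = wear_template(u, 1 - v, "anteromedial"),
         spine = gauss2(u, v, 0.50, 0.50, 0.085, 0.20))
}

#' Synthesize a wear field from pattern weights
#'
#' Linear combination of the five pattern templates plus optional additive
#' Gaussian noise, clipped to \[0, 1\]. Either scattered (u, v) coordinates or
#' a square image grid can be requested.
#'
#' @param weights numeric 5-vector of pattern loadings, ordered
#'   (medial, lateral, anteromedial, posteromedial, spine).
#' @param uv optional 2-column matrix of (u, v) sample coordinates.
#' @param size optional image side length; if given, the field is evaluated
#'   at pixel centres of a `size x size` grid and returned as a [wear_image()].
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed for the noise draw.
#' @return numeric vector of per-sample wear values, or a `wear_image`.
#' @export
generate_wear_field <- function(weights, uv = NULL, size = NULL,
                                noise_sd = 0, seed = 1) {
  if (length(weights) != 5L || !all(is.finite(weights)))
    stop("`weights` must be a finite 5-vector", call. = FALSE)
  if (is.null(uv) && is.null(size)) stop("supply `uv` or `size`", call. = FALSE)
  if (!is.null(size)) {
    ctr <- (seq_len(size) - 0.5) / size
    uv <- cbind(rep(ctr, times = size), rep(ctr, each = size)) # u fast, v slow
  }
  f <- numeric(nrow(uv))
  for (k in seq_along(WEAR_PATTERNS))
    f <- f + weights[k] * wear_template(uv[, 1], uv[, 2], WEAR_PATTERNS[k])
  if (noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(length(f), 0, noise_sd))
  f <- clip01(f)
  if (!is.null(size))
    return(wear_image(matrix(f, size, size, byrow = TRUE))) # rows index v
  f
}

#' Default wear class mixture
#'
#' Mixture over wear classes with prevalences mirroring the pattern taxonomy
#' of end-stage knee OA cohorts (medial wear dominating, then bicompartmental,
#' lateral, tibial-spine impingement and a mixed remainder).
#'
#' @return data frame with class name, prevalence and mean pattern weights.
#' @export
default_wear_classes <- function() {
  data.frame(
    class = c("medial", "bicompartmental", "lateral", "spine", "mixed"),
    prob = c(0.548, 0.252, 0.091, 0.045, 0.064),
    w_medial = c(0.85, 0.70, 0.03, 0.10, 0.40),
    w_lateral = c(0.03, 0.70, 0.85, 0.10, 0.40),
    w_anteromedial = c(0.30, 0.20, 0.05, 0.05, 0.30),
    w_posteromedial = c(0.30, 0.20, 0.05, 0.05, 0.30),
    w_spine = c(0.05, 0.10, 0.05, 0.90, 0.30),
    sd = c(0.12, 0.12, 0.12, 0.12, 0.12))
}

#' Generate a synthetic wear cohort with known latent structure
#'
#' Samples class labels from `class_spec`, draws pattern weights around the
#' class means, and renders each case as a wear image. Ground-truth labels
#' and weights are returned so that latent-recovery can be scored.
#'
#' @param n number of cases (>= 1).
#' @param class_spec class mixture as from [default_wear_classes()].
#' @param noise_sd additive image noise standard deviation.
#' @param size image side length.
#' @param seed integer seed.
#' @return list with `images` (list of `wear_image`), `weights` (n x 5),
#'   `labels`, `seed`.
#' @export
generate_wear_cohort <- function(n, class_spec = default_wear_classes(),
                                 noise_sd = 0.03, size = 32, seed = 1) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (all(class_spec$sd == 0) && nrow(class_spec) == 1L)
    warning("degenerate class_spec: zero variance in all patterns")
  probs <- class_spec$prob / sum(class_spec$prob)
  wcols <- paste0("w_", WEAR_PATTERNS)
  with_seed(seed, {
    labels <- sample(class_spec$class, n, replace = TRUE, prob = probs)
    W <- matrix(0, n, 5, dimnames = list(NULL, WEAR_PATTERNS))
    for (i in seq_len(n)) {
      row <- match(labels[i], class_spec$class)
      W[i, ] <- pmax(0, as.numeric(class_spec[row, wcols]) +
                       stats::rnorm(5, 0, class_spec$sd[row]))
    }
    images <- lapply(seq_len(n), function(i)
      generate_wear_field(W[i, ], size = size, noise_sd = noise_sd,
                          seed = derive_seed(seed, i)))
    list(images = images, weights = W, labels = labels, seed = seed)
  })
}

#' Generate a wear cohort driven by four independent latent factors
#'
#' Four independent standard-normal factors drive the pattern weights through
#' mildly non-linear (quadratic) links with descending strength: factor 1 the
#' medial load, factor 2 the lateral load, factor 3 the antero- vs
#' postero-medial contrast, factor 4 tibial-spine impingement. Used for
#' latent-recovery benchmarking of the polynomial autoencoder.
#'
#' @inheritParams generate_wear_cohort
#' @return list with `images`, `factors` (n x 4), `weights`, `seed`.
#' @export
generate_factor_wear_cohort <- function(n, noise_sd = 0.02, size = 32, seed = 1) {
  with_seed(seed, {
    f <- matrix(stats::rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("factor", 1:4)))
    W <- cbind(medial = 0.45 + 0.30 * f[, 1] + 0.06 * f[, 1]^2,
               lateral = 0.30 + 0.22 * f[, 2] + 0.05 * f[, 2]^2,
               anteromedial = 0.30 + 0.16 * f[, 3] + 0.03 * f[, 3]^2,
               posteromedial = 0.30 - 0.16 * f[, 3] + 0.03 * f[, 3]^2,
               spine = 0.22 + 0.11 * f[, 4] + 0.03 * f[, 4]^2)
    W <- pmax(W, 0)
    images <- lapply(seq_len(n), function(i)
      generate_wear_field(W[i, ], size = size, noise_sd = noise_sd,
                          seed = derive_seed(seed, i)))
    list(images = images, factors = f, weights = W, seed = seed)
  })
}
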