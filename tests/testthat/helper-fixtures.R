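# Shared fixtures and independent oracles for the test suite. Everything is
# built in code; oracles deliberately avoid the package's own implementation
# paths.

# Regular triangulated planar grid on [0, xmax] x [0, ymax] at height z.
make_plane <- function(n = 9, z = 0, xmax = 1, ymax = 1) {
  g <- expand.grid(x = seq(0, xmax, length.out = n),
                   y = seq(0, ymax, length.out = n))
  id <- function(i, j) (j - 1L) * n + i
  faces <- do.call(rbind, lapply(seq_len(n - 1), function(j)
    do.call(rbind, lapply(seq_len(n - 1), function(i)
      rbind(c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
            c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))))))
  triangle_mesh(cbind(g$x, g$y, z), faces)
}

# Open spherical cap mesh (pole + rings), single boundary loop.
make_cap <- function(n_theta = 24, n_ring = 10, phi_max = pi / 2) {
  th <- rep(2 * pi * (0:(n_theta - 1)) / n_theta, n_ring)
  ph <- rep(seq(phi_max / n_ring, phi_max, length.out = n_ring), each = n_theta)
  v <- rbind(c(0, 0, 1), cbind(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph)))
  ring <- function(j, i) 1L + (j - 1L) * n_theta + i
  i2 <- c(2:n_theta, 1L)
  f <- cbind(1L, ring(1, i2), ring(1, seq_len(n_theta)))
  for (j in seq_len(n_ring - 1)) {
    a <- ring(j, seq_len(n_theta)); b <- ring(j, i2)
    cc <- ring(j + 1, i2); d <- ring(j + 1, seq_len(n_theta))
    f <- rbind(f, cbind(a, b, cc), cbind(a, cc, d))
  }
  triangle_mesh(v, f)
}

# Independent HKA oracle: closed-form angle between landmark rays, signed by
# the medial reference, written without package helpers.
oracle_hka <- function(hip, knee, ankle, medial) {
  u <- hip - knee; v <- ankle - knee
  cang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  gamma <- acos(max(-1, min(1, cang))) * 180 / pi
  b <- u / sqrt(sum(u^2)) + v / sqrt(sum(v^2))
  if (sqrt(sum(b^2)) < 1e-9) return(180)
  side <- sign(sum(b * (medial - knee)))
  180 + side * (180 - gamma)
}

# Principal angles (degrees) between the column spaces of two matrices.
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(scale(a, scale = FALSE)))
  qb <- qr.Q(qr(scale(b, scale = FALSE)))
  acos(pmin(1, svd(t(qa) %*% qb)$d)) * 180 / pi
}

# Brute-force point-to-triangle distance by dense barycentric sampling.
oracle_point_tri_dist <- function(p, tri, n = 60) {
  l <- seq(0, 1, length.out = n)
  g <- expand.grid(a = l, b = l)
  g <- g[g$a + g$b <= 1, ]
  pts <- outer(1 - g$a - g$b, tri[1, ]) + outer(g$a, tri[2, ]) + outer(g$b, tri[3, ])
  sqrt(min(rowSums(sweep(pts, 2, p)^2)))
}

# Hand-rolled two-class LDA with pooled covariance; returns predicted class
# label for a single test row (independent of MASS).
oracle_lda_predict <- function(xtr, ytr, xte, positive) {
  ytr <- as.character(ytr)
  lv <- unique(ytr)
  m1 <- colMeans(xtr[ytr == lv[1], , drop = FALSE])
  m2 <- colMeans(xtr[ytr == lv[2], , drop = FALSE])
  n1 <- sum(ytr == lv[1]); n2 <- sum(ytr == lv[2])
  S <- ((n1 - 1) * stats::cov(xtr[ytr == lv[1], , drop = FALSE]) +
          (n2 - 1) * stats::cov(xtr[ytr == lv[2], , drop = FALSE])) / (n1 + n2 - 2)
  Si <- solve(S)
  d1 <- as.numeric(xte %*% Si %*% m1 - 0.5 * sum(m1 * (Si %*% m1)) + log(n1 / (n1 + n2)))
  d2 <- as.numeric(xte %*% Si %*% m2 - 0.5 * sum(m2 * (Si %*% m2)) + log(n2 / (n1 + n2)))
  if (d1 >= d2) lv[1] else lv[2]
}

# Mean silhouette of a labelled 2-D embedding (own implementation).
oracle_silhouette <- function(xy, labels) {
  d <- as.matrix(stats::dist(xy))
  n <- nrow(xy)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Small shared cohorts (built once per test run).
small_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- experiment_config(n_train_ssm = 25)
      params <- kneewear:::sample_cohort_params(cfg, 25, 421)
      limbs <- kneewear:::generate_cohort_limbs(cfg, params, 422)
      cache <<- list(cfg = cfg, limbs = limbs,
                     models = build_limb_models(limbs, variance_kept = 1))
    }
    cache
  }
})
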