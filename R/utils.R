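# Small numeric helpers shared across modules.

clip01 <- function(x) pmin(1, pmax(0, x))

vnorm <- function(x) sqrt(sum(x^2))

unit_vector <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  x / n
}

row_norms <- function(m) sqrt(rowSums(m^2))

#' @noRd
angle_deg <- function(u, v) {
  cu <- vnorm(u); cv <- vnorm(v)
  if (cu < 1e-12 || cv < 1e-12) stop("degenerate vectors in angle computation", call. = FALSE)
  c0 <- sum(u * v) / (cu * cv)
  acos(pmin(1, pmax(-1, c0))) * 180 / pi
}

# Rodrigues rotation about a unit axis, angle in degrees.
rotation_matrix <- function(axis, angle_deg) {
  a <- unit_vector(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Evaluate code with a temporary RNG state; never leaks global RNG changes.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Deterministic stream of sub-seeds below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(offset)) %% 2147483629)
}

# FNV-1a over a deparsed object; used to tag configs and model frames.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.numeric(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
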