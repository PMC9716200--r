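#' Wear image
#'
#' An `S x S` isotropic pixel image of normalized wear values in \[0, 1\] over
#' the flattened articular domain. Row `i` corresponds to
#' `v = (i - 0.5) / S` (anterior -> posterior), column `j` to
#' `u = (j - 0.5) / S` (medial -> lateral).
#'
#' @param pixels square numeric matrix of values in \[0, 1\].
#' @param mask logical matrix of in-domain pixels (defaults to all `TRUE`;
#'   the harmonic flattening maps the whole patch onto the full square).
#' @return an object of class `wear_image`.
#' @export
wear_image <- function(pixels, mask = NULL) {
  pixels <- as.matrix(pixels)
  s <- nrow(pixels)
  if (ncol(pixels) != s) stop("`pixels` must be square", call. = FALSE)
  if (s < 8) stop("image side must be at least 8", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, s, s)
  if (any(pixels[mask] < -1e-9 | pixels[mask] > 1 + 1e-9))
    stop("in-mask pixel values must lie in [0, 1]", call. = FALSE)
  structure(list(pixels = pixels, size = s, mask = mask), class = "wear_image")
}

#' @export
print.wear_image <- function(x, ...) {
  cat(sprintf("wear_image: %d x %d, mean %.3f\n", x$size, x$size,
              mean(x$pixels[x$mask])))
  invisible(x)
}

#' Mirror a wear image
#'
#' `flip_lr()` mirrors medio-laterally (u -> 1 - u), `flip_ap()`
#' antero-posteriorly (v -> 1 - v). Both are exact pixel permutations and
#' involutions.
#'
#' @param image a [wear_image()].
#' @return the mirrored `wear_image`.
#' @export
flip_lr <- function(image) {
  wear_image(image$pixels[, image$size:1, drop = FALSE],
             image$mask[, image$size:1, drop = FALSE])
}

#' @rdname flip_lr
#' @export
flip_ap <- function(image) {
  wear_image(image$pixels[image$size:1, , drop = FALSE],
             image$mask[image$size:1, , drop = FALSE])
}

#' Rasterize scattered wear values to a pixel image
#'
#' Interpolates scattered (u, v, value) samples by a thin-plate regression
#' spline onto the pixel centres of a `size x size` grid; output is clipped
#' to \[0, 1\]. Exact for constant fields and linear ramps (they lie in the
#' spline's null space).
#'
#' @param param a `square_param` from [conformal_flatten()], or a 2-column
#'   (u, v) matrix.
#' @param values normalized wear values at the parameterized vertices,
#'   finite and in \[0, 1\].
#' @param size image side length (default 128).
#' @param k basis dimension of the thin-plate spline (capped at the sample
#'   count).
#' @return a [wear_image()].
#' @export
rasterize <- function(param, values, size = 128, k = NULL) {
  uv <- if (inherits(param, "square_param")) param$uv else as.matrix(param)
  values <- as.numeric(values)
  if (length(values) != nrow(uv)) stop("values/param length mismatch", call. = FALSE)
  if (!all(is.finite(values)) || any(values < -1e-9 | values > 1 + 1e-9))
    stop("values must be finite and in [0, 1]", call. = FALSE)
  if (nrow(uv) < 4) stop("interpolation error: need at least 4 samples", call. = FALSE)
  df <- data.frame(u = uv[, 1], v = uv[, 2], w = values)
  kk <- k %||% min(nrow(uv) - 2L, 120L)
  kk <- max(3L, min(kk, nrow(uv) - 1L))
  fit <- tryCatch(
    suppressWarnings(mgcv::gam(w ~ s(u, v, bs = "tp", k = kk), data = df,
                               method = "REML")),
    error = function(e) NULL)
  ctr <- (seq_len(size) - 0.5) / size
  grid <- data.frame(u = rep(ctr, times = size), v = rep(ctr, each = size))
  if (is.null(fit)) {
    # degenerate designs (e.g. collinear samples): fall back to a plane fit
    fit <- stats::lm(w ~ u + v, data = df)
    px <- stats::predict(fit, grid)
  } else {
    px <- as.numeric(mgcv::predict.gam(fit, grid))
  }
  wear_image(matrix(clip01(px), size, size, byrow = TRUE))
}

#' Bilinear sampling of a wear image
#'
#' @param image a [wear_image()].
#' @param u,v coordinates in \[0, 1\].
#' @return interpolated pixel values.
#' @export
sample_wear_image <- function(image, u, v) {
  s <- image$size
  gx <- pmin(pmax(u * s - 0.5, 0), s - 1)
  gy <- pmin(pmax(v * s - 0.5, 0), s - 1)
  x0 <- pmin(floor(gx), s - 2); y0 <- pmin(floor(gy), s - 2)
  fx <- gx - x0; fy <- gy - y0
  p <- image$pixels
  idx <- function(r, c) p[cbind(r + 1, c + 1)]
  (1 - fx) * (1 - fy) * idx(y0, x0) + fx * (1 - fy) * idx(y0, x0 + 1) +
    (1 - fx) * fy * idx(y0 + 1, x0) + fx * fy * idx(y0 + 1, x0 + 1)
}

#' Write a wear image as CSV
#'
#' Plain-text export of the pixel matrix (rows = v index).
#'
#' @param image a [wear_image()].
#' @param path file path.
#' @export
write_wear_image_csv <- function(image, path) {
  utils::write.table(image$pixels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
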