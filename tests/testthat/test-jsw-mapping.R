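# Joint-space-width maps, conformal flattening and rasterization.

test_that("joint space width matches planar and brute-force oracles", {
  top <- make_plane(11, z = 4, xmax = 10, ymax = 10)
  bottom <- make_plane(11, z = 0, xmax = 10, ymax = 10)
  dm <- compute_jsw(top, bottom, seq_len(nrow(top$vertices)))
  expect_equal(dm$jsw_mm, rep(4, 121), tolerance = 1e-10)
  # single ROI vertex against a brute-force point-triangle oracle
  tri_mesh <- triangle_mesh(rbind(c(-2, -2, 0), c(2, -2, 0), c(0, 3, 0)),
                            matrix(c(1, 2, 3), 1))
  probe <- triangle_mesh(rbind(c(0.2, 0.1, 1.5)), matrix(c(1, 1, 1), 1))
  dm1 <- compute_jsw(probe, tri_mesh, 1L)
  expect_equal(dm1$jsw_mm,
               oracle_point_tri_dist(c(0.2, 0.1, 1.5), tri_mesh$vertices, 400),
               tolerance = 1e-3)
  expect_equal(dm1$jsw_mm, 1.5, tolerance = 1e-9)
  # off-face probe: closest point on an edge
  probe2 <- triangle_mesh(rbind(c(5, 0, 1)), matrix(c(1, 1, 1), 1))
  dm2 <- compute_jsw(probe2, tri_mesh, 1L)
  expect_equal(dm2$jsw_mm, oracle_point_tri_dist(c(5, 0, 1), tri_mesh$vertices, 800),
               tolerance = 5e-3)
  expect_error(compute_jsw(top, bottom, integer(0)), "non-empty")
})

test_that("imposed narrowing reduces the mean joint space width one-to-one", {
  l <- generate_limb(limb_params(hka_deg = 181, tibial_slope_deg = 3), seed = 6)
  roi <- l$template$femur_roi
  d0 <- compute_jsw(l$femur, l$tibia, roi)
  na <- impose_arthritis(l, narrowing_mm = 2)$limb
  d1 <- compute_jsw(na$femur, na$tibia, roi)
  expect_equal(mean(d0$jsw_mm) - mean(d1$jsw_mm), 2, tolerance = 0.1 / 2)
})

test_that("normalization and inversion map joint space to wear", {
  expect_equal(normalize_invert(c(0, 8, 4), reference_mm = 8), c(1, 0, 0.5))
  jsw <- seq(0, 8, by = 0.5)
  w <- normalize_invert(jsw, 8)
  expect_true(all(diff(w) < 0)) # strictly decreasing on [0, reference]
  expect_true(all(w >= 0 & w <= 1))
  expect_error(normalize_invert(c(1, -0.1), 8), "negative")
  expect_error(normalize_invert(c(1, 2), 0), "reference_mm")
})

test_that("flattening a planar square patch is the identity map", {
  patch <- make_plane(9)
  par <- conformal_flatten(patch, orient_axes = list(medial = c(-1, 0, 0),
                                                     anterior = c(0, -1, 0)))
  expect_lt(max(abs(par$uv - patch$vertices[, 1:2])), 1e-8)
  expect_identical(par$n_flipped, 0L)
})

test_that("flattening is intrinsic: rigid motion leaves the chart unchanged", {
  patch <- make_cap(20, 8)
  par0 <- conformal_flatten(patch)
  R <- kneewear:::rotation_matrix(c(2, -1, 1), 47)
  moved <- triangle_mesh(sweep(patch$vertices %*% t(R), 2, c(5, 6, -2), "+"),
                         patch$faces)
  par1 <- conformal_flatten(moved)
  expect_lt(max(abs(par0$uv - par1$uv)), 1e-8)
})

test_that("curved patches flatten without flips and with bounded distortion", {
  pr <- conformal_flatten(make_cap(24, 10))
  expect_identical(pr$n_flipped, 0L)
  expect_true(is.finite(pr$max_qc) && pr$max_qc < 20)
  # boundary vertices land on the square perimeter, order preserved
  buv <- pr$uv[pr$boundary, ]
  on_perimeter <- pmin(pmin(buv[, 1], 1 - buv[, 1]),
                       pmin(buv[, 2], 1 - buv[, 2])) < 1e-9
  expect_true(all(on_perimeter))
  ang <- atan2(buv[, 2] - 0.5, buv[, 1] - 0.5)
  d <- diff(ang)
  d[d > pi] <- d[d > pi] - 2 * pi
  d[d < -pi] <- d[d < -pi] + 2 * pi
  expect_true(all(d > 0) || all(d < 0)) # bijective traversal of the perimeter
  # closed surface (no boundary) rejected
  ball <- generate_limb(limb_params(180), seed = 1)$femur
  expect_error(conformal_flatten(ball), "boundary|topology")
})

test_that("left-right mirroring commutes with the oriented chart", {
  l <- generate_limb(limb_params(182, tibial_slope_deg = 2), seed = 12)
  fl <- kneewear:::flatten_femoral_roi(l)
  mirrored <- l
  mv <- l$femur$vertices
  mv[, 1] <- -mv[, 1]
  mirrored$femur <- triangle_mesh(mv, l$femur$faces[, c(1, 3, 2)])
  patch_m <- kneewear:::submesh(mirrored$femur, l$template$femur_roi)
  par_m <- conformal_flatten(patch_m, orient_axes = list(medial = c(-1, 0, 0),
                                                         anterior = c(0, 1, 0)))
  # mirrored geometry with mirrored axis labels reproduces the same chart
  expect_lt(max(abs(par_m$uv - fl$param$uv)), 1e-6)
})

test_that("rasterization reproduces constants, ramps and smooth fields", {
  patch <- make_plane(15)
  par <- conformal_flatten(patch, orient_axes = list(medial = c(-1, 0, 0),
                                                     anterior = c(0, -1, 0)))
  img_c <- rasterize(par, rep(0.7, nrow(par$uv)), size = 32)
  expect_lt(max(abs(img_c$pixels - 0.7)), 1e-6)
  expect_identical(rasterize(par, par$uv[, 1], size = 128)$size, 128L)
  img_r <- rasterize(par, par$uv[, 1], size = 32)
  ctr <- (seq_len(32) - 0.5) / 32
  expect_lt(max(abs(sweep(img_r$pixels, 2, ctr))), 0.01)
  # round trip through a dense smooth field
  f <- function(u, v) 0.5 + 0.3 * sin(2 * pi * u) * cos(pi * v) * 0.8
  vals <- pmin(1, pmax(0, f(par$uv[, 1], par$uv[, 2])))
  img_s <- rasterize(par, vals, size = 64)
  back <- sample_wear_image(img_s, par$uv[, 1], par$uv[, 2])
  expect_lt(max(abs(back - vals)), 0.02)
  expect_error(rasterize(par$uv[1:3, ], c(0.1, 0.2, 0.3)), "at least 4")
})

test_that("stronger narrowing darkens the wear image monotonically", {
  l <- generate_limb(limb_params(180), seed = 5)
  roi <- l$template$femur_roi
  chart <- kneewear:::flatten_femoral_roi(l)
  means <- vapply(c(0, 1.5, 3), function(nr) {
    limb <- if (nr > 0) impose_arthritis(l, narrowing_mm = nr)$limb else l
    w <- normalize_invert(compute_jsw(limb$femur, limb$tibia, roi), 8)
    img <- rasterize(chart$param, w, size = 32)
    mean(img$pixels[img$mask])
  }, 0)
  expect_true(all(diff(means) > 0))
})
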