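# Robust model-to-mesh fitting and virtual-twin reassembly.

test_that("fitting the model mean returns null coefficients and no outliers", {
  sm <- small_models()
  m <- sm$models$femur
  target <- triangle_mesh(m$mean, sm$models$articulated$template$faces)
  f <- robust_fit(m, target)
  expect_lt(sqrt(sum(f$coefficients^2)), 1e-4)
  expect_identical(sum(f$outlier_mask), 0L)
  expect_true(f$converged)
})

test_that("known-coefficient samples are recovered within 1 percent", {
  sm <- small_models()
  art <- sm$models$articulated
  co <- sample_shape_coefficients(art, 3, seed = 91)
  for (i in 1:3) {
    truth <- limb_from_coefficients(art, co[i, ])
    cf <- as.numeric(t(sm$models$femur$modes) %*%
                       (as.vector(truth$femur$vertices) -
                          as.vector(sm$models$femur$mean)))
    f <- robust_fit(sm$models$femur, truth$femur)
    expect_lt(sqrt(sum((f$coefficients - cf)^2)) / sqrt(sum(cf^2)), 0.01)
  }
})

test_that("outlier bumps are flagged and suppressed in the coefficients", {
  sm <- small_models()
  art <- sm$models$articulated
  truth <- limb_from_coefficients(art, sample_shape_coefficients(art, 1, seed = 13)[1, ])
  omap <- osteophyte_map(truth, fraction = 0.05, magnitude_mm = 3, seed = 5)
  deformed <- impose_arthritis(truth, outlier_map = omap)$limb
  f <- robust_fit(sm$models$femur, deformed$femur)
  bumped <- which(omap$femur > 1)  # core of the bumps
  expect_gt(mean(f$outlier_mask[bumped]), 0.9)
  # robust coefficients beat the non-robust least-squares fit (identical
  # pipeline with outlier rejection disabled)
  ctrue <- as.numeric(t(sm$models$femur$modes) %*%
                        (as.vector(truth$femur$vertices) -
                           as.vector(sm$models$femur$mean)))
  f_lsq <- robust_fit(sm$models$femur, deformed$femur, outlier_sd = Inf)
  err_rob <- sqrt(sum((f$coefficients - ctrue)^2))
  err_lsq <- sqrt(sum((f_lsq$coefficients - ctrue)^2))
  expect_lt(err_rob, err_lsq)
})

test_that("with infinite outlier threshold the fit is a plain projection", {
  sm <- small_models()
  art <- sm$models$articulated
  co <- sample_shape_coefficients(art, 10, seed = 29)
  for (i in 1:10) {
    truth <- limb_from_coefficients(art, co[i, ])
    f <- robust_fit(sm$models$tibia, truth$tibia, outlier_sd = Inf)
    # oracle: direct orthonormal projection with known correspondence
    cp <- as.numeric(t(sm$models$tibia$modes) %*%
                       (as.vector(truth$tibia$vertices) -
                          as.vector(sm$models$tibia$mean)))
    surf_fit <- sweep(kneewear:::model_instance(sm$models$tibia,
                                                f$coefficients) %*% t(f$R),
                      2, f$t, "+")
    surf_proj <- kneewear:::model_instance(sm$models$tibia, cp)
    expect_lt(sqrt(mean(rowSums((surf_fit - surf_proj)^2))), 0.2)
    expect_identical(sum(f$outlier_mask), 0L)
  }
})

test_that("inlier RMS is non-increasing across iterations on clean targets", {
  sm <- small_models()
  art <- sm$models$articulated
  truth <- limb_from_coefficients(art, sample_shape_coefficients(art, 1, seed = 3)[1, ])
  f <- robust_fit(sm$models$femur, truth$femur, outlier_sd = Inf)
  expect_true(all(diff(f$rms_history) <= 1e-6))
})

test_that("twin reconstruction round-trips healthy samples and removes rigid disease misalignment", {
  sm <- small_models()
  art <- sm$models$articulated
  truth <- limb_from_coefficients(art, sample_shape_coefficients(art, 1, seed = 57)[1, ])
  ff <- robust_fit(sm$models$femur, truth$femur)
  tf <- robust_fit(sm$models$tibia, truth$tibia)
  twin <- reconstruct_twin(ff, tf, art, sm$models$femur, sm$models$tibia)
  X <- kneewear:::limb_stack(twin); Y <- kneewear:::limb_stack(truth)
  expect_lt(sqrt(mean(rowSums((X - Y)^2))), 0.1)
  # +5 degrees rigid varus: twin HKA returns to the pre-deformation value
  hka0 <- measure_alignment(truth)$hka_deg
  dis <- impose_arthritis(truth, extra_varus_deg = 5)$limb
  expect_gt(measure_alignment(dis)$hka_deg, hka0 + 4.9)
  ff2 <- robust_fit(sm$models$femur, dis$femur)
  tf2 <- robust_fit(sm$models$tibia, dis$tibia)
  twin2 <- reconstruct_twin(ff2, tf2, art, sm$models$femur, sm$models$tibia)
  expect_lt(abs(measure_alignment(twin2)$hka_deg - hka0), 2)
  # degenerate articulated model with a single pose: twin equals that pose
  l1 <- sm$limbs[[1]]
  m1 <- build_limb_models(list(l1, l1, l1), variance_kept = 1)
  f1 <- robust_fit(m1$femur, l1$femur)
  t1 <- robust_fit(m1$tibia, l1$tibia)
  tw1 <- reconstruct_twin(f1, t1, m1$articulated, m1$femur, m1$tibia)
  aligned <- kneewear:::kabsch(kneewear:::limb_stack(tw1), kneewear:::limb_stack(l1))
  rec <- sweep(kneewear:::limb_stack(tw1) %*% t(aligned$R), 2, aligned$t, "+")
  expect_lt(max(abs(rec - kneewear:::limb_stack(l1))), 1e-6)
  # dimension mismatch rejected
  art_bad <- art
  art_bad$n_vertices <- art$n_vertices - 2L
  expect_error(reconstruct_twin(ff, tf, art_bad, sm$models$femur,
                                sm$models$tibia), "inconsistent model dimensions")
})

test_that("alignment measurement follows the inclusive varus/valgus thresholds", {
  expect_identical(classify_alignment(183), "varus")
  expect_identical(classify_alignment(177), "valgus")
  expect_identical(classify_alignment(180), "neutral")
  expect_identical(classify_alignment(182.99), "neutral")
  # collinear landmarks: neutral 180
  limb <- structure(list(landmarks = list(hip = c(0, 0, 400), knee = c(0, 0, 0),
                                          ankle = c(0, 0, -380),
                                          knee_medial = c(30, 0, 0)),
                         params = NULL), class = "articulated_limb")
  a <- measure_alignment(limb)
  expect_equal(a$hka_deg, 180)
  expect_identical(a$varus_valgus_class, "neutral")
  # constructed 174-degree landmark set measured to numerical precision
  dev <- -6
  d <- dev / 2 * pi / 180
  limb174 <- structure(list(landmarks = list(
    hip = 400 * c(sin(d), 0, cos(d)), knee = c(0, 0, 0),
    ankle = 380 * c(sin(d), 0, -cos(d)), knee_medial = c(30, 0, 0)),
    params = NULL), class = "articulated_limb")
  a174 <- measure_alignment(limb174)
  expect_equal(a174$hka_deg, 174, tolerance = 1e-6 / 174)
  expect_identical(a174$varus_valgus_class, "valgus")
  # rigid invariance of the measurement
  R <- kneewear:::rotation_matrix(c(1, 2, 3), 33)
  shift <- c(12, -7, 5)
  moved <- limb174
  moved$landmarks <- lapply(limb174$landmarks, function(p) as.numeric(R %*% p) + shift)
  expect_equal(measure_alignment(moved)$hka_deg, a174$hka_deg, tolerance = 1e-9)
  # coincident landmarks rejected
  bad <- limb174
  bad$landmarks$hip <- bad$landmarks$knee
  expect_error(measure_alignment(bad), "coincident|degenerate")
})
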