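# Synthetic cohort generator: parametric limbs, arthritic degradation, wear
# fields and the study roster.

test_that("limb generation honours the requested HKA angle", {
  l0 <- generate_limb(limb_params(hka_deg = 180), seed = 1, shape_noise_mm = 0)
  lm <- l0$landmarks
  expect_equal(oracle_hka(lm$hip, lm$knee, lm$ankle, lm$knee_medial), 180,
               tolerance = 0.1 / 180)
  # valgus construction classified per the inclusive 177-degree rule
  l1 <- generate_limb(limb_params(hka_deg = 172), seed = 2)
  a <- measure_alignment(l1)
  expect_lt(abs(a$hka_deg - 172), 0.1)
  expect_identical(a$varus_valgus_class, "valgus")
  # cohort-level: measured HKA unbiased under parameter sampling
  hka_in <- withr::with_seed(31, rnorm(100, 180, 3))
  hka_in <- pmin(pmax(hka_in, 161), 199)
  meas <- vapply(seq_along(hka_in), function(i) {
    l <- generate_limb(limb_params(hka_deg = hka_in[i]), seed = 100 + i)
    lm <- l$landmarks
    oracle_hka(lm$hip, lm$knee, lm$ankle, lm$knee_medial)
  }, 0)
  expect_lt(max(abs(meas - hka_in)), 0.1)
  se <- sd(meas) / sqrt(length(meas))
  expect_lt(abs(mean(meas) - 180), max(3 * se, abs(mean(hka_in) - 180) + 3 * se))
})

test_that("limb generation is seed-deterministic and validates inputs", {
  p <- limb_params(hka_deg = 184, tibial_slope_deg = 3)
  a <- generate_limb(p, seed = 7)
  b <- generate_limb(p, seed = 7)
  expect_identical(a$femur$vertices, b$femur$vertices)
  expect_identical(a$tibia$vertices, b$tibia$vertices)
  c <- generate_limb(p, seed = 8)
  expect_false(identical(a$femur$vertices, c$femur$vertices))
  expect_error(limb_params(hka_deg = NaN), "non-finite")
  expect_error(limb_params(scale_mm = -1), "scale_mm")
  expect_error(limb_params(hka_deg = 150), "160")
  expect_error(generate_limb(p, resolution = 150), "at least 200")
})

test_that("arthritic degradation is exact, recorded, and reversible", {
  l <- generate_limb(limb_params(hka_deg = 183, tibial_slope_deg = 2), seed = 3)
  # identity: nothing imposed
  id <- impose_arthritis(l)
  expect_identical(id$limb$femur$vertices, l$femur$vertices)
  expect_identical(id$limb$tibia$vertices, l$tibia$vertices)
  # imposed rigid varus shifts measured HKA by exactly the requested angle
  lm <- l$landmarks
  hka0 <- oracle_hka(lm$hip, lm$knee, lm$ankle, lm$knee_medial)
  va <- impose_arthritis(l, extra_varus_deg = 4)
  lmv <- va$limb$landmarks
  expect_lt(abs(oracle_hka(lmv$hip, lmv$knee, lmv$ankle, lmv$knee_medial) -
                  (hka0 + 4)), 0.1)
  # osteophyte bumps: max displacement equals the requested magnitude
  omap <- osteophyte_map(l, fraction = 0.05, magnitude_mm = 3, seed = 9)
  expect_equal(max(c(omap$femur, omap$tibia)), 3)
  ob <- impose_arthritis(l, outlier_map = omap)
  disp <- sqrt(rowSums((ob$limb$femur$vertices - l$femur$vertices)^2))
  expect_equal(max(disp), max(omap$femur), tolerance = 1e-10)
  # full deformation subtracts back to machine precision
  full <- impose_arthritis(l, outlier_map = omap, narrowing_mm = 1.5,
                           extra_varus_deg = -3)
  back <- revert_arthritis(full$limb, full$record)
  expect_lt(max(abs(back$femur$vertices - l$femur$vertices)), 1e-9)
  expect_lt(max(abs(back$tibia$vertices - l$tibia$vertices)), 1e-9)
  # non-physical narrowing rejected
  expect_error(impose_arthritis(l, narrowing_mm = 50), "interpenetration")
  expect_error(impose_arthritis(l, narrowing_mm = -1), ">= 0")
})

test_that("wear templates form exact mirror pairs with the expected layout", {
  u <- runif(200); v <- runif(200)
  expect_identical(wear_template(u, v, "lateral"), wear_template(1 - u, v, "medial"))
  expect_identical(wear_template(u, v, "posteromedial"),
                   wear_template(u, 1 - v, "anteromedial"))
  # pure medial field: maximal on the medial half, near zero laterally
  img <- generate_wear_field(c(1, 0, 0, 0, 0), size = 32)
  med <- mean(img$pixels[, 1:16]); lat <- mean(img$pixels[, 17:32])
  expect_gt(med, 10 * lat)
  expect_lt(max(img$pixels[, 28:32]), 0.02)
  # mirroring a pure-medial image gives the pure-lateral image
  lat_img <- generate_wear_field(c(0, 1, 0, 0, 0), size = 32)
  expect_equal(flip_lr(img)$pixels, lat_img$pixels, tolerance = 1e-12)
})

test_that("wear cohort reproduces the class mixture within binomial bounds", {
  coh <- generate_wear_cohort(500, seed = 21)
  spec <- default_wear_classes()
  tab <- table(factor(coh$labels, levels = spec$class))
  for (k in seq_len(nrow(spec))) {
    p <- spec$prob[k]
    lo <- qbinom(0.025, 500, p); hi <- qbinom(0.975, 500, p)
    expect_true(tab[k] >= lo && tab[k] <= hi,
                label = sprintf("class %s count %d in [%d, %d]",
                                spec$class[k], tab[k], lo, hi))
  }
  # determinism of fields given (weights, seed)
  coh2 <- generate_wear_cohort(500, seed = 21)
  expect_identical(coh$images[[5]]$pixels, coh2$images[[5]]$pixels)
  # degenerate single-class zero-variance spec still generates, with warning
  degen <- data.frame(class = "only", prob = 1, w_medial = 0.5, w_lateral = 0,
                      w_anteromedial = 0, w_posteromedial = 0, w_spine = 0, sd = 0)
  expect_warning(generate_wear_cohort(3, class_spec = degen, seed = 1),
                 "degenerate")
})

test_that("roster tallies and exclusion filtering match the study cohort", {
  roster <- generate_roster()
  expect_identical(nrow(roster), 933L)
  expect_identical(sum(roster$sex == "female"), 460L)
  expect_identical(sum(roster$sex == "male"), 473L)
  flags <- roster[c("hip_prosthesis", "knee_prosthesis", "osteosynthesis",
                    "segmentation_error")]
  expect_true(all(rowSums(flags) <= 1)) # mutually exclusive reasons
  expect_identical(sum(Reduce(`|`, flags[roster$sex == "male", ])), 74L)
  ex <- apply_exclusions(roster)
  expect_identical(ex$n_included, 798L)
  expect_identical(sum(ex$included$sex == "female"), 399L)
  expect_identical(sum(ex$included$sex == "male"), 399L)
  expect_identical(ex$counts["female", "hip_prosthesis"], 40L)
  expect_identical(ex$counts["male", "osteosynthesis"], 15L)
  # partition: included + excluded = total
  expect_identical(ex$n_included + ex$n_excluded, nrow(roster))
  # degenerate inputs
  empty <- apply_exclusions(roster[0, ])
  expect_identical(empty$n_included, 0L)
  clean <- roster[!Reduce(`|`, flags), ][1:10, ]
  expect_identical(apply_exclusions(clean)$n_included, 10L)
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  write_roster_csv(roster, path)
  expect_identical(read_roster_csv(path)$hip_prosthesis, roster$hip_prosthesis)
})
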