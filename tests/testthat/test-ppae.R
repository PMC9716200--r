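# Principal polynomial autoencoder: augmentation, training, polynomial
# bottleneck, transforms and component interpretation.

test_that("mirror augmentation quadruples the set and is involutive", {
  coh <- generate_wear_cohort(12, seed = 3, size = 16)
  aug <- augment(coh$images)
  expect_identical(length(aug), 48L)
  im <- coh$images[[1]]
  expect_identical(flip_lr(flip_lr(im))$pixels, im$pixels)
  expect_identical(flip_ap(flip_ap(im))$pixels, im$pixels)
  # per-case contiguous groups: (orig, LR, AP, LR+AP)
  expect_identical(aug[[5]]$pixels, coh$images[[2]]$pixels)
  expect_identical(aug[[6]]$pixels, flip_lr(coh$images[[2]])$pixels)
  # a doubly symmetric image yields four identical copies
  sym <- wear_image(matrix(0.4, 16, 16))
  a4 <- augment(list(sym))
  for (j in 2:4) expect_identical(a4[[j]]$pixels, a4[[1]]$pixels)
})

test_that("training beats the mean-image baseline and is reproducible", {
  coh <- generate_wear_cohort(200, seed = 14, size = 16)
  m <- train_ppae(coh$images, latent_dim = 8, hidden_dim = 32, epochs = 250,
                  seed = 5)
  X <- kneewear:::images_to_matrix(coh$images)
  # oracle baseline: predict the mean image for every case
  baseline <- mean(sweep(X, 2, colMeans(X))^2)
  recon <- kneewear:::ppae_decode(m, kneewear:::ppae_encode(m, coh$images))
  expect_lt(mean((recon - X)^2), 0.5 * baseline)
  expect_lt(m$final_loss, m$loss_history[1])
  m2 <- train_ppae(coh$images, latent_dim = 8, hidden_dim = 32, epochs = 250,
                   seed = 5)
  expect_identical(m$weights, m2$weights)
  expect_error(train_ppae(coh$images[1:10], latent_dim = 8), "at least")
})

test_that("degree-1 bottleneck equals plain SVD scores", {
  coh <- generate_factor_wear_cohort(120, size = 16, seed = 8)
  m <- train_ppae(coh$images, latent_dim = 6, hidden_dim = 32, epochs = 200,
                  seed = 2)
  pb <- fit_polynomial_bottleneck(m, coh$images, degree = 1)
  Z <- kneewear:::ppae_encode(m, coh$images)
  Zc <- sweep(Z, 2, colMeans(Z))
  TT <- Zc %*% svd(Zc)$v
  ord <- pb$model$bottleneck$order
  expect_lt(max(abs(abs(pb$components$scores) - abs(TT[, ord]))), 1e-8)
})

test_that("component scores are exactly decorrelated with descending variance", {
  coh <- generate_factor_wear_cohort(150, size = 16, seed = 18)
  m <- train_ppae(coh$images, latent_dim = 8, hidden_dim = 32, epochs = 250,
                  seed = 6)
  pb <- fit_polynomial_bottleneck(m, coh$images, degree = 2)
  cmp <- pb$components
  cc <- cor(cmp$scores)
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.05)
  expect_true(all(diff(cmp$variance_fraction) <= 1e-12))
  expect_true(all(cmp$variance_fraction >= 0))
  expect_true(all(diff(cmp$cumulative_fraction) >= -1e-12))
  expect_lte(max(cmp$cumulative_fraction), 1 + 1e-9)
  # variance fractions invariant to relabelling (permutation) of cases
  perm <- withr::with_seed(4, sample(length(coh$images)))
  pb2 <- fit_polynomial_bottleneck(m, coh$images[perm], degree = 2)
  expect_equal(pb2$components$variance_fraction, cmp$variance_fraction,
               tolerance = 1e-9)
})

test_that("transform is consistent, centred and size-checked", {
  coh <- generate_factor_wear_cohort(120, size = 16, seed = 28)
  # linear chain at degree 1: the training-set mean image maps to null scores
  m <- train_ppae(coh$images, latent_dim = 4, hidden_dim = 16,
                  activation = "linear", l2_weight = 0, epochs = 1500, seed = 3)
  pb <- fit_polynomial_bottleneck(m, coh$images, degree = 1)
  X <- kneewear:::images_to_matrix(coh$images)
  mean_img <- wear_image(matrix(colMeans(X), 16, 16))
  s0 <- ppae_transform(pb$model, mean_img)
  expect_true(all(abs(s0) < 0.1 * pb$model$bottleneck$component_sd))
  # transform of training images reproduces stored training scores
  tr <- ppae_transform(pb$model, coh$images[1:7])
  expect_lt(max(abs(tr - pb$components$scores[1:7, ])), 1e-6)
  expect_error(ppae_transform(pb$model, wear_image(matrix(0.5, 32, 32))),
               "size")
  # pure-medial vs pure-lateral images score with opposite signs on the
  # medio-lateral component
  med <- generate_wear_field(c(0.9, 0, 0, 0, 0), size = 16)
  lat <- generate_wear_field(c(0, 0.9, 0, 0, 0), size = 16)
  ml <- coh$weights[, "medial"] - coh$weights[, "lateral"]
  ci <- which.max(abs(cor(pb$components$scores, ml)))
  s_med <- ppae_transform(pb$model, med)[1, ci]
  s_lat <- ppae_transform(pb$model, lat)[1, ci]
  expect_lt(s_med * s_lat, 0)
})

test_that("component excursions decode to interpretable, bounded images", {
  coh <- generate_factor_wear_cohort(200, size = 16, seed = 38)
  m <- train_ppae(coh$images, latent_dim = 8, hidden_dim = 32, epochs = 350,
                  seed = 7)
  pb <- fit_polynomial_bottleneck(m, coh$images, degree = 2)
  i0 <- component_wear_interpretation(pb$model, 1, sd_range = 0)
  expect_identical(i0$plus$pixels, i0$minus$pixels)
  ml <- coh$weights[, "medial"] - coh$weights[, "lateral"]
  ci <- which.max(abs(cor(pb$components$scores, ml)))
  sgn <- sign(cor(pb$components$scores[, ci], coh$weights[, "medial"]))
  ip <- component_wear_interpretation(pb$model, ci, sd_range = 2)
  img <- if (sgn > 0) ip$plus else ip$minus
  expect_gt(mean(img$pixels[, 1:8]), mean(img$pixels[, 9:16]))
  for (side in list(ip$plus, ip$minus)) {
    expect_true(all(side$pixels >= 0 & side$pixels <= 1))
  }
  expect_error(component_wear_interpretation(pb$model, 99), "out of range")
})

test_that("mirror augmentation induces sign-equivariant medio-lateral scores", {
  coh <- generate_factor_wear_cohort(120, size = 16, seed = 48)
  m <- train_ppae(augment(coh$images), latent_dim = 6, hidden_dim = 32,
                  epochs = 300, seed = 8)
  pb <- fit_polynomial_bottleneck(m, augment(coh$images), degree = 2)
  S <- ppae_transform(pb$model, coh$images)
  Sf <- ppae_transform(pb$model, lapply(coh$images, flip_lr))
  ml <- coh$weights[, "medial"] - coh$weights[, "lateral"]
  ci <- which.max(abs(cor(S, ml)))
  expect_lt(cor(S[, ci], Sf[, ci]), -0.7) # antisymmetric under LR mirror
})
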