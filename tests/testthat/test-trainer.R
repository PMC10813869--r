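test_that("fold plans partition impacted samples evenly, controls always train", {
  fp <- make_cv_folds(1:74, 75:123, k = 15, seed = 1)
  sizes <- lengths(lapply(fp, `[[`, "test_ids"))
  expect_equal(sort(sizes), c(4, rep(5, 14)))

  # test sets are disjoint and their union is exactly the impacted set
  all_test <- unlist(lapply(fp, `[[`, "test_ids"))
  expect_equal(sort(all_test), 1:74)
  expect_equal(anyDuplicated(all_test), 0)

  for (fold in fp) {
    expect_true(all(75:123 %in% fold$train_ids))
    expect_length(intersect(fold$train_ids, fold$test_ids), 0)
    expect_equal(sort(c(setdiff(fold$train_ids, 75:123), fold$test_ids)), 1:74)
  }

  expect_equal(lengths(lapply(make_cv_folds(1:15, k = 15), `[[`, "test_ids")),
               rep(1L, 15))
  expect_equal(sort(lengths(lapply(make_cv_folds(1:16, k = 15), `[[`, "test_ids"))),
               c(rep(1L, 14), 2L))

  expect_error(make_cv_folds(1:10, k = 0), "k must be")
  expect_error(make_cv_folds(1:10, k = 11), "exceeds")

  expect_identical(make_cv_folds(1:20, k = 4, seed = 5),
                   make_cv_folds(1:20, k = 4, seed = 5))
})

make_tiny_sample <- function(seed, n = 16L, p = 16L) {
  set.seed(seed)
  vol <- array(runif(n * p * p, -1, 1), c(n, p, p))
  list(pan = matrix(runif(n * p, -1, 1), n, p), vol = vol)
}

test_that("a zero learning rate leaves parameters untouched", {
  cfg <- generator_config(patch_side = 16, base_channels = 2, n_levels = 2,
                          seed = 4)
  fit <- train(list(make_tiny_sample(1)), cfg, cfg,
               train_config(learning_rate = 0, steps = 3, seed = 2))
  expect_identical(fit$generator$params, build_generator(cfg)$params)
  expect_identical(fit$discriminator$params, build_discriminator(cfg)$params)
})

test_that("training runs are bit-identical under the same seed", {
  cfg <- generator_config(patch_side = 16, base_channels = 2, n_levels = 2,
                          seed = 4)
  ds <- list(make_tiny_sample(1), make_tiny_sample(2))
  tc <- train_config(learning_rate = 1e-3, steps = 6, seed = 31)
  f1 <- train(ds, cfg, cfg, tc)
  f2 <- train(ds, cfg, cfg, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$generator$params, f2$generator$params)
  # history logs every loss component per step
  expect_equal(nrow(f1$history), 6)
  expect_true(all(c("loss_d", "loss_g_adv", "loss_voxel", "loss_projection",
                    "loss_g_total") %in% names(f1$history)))
  expect_true(all(is.finite(as.matrix(f1$history))))
})

test_that("training does not mutate the input dataset", {
  ds <- list(make_tiny_sample(7))
  snapshot <- lapply(ds, function(s) list(pan = s$pan + 0, vol = s$vol + 0))
  cfg <- generator_config(patch_side = 16, base_channels = 2, n_levels = 2,
                          seed = 4)
  train(ds, cfg, cfg, train_config(learning_rate = 1e-3, steps = 2, seed = 1))
  expect_identical(ds[[1]]$pan, snapshot[[1]]$pan)
  expect_identical(ds[[1]]$vol, snapshot[[1]]$vol)
})

test_that("supervised training (lambda1 = 0) descends the voxel loss", {
  s <- generate_phantom(phantom_spec(width_n = 16, side_p = 16,
                                     vertical_offset_mm = 0, seed = 21))
  cfg <- generator_config(patch_side = 16, base_channels = 4, n_levels = 2,
                          seed = 1)
  fit <- train(list(s), cfg, cfg,
               train_config(learning_rate = 2e-3, steps = 600,
                            weights = loss_weights(0, 1, 0), seed = 5))
  lv <- fit$history$loss_voxel
  # non-increasing over any 200-step window, allowing <= 5% transients
  lag <- 200
  viol <- mean(lv[(lag + 1):length(lv)] > lv[1:(length(lv) - lag)])
  expect_lte(viol, 0.05)
  expect_lt(lv[length(lv)], lv[1])
  # adversarial losses are not computed in the supervised regime
  expect_true(all(is.na(fit$history$loss_d)))
})

test_that("training rejects invalid configurations", {
  s <- make_tiny_sample(1)
  cfg <- generator_config(patch_side = 16, base_channels = 2, n_levels = 2)
  expect_error(train(list(), cfg, cfg), "empty")
  expect_error(train_config(learning_rate = -1), "learning_rate")
  expect_error(train_config(beta1 = 1), "betas")
  expect_error(train_config(d_updates_per_g = 0), "d_updates_per_g")
  bad <- list(pan = matrix(0, 16, 8), vol = array(0, c(16, 8, 8)))
  expect_error(train(list(bad), cfg, cfg, train_config()), "patch side")
})

test_that("reconstruct_volume tiles the generator across the panoramic", {
  # an oracle generator that returns the true 3D patch for each 2D patch
  set.seed(41)
  n <- 40L; p <- 16L
  truth <- rand_vol(n, p, seed = 41)
  pan <- matrix(runif(n * p, -1, 1), n, p)
  lookup_starts <- pan2vol:::patch_starts(n, p %/% 2L)
  key_patches <- lapply(lookup_starts, function(st) {
    w <- min(p, n - st)
    xp <- matrix(0, p, p)
    xp[seq_len(w), ] <- pan[st + seq_len(w), , drop = FALSE]
    xp
  })
  truth_patches <- extract_patches(truth, p, p %/% 2L)$patches
  oracle_gen <- function(xp) {
    for (i in seq_along(key_patches)) {
      if (identical(xp, key_patches[[i]])) return(truth_patches[[i]])
    }
    stop("unexpected patch")
  }
  rec_full <- reconstruct_volume(pan, oracle_gen, patch_side = p, stride = p)
  rec_half <- reconstruct_volume(pan, oracle_gen, patch_side = p, stride = p %/% 2L)
  expect_identical(unclass(rec_full), unclass(truth), ignore_attr = TRUE)
  expect_identical(unclass(rec_half), unclass(truth), ignore_attr = TRUE)
  expect_equal(dim(rec_full), c(n, p, p))

  expect_error(reconstruct_volume(matrix(0, 20, 8), oracle_gen, patch_side = p),
               "height")

  # a trained generator object also slots in, with the width contract
  gen <- build_generator(generator_config(patch_side = 16, base_channels = 2,
                                          n_levels = 2, seed = 2))
  rec <- reconstruct_volume(panoramic(pan), gen)
  expect_equal(dim(rec), c(n, p, p))
})
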