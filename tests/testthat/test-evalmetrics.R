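test_that("SSIM is 1 on identical inputs and symmetric to 1e-12", {
  set.seed(1)
  a <- array(rnorm(16^3), c(16, 16, 16))
  b <- a + array(rnorm(16^3, sd = 0.5), c(16, 16, 16))
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_error(ssim(a, array(0, c(8, 8, 8))), "shape")
  expect_error(ssim(a, b, window = 20), "window")
})

test_that("distinct constant volumes reduce to the luminance term", {
  c1 <- array(0.2, c(10, 10, 10))
  c2 <- array(0.5, c(10, 10, 10))
  C1 <- (0.01 * 2)^2
  lum <- (2 * 0.2 * 0.5 + C1) / (0.2^2 + 0.5^2 + C1)
  expect_equal(ssim(c1, c2), lum, tolerance = 1e-12)
  expect_lt(ssim(c1, c2), 1)
})

test_that("SSIM agrees with a direct per-window oracle", {
  set.seed(2)
  a <- array(runif(12^3, -1, 1), c(12, 12, 12))
  b <- a + array(rnorm(12^3, sd = 0.3), c(12, 12, 12))
  expect_equal(ssim(a, b, window = 5), ssim_oracle(a, b, w = 5),
               tolerance = 1e-6)
})

test_that("SSIM decreases monotonically with added noise", {
  set.seed(3)
  base <- array(runif(16^3, -1, 1), c(16, 16, 16))
  sds <- c(0.05, 0.1, 0.2, 0.4)
  means <- vapply(sds, function(s) {
    mean(vapply(1:20, function(i) {
      set.seed(1000 + i)
      ssim(base, base + array(rnorm(16^3, sd = s), dim(base)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("buccolingual classification follows the depth-thirds rule", {
  p <- 24L
  mk <- function(ap_voxels) {
    vol <- array(0, c(8, p, p))
    roi <- array(FALSE, c(8, p, p))
    for (a in ap_voxels) {
      vol[4, a, 12] <- 1
      roi[4, a, 12] <- TRUE
    }
    list(vol = vol, roi = roi)
  }
  # centroid fractions 0.1, 0.5, 0.9
  expect_equal(classify_buccolingual(mk(2:3)$vol, mk(2:3)$roi), "buccal")
  expect_equal(classify_buccolingual(mk(12:13)$vol, mk(12:13)$roi), "middle")
  expect_equal(classify_buccolingual(mk(22:23)$vol, mk(22:23)$roi), "lingual")
  # f exactly 1/3 (centroid 8.5 of 24) is middle under the half-open rule
  x <- mk(8:9)
  expect_equal(classify_buccolingual(x$vol, x$roi), "middle")
  expect_error(classify_buccolingual(array(0, c(4, 4, 4)),
                                     array(FALSE, c(4, 4, 4))), "empty ROI")
})

test_that("mesiodistal classification compares midline distances with mesial ties", {
  n <- 41L
  mk <- function(rl) {
    vol <- array(0, c(n, 8, 8))
    roi <- array(FALSE, c(n, 8, 8))
    vol[rl, 4, 4] <- 1
    roi[rl, 4, 4] <- TRUE
    list(vol = vol, roi = roi)
  }
  slot <- 5
  x <- mk(15)  # 10 voxels closer to the midline (21)
  expect_equal(classify_mesiodistal(x$vol, x$roi, slot), "mesial")
  x <- mk(3)   # farther from the midline than the slot
  expect_equal(classify_mesiodistal(x$vol, x$roi, slot), "distal")
  x <- mk(5)   # exactly at the slot: tie goes to mesial
  expect_equal(classify_mesiodistal(x$vol, x$roi, slot), "mesial")
  # mirrored slot on the right half behaves symmetrically
  x <- mk(30)
  expect_equal(classify_mesiodistal(x$vol, x$roi, 37), "mesial")
})

test_that("confusion-table accuracy uses half-up percentages", {
  t2 <- confusion_table(c("buccal", "middle", "lingual"),
                        totals = c(36, 12, 26), correct = c(23, 4, 3))
  acc <- accuracy_from_table(t2)
  expect_equal(unname(acc$per_class_pct), c(64L, 33L, 12L))
  expect_equal(acc$overall, 0.41)

  perfect <- confusion_table(c("a", "b"), c(10, 5), c(10, 5))
  pacc <- accuracy_from_table(perfect)
  expect_equal(unname(pacc$per_class_pct), c(100L, 100L))
  expect_equal(pacc$overall, 1.00)

  holed <- confusion_table(c("a", "b"), c(10, 0), c(5, 0))
  expect_true(is.na(accuracy_from_table(holed)$per_class_pct[["b"]]))

  expect_error(confusion_table("a", 3, 4), "correct <= totals")
  expect_error(confusion_table(c("a", "b"), 3, c(1, 1)), "lengths")
})

test_that("evaluate_reconstructions assembles SSIM stats and tables", {
  set.seed(4)
  samples <- lapply(1:6, function(i) {
    generate_phantom(phantom_spec(width_n = 64, side_p = 32,
                                  canine_bl = c("buccal", "middle", "lingual")[(i - 1) %% 3 + 1],
                                  canine_md = c("mesial", "distal")[(i - 1) %% 2 + 1],
                                  seed = 500 + i))
  })
  pairs <- lapply(samples, function(s) {
    list(truth = s$volume, pred = s$volume, crown_roi = s$crown_mask,
         labels = s$labels, slot_rl = s$slot_rl)
  })
  rep <- evaluate_reconstructions(pairs)
  expect_equal(rep$ssim_mean, 1)
  expect_equal(rep$bl_accuracy$overall, 1.00)
  expect_equal(rep$md_accuracy$overall, 1.00)
  expect_equal(sum(rep$bl_table$totals), 6)
  expect_equal(sum(rep$md_table$totals), 6)
  expect_true(rep$ssim_q25 <= rep$ssim_q50 && rep$ssim_q50 <= rep$ssim_q75)

  # quantiles agree with a sort-and-interpolate oracle
  set.seed(5)
  noisy_pairs <- lapply(samples, function(s) {
    list(truth = s$volume,
         pred = volume3d(unclass(s$volume) +
                           array(rnorm(length(s$volume), sd = 0.2),
                                 dim(s$volume)),
                         attr(s$volume, "spacing_mm")),
         crown_roi = s$crown_mask, labels = s$labels, slot_rl = s$slot_rl)
  })
  rep2 <- evaluate_reconstructions(noisy_pairs)
  svals <- sort(rep2$ssim_values)
  oracle_q <- function(prob) {
    h <- (length(svals) - 1) * prob + 1
    lo <- floor(h)
    svals[lo] + (h - lo) * (svals[min(lo + 1, length(svals))] - svals[lo])
  }
  expect_equal(rep2$ssim_q25, oracle_q(0.25), tolerance = 1e-12)
  expect_equal(rep2$ssim_q50, oracle_q(0.50), tolerance = 1e-12)
  expect_equal(rep2$ssim_q75, oracle_q(0.75), tolerance = 1e-12)
  expect_equal(rep2$n_impacted, 6)

  expect_error(evaluate_reconstructions(list()), "empty")
})

test_that("evaluation reports serialize to JSON plus table CSVs", {
  s <- generate_phantom(phantom_spec(width_n = 48, side_p = 32, seed = 9))
  pairs <- list(list(truth = s$volume, pred = s$volume,
                     crown_roi = s$crown_mask, labels = s$labels,
                     slot_rl = s$slot_rl))
  rep <- evaluate_reconstructions(pairs)
  path <- tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$ssim_mean, 1)
  expect_equal(back$params$ssim_window, 7)
  bl_csv <- sub("\\.json$", "_buccolingual.csv", path)
  expect_true(file.exists(bl_csv))
  tab <- read.csv(bl_csv, check.names = FALSE)
  expect_equal(names(tab)[1], "Ground Truth Position")
  unlink(c(path, bl_csv, sub("\\.json$", "_mesiodistal.csv", path)))
})
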