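small_spec <- function(...) {
  phantom_spec(width_n = 96L, side_p = 48L, ...)
}

test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(small_spec(seed = 42))
  b <- generate_phantom(small_spec(seed = 42))
  expect_identical(unclass(a$volume), unclass(b$volume))
  expect_identical(unclass(a$panoramic), unclass(b$panoramic))
  c <- generate_phantom(small_spec(seed = 43))
  expect_false(identical(unclass(a$volume), unclass(c$volume)))
})

test_that("noise-free phantoms contain only the declared tissue levels", {
  s <- generate_phantom(small_spec(noise_sd = 0, seed = 5))
  lv <- sort(unique(as.vector(unclass(s$volume))))
  expect_true(all(lv %in% s$spec$tissue_levels))
  expect_true(length(lv) >= 3)
})

test_that("planted labels are recovered from the ground-truth volume", {
  combos <- expand.grid(bl = c("buccal", "middle", "lingual"),
                        md = c("mesial", "distal"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    s <- generate_phantom(small_spec(canine_bl = combos$bl[i],
                                     canine_md = combos$md[i],
                                     seed = 200 + i))
    expect_true(any(s$crown_mask))
    roi <- pan2vol:::dilate_mask(s$crown_mask, 2)
    expect_equal(classify_buccolingual(s$volume, roi), combos$bl[i])
    expect_equal(classify_mesiodistal(s$volume, roi, s$slot_rl), combos$md[i])
  }
})

test_that("control phantoms carry no canine and no labels", {
  s <- generate_phantom(small_spec(canine_bl = NA, seed = 3))
  expect_null(s$labels)
  expect_false(any(s$crown_mask))
})

test_that("render_panoramic projects along depth and normalizes", {
  const <- volume3d(array(4, c(10, 8, 8)))
  expect_true(all(render_panoramic(const) == 0))

  s <- generate_phantom(small_spec(seed = 10))
  pan <- render_panoramic(s$volume)
  expect_equal(dim(pan), c(dim(s$volume)[1], dim(s$volume)[3]))
  expect_equal(range(pan), c(-1, 1))

  # a single dense tooth on empty background: the brightest panoramic
  # pixel lies inside the tooth's RL/IS silhouette
  x <- array(0, c(32, 16, 16))
  tooth <- pan2vol:::paint_ellipsoid(x, c(10, 8, 8), c(3, 3, 5), 1)
  pan2 <- render_panoramic(volume3d(tooth$arr))
  sil <- apply(tooth$arr > 0, c(1, 3), any)
  peak <- which(unclass(pan2) == max(pan2), arr.ind = TRUE)[1, ]
  expect_true(sil[peak[1], peak[2]])
})

test_that("phantom panoramic equals the clean projection up to noise", {
  # noise-free: the stored panoramic is exactly the rendered projection
  s0 <- generate_phantom(small_spec(seed = 76, noise_sd = 0))
  expect_equal(unclass(render_panoramic(s0$volume)), unclass(s0$panoramic),
               ignore_attr = TRUE)

  # with noise: depth averaging shrinks the volume noise by sqrt(P), but
  # renormalization rescales by 2/range (roughly 2/0.7 here), so a bound
  # of 6 * noise_sd on the mean absolute difference is the noise tolerance
  s <- generate_phantom(small_spec(seed = 77, noise_sd = 0.05))
  rerendered <- render_panoramic(s$volume)  # projection of the noisy volume
  diff <- abs(unclass(rerendered) - unclass(s$panoramic))
  expect_lt(mean(diff), 6 * 0.05)
})

test_that("generate_dataset honours the requested label histogram", {
  counts <- c(buccal_mesial = 2, middle_distal = 1, lingual_mesial = 1,
              control = 2)
  ds <- generate_dataset(counts, small_spec(), seed = 8)
  expect_length(ds, 6)
  labs <- vapply(ds, function(s) {
    if (is.null(s$labels)) "control" else paste(s$labels$bl, s$labels$md, sep = "_")
  }, character(1))
  expect_equal(as.vector(table(factor(labs, levels = names(counts)))),
               as.vector(counts))

  expect_length(generate_dataset(c(control = 0), small_spec(), seed = 1), 0)

  ds2 <- generate_dataset(counts, small_spec(), seed = 8)
  expect_identical(lapply(ds, function(s) unclass(s$volume)),
                   lapply(ds2, function(s) unclass(s$volume)))

  expect_error(generate_dataset(c(sideways = 1), small_spec(), seed = 1),
               "named")
  expect_error(generate_dataset(c(control = -1), small_spec(), seed = 1),
               ">= 0")
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(tissue_levels = c(air = 1, bone = 0.5,
                                              dentine = 0.7, enamel = 1)),
               "air < bone")
  expect_error(phantom_spec(width_n = 16, side_p = 64), "width_n")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  # a crown pushed far above the volume cannot be placed
  expect_error(generate_phantom(small_spec(vertical_offset_mm = 50)),
               "exit the volume")
})

test_that("the example cohort counts reproduce both position marginals", {
  counts <- example_cohort_counts()
  bl <- c(buccal = sum(counts[grep("^buccal", names(counts))]),
          middle = sum(counts[grep("^middle", names(counts))]),
          lingual = sum(counts[grep("^lingual", names(counts))]))
  md <- c(mesial = sum(counts[grep("mesial$", names(counts))]),
          distal = sum(counts[grep("distal$", names(counts))]))
  expect_equal(as.vector(bl), c(36, 12, 26))
  expect_equal(as.vector(md), c(65, 9))
  expect_equal(sum(counts), 123L)
})
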