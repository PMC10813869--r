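test_that("normalize_intensity maps range to [-1, 1] with the affine rule", {
  p <- panoramic(matrix(c(0, 100, 50, 100), 2, 2))
  out <- normalize_intensity(p)
  expect_equal(sort(unique(as.vector(out))), c(-1, 0, 1))
  expect_s3_class(out, "panoramic")

  v <- volume3d(array(c(0, 100), c(2, 1, 1)))
  expect_equal(as.vector(normalize_intensity(v)), c(-1, 1))

  # constant input has no range: maps to the midpoint 0
  const <- volume3d(array(7, c(3, 4, 4)))
  expect_true(all(normalize_intensity(const) == 0))

  bad <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(normalize_intensity(bad), "non-finite")
})

test_that("normalize_intensity is idempotent", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- array(rnorm(4 * 6 * 6, sd = runif(1, 0.1, 10)), c(4, 6, 6))
    once <- normalize_intensity(x)
    expect_identical(normalize_intensity(once), once)
  }
})

test_that("histogram matching follows the rank-based quantile map", {
  # self-matching is the identity for distinct values
  set.seed(3)
  x <- matrix(sample(1:16), 4, 4)
  expect_equal(unclass(histogram_match(x, x)), x, ignore_attr = TRUE)

  # constant template collapses everything onto the constant
  expect_true(all(histogram_match(x, matrix(5, 4, 4)) == 5))

  # 4x4 integer images against the sorted-rank oracle
  set.seed(9)
  src <- matrix(sample(1:16), 4, 4)
  tpl <- matrix(sample(seq(10, 160, by = 10)), 4, 4)
  expect_equal(unclass(histogram_match(src, tpl)), histmatch_oracle(src, tpl),
               ignore_attr = TRUE)

  # matched output has approximately the template's quantile function
  set.seed(11)
  src2 <- matrix(runif(400), 20, 20)
  tpl2 <- matrix(rnorm(400, mean = 4, sd = 2), 20, 20)
  out2 <- histogram_match(src2, tpl2)
  expect_lt(max(abs(quantile(as.vector(out2), 1:9 / 10) -
                    quantile(as.vector(tpl2), 1:9 / 10))), 0.3)

  expect_error(histogram_match(numeric(0), 1:3), "empty")
  expect_error(histogram_match(matrix(1:4, 2), array(1:8, c(2, 2, 2))),
               "dimensionality")
})

test_that("patch extraction starts at every stride multiple below N", {
  v <- rand_vol(64, 16, seed = 1)
  ps <- extract_patches(v, patch_side = 16, stride = 16)
  expect_equal(length(ps$patches), 4)
  expect_equal(ps$starts, c(0L, 16L, 32L, 48L))
  expect_true(all(ps$valid_width == 16))

  # exact fit: one patch, no padding
  v1 <- rand_vol(16, 16, seed = 2)
  ps1 <- extract_patches(v1, 16, 16)
  expect_equal(length(ps1$patches), 1)
  expect_identical(ps1$patches[[1]], unclass(v1), ignore_attr = TRUE)

  # overhang is zero-padded and tracked
  v2 <- rand_vol(20, 16, seed = 3)
  ps2 <- extract_patches(v2, 16, 8)
  expect_equal(length(ps2$patches), 3)  # ceiling(20 / 8)
  expect_equal(ps2$valid_width, c(16L, 12L, 4L))
  expect_true(all(ps2$patches[[3]][5:16, , ] == 0))

  expect_error(extract_patches(v, patch_side = 8, stride = 4), "AP/IS")
  expect_error(extract_patches(v, patch_side = 16, stride = 20), "stride")
})

test_that("patch count equals ceiling(N / S) across geometries", {
  p <- 16
  set.seed(4)
  for (i in 1:25) {
    n <- sample(p:80, 1)
    s <- sample(1:p, 1)
    v <- volume3d(array(0, c(n, p, p)))
    expect_equal(length(extract_patches(v, p, s)$patches), ceiling(n / s))
  }
})

test_that("extract then reassemble is an exact round trip", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(16:48, 1)
    s <- sample(1:16, 1)
    v <- rand_vol(n, 16, seed = seed + 100)
    w <- reassemble_patches(extract_patches(v, 16, s))
    expect_identical(unclass(w), unclass(v), ignore_attr = TRUE)
    expect_equal(attr(w, "spacing_mm"), attr(v, "spacing_mm"))
  }
  expect_error(reassemble_patches(structure(list(patches = list()),
                                            class = "patch_set")),
               "empty")
})

test_that("projections are means along the stated axes", {
  v <- volume3d(array(2.5, c(8, 4, 4)))
  for (pl in c("axial", "coronal", "sagittal")) {
    expect_true(all(project(v, pl) == 2.5))
  }
  expect_equal(dim(project(v, "axial")), c(8, 4))     # (rl, ap)
  expect_equal(dim(project(v, "coronal")), c(8, 4))   # (rl, is)
  expect_equal(dim(project(v, "sagittal")), c(4, 4))  # (ap, is)

  # one voxel of value v in a zero volume: coronal pixel = v / depth
  x <- array(0, c(6, 5, 5))
  x[2, 3, 4] <- 10
  expect_equal(project(volume3d(x[, 1:5, 1:5]), "coronal")[2, 4], 10 / 5)

  expect_error(project(v, "oblique"))

  tri <- project_all(v)
  expect_s3_class(tri, "projection_triple")
  expect_equal(names(tri), c("axial", "coronal", "sagittal"))
})

test_that("projection is linear", {
  set.seed(7)
  u <- array(rnorm(6 * 4 * 4), c(6, 4, 4))
  v <- array(rnorm(6 * 4 * 4), c(6, 4, 4))
  a <- 2.3; b <- -0.7
  for (pl in c("axial", "coronal", "sagittal")) {
    expect_equal(project(volume3d(a * u + b * v), pl),
                 a * project(volume3d(u), pl) + b * project(volume3d(v), pl))
  }
})

test_that("volume and panoramic constructors enforce their invariants", {
  expect_error(volume3d(array(0, c(4, 4, 5))), "AP and IS")
  expect_error(volume3d(array(NA_real_, c(4, 4, 4))), "non-finite")
  expect_error(volume3d(array(0, c(4, 4, 4)), spacing_mm = c(0, 1, 1)),
               "positive")
  expect_error(panoramic(array(0, c(2, 2, 2))), "matrix")
})
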