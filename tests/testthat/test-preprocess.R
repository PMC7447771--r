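make_vol <- function(a, sp = c(1, 1, 1)) image_volume(a, sp)

test_that("whole-image normalization z-scores and is affine-invariant", {
  set.seed(1)
  v <- make_vol(array(rnorm(10^3, 50, 7), c(10, 10, 10)))
  nz <- normalize(v, "whole_image")
  expect_lt(abs(mean(nz$voxels)), 1e-10)
  expect_lt(abs(sd(nz$voxels) - 1), 1e-10)
  # invariance under positive affine transforms of the input
  v2 <- make_vol(3.7 * v$voxels + 12)
  expect_equal(normalize(v2, "whole_image")$voxels, nz$voxels,
               tolerance = 1e-10)
  # idempotence
  expect_equal(normalize(nz, "whole_image")$voxels, nz$voxels,
               tolerance = 1e-10)
  expect_error(normalize(make_vol(array(5, c(4, 4, 4)))), "degenerate")
})

test_that("foreground normalization uses non-air support only", {
  set.seed(2)
  a <- array(rnorm(16^3, sd = 0.5), c(16, 16, 16))       # air ~ 0
  body <- array(FALSE, c(16, 16, 16)); body[5:12, 5:12, 5:12] <- TRUE
  a[body] <- rnorm(sum(body), 100, 10)                   # tissue ~ 100
  v <- make_vol(a)
  nf <- normalize(v, "foreground")
  # air and tissue separate cleanly here, so the transform is exactly the
  # z-score with tissue statistics
  expect_lt(abs(mean(nf$voxels[body])), 1e-10)
  expect_equal(sd(nf$voxels[body]), 1, tolerance = 1e-10)
  expect_equal(nf$voxels, (a - mean(a[body])) / sd(a[body]),
               tolerance = 1e-10)
})

test_that("resampling reproduces linear ramps exactly and fixes spacing", {
  # 0.5 mm ramp I(x) = x resampled to 1.0 mm
  n <- 21
  ramp <- array(rep((0:(n - 1)) * 0.5, n * n), c(n, n, n))
  v <- image_volume(ramp, c(0.5, 0.5, 0.5))
  out <- resample_isotropic(v, list(), 1.0)
  expect_equal(out$image$spacing_mm, c(1, 1, 1))
  expected <- array(rep(0:(dim(out$image$voxels)[1] - 1),
                        prod(dim(out$image$voxels)[2:3])),
                    dim(out$image$voxels))
  expect_equal(out$image$voxels, expected, tolerance = 1e-6)

  # constant volumes stay constant; 1.0 mm input is returned unchanged
  cv <- image_volume(array(3.3, c(8, 8, 8)), c(0.7, 0.9, 1.3))
  expect_true(all(abs(resample_isotropic(cv)$image$voxels - 3.3) < 1e-12))
  iso <- image_volume(array(rnorm(8^3), c(8, 8, 8)), c(1, 1, 1))
  expect_identical(resample_isotropic(iso)$image$voxels, iso$voxels)
  expect_error(resample_isotropic(iso, target_mm = 0), "positive")
})

test_that("masks are resampled nearest-neighbour onto the same grid", {
  a <- array(FALSE, c(20, 20, 20)); a[6:14, 6:14, 6:14] <- TRUE
  v <- image_volume(array(rnorm(20^3), c(20, 20, 20)), c(0.5, 0.5, 0.5))
  m <- seg_mask(a, c(0.5, 0.5, 0.5))
  out <- resample_isotropic(v, list(m), 1.0)
  expect_equal(out$masks[[1]]$spacing_mm, c(1, 1, 1))
  expect_true(all(out$masks[[1]]$voxels %in% c(TRUE, FALSE)))
  # volume in mm^3 approximately preserved
  expect_equal(sum(out$masks[[1]]$voxels) * 1,
               sum(a) * 0.5^3, tolerance = 0.15 * sum(a) * 0.5^3)
})

test_that("bin-width selection maximizes in-range ROIs, smallest width wins ties", {
  expect_equal(select_bin_width(c(1.6, 3.2, 12.8), c(0.05, 0.1, 0.5)), 0.1)
  expect_equal(select_bin_width(6.1, 0.1), 0.1)
  # tie: both widths put the single ROI in range -> smaller returned
  expect_equal(select_bin_width(3.2, c(0.1, 0.05)), 0.05)
  # permutation invariance
  expect_equal(select_bin_width(c(12.8, 1.6, 3.2), c(0.5, 0.1, 0.05)), 0.1)
  expect_error(select_bin_width(numeric(0), 0.1), "nonempty")
})

test_that("bin counts behind the selection rule are the ceiling counts", {
  ranges <- c(1.6, 3.2, 12.8)
  expect_equal(ceiling(ranges / 0.1), c(16, 32, 128))
  expect_equal(ceiling(ranges / 0.05), c(32, 64, 256))
  expect_equal(ceiling(ranges / 0.5), c(4, 7, 26))
})

test_that("discretization follows the anchored floor rule", {
  a <- array(0, c(4, 1, 1)); a[, 1, 1] <- c(0.0, 0.05, 0.1, 0.95)
  v <- image_volume(a, c(1, 1, 1))
  m <- seg_mask(array(TRUE, c(4, 1, 1)), c(1, 1, 1))
  d <- discretize(v, m, discretization_spec(0.1))
  expect_equal(as.vector(d$levels), c(1, 1, 2, 10))
  expect_equal(d$n_levels, 10L)
  # constant ROI -> single level, not an error
  dc <- discretize(image_volume(array(2.2, c(3, 3, 3)), c(1, 1, 1)),
                   seg_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1)))
  expect_equal(dc$n_levels, 1L)
  expect_true(all(dc$levels == 1L))
})

test_that("discretization is invariant under adding a constant", {
  set.seed(3)
  a <- array(rnorm(6^3), c(6, 6, 6))
  m <- seg_mask(array(runif(6^3) < 0.6, c(6, 6, 6)), c(1, 1, 1))
  d1 <- discretize(image_volume(a, c(1, 1, 1)), m)
  # shift by an exact multiple of the bin width to avoid edge re-anchoring
  d2 <- discretize(image_volume(a + 73 * 0.1, c(1, 1, 1)), m)
  expect_identical(d1$levels, d2$levels)
  # level count bounded by ceil(range/width) + 1
  rng <- diff(range(a[m$voxels]))
  expect_lte(d1$n_levels, ceiling(rng / 0.1) + 1)
})

test_that("stationary Haar decomposition preserves energy and handles constants", {
  set.seed(4)
  v <- image_volume(array(rnorm(8 * 6 * 10), c(8, 6, 10)), c(1, 1, 1))
  bands <- wavelet_decompose(v)
  expect_named(bands, c("LLL", "LLH", "LHL", "LHH",
                        "HLL", "HLH", "HHL", "HHH"))
  energy_in <- sum(v$voxels^2)
  energy_out <- sum(vapply(bands, function(b) sum(b$voxels^2), numeric(1)))
  expect_equal(energy_out, energy_in, tolerance = 1e-10)

  cv <- image_volume(array(5, c(4, 4, 4)), c(1, 1, 1))
  cb <- wavelet_decompose(cv)
  expect_equal(unique(as.vector(cb$LLL$voxels)), 5)
  for (nm in setdiff(names(cb), "LLL"))
    expect_lt(max(abs(cb[[nm]]$voxels)), 1e-12)

  tiny <- wavelet_decompose(image_volume(array(rnorm(8), c(2, 2, 2)),
                                         c(1, 1, 1)))
  expect_length(tiny, 8L)
  expect_error(wavelet_decompose(image_volume(array(0, c(1, 4, 4)) +
                                                rnorm(16), c(1, 1, 1))),
               "axis")
})
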