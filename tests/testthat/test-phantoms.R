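test_that("noiseless homogeneous phantom has constant in-lesion intensity", {
  spec <- phantom_spec("easy", radius_mm = 8, grid_shape = c(32, 32, 32),
                       texture_sigma = 0, noise_sigma = 0,
                       edge_smooth_mm = 0, n_dark_foci = 0, seed = 5)
  ph <- make_phantom(spec)
  vals <- ph$image$voxels[ph$mask$voxels]
  expect_equal(length(unique(vals)), 1L)
  expect_equal(unique(vals), 100 + spec$intensity_contrast)
})

test_that("easy phantom volume matches the analytic ellipsoid volume", {
  ph <- make_phantom(phantom_spec("easy", radius_mm = 10,
                                  grid_shape = c(40, 40, 40), seed = 1))
  expect_lt(abs(sum(ph$mask$voxels) - 4 / 3 * pi * 10^3) /
              (4 / 3 * pi * 10^3), 0.05)
})

test_that("randomness enters masks only through stochastic components", {
  e1 <- make_phantom(phantom_spec("easy", radius_mm = 8,
                                  grid_shape = c(32, 32, 32), seed = 1))
  e2 <- make_phantom(phantom_spec("easy", radius_mm = 8,
                                  grid_shape = c(32, 32, 32), seed = 2))
  expect_identical(e1$mask$voxels, e2$mask$voxels)   # deterministic geometry
  c1 <- make_phantom(phantom_spec("challenging", radius_mm = 9,
                                  grid_shape = c(40, 40, 40), seed = 1))
  c2 <- make_phantom(phantom_spec("challenging", radius_mm = 9,
                                  grid_shape = c(40, 40, 40), seed = 2))
  expect_false(identical(c1$mask$voxels, c2$mask$voxels))
  # same seed reproduces bit-identically
  c1b <- make_phantom(phantom_spec("challenging", radius_mm = 9,
                                   grid_shape = c(40, 40, 40), seed = 1))
  expect_identical(c1$image$voxels, c1b$image$voxels)
  expect_identical(c1$mask$voxels, c1b$mask$voxels)
})

test_that("oversized lesions are rejected with the offending axis named", {
  expect_error(make_phantom(phantom_spec("easy", radius_mm = c(30, 5, 5),
                                         grid_shape = c(32, 32, 32))),
               "axis 1")
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec("easy", n_spicules = 2), "n_spicules")
  expect_error(phantom_spec("challenging", n_spicules = 1), "n_spicules")
  expect_error(phantom_spec("easy", texture_sigma = 100), "homogeneous")
})

test_that("identity perturbation reproduces the truth mask exactly", {
  ph <- make_phantom(phantom_spec("challenging", radius_mm = 8,
                                  grid_shape = c(40, 40, 40), seed = 3))
  out <- simulate_observer(ph$mask, perturbation_spec(0, c(0, 0), 1,
                                                      seed = 99))
  expect_identical(out$voxels, ph$mask$voxels)
  expect_equal(dsc(out, ph$mask), 1)
})

test_that("mean DSC against truth decreases with boundary sigma", {
  ph <- make_phantom(phantom_spec("easy", radius_mm = 8,
                                  grid_shape = c(32, 32, 32), seed = 3))
  mean_dsc <- vapply(c(0.5, 1, 2), function(s) {
    mean(vapply(1:50, function(k) {
      o <- simulate_observer(ph$mask, perturbation_spec(s, c(0, 0), 1,
                                                        seed = k))
      dsc(o, ph$mask)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dsc) < 0))
})

test_that("overwhelming perturbation of a tiny lesion errors out", {
  a <- array(FALSE, c(16, 16, 16)); a[8, 8, 8:9] <- TRUE
  tiny <- seg_mask(a, c(1, 1, 1))
  expect_error(simulate_observer(tiny, perturbation_spec(
    boundary_sigma_mm = 0.1, morph_radius_range_mm = c(-6, -6),
    spicule_keep_prob = 1, seed = 1)), "too large")
})

test_that("cohort generation is a pure function of its seed", {
  c1 <- make_cohort(2, 1, 4, base_seed = 11,
                    config = small_cohort_config())
  c2 <- make_cohort(2, 1, 4, base_seed = 11,
                    config = small_cohort_config())
  expect_identical(c1, c2)
  expect_equal(length(c1), 3L)
  expect_equal(length(c1[[1]]$observer_masks), 4L)
  expect_setequal(vapply(c1, `[[`, character(1), "difficulty"),
                  c("easy", "challenging"))
  expect_error(make_cohort(2, 1, n_observers = 1, base_seed = 1),
               "2 observers")
})

test_that("easy phantoms are more spherical than challenging ones", {
  sph <- function(difficulty, seeds) {
    vapply(seeds, function(s) {
      ph <- make_phantom(phantom_spec(difficulty, radius_mm = 9,
                                      grid_shape = c(44, 44, 44), seed = s))
      extract_shape(ph$mask)[["sphericity"]]
    }, numeric(1))
  }
  expect_gt(mean(sph("easy", 1:3)), mean(sph("challenging", 1:3)))
})

test_that("cohort round-trips through NIfTI files on disk", {
  dir <- withr::local_tempdir()
  co <- make_cohort(1, 1, 2, base_seed = 4,
                    config = small_cohort_config())
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$truth_mask$voxels, co[[1]]$truth_mask$voxels)
  expect_equal(back[[2]]$observer_masks$obs2$voxels,
               co[[2]]$observer_masks$obs2$voxels)
  expect_equal(back[[1]]$image$voxels, co[[1]]$image$voxels,
               tolerance = 1e-6)
})
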