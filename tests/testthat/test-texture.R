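disc_from_levels <- function(lev) {
  structure(list(levels = lev, n_levels = max(lev), bin_width = 1,
                 spacing_mm = c(1, 1, 1)), class = "discretized_roi")
}

test_that("constant ROI yields the degenerate closed forms", {
  lev <- array(1L, c(4, 4, 1))
  d <- disc_from_levels(lev)
  tm <- compute_texture(d, "GLCM")
  # single gray level: the only nonzero entry is (1,1) in every direction
  for (m in tm$matrices) {
    expect_equal(dim(m), c(1L, 1L))
    expect_true(m[1, 1] == 0 || m[1, 1] > 0)
  }
  f <- texture_features(tm)
  expect_equal(f[["joint_entropy"]], 0)
  expect_equal(f[["contrast"]], 0)
  expect_equal(texture_features(compute_texture(d, "NGTDM"))[["contrast"]], 0)
})

test_that("GLRLM matches exhaustive run enumeration on the 4x4 toy grid", {
  rows <- rbind(c(1, 2, 2, 3),
                c(1, 2, 3, 3),
                c(4, 2, 4, 1),
                c(4, 1, 2, 3))
  lev <- array(0L, c(4, 4, 1))
  for (i in 1:4) lev[i, , 1] <- rows[i, ]
  d <- disc_from_levels(lev)
  tm <- compute_texture(d, "GLRLM")
  off <- radrobust:::offsets13()
  horiz <- which(apply(off, 1, function(o) all(o == c(0, 1, 0))))
  oracle <- glrlm_oracle(lev, c(0, 1, 0), 4)
  got <- tm$matrices[[horiz]]
  expect_equal(got[, seq_len(ncol(oracle))], oracle)
  expect_true(all(got[, -seq_len(ncol(oracle))] == 0))
})

test_that("checkerboard zones match the flood-fill oracle", {
  lev <- array(0L, c(4, 4, 2))
  idx <- which(array(TRUE, c(4, 4, 2)), arr.ind = TRUE)
  lev[] <- 1L + (idx[, 1] + idx[, 2] + idx[, 3]) %% 2L
  tm <- compute_texture(disc_from_levels(lev), "GLSZM")
  oracle <- glszm_oracle(lev, 2L)
  expect_equal(tm$matrix, oracle)
  # under 26-connectivity the two checkerboard colours are each fully
  # connected: two zones, not 32 singletons
  expect_equal(sum(tm$matrix), 2)
})

test_that("all five texture matrices equal brute-force enumeration on random ROIs", {
  off <- radrobust:::offsets13()
  for (seed in 1:12) {
    d <- random_disc_roi(dim3 = c(5, 5, 4), L = 4, fill = 0.75, seed = seed)
    lev <- d$levels
    tm_glcm <- compute_texture(d, "GLCM")
    tm_glrlm <- compute_texture(d, "GLRLM")
    for (k in sample(nrow(off), 4)) {
      expect_equal(tm_glcm$matrices[[k]], glcm_oracle(lev, off[k, ], 4),
                   info = sprintf("GLCM seed %d dir %d", seed, k))
      oracle_rl <- glrlm_oracle(lev, off[k, ], 4)
      got <- tm_glrlm$matrices[[k]]
      expect_equal(got[, seq_len(ncol(oracle_rl)), drop = FALSE], oracle_rl,
                   info = sprintf("GLRLM seed %d dir %d", seed, k))
    }
    expect_equal(compute_texture(d, "GLSZM")$matrix, glszm_oracle(lev, 4L),
                 info = paste("GLSZM seed", seed))
    ng <- compute_texture(d, "NGTDM")
    oracle_ng <- ngtdm_oracle(lev, 4L)
    expect_equal(ng$s, oracle_ng$s, info = paste("NGTDM seed", seed))
    expect_equal(ng$n, oracle_ng$n, info = paste("NGTDM seed", seed))
    expect_equal(compute_texture(d, "GLDM")$matrix, gldm_oracle(lev, 4L),
                 info = paste("GLDM seed", seed))
  }
})

test_that("GLCM features derive from a probability-normalized matrix", {
  d <- random_disc_roi(dim3 = c(5, 5, 3), L = 3, seed = 77)
  tm <- compute_texture(d, "GLCM")
  for (m in tm$matrices) {
    p <- m / sum(m)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # contrast equals the direct double loop over the normalized matrix
    direct <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
      direct <- direct + p[i, j] * (i - j)^2
    f <- radrobust:::glcm_features(m)
    expect_equal(f[["contrast"]], direct, tolerance = 1e-12)
  }
})

test_that("texture features are invariant under ROI translation", {
  set.seed(5)
  core <- array(sample.int(4, 4^3, replace = TRUE), c(4, 4, 4))
  pad1 <- array(0L, c(10, 10, 10)); pad1[2:5, 2:5, 2:5] <- core
  pad2 <- array(0L, c(10, 10, 10)); pad2[5:8, 4:7, 6:9] <- core
  for (kind in c("GLCM", "GLRLM", "GLSZM", "NGTDM", "GLDM")) {
    f1 <- texture_features(compute_texture(disc_from_levels(pad1), kind))
    f2 <- texture_features(compute_texture(disc_from_levels(pad2), kind))
    expect_equal(f1, f2, info = kind)
  }
})

test_that("invalid texture kind is rejected", {
  expect_error(compute_texture(random_disc_roi(), "GLXX"))
})
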