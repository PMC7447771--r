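test_that("DSC closed forms: identity, disjoint, shifted cube", {
  a <- cube_mask(c(8, 8, 8), c(3, 3, 3), 2)
  expect_equal(dsc(a, a), 1.0)
  b <- cube_mask(c(8, 8, 8), c(6, 6, 6), 2)
  expect_equal(dsc(a, b), 0.0)
  shifted <- cube_mask(c(8, 8, 8), c(4, 3, 3), 2)
  expect_equal(dsc(a, shifted), 0.5)   # 2*4/(8+8)
  expect_error(dsc(seg_mask(array(FALSE, c(8, 8, 8)), c(1, 1, 1)),
                   seg_mask(array(FALSE, c(8, 8, 8)), c(1, 1, 1))),
               "empty")
  expect_error(dsc(a, cube_mask(c(8, 8, 8), c(3, 3, 3), 2,
                                spacing = c(2, 1, 1))), "aligned")
})

test_that("DSC matches the coordinate-set oracle on random masks", {
  for (seed in 1:25) {
    a <- random_mask(c(10, 10, 10), p = 0.3, seed = seed)
    b <- random_mask(c(10, 10, 10), p = 0.3, seed = seed + 1000)
    if (sum(a$voxels) + sum(b$voxels) == 0) next
    expect_lt(abs(dsc(a, b) - dsc_oracle(a, b)), 1e-12)
  }
})

test_that("pairwise DSC covers all observer pairs symmetrically", {
  co <- make_cohort(2, 1, 4, base_seed = 5,
                    config = small_cohort_config())
  pd <- pairwise_dsc(co)
  expect_equal(nrow(pd), 3 * choose(4, 2))
  expect_true(all(pd$dsc >= 0 & pd$dsc <= 1))
  expect_length(attr(pd, "pair_means"), choose(4, 2))
  # identical observers give all-1 rows
  co1 <- co[1]
  co1[[1]]$observer_masks <- rep(co1[[1]]$observer_masks[1], 3)
  names(co1[[1]]$observer_masks) <- paste0("obs", 1:3)
  pd1 <- pairwise_dsc(co1)
  expect_true(all(pd1$dsc == 1))
  expect_equal(attr(pd1, "overall_mean"), 1)
})

test_that("near-zero-variance filter applies the 95 percent modal rule", {
  base <- data.frame(
    tumor_id = rep(sprintf("t%02d", 1:25), each = 4),
    observer_id = rep(paste0("obs", 1:4), 25))
  tbl <- rbind(
    transform(base, feature_name = "const", value = 1),
    transform(base, feature_name = "nearly96",
              value = c(rep(7, 96), 1:4)),
    transform(base, feature_name = "nearly94",
              value = c(rep(7, 94), 1:6)),
    transform(base, feature_name = "varied", value = seq_len(100)))
  out <- nzv_filter(tbl, threshold = 0.95)
  expect_setequal(out$removed$feature_name, c("const", "nearly96"))
  expect_setequal(unique(out$table$feature_name), c("nearly94", "varied"))
})

test_that("ICC(2,1) closed forms and oracle equivalence", {
  # identical rater columns with varying subjects -> 1
  m <- matrix(rep(c(1, 5, 9, 2, 7, 4), 4), ncol = 4)
  expect_equal(icc21(m), 1)
  # all cells equal -> undefined
  expect_true(is.na(icc21(matrix(3, 5, 4))))
  expect_error(icc21(matrix(1:4, 1, 4)), "at least 2")
  set.seed(123)
  for (rep_i in 1:200) {
    m <- matrix(rnorm(24, sd = runif(1, 0.5, 3)), 6, 4) +
      rnorm(6, sd = 2)       # subject effects
    expect_lt(abs(icc21(m) - icc21_oracle(m)), 1e-10)
  }
})

test_that("ICC(2,1) is invariant under shift, scale and permutations", {
  set.seed(7)
  m <- matrix(rnorm(24), 6, 4) + rnorm(6, sd = 1.5)
  v <- icc21(m)
  expect_equal(icc21(m + 100), v, tolerance = 1e-12)
  expect_equal(icc21(m * 42), v, tolerance = 1e-12)
  expect_equal(icc21(m[sample(6), ]), v, tolerance = 1e-12)
  expect_equal(icc21(m[, sample(4)]), v, tolerance = 1e-12)
})

test_that("icc_table classifies with a strict cutoff and deletes subjects listwise", {
  grid <- expand.grid(tumor_id = sprintf("t%d", 1:6),
                      observer_id = paste0("obs", 1:4),
                      stringsAsFactors = FALSE)
  # perfectly reproducible feature -> ICC 1, robust
  perfect <- transform(grid, feature_name = "vol",
                       value = as.numeric(factor(tumor_id)) * 3)
  tab <- icc_table(perfect)
  expect_equal(tab$icc, 1)
  expect_true(tab$robust)
  # boundary: construct a feature whose ICC is exactly the cutoff
  expect_false(icc_table(perfect, cutoff = 1)$robust)
  # missing cells drop the affected tumor only
  missing1 <- perfect
  missing1$value[missing1$tumor_id == "t3" &
                   missing1$observer_id == "obs2"] <- NA
  tab2 <- icc_table(missing1)
  expect_equal(tab2$n_subjects, 5)
  expect_equal(tab2$n_raters, 4)
})

test_that("pure-noise features are not robust", {
  set.seed(42)
  reps <- vapply(1:60, function(i) {
    grid <- expand.grid(tumor_id = sprintf("t%d", 1:10),
                        observer_id = paste0("obs", 1:4),
                        stringsAsFactors = FALSE)
    grid$feature_name <- "noise"
    grid$value <- rnorm(nrow(grid))
    icc_table(grid)$icc
  }, numeric(1))
  expect_lt(abs(mean(reps)), 0.1)   # ICC ~ 0 in expectation
  expect_lt(mean(reps > 0.9), 0.05)
})

test_that("group summaries follow hand arithmetic and print convention", {
  iccs <- data.frame(feature_name = c("a", "b", "c"),
                     icc = c(0.8, 1.0, 0.6),
                     n_subjects = 10, n_raters = 4,
                     robust = c(FALSE, TRUE, FALSE),
                     group = c("g1", "g1", "g2"),
                     filter = "original")
  rep_ <- summarize_robustness(iccs)
  g1 <- rep_$by_group[rep_$by_group$group == "g1", ]
  expect_equal(g1$mean_icc, 0.9)
  expect_equal(rep_$by_group[rep_$by_group$group == "g2", ]$mean_icc, 0.6)
  expect_equal(rep_$overall$mean_icc, 0.8)
  expect_equal(rep_$overall$robust_percentage, 100 / 3)
  expect_equal(format_robust_pct(552, 1328), "41.6% (552/1328)")
})

test_that("stratified comparison: identity, separation and antisymmetry", {
  set.seed(11)
  mk_pd <- function(easy, chall) {
    data.frame(
      tumor_id = c(rep(sprintf("e%d", seq_along(easy)), each = 1),
                   rep(sprintf("c%d", seq_along(chall)), each = 1)),
      observer_a = "obs1", observer_b = "obs2",
      dsc = c(easy, chall),
      difficulty = c(rep("easy", length(easy)),
                     rep("challenging", length(chall))))
  }
  same <- rnorm(20, 0.8, 0.02)
  pd0 <- mk_pd(same, same)
  out0 <- stratified_compare(pd0)
  expect_equal(out0$mean_difference, 0)
  expect_gt(out0$p_value, 0.99)
  pd1 <- mk_pd(rnorm(94, 0.83, 0.03), rnorm(35, 0.75, 0.05))
  out1 <- stratified_compare(pd1)
  expect_lt(out1$p_value, 0.001)
  # swapping strata labels flips the sign of t
  pd_sw <- pd1
  pd_sw$difficulty <- ifelse(pd_sw$difficulty == "easy", "challenging",
                             "easy")
  out_sw <- stratified_compare(pd_sw)
  expect_equal(out_sw$t_statistic, -out1$t_statistic, tolerance = 1e-10)
  expect_error(stratified_compare(mk_pd(rnorm(5, 0.8, 0.1), 0.7)),
               "at least 2")
})
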