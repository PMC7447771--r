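# Compact study conditions for unit tests: smaller grids and lesions keep
# the suite fast while preserving the easy/challenging contrast.
# 1D ROI wrapper: a vector of values as an Nx1x1 image plus full mask
roi_from_values <- function(vals) {
  n <- length(vals)
  list(vol = image_volume(array(vals, c(n, 1, 1)), c(1, 1, 1)),
       mask = seg_mask(array(TRUE, c(n, 1, 1)), c(1, 1, 1)))
}

small_cohort_config <- function() {
  cfg <- cohort_config(grid_shape = c(48, 48, 48))
  cfg$easy$volume_mean_cm3 <- 3.5
  cfg$easy$volume_sd_cm3 <- 0.8
  cfg$easy$volume_min_cm3 <- 2
  cfg$easy$volume_max_cm3 <- 6
  cfg$challenging$volume_mean_cm3 <- 7
  cfg$challenging$volume_sd_cm3 <- 1.2
  cfg$challenging$volume_min_cm3 <- 4.5
  cfg$challenging$volume_max_cm3 <- 9.5
  cfg
}
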