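#' Extraction configuration
#'
#' Settings for the preprocessing + feature-extraction chain: normalization
#' mode, isotropic resampling target, fixed-bin-width discretization (with
#' optional automatic bin-width selection over the cohort's ROI ranges), and
#' single-level wavelet decomposition.
#'
#' @param normalization_mode `"whole_image"` or `"foreground"`.
#' @param target_mm isotropic resampling target (mm); `NULL` disables
#'   resampling.
#' @param bin_width fixed discretization bin width (normalized units).
#' @param bin_width_auto if `TRUE`, select the bin width from the cohort's
#'   ROI ranges with [select_bin_width()].
#' @param bin_width_candidates candidate widths for automatic selection.
#' @param bin_range target bin-count interval for the selection rule.
#' @param wavelet_enabled compute features on the 8 wavelet sub-bands too.
#' @param wavelet_family wavelet family (`"haar"`).
#' @param gldm_alpha GLDM dependence tolerance.
#' @return An `extraction_config` object.
#' @export
extraction_config <- function(normalization_mode = "whole_image",
                              target_mm = 1.0,
                              bin_width = 0.1,
                              bin_width_auto = FALSE,
                              bin_width_candidates = c(0.01, 0.02, 0.05,
                                                       0.1, 0.2, 0.5, 1.0),
                              bin_range = c(16L, 128L),
                              wavelet_enabled = TRUE,
                              wavelet_family = "haar",
                              gldm_alpha = 0) {
  structure(list(normalization_mode = normalization_mode,
                 target_mm = target_mm,
                 bin_width = bin_width, bin_width_auto = bin_width_auto,
                 bin_width_candidates = bin_width_candidates,
                 bin_range = as.integer(bin_range),
                 wavelet_enabled = isTRUE(wavelet_enabled),
                 wavelet_family = wavelet_family,
                 gldm_alpha = gldm_alpha),
            class = "extraction_config")
}

texture_kinds <- c(glcm = "GLCM", glrlm = "GLRLM", glszm = "GLSZM",
                   ngtdm = "NGTDM", gldm = "GLDM")

#' Feature manifest for a configuration
#'
#' Enumerates every feature the extractor produces under `config`, with its
#' group and image filter. Shape features appear only under the `original`
#' filter.
#'
#' @param config an [extraction_config()].
#' @return data.frame with columns `name`, `group`, `filter`.
#' @export
feature_manifest <- function(config = extraction_config()) {
  dummy <- structure(list(
    levels = array(c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L), c(2, 2, 2)),
    n_levels = 2L, bin_width = 1, spacing_mm = c(1, 1, 1)),
    class = "discretized_roi")
  group_names <- c(
    list(firstorder = names(extract_firstorder(
      image_volume(array(stats::rnorm(27), c(3, 3, 3)), c(1, 1, 1)),
      seg_mask(array(1, c(3, 3, 3)), c(1, 1, 1))))),
    lapply(texture_kinds, function(kind)
      names(texture_features(compute_texture(dummy, kind)))))
  filters <- "original"
  if (config$wavelet_enabled)
    filters <- c(filters, paste0("wavelet-", wavelet_band_names()))
  rows <- list(data.frame(
    name = paste0("original_shape_", names(shape_feature_names())),
    group = "shape", filter = "original"))
  for (f in filters) {
    for (g in names(group_names)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(f, g, group_names[[g]], sep = "_"),
        group = g, filter = f)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

shape_feature_names <- function() {
  nm <- c("mesh_volume", "voxel_volume", "surface_area",
          "surface_to_volume_ratio", "sphericity", "maximum_3d_diameter",
          "major_axis_length", "minor_axis_length", "least_axis_length",
          "elongation", "flatness")
  stats::setNames(nm, nm)
}

wavelet_band_names <- function() {
  eg <- expand.grid(c3 = c("L", "H"), c2 = c("L", "H"), c1 = c("L", "H"),
                    stringsAsFactors = FALSE)
  paste0(eg$c1, eg$c2, eg$c3)   # LLL, LLH, ..., HHH (axis order)
}

#' Extract all configured features for one image + mask
#'
#' Runs the preprocessing chain (normalize, resample to isotropic grid),
#' computes shape features on the mask, and first-order plus the five
#' texture families on the original image and (if enabled) each of the 8
#' wavelet sub-bands. Output order follows [feature_manifest()].
#'
#' @param vol an `image_volume`.
#' @param mask an aligned nonempty `seg_mask`.
#' @param config an [extraction_config()].
#' @return named numeric vector (NA = feature undefined for this ROI).
#' @export
extract_all <- function(vol, mask, config = extraction_config()) {
  assert_aligned(vol, mask)
  pre <- preprocess_for_extraction(vol, list(mask), config)
  vec <- extract_on_prepared(pre$filters, pre$masks[[1]], config)
  stopifnot(identical(names(vec), feature_manifest(config)$name))
  vec
}

# normalize + resample + wavelet-decompose once; masks ride along
preprocess_for_extraction <- function(vol, masks, config) {
  v <- normalize(vol, config$normalization_mode)
  if (!is.null(config$target_mm)) {
    rs <- resample_isotropic(v, masks, config$target_mm)
    v <- rs$image; masks <- rs$masks
  }
  filters <- list(original = v)
  if (config$wavelet_enabled) {
    wb <- wavelet_decompose(v, config$wavelet_family)
    names(wb) <- paste0("wavelet-", names(wb))
    filters <- c(filters, wb)
  }
  list(filters = filters, masks = masks)
}

extract_on_prepared <- function(filters, mask, config) {
  spec <- discretization_spec(config$bin_width, config$bin_range)
  out <- stats::setNames(
    extract_shape(mask),
    paste0("original_shape_", names(shape_feature_names())))
  for (f in names(filters)) {
    img <- filters[[f]]
    fo <- extract_firstorder(img, mask, spec)
    names(fo) <- paste(f, "firstorder", names(fo), sep = "_")
    out <- c(out, fo)
    disc <- discretize(img, mask, spec)
    for (g in names(texture_kinds)) {
      tm <- compute_texture(disc, texture_kinds[[g]],
                            params = list(alpha = config$gldm_alpha))
      tf <- texture_features(tm)
      names(tf) <- paste(f, g, names(tf), sep = "_")
      out <- c(out, tf)
    }
  }
  out
}

#' Extract features for a whole cohort into a long-format table
#'
#' Per tumor, the image is normalized, resampled and wavelet-decomposed
#' once; features are then extracted against every observer's mask. When
#' `config$bin_width_auto` is set, a single shared bin width is first
#' selected from all (tumor, observer) ROI intensity ranges.
#'
#' @param cohort list of observer sets from [make_cohort()] /
#'   [read_cohort()].
#' @param config an [extraction_config()].
#' @return A `feature_table`: long data.frame (tumor_id, observer_id,
#'   feature_name, value) with attributes `difficulty` (named vector per
#'   tumor) and `bin_width` (the width actually used).
#' @export
cohort_feature_table <- function(cohort, config = extraction_config()) {
  prepared <- lapply(cohort, function(os)
    preprocess_for_extraction(os$image, os$observer_masks, config))
  if (isTRUE(config$bin_width_auto)) {
    ranges <- unlist(lapply(prepared, function(pre)
      vapply(pre$masks, function(m) {
        x <- pre$filters$original$voxels[m$voxels]
        diff(range(x))
      }, numeric(1))))
    ranges <- ranges[ranges > 0]
    config$bin_width <- select_bin_width(
      ranges, config$bin_width_candidates,
      discretization_spec(config$bin_width, config$bin_range))
  }
  rows <- list()
  for (t in seq_along(cohort)) {
    os <- cohort[[t]]
    pre <- prepared[[t]]
    for (k in seq_along(pre$masks)) {
      vec <- extract_on_prepared(pre$filters, pre$masks[[k]], config)
      rows[[length(rows) + 1L]] <- data.frame(
        tumor_id = os$tumor_id,
        observer_id = names(os$observer_masks)[k],
        feature_name = names(vec), value = unname(vec))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "difficulty") <- stats::setNames(
    vapply(cohort, `[[`, character(1), "difficulty"),
    vapply(cohort, `[[`, character(1), "tumor_id"))
  attr(out, "bin_width") <- config$bin_width
  class(out) <- c("feature_table", "data.frame")
  out
}
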