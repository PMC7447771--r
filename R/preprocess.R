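#' Intensity discretization settings
#'
#' @param bin_width fixed bin width in (normalized) intensity units.
#' @param target_bin_range integer interval of acceptable per-ROI bin counts
#'   used by the bin-width selection rule.
#' @return A `discretization_spec` object.
#' @export
discretization_spec <- function(bin_width = 0.1,
                                target_bin_range = c(16L, 128L)) {
  stopifnot(bin_width > 0, length(target_bin_range) == 2L,
            target_bin_range[1] >= 1, target_bin_range[1] <= target_bin_range[2])
  structure(list(bin_width = as.numeric(bin_width),
                 target_bin_range = as.integer(target_bin_range)),
            class = "discretization_spec")
}

#' Normalize image intensities
#'
#' Two conventions are supported. `whole_image` centers and scales using the
#' mean and standard deviation of all voxels. `foreground` first identifies
#' the air background (Otsu threshold on the intensity histogram; the largest
#' connected below-threshold component is taken as air), computes mean and
#' standard deviation over non-background voxels only, and applies the same
#' affine transform to every voxel.
#'
#' @param vol an `image_volume` with more than one distinct intensity.
#' @param mode `"whole_image"` or `"foreground"`.
#' @return the normalized `image_volume`.
#' @export
normalize <- function(vol, mode = c("whole_image", "foreground")) {
  mode <- match.arg(mode)
  v <- vol$voxels
  support <- if (mode == "foreground") !background_air(v) else
    array(TRUE, dim(v))
  mu <- mean(v[support])
  sigma <- stats::sd(v[support])
  if (!is.finite(sigma) || sigma < 1e-12)
    stop("degenerate image: zero intensity variance over the normalization ",
         "support", call. = FALSE)
  image_volume((v - mu) / sigma, vol$spacing_mm, vol$origin_mm)
}

# Otsu threshold over a 256-bin histogram; air = largest connected component
# of below-threshold voxels (6-connectivity).
background_air <- function(v) {
  thr <- otsu_threshold(v)
  below <- array(v < thr, dim(v))
  if (!any(below)) return(array(FALSE, dim(v)))
  lab <- label_components(below, connectivity = 6)
  keep <- which.max(tabulate(lab[lab > 0L]))
  lab == keep
}

otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (diff(rng) < 1e-12) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  edges[k + 1L]
}

#' Resample a volume (and its masks) to an isotropic grid
#'
#' The image is interpolated trilinearly onto a `target_mm` isotropic grid
#' covering the original extent; masks are resampled by nearest neighbour
#' onto the same grid. Output spacing is exactly `target_mm` on every axis.
#'
#' @param vol an `image_volume`.
#' @param masks list of `seg_mask` aligned with `vol` (may be empty).
#' @param target_mm target voxel size in mm.
#' @return list with `image` and `masks` on the new grid.
#' @export
resample_isotropic <- function(vol, masks = list(), target_mm = 1.0) {
  if (target_mm <= 0) stop("target_mm must be positive", call. = FALSE)
  for (m in masks) assert_aligned(vol, m)
  dm <- dim(vol$voxels)
  sp <- vol$spacing_mm
  if (all(abs(sp - target_mm) < 1e-12)) {
    return(list(image = vol, masks = masks))
  }
  # new index grid stays within the original extent (no extrapolation)
  n_new <- pmax(2L, floor((dm - 1) * sp / target_mm) + 1L)
  # continuous source index (1-based) of each target voxel centre, per axis
  src <- lapply(1:3, function(ax)
    (seq_len(n_new[ax]) - 1) * target_mm / sp[ax] + 1)
  img <- trilinear_sample(vol$voxels, src)
  out_masks <- lapply(masks, function(m) {
    nn <- lapply(1:3, function(ax) pmin(dm[ax], pmax(1L, round(src[[ax]]))))
    seg_mask(m$voxels[nn[[1]], nn[[2]], nn[[3]]],
             rep(target_mm, 3), m$origin_mm)
  })
  list(image = image_volume(img, rep(target_mm, 3), vol$origin_mm),
       masks = out_masks)
}

# Vectorized separable trilinear sampling of a 3D array at the tensor grid
# given by per-axis continuous 1-based indices.
trilinear_sample <- function(a, src) {
  dm <- dim(a)
  lo <- lapply(1:3, function(ax) pmin(dm[ax] - 1L, pmax(1L, floor(src[[ax]]))))
  fr <- lapply(1:3, function(ax) pmin(1, pmax(0, src[[ax]] - lo[[ax]])))
  n <- vapply(src, length, integer(1))
  out <- array(0, n)
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    w <- outer(outer(if (bx) fr[[1]] else 1 - fr[[1]],
                     if (by) fr[[2]] else 1 - fr[[2]]),
               if (bz) fr[[3]] else 1 - fr[[3]])
    out <- out + w * a[lo[[1]] + bx, lo[[2]] + by, lo[[3]] + bz,
                       drop = FALSE]
  }
  out
}

#' Select a shared fixed bin width from per-ROI intensity ranges
#'
#' For each candidate width `w`, counts how many ROIs have
#' `ceiling(range / w)` inside the target bin-count interval, and returns the
#' width maximizing that count; ties are broken toward the smallest width.
#'
#' @param roi_ranges positive per-ROI intensity ranges.
#' @param candidates candidate bin widths.
#' @param spec a [discretization_spec()] carrying the target bin interval.
#' @return the selected bin width (an element of `candidates`).
#' @export
select_bin_width <- function(roi_ranges,
                             candidates = c(0.01, 0.02, 0.05, 0.1, 0.2,
                                            0.5, 1.0),
                             spec = discretization_spec()) {
  if (!length(roi_ranges) || !length(candidates))
    stop("roi_ranges and candidates must be nonempty", call. = FALSE)
  stopifnot(all(roi_ranges > 0), all(candidates > 0))
  lo <- spec$target_bin_range[1]
  hi <- spec$target_bin_range[2]
  counts <- vapply(candidates, function(w) {
    nb <- ceiling(roi_ranges / w)
    sum(nb >= lo & nb <= hi)
  }, numeric(1))
  best <- counts == max(counts)
  min(candidates[best])
}

#' Discretize ROI intensities with a fixed bin width
#'
#' Bin edges are anchored at integer multiples of the bin width:
#' `level(x) = floor(I(x)/w) - floor(min_ROI/w) + 1`. The result is restricted
#' to the mask's bounding box, with 0 outside the ROI.
#'
#' @param vol an `image_volume`.
#' @param mask an aligned, nonempty `seg_mask`.
#' @param spec a [discretization_spec()].
#' @return A `discretized_roi`: list with `levels` (integer grid over the
#'   bounding box, 0 outside ROI), `n_levels`, `bin_width`, `spacing_mm`.
#' @export
discretize <- function(vol, mask, spec = discretization_spec()) {
  assert_aligned(vol, mask)
  if (n_foreground(mask) == 0L) stop("empty mask", call. = FALSE)
  bb <- mask_bbox(mask$voxels, 0L)
  v <- vol$voxels[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  m <- mask$voxels[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  w <- spec$bin_width
  lev <- array(0L, dim(v))
  base <- floor(min(v[m]) / w)
  lev[m] <- as.integer(floor(v[m] / w) - base + 1L)
  structure(list(levels = lev, n_levels = max(lev), bin_width = w,
                 spacing_mm = vol$spacing_mm),
            class = "discretized_roi")
}

#' Single-level 3D stationary wavelet decomposition
#'
#' Separable undecimated (stationary) discrete wavelet transform with
#' circular boundary handling. Low- and high-pass filters are applied along
#' each axis in turn, producing 8 same-size sub-bands labelled `LLL` ... `HHH`
#' (letter order = axis order). With the default Haar filters
#' (1/2, 1/2) and (1/2, -1/2) the transform preserves total energy exactly,
#' and sub-bands stay on the original grid so segmentation masks apply
#' unchanged.
#'
#' @param vol an `image_volume` with every axis of length >= 2.
#' @param family wavelet family; `"haar"` is implemented.
#' @return named list of 8 `image_volume` sub-bands.
#' @export
wavelet_decompose <- function(vol, family = "haar") {
  if (!identical(family, "haar"))
    stop("unsupported wavelet family: ", family, call. = FALSE)
  dm <- dim(vol$voxels)
  short <- which(dm < 2L)
  if (length(short))
    stop("axis ", short[1], " too short for wavelet decomposition",
         call. = FALSE)
  lp <- c(0.5, 0.5)
  hp <- c(0.5, -0.5)
  filt_axis <- function(a, h, axis) {
    # circular convolution y[i] = h[1]*a[i] + h[2]*a[i+1] along `axis`
    nxt <- shift_circular(a, axis)
    h[1] * a + h[2] * nxt
  }
  bands <- list(L = vol$voxels)
  for (axis in 1:3) {
    new <- list()
    for (nm in names(bands)) {
      new[[paste0(nm, "L")]] <- filt_axis(bands[[nm]], lp, axis)
      new[[paste0(nm, "H")]] <- filt_axis(bands[[nm]], hp, axis)
    }
    bands <- new
  }
  names(bands) <- sub("^L", "", names(bands))   # strip seed letter
  # name letters accumulated as axis1, axis2, axis3
  lapply(bands, function(b) image_volume(b, vol$spacing_mm, vol$origin_mm))
}

# Circular shift by +1 along one axis (a[i] -> a[i+1], wrapping).
shift_circular <- function(a, axis) {
  dm <- dim(a)
  idx <- lapply(dm, seq_len)
  idx[[axis]] <- c(2:dm[axis], 1L)
  a[idx[[1]], idx[[2]], idx[[3]]]
}
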