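#' Image volumes and segmentation masks
#'
#' An `image_volume` is a 3D scalar grid with per-axis voxel spacing (mm) and
#' a world origin (mm); a `seg_mask` is a binary grid with the same geometry.
#' World position of voxel index (i, j, k) (0-based) is
#' `origin + c(i, j, k) * spacing`. These two containers are what every stage
#' of the pipeline consumes and produces.
#'
#' @param voxels numeric 3D array (logical or 0/1 for masks).
#' @param spacing_mm positive numeric of length 3, voxel size per axis in mm.
#' @param origin_mm numeric of length 3, world coordinate of voxel (0,0,0).
#' @return An object of class `image_volume` or `seg_mask`.
#' @examples
#' v <- image_volume(array(rnorm(27), c(3, 3, 3)), c(1, 1, 1))
#' m <- seg_mask(array(c(rep(0, 13), 1, rep(0, 13)), c(3, 3, 3)), c(1, 1, 1))
#' check_aligned(v, m)
#' @export
image_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  voxels <- as_grid3d(voxels)
  stopifnot(all(is.finite(voxels)))
  geom_check(spacing_mm, origin_mm)
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
seg_mask <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  voxels <- as_grid3d(voxels)
  u <- unique(as.vector(voxels))
  if (!all(u %in% c(0, 1)))
    stop("mask voxels must be binary (0/1)", call. = FALSE)
  geom_check(spacing_mm, origin_mm)
  structure(list(voxels = array(voxels != 0, dim(voxels)),
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "seg_mask")
}

as_grid3d <- function(voxels) {
  if (is.null(dim(voxels)) || length(dim(voxels)) != 3L)
    stop("expected a 3D array, got ",
         paste(dim(voxels) %||% length(voxels), collapse = "x"),
         call. = FALSE)
  if (is.logical(voxels)) voxels else voxels + 0
}

geom_check <- function(spacing_mm, origin_mm) {
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(origin_mm) == 3L, all(is.finite(origin_mm)))
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume", paste(dim(x$voxels), collapse = "x"),
      "spacing", paste(signif(x$spacing_mm, 4), collapse = "x"), "mm\n")
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat("seg_mask", paste(dim(x$voxels), collapse = "x"),
      "spacing", paste(signif(x$spacing_mm, 4), collapse = "x"),
      "mm |", sum(x$voxels), "foreground voxels\n")
  invisible(x)
}

n_foreground <- function(mask) sum(mask$voxels)

#' Check geometric alignment of a volume and a mask
#'
#' @param vol an `image_volume`.
#' @param mask a `seg_mask` (or second `image_volume`).
#' @param tol_mm metadata tolerance in mm.
#' @return `TRUE` iff shape, spacing and origin all match within `tol_mm`.
#' @export
check_aligned <- function(vol, mask, tol_mm = 1e-6) {
  identical(dim(vol$voxels), dim(mask$voxels)) &&
    all(abs(vol$spacing_mm - mask$spacing_mm) <= tol_mm) &&
    all(abs(vol$origin_mm - mask$origin_mm) <= tol_mm)
}

assert_aligned <- function(vol, mask) {
  if (!check_aligned(vol, mask))
    stop("image and mask geometry are not aligned", call. = FALSE)
  invisible(TRUE)
}

#' Read and write volumes as NIfTI-1
#'
#' Volumes are stored axis-aligned; spacing and origin are carried in the
#' sform matrix. Images are written as 32-bit float, masks as unsigned 8-bit.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param x an `image_volume` or `seg_mask`.
#' @param mask logical; read the file as a binary mask.
#' @return `read_volume` returns an `image_volume` (or `seg_mask` when
#'   `mask = TRUE`); `write_volume` returns `path` invisibly.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to parse NIfTI file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))   # drop NIfTI bookkeeping attributes
  if (length(dim(a)) != 3L)
    stop("expected 3D data in ", path, ", got ",
         length(dim(a)), "D", call. = FALSE)
  xf <- RNifti::xform(img)
  spacing <- abs(diag(xf)[1:3])
  origin <- xf[1:3, 4]
  if (mask) seg_mask(a != 0, spacing, origin) else
    image_volume(a, spacing, origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, c("image_volume", "seg_mask")))
  dtype <- if (inherits(x, "seg_mask")) "uint8" else "float"
  a <- if (inherits(x, "seg_mask")) array(as.integer(x$voxels),
                                          dim(x$voxels)) else x$voxels
  img <- RNifti::asNifti(a, datatype = dtype)
  sf <- diag(c(x$spacing_mm, 1))
  sf[1:3, 4] <- x$origin_mm
  RNifti::`sform<-`(img, structure(sf, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}
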