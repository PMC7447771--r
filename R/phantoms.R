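#' Specification of a synthetic tumor phantom
#'
#' Describes one simulated contrast-enhancing lesion: an (optionally
#' modulated) ellipsoid with additive intra-lesion texture and background
#' noise. Two morphology classes are supported: `"easy"` lesions are
#' homogeneous, round and sharp-margined; `"challenging"` lesions are larger,
#' heterogeneous and spiculated, with an irregular margin.
#'
#' @param difficulty `"easy"` or `"challenging"`.
#' @param radius_mm base ellipsoid semi-axes in mm (length 1 or 3).
#' @param grid_shape voxels per axis.
#' @param spacing_mm voxel size per axis (mm).
#' @param n_spicules number of spicules (must be 0 for easy, >= 3 for
#'   challenging).
#' @param spicule_length_mm spicule length (mm).
#' @param intensity_contrast lesion-minus-background mean intensity
#'   difference, arbitrary units.
#' @param texture_sigma amplitude of the smoothed intra-lesion intensity
#'   field; easy lesions must stay below `homogeneous_bound`.
#' @param noise_sigma additive white-noise amplitude over the whole grid.
#' @param edge_smooth_mm Gaussian blur (mm) applied to the lesion's
#'   contrast profile, emulating the scanner point-spread function and
#'   partial-volume grading at the margin; 0 gives a hard-edged lesion.
#' @param n_dark_foci number of small interior low-signal foci
#'   (non-enhancing components such as necrosis or septations); they anchor
#'   the ROI intensity minimum inside the lesion. 0 disables them.
#' @param dark_focus_radius_mm radius of each dark focus.
#' @param margin_irregularity relative amplitude of the smoothed radial
#'   modulation of the lesion boundary (0 = perfectly smooth margin).
#' @param homogeneous_bound upper bound on `texture_sigma / intensity_contrast`
#'   for a lesion to qualify as homogeneous ("easy").
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(difficulty = c("easy", "challenging"),
                         radius_mm = 10,
                         grid_shape = c(64, 64, 64),
                         spacing_mm = c(1, 1, 1),
                         n_spicules = if (difficulty[1] == "easy") 0L else 4L,
                         spicule_length_mm = 5,
                         intensity_contrast = 150,
                         texture_sigma = if (difficulty[1] == "easy") 10 else 45,
                         noise_sigma = 10,
                         edge_smooth_mm = 0.8,
                         n_dark_foci = 3L,
                         dark_focus_radius_mm = 1.2,
                         margin_irregularity =
                           if (difficulty[1] == "easy") 0 else 0.12,
                         homogeneous_bound = 0.15,
                         seed = 1L) {
  difficulty <- match.arg(difficulty)
  radius_mm <- rep(as.numeric(radius_mm), length.out = 3)
  spec <- structure(list(
    difficulty = difficulty, radius_mm = radius_mm,
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    n_spicules = as.integer(n_spicules),
    spicule_length_mm = as.numeric(spicule_length_mm),
    intensity_contrast = as.numeric(intensity_contrast),
    texture_sigma = as.numeric(texture_sigma),
    noise_sigma = as.numeric(noise_sigma),
    edge_smooth_mm = as.numeric(edge_smooth_mm),
    n_dark_foci = as.integer(n_dark_foci),
    dark_focus_radius_mm = as.numeric(dark_focus_radius_mm),
    margin_irregularity = as.numeric(margin_irregularity),
    homogeneous_bound = as.numeric(homogeneous_bound),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(all(spec$radius_mm > 0), all(spec$spacing_mm > 0),
            all(spec$grid_shape >= 8), spec$spicule_length_mm > 0,
            spec$noise_sigma >= 0, spec$texture_sigma >= 0,
            spec$edge_smooth_mm >= 0, spec$n_dark_foci >= 0,
            spec$dark_focus_radius_mm > 0, spec$margin_irregularity >= 0)
  if (spec$difficulty == "easy") {
    if (spec$n_spicules != 0L)
      stop("easy phantoms must have n_spicules = 0", call. = FALSE)
    if (spec$texture_sigma > spec$homogeneous_bound * spec$intensity_contrast)
      stop("easy phantoms must be homogeneous: texture_sigma exceeds ",
           "homogeneous_bound * intensity_contrast", call. = FALSE)
  } else if (spec$n_spicules < 3L) {
    stop("challenging phantoms need n_spicules >= 3", call. = FALSE)
  }
  invisible(spec)
}

#' Generate a synthetic tumor image and its ground-truth mask
#'
#' Builds the lesion as a voxelized ellipsoid whose radius is optionally
#' modulated by a smoothed random field (irregular margin) and decorated with
#' tapering spicules; the image is background plus `intensity_contrast`
#' inside the lesion, a smoothed intra-lesion texture field, and white
#' background noise. Spicule voxel sets are attached to the mask (attribute
#' `"spicules"`) so observer simulation can drop spicules individually.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (an `image_volume`) and `mask` (a `seg_mask`).
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  dm <- spec$grid_shape
  sp <- spec$spacing_mm
  half_extent <- (dm - 1) * sp / 2
  reach <- spec$radius_mm * (1 + spec$margin_irregularity) +
    (if (spec$n_spicules > 0) spec$spicule_length_mm else 0) + 2
  for (ax in 1:3) {
    if (reach[ax] > half_extent[ax])
      stop(sprintf(
        "lesion does not fit in grid along axis %d: needs %.1f mm, has %.1f mm",
        ax, reach[ax], half_extent[ax]), call. = FALSE)
  }
  cx <- lapply(1:3, function(ax) ((seq_len(dm[ax]) - 1) * sp[ax]) -
                 half_extent[ax])
  X <- array(rep(cx[[1]], times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(cx[[2]], each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(cx[[3]], each = dm[1] * dm[2]), dm)

  with_seed(spec$seed, {
    # ellipsoid radial coordinate; <= 1 is inside the unmodulated lesion
    u <- sqrt((X / spec$radius_mm[1])^2 + (Y / spec$radius_mm[2])^2 +
                (Z / spec$radius_mm[3])^2)
    if (spec$margin_irregularity > 0) {
      bump <- smooth_noise_field(dm, 3 / mean(sp))
      core <- u <= 1 + spec$margin_irregularity * bump
    } else {
      core <- u <= 1
    }

    spicules <- list()
    if (spec$n_spicules > 0) {
      dirs <- matrix(stats::rnorm(3 * spec$n_spicules), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      pts <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
      for (s in seq_len(spec$n_spicules)) {
        d <- dirs[s, ]
        # surface point of the ellipsoid along direction d
        tsurf <- 1 / sqrt(sum((d / spec$radius_mm)^2))
        p0 <- d * (tsurf - 1)          # anchor just inside the surface
        p1 <- d * (tsurf + spec$spicule_length_mm)
        seg <- p1 - p0
        len2 <- sum(seg^2)
        tproj <- pmin(1, pmax(0, ((pts[, 1] - p0[1]) * seg[1] +
                                    (pts[, 2] - p0[2]) * seg[2] +
                                    (pts[, 3] - p0[3]) * seg[3]) / len2))
        dx <- pts[, 1] - (p0[1] + tproj * seg[1])
        dy <- pts[, 2] - (p0[2] + tproj * seg[2])
        dz <- pts[, 3] - (p0[3] + tproj * seg[3])
        rad <- 1.6 - 1.1 * tproj       # tapering spicule radius (mm)
        inside <- (dx^2 + dy^2 + dz^2) <= rad^2
        spic_idx <- which(inside & !as.vector(core))
        if (length(spic_idx)) spicules[[length(spicules) + 1L]] <- spic_idx
      }
    }

    mask <- core
    for (s in spicules) mask[s] <- TRUE

    profile <- mask + 0
    if (spec$edge_smooth_mm > 0)
      profile <- fft_gauss_smooth(profile, spec$edge_smooth_mm / sp)
    img <- 100 + spec$intensity_contrast * profile
    if (spec$texture_sigma > 0) {
      tex <- smooth_noise_field(dm, 2.5 / mean(sp))
      img[mask] <- img[mask] + spec$texture_sigma * tex[mask]
    }
    if (spec$n_dark_foci > 0) {
      # interior non-enhancing foci: deep in the core so every plausible
      # observer contour contains them; they fix the ROI intensity minimum
      for (fi in seq_len(spec$n_dark_foci)) {
        u_f <- stats::rnorm(3)
        u_f <- u_f / sqrt(sum(u_f^2)) * stats::runif(1)^(1 / 3) * 0.5
        ctr <- u_f * spec$radius_mm
        d2 <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2
        img[d2 <= spec$dark_focus_radius_mm^2] <-
          100 - 0.3 * spec$intensity_contrast
      }
    }
    if (spec$noise_sigma > 0)
      img <- img + stats::rnorm(length(img), sd = spec$noise_sigma)

    m <- seg_mask(mask, sp)
    attr(m, "spicules") <- spicules
    list(image = image_volume(img, sp), mask = m)
  })
}

#' Specification of a simulated observer's segmentation behaviour
#'
#' An observer's mask is modelled as the true lesion surface displaced by a
#' smoothed Gaussian field (boundary placement error), followed by a random
#' uniform dilation/erosion (systematic over-/under-segmentation on that
#' tumor) and per-spicule retention (an observer may not include every
#' spicule).
#'
#' @param boundary_sigma_mm standard deviation (mm) of the smoothed random
#'   surface displacement field.
#' @param morph_radius_range_mm signed range (mm) of the random
#'   dilation/erosion radius: the radius is drawn uniformly from this
#'   interval, positive values dilate, negative values erode; `c(0, 0)`
#'   disables it.
#' @param spicule_keep_prob probability each spicule is included.
#' @param seed integer seed.
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(boundary_sigma_mm = 1,
                              morph_radius_range_mm = c(-0.5, 0.5),
                              spicule_keep_prob = 1,
                              seed = 1L) {
  stopifnot(boundary_sigma_mm >= 0, length(morph_radius_range_mm) == 2L,
            morph_radius_range_mm[1] <= morph_radius_range_mm[2],
            spicule_keep_prob >= 0, spicule_keep_prob <= 1)
  structure(list(boundary_sigma_mm = as.numeric(boundary_sigma_mm),
                 morph_radius_range_mm = as.numeric(morph_radius_range_mm),
                 spicule_keep_prob = as.numeric(spicule_keep_prob),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Simulate one observer's manual segmentation of a lesion
#'
#' @param truth ground-truth `seg_mask` (nonempty), as returned by
#'   [make_phantom()].
#' @param pert a [perturbation_spec()].
#' @param max_retries redraws allowed when a perturbation empties the mask.
#' @return A nonempty `seg_mask` on the same grid.
#' @export
simulate_observer <- function(truth, pert, max_retries = 5L) {
  stopifnot(inherits(truth, "seg_mask"), inherits(pert, "perturbation_spec"))
  if (n_foreground(truth) == 0L) stop("truth mask is empty", call. = FALSE)
  identity_pert <- pert$boundary_sigma_mm == 0 &&
    all(pert$morph_radius_range_mm == 0) && pert$spicule_keep_prob == 1
  if (identity_pert) return(truth)

  sp <- truth$spacing_mm
  dm <- dim(truth$voxels)
  spicules <- attr(truth, "spicules") %||% list()
  band <- 4 * pert$boundary_sigma_mm + max(abs(pert$morph_radius_range_mm)) + 3

  # all morphology happens within `band` mm of the lesion surface, so work
  # on the lesion bounding box (padded by the band) for speed
  pad <- ceiling(band / sp) + 2L
  bb <- mask_bbox(truth$voxels, pad)
  tv <- truth$voxels[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  sub_dm <- dim(tv)
  spic_sub <- lapply(spicules, function(idx) remap_indices(idx, dm, bb))

  with_seed(pert$seed, {
    sd0 <- signed_distance(tv, sp, max_mm = band)
    for (try in seq_len(max_retries)) {
      m <- if (pert$boundary_sigma_mm > 0) {
        g <- smooth_noise_field(sub_dm, 3 / mean(sp)) * pert$boundary_sigma_mm
        sd0 + g < 0
      } else tv
      if (any(pert$morph_radius_range_mm != 0)) {
        r <- stats::runif(1, pert$morph_radius_range_mm[1],
                          pert$morph_radius_range_mm[2])
        if (any(m) && r != 0) {
          sd1 <- signed_distance(m, sp, max_mm = abs(r) + 2)
          m <- sd1 - r < 0
        }
      }
      if (pert$spicule_keep_prob < 1 && length(spic_sub)) {
        drop <- stats::runif(length(spic_sub)) > pert$spicule_keep_prob
        for (s in which(drop)) m[spic_sub[[s]]] <- FALSE
      }
      if (any(m)) {
        lab <- label_components(m, connectivity = 26)
        keep <- which.max(tabulate(lab[lab > 0L]))
        full <- array(FALSE, dm)
        full[bb[[1]], bb[[2]], bb[[3]]] <- lab == keep
        return(seg_mask(full, sp, truth$origin_mm))
      }
    }
    stop("observer perturbation emptied the mask after ", max_retries,
         " attempts; perturbation too large for this lesion", call. = FALSE)
  })
}

# Padded bounding box of a logical array, as a list of 3 index vectors.
mask_bbox <- function(mask, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  dm <- dim(mask)
  pad <- rep(pad, length.out = 3)
  lapply(1:3, function(ax) {
    lo <- max(1L, min(idx[, ax]) - pad[ax])
    hi <- min(dm[ax], max(idx[, ax]) + pad[ax])
    lo:hi
  })
}

# Remap linear indices on the full grid into linear indices on the cropped
# grid defined by bbox index vectors (dropping voxels outside the box).
remap_indices <- function(idx, dm, bb) {
  if (!length(idx)) return(integer(0))
  co <- arrayInd(idx, dm)
  off <- vapply(bb, function(v) v[1] - 1L, integer(1))
  nd <- vapply(bb, length, integer(1))
  co <- sweep(co, 2, off)
  ok <- co[, 1] >= 1 & co[, 1] <= nd[1] & co[, 2] >= 1 & co[, 2] <= nd[2] &
    co[, 3] >= 1 & co[, 3] <= nd[3]
  co <- co[ok, , drop = FALSE]
  co[, 1] + (co[, 2] - 1L) * nd[1] + (co[, 3] - 1L) * nd[1] * nd[2]
}

#' Default cohort configuration
#'
#' Study conditions for the synthetic cohort: lesion volumes are drawn per
#' difficulty class (means 5.3 and 10.4 cm3 for easy and challenging), and
#' each class carries its own observer perturbation scale, chosen so that
#' pairwise Dice agreement falls around 0.83 (easy) and 0.75 (challenging).
#'
#' @param grid_shape,spacing_mm phantom grid geometry.
#' @return nested list of class parameters consumed by [make_cohort()].
#' @export
cohort_config <- function(grid_shape = c(64, 64, 64),
                          spacing_mm = c(1, 1, 1)) {
  list(
    grid_shape = grid_shape,
    spacing_mm = spacing_mm,
    easy = list(
      volume_mean_cm3 = 5.3, volume_sd_cm3 = 1.5, volume_min_cm3 = 2,
      volume_max_cm3 = 12,
      contrast_range = c(100, 200), texture_rel_range = c(0.03, 0.13),
      boundary_sigma_mm = 1.4, morph_radius_range_mm = c(-0.5, 0.5),
      spicule_keep_prob = 1),
    challenging = list(
      volume_mean_cm3 = 10.4, volume_sd_cm3 = 2.5, volume_min_cm3 = 5,
      volume_max_cm3 = 18,
      contrast_range = c(100, 200), texture_rel_range = c(0.25, 0.45),
      boundary_sigma_mm = 2.0, morph_radius_range_mm = c(-0.8, 0.8),
      spicule_keep_prob = 0.7)
  )
}

#' Generate the full synthetic study cohort
#'
#' Challenging lesions are drawn with larger mean volume and larger observer
#' perturbations than easy ones. Per-tumor and per-observer seeds are mixed
#' deterministically from `base_seed`, so the cohort is a pure function of
#' its arguments.
#'
#' @param n_easy,n_challenging number of tumors per class (>= 1).
#' @param n_observers simulated observers per tumor (>= 2).
#' @param base_seed integer seed for the whole cohort.
#' @param config cohort parameters, see [cohort_config()].
#' @return list of observer sets, each with elements `tumor_id`, `image`,
#'   `truth_mask`, `observer_masks` (named list), `difficulty`.
#' @export
make_cohort <- function(n_easy, n_challenging, n_observers = 4L,
                        base_seed = 1L, config = cohort_config()) {
  stopifnot(n_easy >= 1, n_challenging >= 1)
  if (n_observers < 2) stop("need at least 2 observers", call. = FALSE)
  difficulties <- c(rep("easy", n_easy), rep("challenging", n_challenging))
  lapply(seq_along(difficulties), function(t) {
    diff <- difficulties[t]
    cls <- config[[diff]]
    seed_t <- mix_seed(base_seed, t)
    spec <- with_seed(seed_t, {
      v <- min(cls$volume_max_cm3 %||% Inf,
               max(cls$volume_min_cm3,
                   stats::rnorm(1, cls$volume_mean_cm3, cls$volume_sd_cm3)))
      r <- (3 * v * 1000 / (4 * pi))^(1 / 3)
      aniso <- exp(stats::rnorm(3, sd = 0.08))
      aniso <- aniso / prod(aniso)^(1 / 3)   # volume-preserving anisotropy
      nsp <- if (diff == "challenging") sample(3:6, 1) else 0L
      # lesions differ in enhancement and internal heterogeneity: this
      # between-tumor variance is the subject signal the ICC resolves
      contrast <- stats::runif(1, cls$contrast_range[1],
                               cls$contrast_range[2])
      tex <- contrast * stats::runif(1, cls$texture_rel_range[1],
                                     cls$texture_rel_range[2])
      phantom_spec(difficulty = diff, radius_mm = r * aniso,
                   grid_shape = config$grid_shape,
                   spacing_mm = config$spacing_mm,
                   n_spicules = nsp,
                   spicule_length_mm = stats::runif(1, 3.5, 5.5),
                   intensity_contrast = contrast,
                   texture_sigma = tex,
                   seed = mix_seed(seed_t, 1L))
    })
    ph <- make_phantom(spec)
    obs <- lapply(seq_len(n_observers), function(k) {
      simulate_observer(ph$mask, perturbation_spec(
        boundary_sigma_mm = cls$boundary_sigma_mm,
        morph_radius_range_mm = cls$morph_radius_range_mm,
        spicule_keep_prob = cls$spicule_keep_prob,
        seed = mix_seed(seed_t, 1000L + k)))
    })
    names(obs) <- paste0("obs", seq_len(n_observers))
    list(tumor_id = sprintf("tumor%03d", t), image = ph$image,
         truth_mask = ph$mask, observer_masks = obs, difficulty = diff,
         spec = spec)
  })
}

#' Write a cohort to disk as NIfTI volumes plus a JSON manifest
#'
#' @param cohort as returned by [make_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort, function(os) {
    img_f <- file.path(dir, paste0("image_", os$tumor_id, ".nii.gz"))
    tru_f <- file.path(dir, paste0("truth_", os$tumor_id, ".nii.gz"))
    write_volume(os$image, img_f)
    write_volume(os$truth_mask, tru_f)
    obs_f <- vapply(names(os$observer_masks), function(k) {
      f <- file.path(dir, paste0(k, "_", os$tumor_id, ".nii.gz"))
      write_volume(os$observer_masks[[k]], f)
      f
    }, character(1))
    list(tumor_id = os$tumor_id, difficulty = os$difficulty,
         seed = os$spec$seed, image = img_f, truth = tru_f,
         observers = as.list(obs_f))
  })
  path <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `cohort_manifest.json`.
#' @return list of observer sets as produced by [make_cohort()] (without
#'   phantom specs).
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "cohort_manifest.json")
  if (!file.exists(path)) stop("no cohort manifest in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(path)
  lapply(manifest, function(e) {
    obs <- lapply(e$observers, function(f) read_volume(f, mask = TRUE))
    names(obs) <- names(e$observers)
    list(tumor_id = e$tumor_id, image = read_volume(e$image),
         truth_mask = read_volume(e$truth, mask = TRUE),
         observer_masks = obs, difficulty = e$difficulty)
  })
}
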