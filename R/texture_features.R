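# Scalar features from texture matrices (IBSI-style definitions).
# Direction-resolved families (GLCM, GLRLM) compute each feature per
# direction and report the mean over the 13 directions; features undefined
# for a degenerate matrix (e.g. correlation of a single-level ROI) are NA.

#' Scalar features of a texture matrix
#'
#' @param tm a `texture_matrix` from [compute_texture()].
#' @return named numeric vector; names carry no group prefix.
#' @export
texture_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix"))
  switch(tm$kind,
    GLCM = avg_over_directions(tm$matrices, glcm_features),
    GLRLM = avg_over_directions(tm$matrices, function(m)
      glrlm_features(m, tm$n_voxels)),
    GLSZM = glszm_features(tm$matrix, tm$n_voxels),
    NGTDM = ngtdm_features(tm$s, tm$n),
    GLDM = gldm_features(tm$matrix))
}

avg_over_directions <- function(mats, fn) {
  # directions with no voxel pairs (e.g. out-of-plane for a single-slice
  # ROI) carry no counts and are excluded from the average
  keep <- vapply(mats, sum, numeric(1)) > 0
  if (!any(keep)) return(fn(matrix(1, 1, 1)) * NA_real_)
  vals <- lapply(mats[keep], fn)
  m <- do.call(rbind, vals)
  colMeans(m)   # NA propagates if a populated direction is degenerate
}

glcm_features <- function(counts) {
  tot <- sum(counts)
  L <- nrow(counts)
  if (tot == 0) {
    nm <- names(glcm_features(matrix(1, 1, 1)))
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  }
  p <- counts / tot
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sigx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(L) - muy)^2 * py))

  # diagonal (difference) and cross-diagonal (sum) distributions
  k_d <- 0:(L - 1)
  pxmy <- as.vector(rowsum(as.vector(p), as.vector(abs(i - j))))
  k_s <- 2:(2 * L)
  pxpy <- as.vector(rowsum(as.vector(p), as.vector(i + j)))

  da <- sum(k_d * pxmy)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p)
  hx <- ent(px); hy <- ent(py)
  pxy_ind <- outer(px, py)
  hxy1 <- -sum(p[pxy_ind > 0] * log2(pxy_ind[pxy_ind > 0]))
  hxy2 <- ent(pxy_ind)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sigx > 0 && sigy > 0)
    (sum(i * j * p) - mux * muy) / (sigx * sigy) else NA_real_

  mcc <- if (L == 1L) 1 else {
    # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
    A <- sweep(p, 1, ifelse(px > 0, px, 1), `/`)
    B <- sweep(p, 2, ifelse(py > 0, py, 1), `/`)
    Q <- A %*% t(B)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(0, ev[2]))
  }

  c(autocorrelation = sum(i * j * p),
    joint_average = mux,
    cluster_prominence = sum((i + j - mux - muy)^4 * p),
    cluster_shade = sum((i + j - mux - muy)^3 * p),
    cluster_tendency = sum((i + j - mux - muy)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    difference_average = da,
    difference_entropy = ent(pxmy),
    difference_variance = sum((k_d - da)^2 * pxmy),
    joint_energy = sum(p^2),
    joint_entropy = hxy,
    imc1 = imc1,
    imc2 = imc2,
    idm = sum(p / (1 + (i - j)^2)),
    idmn = sum(p / (1 + ((i - j) / L)^2)),
    id = sum(p / (1 + abs(i - j))),
    idn = sum(p / (1 + abs(i - j) / L)),
    inverse_variance = sum(p[i != j] / (i - j)[i != j]^2),
    maximum_probability = max(p),
    sum_average = sum(k_s * pxpy),
    sum_entropy = ent(pxpy),
    sum_squares = sum((i - mux)^2 * p),
    mcc = mcc)
}

# Shared run-length / zone-size style formulas: P is an L x S count matrix
# (gray level x size), npix the ROI voxel count.
size_family_features <- function(P, npix, prefix_small, prefix_large,
                                 size_name) {
  Ns <- sum(P)
  L <- nrow(P); S <- ncol(P)
  i <- matrix(seq_len(L), L, S)
  s <- matrix(seq_len(S), L, S, byrow = TRUE)
  pn <- P / Ns
  mu_i <- sum(i * pn); mu_s <- sum(s * pn)
  ent <- { q <- pn[pn > 0]; -sum(q * log2(q)) }
  vals <- c(
    sum(P / s^2) / Ns,
    sum(P * s^2) / Ns,
    sum(rowSums(P)^2) / Ns,
    sum(rowSums(P)^2) / Ns^2,
    sum(colSums(P)^2) / Ns,
    sum(colSums(P)^2) / Ns^2,
    Ns / npix,
    sum((i - mu_i)^2 * pn),
    sum((s - mu_s)^2 * pn),
    ent,
    sum(P / i^2) / Ns,
    sum(P * i^2) / Ns,
    sum(P / (i^2 * s^2)) / Ns,
    sum(P * i^2 / s^2) / Ns,
    sum(P * s^2 / i^2) / Ns,
    sum(P * i^2 * s^2) / Ns)
  names(vals) <- c(
    paste0(prefix_small, "_emphasis"),
    paste0(prefix_large, "_emphasis"),
    "gray_level_nonuniformity",
    "gray_level_nonuniformity_normalized",
    paste0(size_name, "_nonuniformity"),
    paste0(size_name, "_nonuniformity_normalized"),
    paste0(size_name, "_percentage"),
    "gray_level_variance",
    paste0(size_name, "_variance"),
    paste0(size_name, "_entropy"),
    "low_gray_level_emphasis",
    "high_gray_level_emphasis",
    paste0(prefix_small, "_low_gray_level_emphasis"),
    paste0(prefix_small, "_high_gray_level_emphasis"),
    paste0(prefix_large, "_low_gray_level_emphasis"),
    paste0(prefix_large, "_high_gray_level_emphasis"))
  vals
}

glrlm_features <- function(P, npix)
  size_family_features(P, npix, "short_run", "long_run", "run")

glszm_features <- function(P, npix)
  size_family_features(P, npix, "small_area", "large_area", "zone")

ngtdm_features <- function(s, n) {
  Nvp <- sum(n)
  p <- n / Nvp
  act <- which(p > 0)
  Ngp <- length(act)
  ii <- act
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (Ngp > 1) {
    sum(outer(p[act], p[act]) * outer(ii, ii, `-`)^2) /
      (Ngp * (Ngp - 1)) * sum(s) / Nvp
  } else 0
  busy_den <- sum(abs(outer(ii * p[act], ii * p[act], `-`)))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  cplx <- if (Nvp > 0 && Ngp > 0) {
    pi_ <- p[act]; si <- s[act]
    num <- outer(ii, ii, function(a, b) abs(a - b)) *
      (outer(pi_ * si, rep(1, Ngp)) + outer(rep(1, Ngp), pi_ * si)) /
      (outer(pi_, rep(1, Ngp)) + outer(rep(1, Ngp), pi_))
    sum(num) / Nvp
  } else 0
  strength <- if (sum(s) > 0 && Ngp > 1) {
    sum((outer(p[act], p[act], `+`)) * outer(ii, ii, `-`)^2) / sum(s)
  } else 0
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = cplx, strength = strength)
}

gldm_features <- function(P) {
  Ns <- sum(P)
  L <- nrow(P); D <- ncol(P)
  i <- matrix(seq_len(L), L, D)
  d <- matrix(seq_len(D), L, D, byrow = TRUE)
  pn <- P / Ns
  mu_i <- sum(i * pn); mu_d <- sum(d * pn)
  q <- pn[pn > 0]
  c(small_dependence_emphasis = sum(P / d^2) / Ns,
    large_dependence_emphasis = sum(P * d^2) / Ns,
    gray_level_nonuniformity = sum(rowSums(P)^2) / Ns,
    dependence_nonuniformity = sum(colSums(P)^2) / Ns,
    dependence_nonuniformity_normalized = sum(colSums(P)^2) / Ns^2,
    gray_level_variance = sum((i - mu_i)^2 * pn),
    dependence_variance = sum((d - mu_d)^2 * pn),
    dependence_entropy = -sum(q * log2(q)),
    low_gray_level_emphasis = sum(P / i^2) / Ns,
    high_gray_level_emphasis = sum(P * i^2) / Ns,
    small_dependence_low_gray_level_emphasis = sum(P / (i^2 * d^2)) / Ns,
    small_dependence_high_gray_level_emphasis = sum(P * i^2 / d^2) / Ns,
    large_dependence_low_gray_level_emphasis = sum(P * d^2 / i^2) / Ns,
    large_dependence_high_gray_level_emphasis = sum(P * i^2 * d^2) / Ns)
}
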