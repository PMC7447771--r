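# Texture matrices over discretized ROIs.
#
# All five families operate on a `discretized_roi` (integer levels 1..L
# inside the ROI, 0 outside). GLCM and GLRLM are direction-resolved (13
# unique 3D directions at Chebyshev distance 1); GLSZM zones use
# 26-connectivity; NGTDM and GLDM use the full 26-neighbourhood at distance
# 1. Matrices hold raw counts; normalization happens in the feature
# formulas.

#' Compute a texture matrix from a discretized ROI
#'
#' @param disc a `discretized_roi` from [discretize()].
#' @param kind one of `"GLCM"`, `"GLRLM"`, `"GLSZM"`, `"NGTDM"`, `"GLDM"`.
#' @param params optional list: `alpha` (GLDM dependence tolerance,
#'   default 0).
#' @return A `texture_matrix` object. GLCM/GLRLM carry one count matrix per
#'   direction (`$matrices`); GLSZM/GLDM a single matrix (`$matrix`); NGTDM
#'   per-level vectors (`$s`, `$n`).
#' @export
compute_texture <- function(disc, kind = c("GLCM", "GLRLM", "GLSZM",
                                           "NGTDM", "GLDM"),
                            params = list()) {
  stopifnot(inherits(disc, "discretized_roi"))
  kind <- match.arg(kind)
  lev <- disc$levels
  L <- disc$n_levels
  if (L < 1L) stop("discretized ROI has no levels", call. = FALSE)
  out <- switch(kind,
    GLCM = list(matrices = glcm_matrices(lev, L)),
    GLRLM = list(matrices = glrlm_matrices(lev, L)),
    GLSZM = list(matrix = glszm_matrix(lev, L)),
    NGTDM = ngtdm_sums(lev, L),
    GLDM = list(matrix = gldm_matrix(lev, L, params$alpha %||% 0)))
  structure(c(list(kind = kind, n_levels = L,
                   n_voxels = sum(lev > 0L), params = params), out),
            class = "texture_matrix")
}

# level pairs (a, b) of voxels separated by offset d, both inside the ROI
level_pairs <- function(lev, d) {
  dm <- dim(lev)
  rx <- if (d[1] >= 0) seq_len(dm[1] - d[1]) else (1 - d[1]):dm[1]
  ry <- if (d[2] >= 0) seq_len(dm[2] - d[2]) else (1 - d[2]):dm[2]
  rz <- if (d[3] >= 0) seq_len(dm[3] - d[3]) else (1 - d[3]):dm[3]
  if (!length(rx) || !length(ry) || !length(rz))
    return(cbind(integer(0), integer(0)))
  a <- lev[rx, ry, rz, drop = FALSE]
  b <- lev[rx + d[1], ry + d[2], rz + d[3], drop = FALSE]
  ok <- a > 0L & b > 0L
  cbind(a[ok], b[ok])
}

glcm_matrices <- function(lev, L) {
  off <- offsets13()
  lapply(seq_len(nrow(off)), function(k) {
    pr <- level_pairs(lev, off[k, ])
    counts <- tabulate(pr[, 1] + (pr[, 2] - 1L) * L, nbins = L * L)
    m <- matrix(counts, L, L)
    m + t(m)   # symmetric co-occurrences
  })
}

glrlm_matrices <- function(lev, L) {
  co <- which(lev > 0L, arr.ind = TRUE)
  l <- lev[lev > 0L]
  dm <- dim(lev)
  M <- 4 * max(dm) + 3
  offc <- 2 * max(dm) + 1
  off <- offsets13()
  lapply(seq_len(nrow(off)), function(k) {
    d <- off[k, ]
    ax <- which(d != 0)[1]
    t_par <- co[, ax] * sign(d[ax])
    k1 <- co[, 1] - t_par * d[1]
    k2 <- co[, 2] - t_par * d[2]
    k3 <- co[, 3] - t_par * d[3]
    key <- (k1 + offc) + (k2 + offc) * M + (k3 + offc) * M * M
    ord <- order(key, t_par)
    ks <- key[ord]; ts <- t_par[ord]; ls <- l[ord]
    n <- length(ord)
    newrun <- c(TRUE, ks[-1] != ks[-n] | ts[-1] != ts[-n] + 1 |
                  ls[-1] != ls[-n])
    starts <- which(newrun)
    rl <- diff(c(starts, n + 1L))
    rlev <- ls[starts]
    maxlen <- max(rl)
    counts <- tabulate(rlev + (rl - 1L) * L, nbins = L * maxlen)
    matrix(counts, L, maxlen)
  })
}

glszm_matrix <- function(lev, L) {
  dm <- dim(lev)
  idx <- which(lev > 0L)
  n <- length(idx)
  vid <- array(0L, dm)
  vid[idx] <- seq_len(n)
  off <- offsets13()
  edges <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb_vid <- shift3d(vid, off[k, ], fill = 0L)
    nb_lev <- shift3d(lev, off[k, ], fill = 0L)
    both <- lev > 0L & nb_vid > 0L & nb_lev == lev
    if (any(both)) edges <- c(edges, rbind(vid[both], nb_vid[both]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  zone_size <- comp$csize
  zone_level <- lev[idx][match(seq_len(comp$no), comp$membership)]
  maxsz <- max(zone_size)
  counts <- tabulate(zone_level + (zone_size - 1L) * L, nbins = L * maxsz)
  matrix(counts, L, maxsz)
}

ngtdm_sums <- function(lev, L) {
  valid <- lev > 0L
  nbsum <- array(0, dim(lev))
  nbcnt <- array(0L, dim(lev))
  off26 <- offsets26()
  for (k in seq_len(nrow(off26))) {
    d <- off26[k, ]
    sl <- shift3d(lev, d, fill = 0L)
    nbsum <- nbsum + sl
    nbcnt <- nbcnt + (sl > 0L)
  }
  use <- valid & nbcnt > 0L
  avg <- nbsum[use] / nbcnt[use]
  li <- lev[use]
  s <- numeric(L)
  if (length(li)) {
    agg <- rowsum(abs(li - avg), li)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  n <- tabulate(li, nbins = L)
  list(s = s, n = n)
}

gldm_matrix <- function(lev, L, alpha = 0) {
  dep <- array(0L, dim(lev))
  off26 <- offsets26()
  for (k in seq_len(nrow(off26))) {
    d <- off26[k, ]
    sl <- shift3d(lev, d, fill = 0L)
    dep <- dep + (sl > 0L & abs(sl - lev) <= alpha)
  }
  inroi <- lev > 0L
  # dependence size = dependent neighbours + the centre voxel itself
  j <- dep[inroi] + 1L
  i <- lev[inroi]
  maxdep <- max(j)
  counts <- tabulate(i + (j - 1L) * L, nbins = L * maxdep)
  matrix(counts, L, maxdep)
}
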