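# Internal array and randomness helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mix a base seed with an index into a derived 31-bit seed
#'
#' Splitmix-style integer mixing so per-tumor / per-stage seeds are a pure
#' function of (base_seed, index) and independent of generation order.
#' @keywords internal
mix_seed <- function(base_seed, index) {
  x <- (as.double(base_seed) * 2654435761 + as.double(index) * 40503 + 12345) %% 2147483647
  as.integer(x)
}

# Evaluate expr with a local RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# The 13 unique displacement vectors covering 26-connectivity (each paired
# with its negation gives the full neighbourhood).
offsets13 <- function() {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  keep <- off$dz > 0 | (off$dz == 0 & off$dy > 0) |
    (off$dz == 0 & off$dy == 0 & off$dx > 0)
  as.matrix(off[keep, , drop = FALSE])
}

offsets26 <- function() {
  o <- offsets13()
  rbind(o, -o)
}

# Shift a 3D array by integer offset d, padding with `fill`.
shift3d <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (d[k] >= 0) {
      if (d[k] >= dm[k]) return(out)
      src[[k]] <- 1:(dm[k] - d[k]); dst[[k]] <- (1 + d[k]):dm[k]
    } else {
      if (-d[k] >= dm[k]) return(out)
      src[[k]] <- (1 - d[k]):dm[k]; dst[[k]] <- 1:(dm[k] + d[k])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Gaussian-smoothed white noise field with approximately unit variance.
# Smoothing is done with a circular FFT filter (Gaussian transfer function),
# which is fast and exactly reproducible.
smooth_noise_field <- function(dim3, sigma_vox) {
  noise <- array(stats::rnorm(prod(dim3)), dim3)
  sm <- fft_gauss_smooth(noise, sigma_vox)
  s <- stats::sd(sm)
  if (s < .Machine$double.eps) return(array(0, dim3))
  sm / s
}

# Separable Gaussian smoothing of a 3D array via FFT (circular boundary).
fft_gauss_smooth <- function(a, sigma_vox) {
  dm <- dim(a)
  sigma_vox <- rep(sigma_vox, length.out = 3)
  if (all(sigma_vox <= 0)) return(a)
  g <- function(n, s) {
    if (s <= 0) return(rep(1, n))
    freq <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
    exp(-2 * pi^2 * s^2 * freq^2)
  }
  tf <- outer(outer(g(dm[1], sigma_vox[1]), g(dm[2], sigma_vox[2])),
              g(dm[3], sigma_vox[3]))
  Re(stats::fft(stats::fft(a) * tf, inverse = TRUE)) / prod(dm)
}

# Chamfer distance transform: distance (mm) from each voxel to the nearest
# TRUE voxel of `mask`, propagated over the 26-neighbourhood with weights
# |offset * spacing|. `max_mm` bounds propagation for speed; distances beyond
# it are clamped to max_mm.
chamfer_distance <- function(mask, spacing, max_mm = Inf) {
  dm <- dim(mask)
  d <- array(ifelse(mask, 0, Inf), dm)
  off <- offsets26()
  w <- sqrt((off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
              (off[, 3] * spacing[3])^2)
  n_iter <- if (is.finite(max_mm)) ceiling(max_mm / min(spacing)) + 1L else
    max(dm)
  for (it in seq_len(n_iter)) {
    changed <- FALSE
    for (k in seq_len(nrow(off))) {
      cand <- shift3d(d, off[k, ], fill = Inf) + w[k]
      upd <- cand < d
      if (any(upd)) {
        d[upd] <- cand[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (is.finite(max_mm)) d[d > max_mm] <- max_mm
  d
}

# Signed distance (mm): negative inside the mask, positive outside, zero
# nowhere (voxel centres are never exactly on the implied surface).
signed_distance <- function(mask, spacing, max_mm = Inf) {
  pos <- chamfer_distance(mask, spacing, max_mm)
  neg <- chamfer_distance(!mask, spacing, max_mm)
  pos - neg
}

# Connected components of a logical 3D array (26- or 6-connectivity) using
# igraph. Returns integer labels (0 = background).
label_components <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  labels <- array(0L, dm)
  if (n == 0L) return(labels)
  vid <- array(0L, dm)
  vid[idx] <- seq_len(n)
  off <- if (connectivity == 26) offsets13() else
    matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  edges <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb <- shift3d(vid, off[k, ], fill = 0L)
    both <- mask & nb > 0L
    if (any(both)) edges <- c(edges, rbind(vid[both], nb[both]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  labels
}
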