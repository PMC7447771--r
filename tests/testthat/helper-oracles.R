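# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use naive explicit loops / set
# operations and share no code with the package internals.

# DSC via explicit coordinate-set intersection
dsc_oracle <- function(a, b) {
  ca <- apply(which(a$voxels, arr.ind = TRUE), 1, paste, collapse = ",")
  cb <- apply(which(b$voxels, arr.ind = TRUE), 1, paste, collapse = ",")
  2 * length(intersect(ca, cb)) / (length(ca) + length(cb))
}

# ICC(2,1) via stats::aov mean squares (full two-way ANOVA decomposition)
icc21_oracle <- function(m) {
  df <- data.frame(value = as.vector(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]][,
                                                                     "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# all 26-neighbourhood offsets, plain loops
all_offsets26 <- function() {
  out <- NULL
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    if (dx != 0 || dy != 0 || dz != 0) out <- rbind(out, c(dx, dy, dz))
  out
}

in_bounds <- function(p, dm) all(p >= 1) && all(p <= dm)

# GLCM for one direction: symmetric co-occurrence counts by direct loop
glcm_oracle <- function(lev, d, L) {
  dm <- dim(lev)
  m <- matrix(0, L, L)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    for (s in list(d, -d)) {
      q <- c(x, y, z) + s
      if (in_bounds(q, dm)) {
        j <- lev[q[1], q[2], q[3]]
        if (j > 0) m[i, j] <- m[i, j] + 1
      }
    }
  }
  m
}

# GLRLM for one direction: enumerate maximal runs by walking each line
glrlm_oracle <- function(lev, d, L) {
  dm <- dim(lev)
  counts <- list()
  bump <- function(i, l) {
    key <- paste(i, l)
    counts[[key]] <<- (counts[[key]] %||% 0) + 1
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    p <- c(x, y, z)
    i <- lev[x, y, z]
    if (i == 0) next
    prev <- p - d
    prev_same <- in_bounds(prev, dm) && lev[prev[1], prev[2], prev[3]] == i
    if (prev_same) next       # not a run start
    len <- 1
    q <- p + d
    while (in_bounds(q, dm) && lev[q[1], q[2], q[3]] == i) {
      len <- len + 1
      q <- q + d
    }
    bump(i, len)
  }
  maxlen <- 0
  for (key in names(counts))
    maxlen <- max(maxlen, as.integer(strsplit(key, " ")[[1]][2]))
  m <- matrix(0, L, max(1, maxlen))
  for (key in names(counts)) {
    il <- as.integer(strsplit(key, " ")[[1]])
    m[il[1], il[2]] <- counts[[key]]
  }
  m
}

# GLSZM via explicit flood fill (BFS, 26-connectivity)
glszm_oracle <- function(lev, L) {
  dm <- dim(lev)
  seen <- array(FALSE, dm)
  off <- all_offsets26()
  zones <- list()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (seen[x, y, z] || lev[x, y, z] == 0) next
    level <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(off))) {
        q <- p + off[k, ]
        if (in_bounds(q, dm) && !seen[q[1], q[2], q[3]] &&
            lev[q[1], q[2], q[3]] == level) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level, size)
  }
  maxsz <- max(vapply(zones, `[`, numeric(1), 2))
  m <- matrix(0, L, maxsz)
  for (zn in zones) m[zn[1], zn[2]] <- m[zn[1], zn[2]] + 1
  m
}

# NGTDM sums s_i and counts n_i by direct neighbour loops
ngtdm_oracle <- function(lev, L) {
  dm <- dim(lev)
  off <- all_offsets26()
  s <- numeric(L); n <- integer(L)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    vals <- c()
    for (k in seq_len(nrow(off))) {
      q <- c(x, y, z) + off[k, ]
      if (in_bounds(q, dm) && lev[q[1], q[2], q[3]] > 0)
        vals <- c(vals, lev[q[1], q[2], q[3]])
    }
    if (length(vals)) {
      s[i] <- s[i] + abs(i - mean(vals))
      n[i] <- n[i] + 1L
    }
  }
  list(s = s, n = n)
}

# GLDM dependence matrix (alpha tolerance; size = dependents + centre)
gldm_oracle <- function(lev, L, alpha = 0) {
  dm <- dim(lev)
  off <- all_offsets26()
  entries <- NULL
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    dep <- 0
    for (k in seq_len(nrow(off))) {
      q <- c(x, y, z) + off[k, ]
      if (in_bounds(q, dm) && lev[q[1], q[2], q[3]] > 0 &&
          abs(lev[q[1], q[2], q[3]] - i) <= alpha)
        dep <- dep + 1
    }
    entries <- rbind(entries, c(i, dep + 1))
  }
  m <- matrix(0, L, max(entries[, 2]))
  for (r in seq_len(nrow(entries)))
    m[entries[r, 1], entries[r, 2]] <- m[entries[r, 1], entries[r, 2]] + 1
  m
}

# random discretized ROI for oracle comparisons
random_disc_roi <- function(dim3 = c(6, 6, 6), L = 4, fill = 0.7,
                            seed = 1) {
  set.seed(seed)
  lev <- array(0L, dim3)
  inroi <- array(stats::runif(prod(dim3)) < fill, dim3)
  lev[inroi] <- sample.int(L, sum(inroi), replace = TRUE)
  structure(list(levels = lev, n_levels = L, bin_width = 1,
                 spacing_mm = c(1, 1, 1)), class = "discretized_roi")
}

# random blob-ish mask for DSC checks
random_mask <- function(dim3 = c(12, 12, 12), p = 0.3, seed = 1) {
  set.seed(seed)
  seg_mask(array(stats::runif(prod(dim3)) < p, dim3), c(1, 1, 1))
}

# small solid cube mask helper
cube_mask <- function(dim3, from, size, spacing = c(1, 1, 1)) {
  a <- array(FALSE, dim3)
  a[from[1]:(from[1] + size - 1), from[2]:(from[2] + size - 1),
    from[3]:(from[3] + size - 1)] <- TRUE
  seg_mask(a, spacing)
}
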