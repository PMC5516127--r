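# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Flood fill over 26-connectivity using an explicit queue on a logical array.
oracle_flood_fill <- function(arr) {
  d <- dim(arr)
  labels <- array(0L, dim = d)
  nxt <- 0L
  neigh <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, ds = -1:1))
  neigh <- neigh[rowSums(abs(neigh)) > 0, ]
  for (s in seq_len(d[3])) for (c in seq_len(d[2])) for (r in seq_len(d[1])) {
    if (!arr[r, c, s] || labels[r, c, s] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c, s))
    labels[r, c, s] <- nxt
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(neigh))) {
        q <- p + neigh[k, ]
        if (any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3]) next
        if (arr[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0L) {
          labels[q[1], q[2], q[3]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  labels
}

# Exhaustive Otsu: try every candidate cut, recompute class variances from
# first principles.
oracle_otsu <- function(v) {
  v <- as.numeric(v)
  u <- sort(unique(v))
  if (length(u) < 2) return(NA_real_)
  best <- -Inf; best_t <- NA_real_
  for (i in seq_len(length(u) - 1)) {
    t <- (u[i] + u[i + 1]) / 2
    g0 <- v[v <= t]; g1 <- v[v > t]
    w0 <- length(g0) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

# Exhaustive support-weighted normalized cross-correlation over the full
# shift grid, with scalar loops over the overlap pixels: NCC times
# log(1 + #positions where both images exceed their own upper decile).
oracle_shift <- function(a, b, R = 10) {
  d <- dim(a)
  qa <- quantile(a, 0.9); qb <- quantile(b, 0.9)
  best <- c(NA_integer_, NA_integer_); best_score <- -Inf
  for (dx in -R:R) for (dy in -R:R) {
    av <- c(); bv <- c(); n_sup <- 0
    for (r in 1:d[1]) for (cc in 1:d[2]) {
      rb <- r + dy; cb <- cc + dx
      if (rb >= 1 && rb <= d[1] && cb >= 1 && cb <= d[2]) {
        av <- c(av, a[r, cc]); bv <- c(bv, b[rb, cb])
        if (a[r, cc] > qa && b[rb, cb] > qb) n_sup <- n_sup + 1
      }
    }
    if (length(av) < 2 || sd(av) == 0 || sd(bv) == 0) next
    score <- sum((av - mean(av)) * (bv - mean(bv))) /
      sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2)) * log1p(n_sup)
    if (score > best_score + 1e-12) { best_score <- score; best <- c(dx, dy) }
  }
  best
}

# Greedy one-to-one matching re-implemented over an O(n^2) distance table.
oracle_pairs <- function(pre_xyz, post_xyz, max_dist) {
  out <- NULL
  cand <- NULL
  for (i in seq_len(nrow(pre_xyz))) for (j in seq_len(nrow(post_xyz))) {
    dd <- sqrt(sum((pre_xyz[i, ] - post_xyz[j, ])^2))
    if (dd <= max_dist) cand <- rbind(cand, c(i, j, dd))
  }
  if (is.null(cand)) {
    return(data.frame(pre = integer(0), post = integer(0), dist = numeric(0)))
  }
  cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  upre <- c(); upost <- c(); out <- NULL
  for (k in seq_len(nrow(cand))) {
    if (!(cand[k, 1] %in% upre) && !(cand[k, 2] %in% upost)) {
      out <- rbind(out, cand[k, ])
      upre <- c(upre, cand[k, 1]); upost <- c(upost, cand[k, 2])
    }
  }
  data.frame(pre = out[, 1], post = out[, 2], dist = out[, 3])
}

# Independent section-span recount from raw voxel indices.
oracle_span <- function(voxels, dims) {
  ny <- dims[1]; nx <- dims[2]
  length(unique((voxels - 1L) %/% (ny * nx)))
}

# Build a binary_mask-like object from a logical array for direct labeling
# tests (bypasses thresholding).
raw_mask <- function(arr, px = 0.1, dz = 0.07, channel = "test") {
  structure(list(data = arr, channel = channel, pixel_size_um = px,
                 section_thickness_um = dz, origin_um = c(0, 0),
                 method = "manual",
                 thresholds = tibble::tibble(section = integer(0),
                                             algorithm = character(0),
                                             value = numeric(0))),
            class = "binary_mask")
}

# Random sparse logical volume with a given foreground probability.
random_sparse_mask <- function(dims, p = 0.03) {
  array(stats::runif(prod(dims)) < p, dim = dims)
}

# Small fast scene configuration for tests that do not need the default
# study-size field of view.
small_scene <- function(...) {
  defaults <- list(footprint_um = c(6, 6), n_sections = 12,
                   density_presynapse_um3 = 0.5,
                   density_postsynapse_um3 = 0.4, speckle_count = 2)
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}
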