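# Independent oracles: deliberately naive brute-force implementations used
# only to check the package's vectorized paths on small inputs.

# AUC by exhaustive comparison of every (positive, negative) score pair.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Percentile by explicit linear interpolation between order statistics.
oracle_percentile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# GLCM counts by a triple loop over every voxel and offset (symmetric).
oracle_glcm_counts <- function(levels, offsets, n_levels) {
  d3 <- dim(levels)
  counts <- matrix(0, n_levels, n_levels)
  for (x in seq_len(d3[1])) for (y in seq_len(d3[2])) for (z in seq_len(d3[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(offsets))) {
      nx <- x + offsets[r, 1]; ny <- y + offsets[r, 2]; nz <- z + offsets[r, 3]
      if (nx < 1 || nx > d3[1] || ny < 1 || ny > d3[2] || nz < 1 || nz > d3[3])
        next
      b <- levels[nx, ny, nz]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts
}

# Run counting by walking every line voxel-by-voxel.
oracle_run_counts <- function(levels, offsets, n_levels) {
  d3 <- dim(levels)
  max_len <- max(d3) * 2
  counts <- matrix(0, n_levels, max_len)
  inside <- function(v) all(v >= 1) && all(v <= d3)
  for (r in seq_len(nrow(offsets))) {
    d <- offsets[r, ]
    for (x in seq_len(d3[1])) for (y in seq_len(d3[2])) for (z in seq_len(d3[3])) {
      start <- c(x, y, z)
      prev <- start - d
      if (inside(prev)) next  # only line starts
      v <- start
      cur_level <- NA; cur_len <- 0
      while (inside(v)) {
        g <- levels[v[1], v[2], v[3]]
        if (!is.na(g) && !is.na(cur_level) && g == cur_level) {
          cur_len <- cur_len + 1
        } else {
          if (!is.na(cur_level))
            counts[cur_level, cur_len] <- counts[cur_level, cur_len] + 1
          cur_level <- g
          cur_len <- if (is.na(g)) 0 else 1
        }
        v <- v + d
      }
      if (!is.na(cur_level))
        counts[cur_level, cur_len] <- counts[cur_level, cur_len] + 1
    }
  }
  counts[, seq_len(max(which(colSums(counts) > 0))), drop = FALSE]
}

# Connected components of equal level via an igraph adjacency graph.
oracle_zone_count <- function(levels, connectivity_offsets) {
  idx <- which(!is.na(levels))
  if (length(idx) == 0) return(0)
  d3 <- dim(levels)
  coords <- arrayInd(idx, d3)
  id_of <- stats::setNames(seq_along(idx), idx)
  edges <- integer(0)
  for (k in seq_along(idx)) {
    for (r in seq_len(nrow(connectivity_offsets))) {
      nb <- coords[k, ] + connectivity_offsets[r, ]
      if (any(nb < 1) || any(nb > d3)) next
      li <- nb[1] + (nb[2] - 1) * d3[1] + (nb[3] - 1) * d3[1] * d3[2]
      if (!is.na(levels[li]) && levels[li] == levels[idx[k]])
        edges <- c(edges, k, id_of[[as.character(li)]])
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  igraph::components(g)$no
}

# A 1-D "strip" volume whose ROI holds the given values.
strip_volume <- function(values, mask = rep(1L, length(values))) {
  case_volume("strip", array(values, c(length(values), 1, 1)),
              array(as.integer(mask), c(length(values), 1, 1)))
}

# Random small phantom with an irregular mask; deterministic per seed.
random_small_volume <- function(seed, shape = c(4, 4, 4), n_levels_src = 4) {
  set.seed(seed)
  img <- array(sample.int(n_levels_src, prod(shape), replace = TRUE), shape)
  mask <- array(0L, shape)
  while (sum(mask) < 2) mask <- array(rbinom(prod(shape), 1, 0.6), shape)
  case_volume(paste0("rand", seed), img, mask)
}

all_26_offsets <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
}
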