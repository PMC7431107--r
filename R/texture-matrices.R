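# Texture matrices: gray level co-occurrence (GLCM), run length (GLRLM),
# and size zone (GLSZM). All operate on a quantized ROI and aggregate over
# a direction set by summing counts before normalization.

texture_matrix <- function(family, counts, extra = list()) {
  total <- sum(counts)
  normalized <- if (total > 0) counts / total else counts
  structure(c(list(family = family, counts = counts, normalized = normalized),
              extra),
            class = "texture_matrix")
}

#' @method print texture_matrix
#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("<texture_matrix> %s %dx%d, %d counts\n", x$family,
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Gray level co-occurrence matrix
#'
#' Counts pairs of gray levels observed at a fixed voxel offset, accumulated
#' symmetrically (each pair counted in both orders), summed over the
#' direction set, then normalized to a joint probability `p(i, j)`.
#'
#' @param q A [quantize()]d ROI.
#' @param distance Offset length in voxels (default 1).
#' @param directions Integer matrix of offsets (rows `(dx, dy, dz)`), or
#'   `NULL` to resolve from `mode`.
#' @param mode `"auto"` (3-D when the ROI spans more than one slice, else
#'   in-plane 2-D), `"2d"`, or `"3d"`.
#' @return A `texture_matrix` with `family = "GLCM"`; `counts` and
#'   `normalized` are `n_levels` x `n_levels`.
#' @export
glcm <- function(q, distance = 1L, directions = NULL, mode = "auto") {
  stopifnot(inherits(q, "quantized_roi"))
  if (distance < 1L) stop_input("distance must be >= 1")
  if (is.null(directions)) directions <- resolve_offsets(q, mode)
  if (nrow(directions) == 0L) stop_input("direction set is empty")
  ng <- q$n_levels
  L <- q$levels
  d3 <- dim(L)
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(directions))) {
    off <- directions[r, ] * distance
    sub <- shifted_pairs(L, off, d3)
    if (is.null(sub)) next
    ok <- !is.na(sub$a) & !is.na(sub$b)
    if (!any(ok)) next
    idx <- (sub$a[ok] - 1L) * ng + sub$b[ok]
    tab <- tabulate(idx, nbins = ng * ng)
    m <- matrix(tab, ng, ng, byrow = TRUE)
    counts <- counts + m + t(m)  # symmetric accumulation
  }
  texture_matrix("GLCM", counts,
                 extra = list(n_directions = nrow(directions)))
}

# Values of L at every in-bounds voxel v (a) and v + off (b).
shifted_pairs <- function(L, off, d3) {
  rng <- vector("list", 3)
  for (k in 1:3) {
    lo <- max(1L, 1L - off[k]); hi <- min(d3[k], d3[k] - off[k])
    if (lo > hi) return(NULL)
    rng[[k]] <- lo:hi
  }
  a <- L[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  b <- L[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3], drop = FALSE]
  list(a = as.vector(a), b = as.vector(b))
}

#' Gray level run length matrix
#'
#' Counts maximal runs of identical gray level along each direction, summed
#' over the direction set. Rows index gray level, columns run length.
#'
#' @inheritParams glcm
#' @return A `texture_matrix` with `family = "GLRLM"` and extras
#'   `n_voxels`, `n_directions`.
#' @export
glrlm <- function(q, directions = NULL, mode = "auto") {
  stopifnot(inherits(q, "quantized_roi"))
  if (is.null(directions)) directions <- resolve_offsets(q, mode)
  if (nrow(directions) == 0L) stop_input("direction set is empty")
  ng <- q$n_levels
  L <- q$levels
  d3 <- dim(L)
  n <- prod(d3)
  xs <- as.vector(slice.index(L, 1))
  ys <- as.vector(slice.index(L, 2))
  zs <- as.vector(slice.index(L, 3))
  lev <- as.vector(L)
  max_len <- max(d3) * 2L  # diagonal runs cannot exceed the longest axis
  counts <- matrix(0, ng, max_len)
  for (r in seq_len(nrow(directions))) {
    d <- directions[r, ]
    k <- sum(d^2)
    # integer line key: k*v - (v.d)*d is constant along the line v + t*d,
    # and v.d increases by k per step, so it orders voxels within a line
    dt <- xs * d[1] + ys * d[2] + zs * d[3]
    kx <- k * xs - dt * d[1]; ky <- k * ys - dt * d[2]; kz <- k * zs - dt * d[3]
    o <- order(kx, ky, kz, dt)
    lv <- lev[o]
    same_line <- c(FALSE, kx[o][-1] == kx[o][-n] & ky[o][-1] == ky[o][-n] &
                     kz[o][-1] == kz[o][-n])
    prev <- c(NA, lv[-n])
    new_run <- !same_line | is.na(lv) | is.na(prev) | (lv != prev)
    run_id <- cumsum(new_run)
    keep <- !is.na(lv)
    if (!any(keep)) next
    rl <- rle(run_id[keep])
    run_levels <- lv[keep][cumsum(rl$lengths)]
    for (i in seq_along(rl$lengths)) {
      counts[run_levels[i], rl$lengths[i]] <- counts[run_levels[i], rl$lengths[i]] + 1
    }
  }
  last <- max(which(colSums(counts) > 0))
  counts <- counts[, seq_len(last), drop = FALSE]
  texture_matrix("GLRLM", counts,
                 extra = list(n_voxels = sum(q$mask),
                              n_directions = nrow(directions)))
}

#' Gray level size zone matrix
#'
#' Decomposes the ROI into zones — connected components of equal gray level
#' (26-connectivity in 3-D, 8-connectivity in-plane) — and counts zones by
#' gray level (rows) and zone size in voxels (columns). Direction-free.
#'
#' @inheritParams glcm
#' @return A `texture_matrix` with `family = "GLSZM"` and extras
#'   `n_voxels`, `zone_sizes` (per-zone sizes, for auditing).
#' @export
glszm <- function(q, mode = "auto") {
  stopifnot(inherits(q, "quantized_roi"))
  offs <- if (identical(mode, "2d") ||
              (identical(mode, "auto") && nrow(resolve_offsets(q, mode)) == 4L)) {
    o <- offsets_2d(); rbind(o, -o)
  } else {
    o <- offsets_3d(); rbind(o, -o)
  }
  ng <- q$n_levels
  L <- q$levels
  d3 <- dim(L)
  zones <- flood_zones(L, offs, d3)
  max_size <- max(zones$size)
  counts <- matrix(0, ng, max_size)
  for (i in seq_along(zones$size)) {
    counts[zones$level[i], zones$size[i]] <- counts[zones$level[i], zones$size[i]] + 1
  }
  texture_matrix("GLSZM", counts,
                 extra = list(n_voxels = sum(q$mask),
                              zone_sizes = zones$size))
}

# Label connected components of equal level by frontier-expanding flood
# fill over the given neighbor offsets. Returns per-zone level and size.
flood_zones <- function(L, offs, d3) {
  n <- prod(d3)
  lin <- which(!is.na(L))
  visited <- logical(n)
  lev_v <- as.vector(L)
  # precompute coordinates for bounds checks
  coords <- arrayInd(seq_len(n), d3)
  zone_level <- integer(0); zone_size <- integer(0)
  for (s in lin) {
    if (visited[s]) next
    g <- lev_v[s]
    frontier <- s
    visited[s] <- TRUE
    size <- 0L
    while (length(frontier)) {
      size <- size + length(frontier)
      cur <- coords[frontier, , drop = FALSE]
      nxt <- integer(0)
      for (r in seq_len(nrow(offs))) {
        nb <- cur
        nb[, 1] <- nb[, 1] + offs[r, 1]
        nb[, 2] <- nb[, 2] + offs[r, 2]
        nb[, 3] <- nb[, 3] + offs[r, 3]
        ok <- nb[, 1] >= 1 & nb[, 1] <= d3[1] & nb[, 2] >= 1 & nb[, 2] <= d3[2] &
          nb[, 3] >= 1 & nb[, 3] <= d3[3]
        if (!any(ok)) next
        li <- nb[ok, 1] + (nb[ok, 2] - 1L) * d3[1] + (nb[ok, 3] - 1L) * d3[1] * d3[2]
        li <- li[!visited[li] & !is.na(lev_v[li]) & lev_v[li] == g]
        if (length(li)) {
          visited[li] <- TRUE
          nxt <- c(nxt, li)
        }
      }
      frontier <- unique(nxt)
    }
    zone_level <- c(zone_level, g)
    zone_size <- c(zone_size, size)
  }
  list(level = zone_level, size = zone_size)
}
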