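# Gray-level quantization of the ROI, the step preceding every texture matrix.

#' Quantize in-ROI intensities to a fixed number of gray levels
#'
#' Equal-width bins spanning the `[min, max]` of the in-ROI intensities
#' (fixed bin count, so bins shift with the data range and texture features
#' are invariant to adding a constant to all intensities). The maximum
#' intensity is assigned to bin `n_bins`. A constant ROI collapses to a
#' single level.
#'
#' @param volume A [case_volume()].
#' @param n_bins Number of gray levels (default 32).
#' @return A `quantized_roi`: list with `levels` (3-D integer array,
#'   `NA` outside the ROI), `n_levels`, `bin_edges`, `mask`, `spacing`.
#' @export
quantize <- function(volume, n_bins = 32L) {
  stopifnot(inherits(volume, "case_volume"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop_input("n_bins must be >= 1")
  v <- roi_values(volume)
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    lev <- array(NA_integer_, dim(volume$image))
    lev[volume$mask == 1L] <- 1L
    return(structure(list(levels = lev, n_levels = 1L,
                          bin_edges = c(lo, hi), mask = volume$mask,
                          spacing = volume$spacing),
                     class = "quantized_roi"))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  width <- (hi - lo) / n_bins
  lv <- pmin(floor((v - lo) / width) + 1L, n_bins)
  lev <- array(NA_integer_, dim(volume$image))
  lev[volume$mask == 1L] <- as.integer(lv)
  structure(list(levels = lev, n_levels = n_bins, bin_edges = edges,
                 mask = volume$mask, spacing = volume$spacing),
            class = "quantized_roi")
}

#' @method print quantized_roi
#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %d levels over %d ROI voxels\n",
              x$n_levels, sum(x$mask)))
  invisible(x)
}

# The 13 unique 3-D offsets at unit distance (one representative per
# opposite pair of the 26-neighborhood).
offsets_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  # keep the lexicographically positive representative of each +/- pair
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# The 4 unique in-plane offsets (0, 45, 90, 135 degrees).
offsets_2d <- function() {
  matrix(c(1, 0, 0,
           0, 1, 0,
           1, 1, 0,
           1, -1, 0), ncol = 3, byrow = TRUE)
}

# Resolve the direction set: 3-D when the ROI spans more than one slice
# along the third axis, else in-plane 2-D (mode = "auto").
resolve_offsets <- function(q, mode = c("auto", "2d", "3d")) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    z_extent <- length(unique(which(q$mask == 1L, arr.ind = TRUE)[, 3]))
    mode <- if (z_extent > 1L) "3d" else "2d"
  }
  if (mode == "3d") offsets_3d() else offsets_2d()
}
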