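# Feature definitions follow the IBSI reference formulations. All variance
# and standard-deviation quantities use the population (divide-by-N)
# convention; percentiles use linear interpolation between closest ranks.

#' Gray level co-occurrence features
#'
#' Computed from a normalized GLCM `p(i, j)`. Includes autocorrelation
#' (`glcm_autocorrelation`, the AC feature), joint average, variance,
#' contrast, dissimilarity, correlation, energy (angular second moment),
#' entropy (log2), homogeneity (inverse difference moment), and cluster
#' shade/prominence. When the ROI holds a single gray level the marginal
#' variance is zero and correlation is reported as 0.
#'
#' @param m A `texture_matrix` with `family = "GLCM"`.
#' @return Named numeric vector.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), identical(m$family, "GLCM"))
  p <- m$normalized
  ng <- nrow(p)
  if (sum(p) == 0) stop_input("empty GLCM")
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  mu_i <- sum(i * p)  # symmetric matrix: row and column marginals agree
  mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p)
  var_j <- sum((j - mu_j)^2 * p)
  corr <- if (var_i > 0 && var_j > 0)
    (sum(i * j * p) - mu_i * mu_j) / sqrt(var_i * var_j) else 0
  pos <- p[p > 0]
  c(glcm_autocorrelation = sum(i * j * p),
    glcm_joint_average = mu_i,
    glcm_joint_variance = var_i,
    glcm_contrast = sum((i - j)^2 * p),
    glcm_dissimilarity = sum(abs(i - j) * p),
    glcm_correlation = corr,
    glcm_energy = sum(p^2),
    glcm_entropy = -sum(pos * log2(pos)),
    glcm_homogeneity = sum(p / (1 + (i - j)^2)),
    glcm_cluster_shade = sum((i + j - mu_i - mu_j)^3 * p),
    glcm_cluster_prominence = sum((i + j - mu_i - mu_j)^4 * p))
}

#' Gray level run length features
#'
#' Short/long run emphasis, gray level and run length non-uniformity, run
#' percentage, low/high gray level run emphasis, run and gray level
#' variance, and run entropy, from the direction-aggregated run length
#' matrix. Run percentage divides total runs by (ROI voxels x number of
#' directions), so a single all-one-level line scanned in one direction
#' gives RP = 1/length.
#'
#' @param q A [quantize()]d ROI.
#' @param directions,mode Passed to [glrlm()].
#' @return Named numeric vector.
#' @export
glrlm_features <- function(q, directions = NULL, mode = "auto") {
  m <- glrlm(q, directions = directions, mode = mode)
  r <- m$counts
  nr <- sum(r)
  p <- m$normalized
  i <- matrix(seq_len(nrow(r)), nrow(r), ncol(r))
  l <- t(matrix(seq_len(ncol(r)), ncol(r), nrow(r)))
  mu_i <- sum(i * p)
  mu_l <- sum(l * p)
  pos <- p[p > 0]
  c(glrlm_sre = sum(p / l^2),
    glrlm_lre = sum(p * l^2),
    glrlm_gln = sum(rowSums(r)^2) / nr,
    glrlm_rln = sum(colSums(r)^2) / nr,
    glrlm_rp = nr / (m$n_voxels * m$n_directions),
    glrlm_lglre = sum(p / i^2),
    glrlm_hglre = sum(p * i^2),
    glrlm_gray_level_variance = sum((i - mu_i)^2 * p),
    glrlm_run_length_variance = sum((l - mu_l)^2 * p),
    glrlm_run_entropy = -sum(pos * log2(pos)))
}

#' Gray level size zone features
#'
#' Small/large area emphasis, gray level and size zone non-uniformity, zone
#' percentage, low/high gray level zone emphasis, zone size variance, zone
#' entropy, and gray level variance (`glszm_gray_level_variance`, the GLV
#' feature).
#'
#' @param q A [quantize()]d ROI.
#' @param mode Passed to [glszm()].
#' @return Named numeric vector.
#' @export
glszm_features <- function(q, mode = "auto") {
  m <- glszm(q, mode = mode)
  s <- m$counts
  nz <- sum(s)
  p <- m$normalized
  i <- matrix(seq_len(nrow(s)), nrow(s), ncol(s))
  z <- t(matrix(seq_len(ncol(s)), ncol(s), nrow(s)))
  mu_i <- sum(i * p)
  mu_z <- sum(z * p)
  pos <- p[p > 0]
  c(glszm_sae = sum(p / z^2),
    glszm_lae = sum(p * z^2),
    glszm_gln = sum(rowSums(s)^2) / nz,
    glszm_szn = sum(colSums(s)^2) / nz,
    glszm_zp = nz / m$n_voxels,
    glszm_lglze = sum(p / i^2),
    glszm_hglze = sum(p * i^2),
    glszm_gray_level_variance = sum((i - mu_i)^2 * p),
    glszm_zone_size_variance = sum((z - mu_z)^2 * p),
    glszm_zone_entropy = -sum(pos * log2(pos)))
}

#' First-order (histogram) features of the in-ROI intensities
#'
#' Includes the 10th percentile (`firstorder_10percentile`, the 10Per
#' feature) and the interquartile range (`firstorder_iqr`, the IR feature,
#' P75 - P25), both with linear interpolation between closest ranks.
#' Entropy is computed on the equal-width quantized histogram. Skewness and
#' kurtosis (non-excess) are 0 for a constant ROI.
#'
#' @param volume A [case_volume()].
#' @param n_bins Bin count for the entropy histogram (default 32).
#' @return Named numeric vector.
#' @export
first_order_features <- function(volume, n_bins = 32L) {
  v <- roi_values(volume)
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - mu)^4) / m2^2 else 0
  qs <- unname(stats::quantile(v, c(0.10, 0.25, 0.75, 0.90), type = 7))
  f <- quantize(volume, n_bins)
  h <- tabulate(f$levels[!is.na(f$levels)], nbins = f$n_levels) / n
  hp <- h[h > 0]
  c(firstorder_mean = mu,
    firstorder_median = stats::median(v),
    firstorder_min = min(v),
    firstorder_max = max(v),
    firstorder_range = max(v) - min(v),
    firstorder_variance = m2,
    firstorder_std = sqrt(m2),
    firstorder_skewness = skew,
    firstorder_kurtosis = kurt,
    firstorder_energy = sum(v^2),
    firstorder_entropy = -sum(hp * log2(hp)),
    firstorder_10percentile = qs[1],
    firstorder_90percentile = qs[4],
    firstorder_iqr = qs[3] - qs[2])
}

#' Shape features of the ROI mask
#'
#' Voxel-counting volume, surface area by face counting of the voxelized
#' boundary (each exposed voxel face contributes its physical area),
#' sphericity `pi^(1/3) (6V)^(2/3) / A`, surface-to-volume ratio, and the
#' maximum 3-D diameter over boundary-voxel centers. Face counting
#' overestimates the area of smooth shapes, so sphericity of a voxelized
#' sphere sits below 1 by a discretization bias.
#'
#' @param volume A [case_volume()].
#' @return Named numeric vector.
#' @export
shape_features <- function(volume) {
  mk <- volume$mask
  sp <- volume$spacing
  d3 <- dim(mk)
  vol <- sum(mk) * prod(sp)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- 0
  exposed <- array(FALSE, d3)
  for (axis in 1:3) {
    for (sgn in c(-1L, 1L)) {
      off <- c(0L, 0L, 0L); off[axis] <- sgn
      nb <- shifted_pairs(mk, off, d3)
      # faces against the volume border are always exposed
      rng <- lapply(1:3, function(k) {
        lo <- max(1L, 1L - off[k]); hi <- min(d3[k], d3[k] - off[k]); lo:hi
      })
      inb <- array(FALSE, d3)
      inb[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
      nb_full <- array(0L, d3)
      nb_full[inb] <- nb$b
      exp_here <- mk == 1L & (!inb | nb_full == 0L)
      area <- area + sum(exp_here) * face_area[axis]
      exposed <- exposed | exp_here
    }
  }
  sphericity <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  bc <- which(exposed, arr.ind = TRUE)
  bc <- sweep(bc, 2, sp, `*`)
  max_diam <- if (nrow(bc) > 1) {
    max(stats::dist(bc))
  } else 0
  c(shape_volume = vol,
    shape_surface_area = area,
    shape_sphericity = sphericity,
    shape_surface_to_volume = area / vol,
    shape_max_diameter = max_diam,
    shape_voxel_count = sum(mk))
}
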