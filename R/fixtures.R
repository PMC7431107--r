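# Synthetic phantoms and feature tables with known ground truth, so the
# whole pipeline is testable without any imaging dataset.

#' Describe a synthetic image phantom
#'
#' @param shape Integer 3-vector: volume dimensions in voxels.
#' @param lesion Lesion geometry: `"sphere"` or `"box"`.
#' @param center Lesion center (voxel coordinates, may be fractional).
#' @param radius Lesion radius in voxels (half edge length for a box).
#' @param texture In-lesion intensity pattern: `"constant"`,
#'   `"checkerboard"`, `"noise"` (Gaussian with `mu`, `sigma`) or
#'   `"gradient"` (linear ramp along the first axis).
#' @param mu,sigma Mean and standard deviation of the `"noise"` texture.
#' @param spacing Voxel edge lengths in mm.
#' @param seed Integer seed for the noise texture.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(16L, 16L, 8L), lesion = c("sphere", "box"),
                         center = (shape + 1) / 2, radius = min(shape) / 3,
                         texture = c("constant", "checkerboard", "noise", "gradient"),
                         mu = 100, sigma = 10, spacing = c(1, 1, 1), seed = 1L) {
  lesion <- match.arg(lesion)
  texture <- match.arg(texture)
  stopifnot(length(shape) == 3, all(shape >= 1), length(spacing) == 3,
            all(spacing > 0), radius > 0)
  if (any(center - radius < 1) || any(center + radius > shape))
    stop_input("lesion does not fit inside the volume")
  structure(list(shape = as.integer(shape), lesion = lesion, center = center,
                 radius = radius, texture = texture, mu = mu, sigma = sigma,
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic case volume from a phantom description
#'
#' Deterministic given the spec (the seed is part of the spec): repeated
#' calls return identical volumes.
#'
#' @param spec A [phantom_spec()].
#' @param case_id Case identifier attached to the volume.
#' @return A [case_volume()].
#' @export
make_phantom <- function(spec, case_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  ix <- slice.index(array(0, d), 1)
  iy <- slice.index(array(0, d), 2)
  iz <- slice.index(array(0, d), 3)
  mask <- if (spec$lesion == "sphere") {
    (ix - spec$center[1])^2 + (iy - spec$center[2])^2 + (iz - spec$center[3])^2 <=
      spec$radius^2
  } else {
    abs(ix - spec$center[1]) <= spec$radius &
      abs(iy - spec$center[2]) <= spec$radius &
      abs(iz - spec$center[3]) <= spec$radius
  }
  img <- switch(spec$texture,
    constant = array(spec$mu, d),
    checkerboard = spec$mu + spec$sigma * ((ix + iy + iz) %% 2),
    gradient = spec$mu + spec$sigma * (ix - 1) / max(d[1] - 1, 1),
    noise = with_seed(spec$seed, array(stats::rnorm(prod(d), spec$mu, spec$sigma), d))
  )
  case_volume(case_id, img, array(mask, d) * 1L, spec$spacing)
}

#' Describe a synthetic feature table
#'
#' Emulates a radiomics matrix with a known informative subset: informative
#' features are shifted between classes by a standardized mean difference
#' `effect_size`; the remaining features are pure noise. An optional
#' equicorrelated block of near-duplicate features exercises the
#' correlation-redundancy filter.
#'
#' @param n_pos,n_neg Cases per class (label 1 / label 0).
#' @param n_features Total feature count.
#' @param n_informative Number of class-separating features (first columns).
#' @param effect_size Standardized mean difference between classes.
#' @param block_size,block_rho Size and common correlation of an
#'   equicorrelated noise block appended after the informative features
#'   (`block_size = 0` disables it).
#' @param seed Integer seed.
#' @return A `table_spec` list.
#' @export
table_spec <- function(n_pos = 100L, n_neg = 100L, n_features = 50L,
                       n_informative = min(5L, n_features), effect_size = 1.5,
                       block_size = 0L, block_rho = 0.95, seed = 1L) {
  stopifnot(n_informative <= n_features, effect_size >= 0,
            n_informative + block_size <= n_features,
            n_pos >= 1, n_neg >= 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, block_size = as.integer(block_size),
                 block_rho = block_rho, seed = as.integer(seed)),
            class = "table_spec")
}

#' Generate a synthetic feature table with a known informative set
#'
#' Informative features are drawn `Normal(+d/2, 1)` for the positive class
#' and `Normal(-d/2, 1)` for the negative class; noise features are
#' `Normal(0, 1)` in both. A pure function of the spec.
#'
#' @param spec A [table_spec()].
#' @return A [feature_table()] with attribute `informative`: the names of
#'   the informative features.
#' @export
make_table <- function(spec) {
  stopifnot(inherits(spec, "table_spec"))
  n <- spec$n_pos + spec$n_neg
  labels <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  with_seed(spec$seed, {
    X <- matrix(stats::rnorm(n * spec$n_features), n, spec$n_features)
    if (spec$n_informative > 0) {
      shift <- ifelse(labels == 1L, spec$effect_size / 2, -spec$effect_size / 2)
      X[, seq_len(spec$n_informative)] <-
        X[, seq_len(spec$n_informative), drop = FALSE] + shift
    }
    if (spec$block_size > 1) {
      idx <- spec$n_informative + seq_len(spec$block_size)
      base <- stats::rnorm(n)
      r <- spec$block_rho
      for (j in idx) X[, j] <- sqrt(r) * base + sqrt(1 - r) * stats::rnorm(n)
    }
    ord <- sample.int(n)  # interleave classes so folds are not degenerate
    X <- X[ord, , drop = FALSE]
    labels <- labels[ord]
  })
  fnames <- sprintf("feat_%03d", seq_len(spec$n_features))
  tab <- feature_table(case_ids = sprintf("case_%03d", seq_len(n)),
                       labels = labels, features = X, feature_names = fnames)
  attr(tab, "informative") <- fnames[seq_len(spec$n_informative)]
  tab
}

#' A class-imbalance preset with 68 positive and 184 negative cases
#'
#' Ships the composition used throughout the split and balancing tests:
#' 68 positives versus 184 negatives, mirroring a typical imbalanced
#' clinical cohort.
#'
#' @param n_features,n_informative,effect_size,seed Passed to [table_spec()].
#' @return A [feature_table()].
#' @export
make_imbalanced_table <- function(n_features = 20L, n_informative = 3L,
                                  effect_size = 1.0, seed = 7L) {
  make_table(table_spec(n_pos = 68L, n_neg = 184L, n_features = n_features,
                        n_informative = n_informative,
                        effect_size = effect_size, seed = seed))
}

#' Write a root folder of phantom cases in the on-disk layout the extractor reads
#'
#' Creates one sub-folder per case under `root`, each holding the image
#' series and ROI mask as NIfTI files.
#'
#' @param root Directory to create case sub-folders under.
#' @param n_cases Number of cases.
#' @param image_names File names (without extension) of the image series to
#'   write per case.
#' @param roi_name File name (without extension) of the ROI mask.
#' @param seed Base seed; case `i` uses `seed + i`.
#' @return Invisibly, the vector of case directories.
#' @export
write_phantom_cases <- function(root, n_cases = 3L,
                                image_names = "image", roi_name = "roi",
                                seed = 1L) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  dirs <- character(n_cases)
  for (i in seq_len(n_cases)) {
    id <- sprintf("case_%03d", i)
    d <- file.path(root, id)
    dir.create(d, showWarnings = FALSE)
    for (s in seq_along(image_names)) {
      vol <- make_phantom(phantom_spec(texture = "noise",
                                       seed = seed + i * 101L + s),
                          case_id = id)
      write_case_volume(vol, file.path(d, paste0(image_names[s], ".nii.gz")),
                        what = "image")
      if (s == 1L)
        write_case_volume(vol, file.path(d, paste0(roi_name, ".nii.gz")),
                          what = "mask")
    }
    dirs[i] <- d
  }
  invisible(dirs)
}
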