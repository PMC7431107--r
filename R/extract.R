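# Batch extraction: one folder per case, each holding image series and a
# shared ROI mask; one feature row per case.

#' Extraction configuration
#'
#' @param image_names File names (without `.nii`/`.nii.gz` extension) of the
#'   image series present in every case folder.
#' @param roi_name File name (without extension) of the binary ROI mask.
#' @param n_bins Gray levels for quantization (default 32).
#' @param distance GLCM offset distance in voxels.
#' @param families Feature families to compute; any of `"shape"`,
#'   `"firstorder"`, `"glcm"`, `"glrlm"`, `"glszm"`.
#' @param mode Texture geometry: `"auto"` (3-D when the ROI spans more than
#'   one slice), `"2d"`, or `"3d"`.
#' @return A list of class `extract_config`.
#' @export
extract_config <- function(image_names = "image", roi_name = "roi",
                           n_bins = 32L, distance = 1L,
                           families = c("shape", "firstorder", "glcm",
                                        "glrlm", "glszm"),
                           mode = "auto") {
  families <- match.arg(families, several.ok = TRUE)
  structure(list(image_names = image_names, roi_name = roi_name,
                 n_bins = as.integer(n_bins), distance = as.integer(distance),
                 families = families, mode = mode),
            class = "extract_config")
}

# Find "<dir>/<name>.nii.gz" or "<dir>/<name>.nii".
find_nifti <- function(dir, name) {
  for (ext in c(".nii.gz", ".nii")) {
    p <- file.path(dir, paste0(name, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Extract all configured features for one case folder
#'
#' Non-shape features are computed once per image series and prefixed with
#' the series name; shape features depend only on the ROI and appear once.
#'
#' @param case_dir Path to the case folder.
#' @param config An [extract_config()].
#' @return Named numeric vector of features, with attribute `case_id`.
#' @export
extract_case <- function(case_dir, config = extract_config()) {
  roi_path <- find_nifti(case_dir, config$roi_name)
  if (is.null(roi_path))
    stop_input("missing ROI file '", config$roi_name, "' in ", case_dir)
  out <- numeric(0)
  case_id <- basename(case_dir)
  for (series in config$image_names) {
    img_path <- find_nifti(case_dir, series)
    if (is.null(img_path))
      stop_input("missing image file '", series, "' in ", case_dir)
    vol <- read_case_volume(case_id, img_path, roi_path)
    feats <- extract_volume_features(vol, config, include_shape = FALSE)
    names(feats) <- paste(series, names(feats), sep = "_")
    out <- c(out, feats)
  }
  if ("shape" %in% config$families) {
    roi_vol <- read_case_volume(case_id, roi_path, roi_path)
    out <- c(shape_features(roi_vol), out)
  }
  if (anyDuplicated(names(out))) stop_input("duplicate feature names")
  attr(out, "case_id") <- case_id
  out
}

#' Compute the configured feature families for a single volume
#'
#' @param volume A [case_volume()].
#' @param config An [extract_config()].
#' @param include_shape Whether to include the shape block.
#' @return Named numeric vector.
#' @export
extract_volume_features <- function(volume, config = extract_config(),
                                    include_shape = TRUE) {
  out <- numeric(0)
  if (include_shape && "shape" %in% config$families)
    out <- c(out, shape_features(volume))
  if ("firstorder" %in% config$families)
    out <- c(out, first_order_features(volume, n_bins = config$n_bins))
  needs_q <- any(c("glcm", "glrlm", "glszm") %in% config$families)
  if (needs_q) {
    q <- quantize(volume, config$n_bins)
    if ("glcm" %in% config$families)
      out <- c(out, glcm_features(glcm(q, distance = config$distance,
                                       mode = config$mode)))
    if ("glrlm" %in% config$families)
      out <- c(out, glrlm_features(q, mode = config$mode))
    if ("glszm" %in% config$families)
      out <- c(out, glszm_features(q, mode = config$mode))
  }
  out
}

#' Extract features for every case folder under a root directory
#'
#' Case folders are processed in sorted order; per-case failures (missing
#' or unreadable files) are recorded in the log and the batch continues.
#'
#' @param root_dir Root folder holding one sub-folder per case.
#' @param config An [extract_config()].
#' @param labels Optional named vector (`case_id -> 0/1`) joined onto the
#'   output; cases without a label get `NA` for the user to fill in.
#' @param log A log object from `new_log()`, or `NULL`.
#' @return A [feature_table()]; rows sorted by case id.
#' @export
extract_batch <- function(root_dir, config = extract_config(), labels = NULL,
                          log = NULL) {
  if (!dir.exists(root_dir)) stop_input("root directory not found: ", root_dir)
  dirs <- sort(list.dirs(root_dir, recursive = FALSE))
  if (length(dirs) == 0L) stop_input("no case sub-folders under ", root_dir)
  rows <- list()
  for (d in dirs) {
    res <- tryCatch(suppressWarnings(extract_case(d, config)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      log_line(log, "extract failed for case '", basename(d), "': ",
               conditionMessage(res))
    } else {
      rows[[basename(d)]] <- res
    }
  }
  if (length(rows) == 0L) stop_input("no case could be extracted")
  fnames <- names(rows[[1]])
  X <- do.call(rbind, lapply(rows, function(r) unname(r[fnames])))
  ids <- names(rows)
  labs <- if (is.null(labels)) rep(NA_integer_, length(ids)) else
    as.integer(labels[ids])
  feature_table(case_ids = ids, labels = labs, features = X,
                feature_names = fnames)
}
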