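# The case-by-feature matrix: construction, CSV I/O, validity audit,
# stratified splitting, and class balancing.

#' Construct a feature table
#'
#' The central container: unique ordered case identifiers, binary labels
#' (1 = positive class; `NA` allowed only for freshly extracted tables not
#' yet labeled), and a numeric case-by-feature matrix with unique feature
#' names.
#'
#' @param case_ids Character vector of unique case identifiers.
#' @param labels Integer vector in `{0, 1}` (or `NA` before labeling).
#' @param features Numeric matrix, one row per case.
#' @param feature_names Character vector of unique column names.
#' @param role `"train"`, `"test"`, or `"unsplit"`; balancing refuses
#'   tables flagged as test.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(case_ids, labels, features, feature_names = colnames(features),
                          role = "unsplit") {
  case_ids <- as.character(case_ids)
  features <- as.matrix(features)
  if (anyDuplicated(case_ids)) {
    dup <- unique(case_ids[duplicated(case_ids)])
    stop_input("duplicate case ids: ", paste(dup, collapse = ", "))
  }
  if (is.null(feature_names)) feature_names <- sprintf("V%d", seq_len(ncol(features)))
  if (anyDuplicated(feature_names)) stop_input("duplicate feature names")
  if (nrow(features) != length(case_ids) || length(labels) != length(case_ids))
    stop_input("case_ids, labels and feature rows must align")
  if (ncol(features) != length(feature_names))
    stop_input("feature_names must match feature columns")
  bad <- stats::na.omit(setdiff(unique(labels), c(0L, 1L)))
  if (length(bad))
    stop_input("labels must be 0/1; offending values: ",
               paste(bad, collapse = ", "))
  dimnames(features) <- list(case_ids, feature_names)
  structure(list(case_ids = case_ids, labels = as.integer(labels),
                 features = features, feature_names = as.character(feature_names),
                 role = role),
            class = "feature_table")
}

#' @method print feature_table
#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d cases x %d features (%s)",
              length(x$case_ids), length(x$feature_names), x$role))
  if (!anyNA(x$labels))
    cat(sprintf("; %d positive / %d negative", sum(x$labels == 1L),
                sum(x$labels == 0L)))
  cat("\n")
  invisible(x)
}

#' @method dim feature_table
#' @export
dim.feature_table <- function(x) dim(x$features)

# Subset rows, preserving metadata.
table_rows <- function(tab, idx, role = tab$role) {
  feature_table(tab$case_ids[idx], tab$labels[idx],
                tab$features[idx, , drop = FALSE], tab$feature_names,
                role = role)
}

table_cols <- function(tab, keep) {
  feature_table(tab$case_ids, tab$labels,
                tab$features[, keep, drop = FALSE],
                tab$feature_names[keep], role = tab$role)
}

#' Load a feature matrix from CSV, auditing cell validity
#'
#' Expects the on-disk dialect: first column the case index, one column
#' headed `label` holding the binary outcome, all remaining columns numeric
#' features. Cells that are empty, non-numeric text, or infinite are
#' recorded in the validity report rather than silently dropped (the cell
#' itself becomes `NA` in the matrix).
#'
#' @param path CSV file path.
#' @param log Optional log object.
#' @return List with `table` (a [feature_table()]) and `report` (a
#'   `validity_report`: data frame of bad cells plus derived `bad_cases`,
#'   `bad_features`).
#' @export
load_table <- function(path, log = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop_input("need at least a case index and a label column")
  lab_col <- which(names(raw) == "label")
  if (length(lab_col) == 0L) {
    lab_col <- which(tolower(names(raw)) == "label")
    if (length(lab_col)) log_line(log, "label column matched case-insensitively: '",
                                  names(raw)[lab_col[1]], "'")
  }
  if (length(lab_col) == 0L) stop_input("no 'label' column in ", path)
  lab_col <- lab_col[1]
  case_ids <- raw[[1]]
  lab_raw <- raw[[lab_col]]
  labs <- suppressWarnings(as.numeric(lab_raw))
  if (!all(is.na(labs) | labs %in% c(0, 1))) {
    off <- unique(lab_raw[!is.na(labs) & !(labs %in% c(0, 1))])
    stop_input("labels must be 0/1; offending values: ",
               paste(off, collapse = ", "))
  }
  feat_cols <- setdiff(seq_along(raw), c(1L, lab_col))
  fnames <- names(raw)[feat_cols]
  n <- nrow(raw)
  X <- matrix(NA_real_, n, length(feat_cols))
  bad <- list()
  for (k in seq_along(feat_cols)) {
    txt <- trimws(raw[[feat_cols[k]]])
    num <- suppressWarnings(as.numeric(txt))
    is_null <- is.na(txt) | txt == "" | toupper(txt) %in% c("NA", "NAN", "NULL")
    is_text <- !is_null & is.na(num)
    is_inf <- !is.na(num) & !is.finite(num)
    num[is_inf] <- NA_real_
    X[, k] <- num
    for (i in which(is_null)) bad[[length(bad) + 1L]] <-
      data.frame(case_id = case_ids[i], feature = fnames[k], reason = "null")
    for (i in which(is_text)) bad[[length(bad) + 1L]] <-
      data.frame(case_id = case_ids[i], feature = fnames[k], reason = "non-numeric")
    for (i in which(is_inf)) bad[[length(bad) + 1L]] <-
      data.frame(case_id = case_ids[i], feature = fnames[k], reason = "infinite")
  }
  bad_cells <- if (length(bad)) do.call(rbind, bad) else
    data.frame(case_id = character(0), feature = character(0),
               reason = character(0))
  report <- structure(list(bad_cells = bad_cells,
                           bad_cases = unique(bad_cells$case_id),
                           bad_features = unique(bad_cells$feature)),
                      class = "validity_report")
  for (i in seq_len(nrow(bad_cells)))
    log_line(log, "invalid cell: case '", bad_cells$case_id[i], "', feature '",
             bad_cells$feature[i], "' (", bad_cells$reason[i], ")")
  tab <- feature_table(case_ids, as.integer(labs), X, fnames)
  list(table = tab, report = report)
}

#' @method print validity_report
#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> %d bad cells (%d cases, %d features)\n",
              nrow(x$bad_cells), length(x$bad_cases), length(x$bad_features)))
  invisible(x)
}

#' Write a feature table in the CSV dialect the loader reads
#'
#' First column `CaseID`, second column `label` (empty when unlabeled),
#' then the features. A clean table round-trips bit-identically through
#' [load_table()].
#'
#' @param tab A [feature_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table_csv <- function(tab, path) {
  df <- data.frame(CaseID = tab$case_ids,
                   label = tab$labels,
                   tab$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Remove invalid cases or features found by the audit
#'
#' @param tab A [feature_table()].
#' @param report The `validity_report` from [load_table()] for this table.
#' @param mode `"cases"` removes every row with a bad cell; `"features"`
#'   removes every column with a bad cell.
#' @param log Optional log; one line per removal.
#' @return The cleaned [feature_table()]. Idempotent on clean tables.
#' @export
drop_invalid <- function(tab, report, mode = c("cases", "features"), log = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tab, "feature_table"), inherits(report, "validity_report"))
  if (mode == "cases") {
    drop <- tab$case_ids %in% report$bad_cases
    if (all(drop)) stop_input("removing all invalid cases would empty the table")
    for (id in tab$case_ids[drop]) log_line(log, "removed case '", id, "'")
    table_rows(tab, !drop)
  } else {
    drop <- tab$feature_names %in% report$bad_features
    if (all(drop)) stop_input("removing all invalid features would empty the table")
    for (f in tab$feature_names[drop]) log_line(log, "removed feature '", f, "'")
    table_cols(tab, !drop)
  }
}

#' Stratified train/test split preserving the class ratio
#'
#' Per class, the training count is the nearest integer to
#' `(1 - test_fraction) x class size` (ties round to even, R's default);
#' membership is chosen by a seeded shuffle within each class. With 68
#' positives and 184 negatives at `test_fraction = 0.3` this yields a
#' training set of 48 + 129 = 177 cases and a test set of 75.
#'
#' @param tab A labeled [feature_table()].
#' @param test_fraction Fraction held out, in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` feature tables (roles set).
#' @export
stratified_split <- function(tab, test_fraction, seed = 1L) {
  stopifnot(inherits(tab, "feature_table"))
  if (anyNA(tab$labels)) stop_input("table has unlabeled cases")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_input("test_fraction must be in (0, 1)")
  train_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(tab$labels == cls)
    if (length(idx) < 2L) stop_input("class ", cls, " has fewer than 2 cases")
    n_train <- round((1 - test_fraction) * length(idx))
    if (n_train == 0L || n_train == length(idx))
      stop_input("class ", cls, " would be empty in one part")
    picked <- with_seed(derive_seed(seed, paste0("split", cls)),
                        sample(idx, n_train))
    train_idx <- c(train_idx, picked)
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(tab$case_ids), train_idx)
  list(train = table_rows(tab, train_idx, role = "train"),
       test = table_rows(tab, test_idx, role = "test"))
}

#' Balance the classes of a training table
#'
#' Methods: `down` subsamples the majority class (without replacement) to
#' the minority size; `up` resamples the minority with replacement to the
#' majority size; `smote` synthesizes minority points
#' `x + u (x_nn - x)`, `u ~ Uniform(0, 1)`, with `x_nn` one of the `k`
#' nearest minority neighbors (Euclidean), until the classes are equal;
#' `smotetomek` runs SMOTE and then removes both members of every Tomek
#' link. Original rows are never modified; tables flagged as test are
#' refused.
#'
#' @param tab A labeled training [feature_table()].
#' @param method One of `"down"`, `"up"`, `"smote"`, `"smotetomek"`.
#' @param seed Integer seed.
#' @param k_neighbors SMOTE neighborhood size (default 5).
#' @return A balanced [feature_table()].
#' @export
balance <- function(tab, method = c("down", "up", "smote", "smotetomek"),
                    seed = 1L, k_neighbors = 5L) {
  method <- match.arg(method)
  stopifnot(inherits(tab, "feature_table"))
  if (identical(tab$role, "test"))
    stop_input("refusing to balance a test table; balancing applies to training data only")
  if (anyNA(tab$labels)) stop_input("table has unlabeled cases")
  n1 <- sum(tab$labels == 1L); n0 <- sum(tab$labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_input("both classes must be present")
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  if (method == "down") {
    if (n_min == n_maj) return(tab)
    maj_idx <- which(tab$labels != minority)
    keep_maj <- with_seed(derive_seed(seed, "down"), sample(maj_idx, n_min))
    keep <- sort(c(which(tab$labels == minority), keep_maj))
    return(table_rows(tab, keep))
  }
  if (method == "up") {
    if (n_min == n_maj) return(tab)
    min_idx <- which(tab$labels == minority)
    extra <- with_seed(derive_seed(seed, "up"),
                       sample(min_idx, n_maj - n_min, replace = TRUE))
    idx <- c(seq_along(tab$case_ids), extra)
    out <- table_rows_dup(tab, idx)
    return(out)
  }
  # smote / smotetomek
  syn <- smote_points(tab, minority, n_maj - n_min, seed, k_neighbors)
  out <- rbind_table(tab, syn$X, rep(minority, nrow(syn$X)))
  if (method == "smotetomek") out <- remove_tomek_links(out)
  out
}

# Row-subset allowing duplicates (synthesizes fresh ids for repeats).
table_rows_dup <- function(tab, idx) {
  ids <- tab$case_ids[idx]
  dup <- duplicated(ids)
  ids[dup] <- paste0(ids[dup], "_up", cumsum(dup)[dup])
  feature_table(ids, tab$labels[idx], tab$features[idx, , drop = FALSE],
                tab$feature_names, role = tab$role)
}

rbind_table <- function(tab, new_X, new_labels) {
  if (nrow(new_X) == 0L) return(tab)
  ids <- c(tab$case_ids, sprintf("synthetic_%03d", seq_len(nrow(new_X))))
  feature_table(ids, c(tab$labels, as.integer(new_labels)),
                rbind(tab$features, new_X), tab$feature_names, role = tab$role)
}

# SMOTE interpolation among minority-class rows.
smote_points <- function(tab, minority, n_new, seed, k_neighbors) {
  X_min <- tab$features[tab$labels == minority, , drop = FALSE]
  m <- nrow(X_min)
  if (m <= k_neighbors)
    stop_input("SMOTE needs minority size > k_neighbors (", m, " <= ",
               k_neighbors, ")")
  if (n_new == 0L) return(list(X = X_min[0, , drop = FALSE]))
  D <- as.matrix(stats::dist(X_min))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(r) order(r)[seq_len(k_neighbors)]))
  with_seed(derive_seed(seed, "smote"), {
    base <- sample.int(m, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    X_new <- X_min[base, , drop = FALSE] +
      u * (X_min[pick, , drop = FALSE] - X_min[base, , drop = FALSE])
  })
  list(X = X_new)
}

# Tomek links: cross-class pairs that are mutual nearest neighbors.
remove_tomek_links <- function(tab) {
  D <- as.matrix(stats::dist(tab$features))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  drop <- logical(length(nn))
  for (i in seq_along(nn)) {
    j <- nn[i]
    if (nn[j] == i && tab$labels[i] != tab$labels[j]) drop[c(i, j)] <- TRUE
  }
  if (all(drop)) return(tab)
  table_rows(tab, !drop)
}
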