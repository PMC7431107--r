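make_csv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, "t.csv")
  writeLines(lines, p)
  p
}

test_that("a clean table loads with an empty validity report", {
  p <- make_csv(c("CaseID,label,f1,f2,f3",
                  "a,1,0.1,2,3", "b,0,0.2,4,5", "c,1,0.3,6,7", "d,0,0.4,8,9"))
  got <- load_table(p)
  expect_equal(dim(got$table), c(4L, 3L))
  expect_equal(nrow(got$report$bad_cells), 0L)
  expect_equal(got$table$labels, c(1L, 0L, 1L, 0L))
})

test_that("invalid cells are recorded with their reason, not dropped silently", {
  p <- make_csv(c("CaseID,label,f1,f2",
                  "a,1,NA,2", "b,0,3,abc", "c,1,Inf,4", "d,0,5,6"))
  got <- load_table(p)
  bad <- got$report$bad_cells
  expect_setequal(bad$reason, c("null", "non-numeric", "infinite"))
  expect_setequal(got$report$bad_cases, c("a", "b", "c"))
  expect_setequal(got$report$bad_features, c("f1", "f2"))
})

test_that("non-binary labels and duplicate ids are rejected by name", {
  p <- make_csv(c("CaseID,label,f1", "a,0,1", "b,1,2", "c,2,3"))
  expect_error(load_table(p), "2")
  p2 <- make_csv(c("CaseID,label,f1", "a,0,1", "a,1,2"))
  expect_error(load_table(p2), "duplicate case ids")
  p3 <- make_csv(c("CaseID,outcome,f1", "a,0,1"))
  expect_error(load_table(p3), "label")
})

test_that("drop_invalid removes exactly the flagged cases or features", {
  p <- make_csv(c("CaseID,label,f1,f2,f3",
                  "a,1,NA,2,3", "b,0,1,2,3", "c,1,4,5,6", "d,0,7,8,9"))
  got <- load_table(p)
  by_case <- drop_invalid(got$table, got$report, "cases")
  expect_equal(by_case$case_ids, c("b", "c", "d"))
  by_feat <- drop_invalid(got$table, got$report, "features")
  expect_equal(by_feat$feature_names, c("f2", "f3"))
  # idempotent on a clean table
  clean <- load_table(make_csv(c("CaseID,label,f1", "a,1,1", "b,0,2")))
  expect_equal(drop_invalid(clean$table, clean$report, "cases"), clean$table)
})

test_that("write/load round trip is byte-identical for clean tables", {
  tab <- make_table(table_spec(n_pos = 5, n_neg = 5, n_features = 4, seed = 2))
  td <- withr::local_tempdir()
  p1 <- file.path(td, "a.csv"); p2 <- file.path(td, "b.csv")
  write_table_csv(tab, p1)
  write_table_csv(load_table(p1)$table, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the stratified split reproduces per-class rounded counts", {
  tab <- make_imbalanced_table()  # 68 positives, 184 negatives
  sp <- stratified_split(tab, 0.3, seed = 1)
  expect_equal(length(sp$train$case_ids), 177L)
  expect_equal(length(sp$test$case_ids), 75L)
  expect_equal(sum(sp$train$labels == 1L), 48L)
  expect_equal(sum(sp$train$labels == 0L), 129L)
  # symmetric half split
  small <- make_table(table_spec(n_pos = 10, n_neg = 10, n_features = 3, seed = 4))
  sp2 <- stratified_split(small, 0.5, seed = 2)
  expect_equal(as.vector(table(sp2$train$labels)), c(5L, 5L))
  expect_equal(as.vector(table(sp2$test$labels)), c(5L, 5L))
  # partition and determinism
  expect_setequal(c(sp$train$case_ids, sp$test$case_ids), tab$case_ids)
  sp_again <- stratified_split(tab, 0.3, seed = 1)
  expect_identical(sp$train$case_ids, sp_again$train$case_ids)
  sp_other <- stratified_split(tab, 0.3, seed = 2)
  expect_false(identical(sp$train$case_ids, sp_other$train$case_ids))
})

test_that("class ratios survive the split within one case per class", {
  for (seed in 1:5) {
    tab <- make_table(table_spec(n_pos = 30 + seed, n_neg = 71, n_features = 3,
                                 seed = seed))
    sp <- stratified_split(tab, 0.25, seed = seed)
    for (cls in 0:1) {
      n_cls <- sum(tab$labels == cls)
      expect_equal(sum(sp$train$labels == cls), round(0.75 * n_cls))
    }
  }
})

test_that("down/up sampling balance classes without inventing values", {
  tab <- make_table(table_spec(n_pos = 20, n_neg = 60, n_features = 5, seed = 3))
  dn <- balance(tab, "down", seed = 1)
  expect_equal(as.vector(table(dn$labels)), c(20L, 20L))
  expect_true(all(dn$case_ids %in% tab$case_ids))
  up <- balance(tab, "up", seed = 1)
  expect_equal(as.vector(table(up$labels)), c(60L, 60L))
  expect_true(all(up$features %in% tab$features))
  # already balanced -> unchanged
  bal <- make_table(table_spec(n_pos = 10, n_neg = 10, n_features = 3, seed = 5))
  expect_equal(balance(bal, "down", seed = 1), bal)
  expect_equal(balance(bal, "up", seed = 1), bal)
})

test_that("SMOTE points lie on segments between minority neighbors", {
  tab <- make_table(table_spec(n_pos = 20, n_neg = 60, n_features = 4, seed = 6))
  sm <- balance(tab, "smote", seed = 2)
  expect_equal(as.vector(table(sm$labels)), c(60L, 60L))
  orig <- tab$features[tab$labels == 1L, , drop = FALSE]
  syn <- sm$features[grepl("^synthetic_", sm$case_ids), , drop = FALSE]
  expect_equal(nrow(syn), 40L)
  for (i in seq_len(nrow(syn))) {
    # convexity oracle: some original pair (a, b) with syn = a + u (b - a)
    on_segment <- FALSE
    for (a in seq_len(nrow(orig))) {
      d <- syn[i, ] - orig[a, ]
      for (b in seq_len(nrow(orig))) {
        if (b == a) next
        e <- orig[b, ] - orig[a, ]
        u <- sum(d * e) / sum(e * e)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((d - u * e)^2)) < 1e-8) { on_segment <- TRUE; break }
      }
      if (on_segment) break
    }
    expect_true(on_segment)
  }
  # original rows unchanged
  expect_true(all(tab$case_ids %in% sm$case_ids))
})

test_that("SMOTETomek equalizes then strips cross-class nearest-neighbor pairs", {
  tab <- make_table(table_spec(n_pos = 20, n_neg = 60, n_features = 4,
                               effect_size = 2, seed = 8))
  st <- balance(tab, "smotetomek", seed = 2)
  # no remaining Tomek link
  D <- as.matrix(dist(st$features)); diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  for (i in seq_along(nn)) {
    j <- nn[i]
    expect_false(nn[j] == i && st$labels[i] != st$labels[j])
  }
})

test_that("balancing refuses test tables and single-class tables", {
  tab <- make_table(table_spec(n_pos = 10, n_neg = 20, n_features = 3, seed = 9))
  sp <- stratified_split(tab, 0.3, seed = 1)
  expect_error(balance(sp$test, "down"), "test")
  solo <- feature_table(letters[1:4], rep(1L, 4), matrix(rnorm(8), 4))
  expect_error(balance(solo, "down"), "class")
})
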