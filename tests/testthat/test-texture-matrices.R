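# GLCM ---------------------------------------------------------------------

test_that("GLCM matches hand-enumerated pairs on a 1-D strip", {
  q <- quantize(strip_volume(c(1, 1, 2)), 2)
  m <- glcm(q, directions = matrix(c(1, 0, 0), 1))
  expect_equal(m$counts, matrix(c(2, 1, 1, 0), 2, 2))
  expect_equal(m$normalized, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
})

test_that("a constant ROI yields the single-cell unit matrix", {
  q <- quantize(strip_volume(rep(3, 5)), 8)
  m <- glcm(q, directions = matrix(c(1, 0, 0), 1))
  expect_equal(m$normalized, matrix(1, 1, 1))
})

test_that("GLCM equals the brute-force pair oracle on random phantoms", {
  for (seed in 1:6) {
    v <- random_small_volume(seed)
    q <- quantize(v, 3)
    m <- glcm(q, mode = "3d")
    oracle <- oracle_glcm_counts(q$levels, radexplore:::offsets_3d(),
                                 q$n_levels)
    expect_equal(m$counts, oracle)
    expect_equal(sum(m$normalized), 1)
    expect_equal(m$counts, t(m$counts))  # symmetric accumulation
  }
})

# GLRLM --------------------------------------------------------------------

test_that("run lengths match the spec's strip examples", {
  q <- quantize(strip_volume(rep(7, 3)), 4)
  f <- glrlm_features(q, directions = matrix(c(1, 0, 0), 1))
  expect_equal(unname(f["glrlm_rp"]), 1 / 3)       # one run over 3 voxels
  expect_equal(unname(f["glrlm_lre"]), 9)          # single run of length 3

  q2 <- quantize(strip_volume(c(1, 9, 1)), 2)
  f2 <- glrlm_features(q2, directions = matrix(c(1, 0, 0), 1))
  expect_equal(unname(f2["glrlm_sre"]), 1)         # all runs length 1
})

test_that("GLRLM equals the line-walking oracle on random phantoms", {
  for (seed in 1:6) {
    v <- random_small_volume(seed)
    q <- quantize(v, 3)
    m <- glrlm(q, mode = "3d")
    oracle <- oracle_run_counts(q$levels, radexplore:::offsets_3d(),
                                q$n_levels)
    expect_equal(m$counts, oracle)
    # every voxel sits in exactly one run per direction
    i <- matrix(seq_len(nrow(m$counts)), nrow(m$counts), ncol(m$counts))
    l <- t(matrix(seq_len(ncol(m$counts)), ncol(m$counts), nrow(m$counts)))
    expect_equal(sum(m$counts * l), sum(v$mask) * nrow(radexplore:::offsets_3d()))
  }
})

# GLSZM --------------------------------------------------------------------

test_that("zone decomposition partitions the ROI", {
  for (seed in 1:6) {
    v <- random_small_volume(seed)
    q <- quantize(v, 3)
    m <- glszm(q, mode = "3d")
    expect_equal(sum(m$zone_sizes), sum(v$mask))
    z <- t(matrix(seq_len(ncol(m$counts)), ncol(m$counts), nrow(m$counts)))
    expect_equal(sum(m$counts * z), sum(v$mask))
  }
})

test_that("zone count equals the independent flood-fill oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:6) {
    v <- random_small_volume(seed)
    q <- quantize(v, 3)
    m <- glszm(q, mode = "3d")
    expect_equal(sum(m$counts), oracle_zone_count(q$levels, all_26_offsets()))
  }
})

test_that("two equal-size zones at levels 1 and 3 give GLV = 1", {
  img <- array(5, c(5, 1, 1))
  msk <- array(0L, c(5, 1, 1))
  img[1:2] <- 0; img[4:5] <- 10
  msk[c(1, 2, 4, 5)] <- 1L
  q <- quantize(case_volume("z", img, msk), 3)
  f <- glszm_features(q)
  expect_equal(unname(f["glszm_gray_level_variance"]), 1)
})

test_that("a constant ROI is a single zone with zero gray level variance", {
  q <- quantize(strip_volume(rep(2, 9)), 16)
  m <- glszm(q)
  expect_equal(sum(m$counts), 1)
  expect_equal(unname(glszm_features(q)["glszm_gray_level_variance"]), 0)
})

# shared invariants ---------------------------------------------------------

test_that("texture features are invariant to an intensity shift", {
  v <- random_small_volume(11, shape = c(5, 5, 3), n_levels_src = 6)
  v2 <- case_volume(v$case_id, v$image + 137.5, v$mask, v$spacing)
  for (fun in list(function(x) glcm_features(glcm(x, mode = "3d")),
                   function(x) glrlm_features(x, mode = "3d"),
                   function(x) glszm_features(x, mode = "3d"))) {
    expect_equal(fun(quantize(v, 4)), fun(quantize(v2, 4)))
  }
})

test_that("direction-aggregated features are invariant to axis permutation", {
  v <- random_small_volume(13, shape = c(4, 4, 4), n_levels_src = 5)
  vr <- case_volume(v$case_id, aperm(v$image, c(2, 3, 1)),
                    aperm(v$mask, c(2, 3, 1)), v$spacing)
  q <- quantize(v, 4); qr <- quantize(vr, 4)
  expect_equal(glcm_features(glcm(q, mode = "3d")),
               glcm_features(glcm(qr, mode = "3d")))
  expect_equal(glrlm_features(q, mode = "3d"), glrlm_features(qr, mode = "3d"))
  expect_equal(glszm_features(q, mode = "3d"), glszm_features(qr, mode = "3d"))
})
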