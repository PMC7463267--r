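test_that("AC reproduces the hand-worked lag-1 example", {
  # single informative column (1, 3, 2), mean 2:
  # AC = ((1-2)(3-2) + (3-2)(2-2)) / 2 = -0.5
  p <- two_col_profile(c(1, 3, 2), c(0, 0, 0))
  v <- ac_features(p, LG = 1)
  expect_equal(v$values[1], -0.5)
  expect_equal(v$feature_ids[1], "AC:A:lg=1")
  expect_equal(sum(v$values != 0), 1L)  # constant columns give exactly 0
})

test_that("CC reproduces the hand-worked asymmetric example", {
  # a = (1,3,2) mean 2; b = (0,2,4) mean 2:
  # CC(a,b,1) = ((1-2)(2-2) + (3-2)(4-2))/2 = 1; CC(b,a,1) = -1
  p <- two_col_profile(c(1, 3, 2), c(0, 2, 4))
  v <- cc_features(p, LG = 1)
  expect_equal(v$values[v$feature_ids == "CC:A:R:lg=1"], 1.0)
  expect_equal(v$values[v$feature_ids == "CC:R:A:lg=1"], -1.0)
})

test_that("constant-column profiles yield all-zero AC and CC", {
  X <- matrix(rep(seq(-5, 5, length.out = 20), each = 12), 12, 20)
  colnames(X) <- pssm_alphabet()
  p <- new_pssm_profile("const", strrep("A", 12), X)
  expect_true(all(acc_features(p, 4)$values == 0))
})

test_that("SD handles the degenerate boundary cases", {
  z <- two_col_profile(rep(0, 6), rep(0, 6))
  expect_true(all(sd_features(z, 4)$values == 0))
  X <- matrix(1, 5, 20, dimnames = list(NULL, pssm_alphabet()))
  ones <- new_pssm_profile("ones", strrep("A", 5), X)
  v <- sd_features(ones, 4)  # exactly L - k = 1 product term of 1*1
  expect_true(all(v$values == 1))
  expect_length(v$values, 400L)
})

test_that("block sizes follow 20*LG, 380*LG, 400*LG, 400 for LG,k in 1..6", {
  p <- random_profile(30, seed = 42)
  for (g in 1:6) {
    expect_length(ac_features(p, g)$values, 20L * g)
    expect_length(cc_features(p, g)$values, 380L * g)
    expect_length(acc_features(p, g)$values, 400L * g)
  }
  for (k in 1:6) expect_length(sd_features(p, k)$values, 400L)
})

test_that("production extractors agree with the naive-loop oracles", {
  for (s in 1:5) {
    p <- random_profile(sample(10:30, 1), seed = 500 + s)
    expect_equal(ac_features(p, 3)$values, naive_ac(p$scores, 3),
                 tolerance = 1e-9)
    expect_equal(cc_features(p, 3)$values, naive_cc(p$scores, 3),
                 tolerance = 1e-9)
    expect_equal(sd_features(p, 4)$values, naive_sd(p$scores, 4),
                 tolerance = 1e-9)
  }
})

test_that("CC evaluated at i1 = i2 reproduces AC for that column and lag", {
  p <- random_profile(20, seed = 9)
  Xc <- sweep(p$scores, 2, colMeans(p$scores))
  for (lg in 1:3) {
    cc_diag <- colSums(Xc[1:(20 - lg), ] * Xc[(1 + lg):20, ]) / (20 - lg)
    expect_equal(unname(cc_diag), ac_features(p, lg)$values[(lg - 1) * 20 + 1:20],
                 tolerance = 1e-12)
  }
})

test_that("ACC is shift-invariant per column; SD is not", {
  p <- random_profile(25, seed = 13)
  q <- p
  q$scores[, 5] <- q$scores[, 5] + 7
  expect_equal(acc_features(q, 4)$values, acc_features(p, 4)$values,
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(sd_features(q, 4)$values,
                                sd_features(p, 4)$values)))
})

test_that("short profiles are rejected naming the protein", {
  p <- random_profile(4, id = "shorty", seed = 3)
  expect_error(ac_features(p, 4), "shorty")
  expect_error(sd_features(p, 4), "shorty")
  expect_error(cc_features(p, 7), "shorty")
})

test_that("fuse concatenates blocks of the same protein only", {
  p <- random_profile(20, id = "pa", seed = 1)
  a <- acc_features(p, 4); s <- sd_features(p, 4)
  f <- fuse(a, s)
  expect_length(f$values, 2000L)
  expect_identical(f$feature_ids, c(a$feature_ids, s$feature_ids))
  expect_identical(f$values, c(a$values, s$values))
  other <- sd_features(random_profile(20, id = "pb", seed = 2), 4)
  expect_error(fuse(a, other), "different proteins")
})

test_that("build_feature_matrix composes, fails fast, shares column ids", {
  ps <- lapply(1:3, function(i) random_profile(15, sprintf("p%d", i),
                                               seed = 70 + i))
  d <- build_feature_matrix(ps, c("x", "y", "x"))
  expect_equal(dim(d$matrix), c(3L, 2000L))
  expect_identical(colnames(d$matrix), d$feature_ids)
  expect_equal(d$protein_ids, c("p1", "p2", "p3"))
  ps2 <- c(ps, list(random_profile(4, "tiny", seed = 99)))
  expect_error(build_feature_matrix(ps2, c("x", "y", "x", "y")), "tiny")
})

test_that("extraction is deterministic (bit-identical on repeat)", {
  p <- random_profile(40, seed = 123)
  cfg <- feature_config()
  expect_identical(extract_features(p, cfg)$values,
                   extract_features(p, cfg)$values)
})
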