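test_that("bin summaries tile the axis and match hand enumeration", {
  one <- bin_summaries(7L, 2)
  expect_equal(one$bin_low, 5)
  expect_equal(one$bin_high, 9)
  expect_equal(one$median_abundance, 2)
  expect_equal(one$mean_abundance, 2)
  expect_equal(one$n, 1L)

  b <- bin_summaries(c(44L, 44L, 45L), c(0, 2, 6))
  expect_equal(b$bin_low, c(40, 45))
  expect_equal(b[b$bin_low == 40, ]$n, 2L)
  expect_equal(b[b$bin_low == 40, ]$median_abundance, 1)
  expect_equal(b[b$bin_low == 40, ]$mean_abundance, 1)
  expect_equal(b[b$bin_low == 45, ]$median_abundance, 6)

  set.seed(8)
  topt <- sample(4:85, 400, replace = TRUE)
  ab <- rpois(400, 2)
  bb <- bin_summaries(topt, ab)
  expect_equal(nrow(bb), 18)                 # 4..85 spans 18 five-degree bins
  expect_true(all(bb$bin_high - bb$bin_low == 4))
  expect_true(all(bb$bin_low %% 5 == 0))
  expect_equal(sum(bb$n), 400L)
  expect_error(bin_summaries(4.5, 1), "integer-rounded")
})

test_that("D curve matches exhaustive split enumeration on the 4-point toy", {
  topt <- c(10L, 20L, 50L, 60L)
  ab <- c(1, 1, 3, 5)
  dc <- d_curve(topt, ab)
  expect_equal(range(dc$i), c(11, 60))
  # independent enumeration of every split point
  for (k in seq_len(nrow(dc))) {
    i <- dc$i[k]
    expect_equal(dc$d[k], mean(ab[topt >= i]) / mean(ab[topt < i]))
  }
  expect_true(all(dc$d[dc$i >= 11 & dc$i <= 20] == 3))
  expect_true(all(dc$d[dc$i >= 21 & dc$i <= 50] == 4))
  expect_true(all(dc$d[dc$i >= 51 & dc$i <= 60] == 3))
})

test_that("D curve handles constants, zeros, reordering and scaling", {
  topt <- c(10L, 20L, 30L, 40L)
  expect_true(all(d_curve(topt, rep(2, 4))$d == 1))

  dz <- d_curve(topt, c(0, 0, 1, 2))
  expect_false(all(dz$finite))
  expect_true(all(is.infinite(dz$d[!dz$finite])))
  expect_true(all(dz$i[!dz$finite] <= 30))

  set.seed(5)
  t2 <- sample(4:85, 60, replace = TRUE)
  a2 <- rpois(60, 3)
  perm <- sample(60)
  expect_equal(d_curve(t2, a2)$d, d_curve(t2[perm], a2[perm])$d)
  expect_equal(d_curve(t2, a2)$d, d_curve(t2, a2 * 3.7)$d, tolerance = 1e-12)

  expect_error(d_curve(rep(37L, 5), 1:5), "degenerate")
})

test_that("windowed maximum takes the smallest-i finite maximum", {
  dc <- d_curve(c(10L, 20L, 50L, 60L), c(1, 1, 3, 5))
  dm <- d_max(dc)
  expect_equal(dm$d_max, 4)
  expect_equal(dm$argmax_i, 21L)
  expect_equal(dm$window, c(20, 64))

  flat <- d_max(d_curve(c(10L, 30L, 50L), rep(2, 3)))
  expect_equal(flat$d_max, 1)

  dz <- d_curve(c(21L, 25L, 40L), c(0, 1, 2))
  dmz <- d_max(dz)
  expect_true(is.finite(dmz$d_max))
  expect_gt(dmz$n_infinite, 0)

  expect_error(d_max(dc, lo = 90, hi = 99), "disjoint")
})

test_that("permutation test: observed statistic is seed-free, p-variants relate", {
  set.seed(14)
  topt <- sample(10:70, 120, replace = TRUE)
  ab <- rnbinom(120, mu = 1 + 3 * (topt > 45), size = 1)
  p1 <- permutation_test(topt, ab, n_perm = 99, seed = 1)
  p2 <- permutation_test(topt, ab, n_perm = 99, seed = 2)
  expect_equal(p1$observed$d_max, p2$observed$d_max)
  expect_equal(p1$observed$argmax_i, p2$observed$argmax_i)
  # same seed reproduces the null draw exactly
  p1b <- permutation_test(topt, ab, n_perm = 99, seed = 1)
  expect_equal(p1$null_dmax, p1b$null_dmax)
  # conservative variant is (k+1)/(n+1) of the same null sample
  pc <- permutation_test(topt, ab, n_perm = 99, seed = 1,
                         p_variant = "conservative")
  k <- sum(p1$null_dmax > p1$observed$d_max, na.rm = TRUE)
  expect_equal(p1$p_value, k / 99)
  expect_equal(pc$p_value, (k + 1) / 100)
  expect_error(permutation_test(topt, rep(1, 120), seed = 1), "constant")
})

test_that("exhaustive assignment enumeration gives p = 1/252 on the two-block toy", {
  topt <- c(rep(10L, 5), rep(70L, 5))
  ab <- c(rep(1, 5), rep(9, 5))
  obs <- d_max(d_curve(topt, ab))$d_max
  expect_equal(obs, 9)
  # all C(10,5) = 252 distinct assignments of abundances to the low block
  combs <- combn(10, 5)
  null_d <- apply(combs, 2, function(lowpos) {
    a <- numeric(10)
    a[1:5] <- ab[lowpos]
    a[6:10] <- ab[-lowpos]
    d_max(d_curve(topt, a))$d_max
  })
  expect_equal(ncol(combs), 252)
  expect_equal(mean(null_d >= obs), 1 / 252)
})

test_that("permutation p-values are uniform when abundance is exchangeable", {
  set.seed(99)
  n <- 150
  topt <- sample(4:85, n, replace = TRUE)
  ps <- vapply(1:200, function(r) {
    ab <- rnbinom(n, mu = 2, size = 1)
    ab[runif(n) < 0.5] <- 0
    if (var(ab) == 0) return(NA_real_)
    permutation_test(topt, ab, n_perm = 99, seed = r)$p_value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.05)
})
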