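# smaller-than-default windows keep these scans fast; the window-count law
# is size-free
test_that("segmental scan obeys the window-count law with planted constant runs", {
  set.seed(51)
  n <- 70
  W <- 20
  tr <- simulate_tree(n, seed = 51)
  # plant a constant-Topt run longer than the window
  topt <- c(rep(37, 25), sort(sample(setdiff(4:85, 37), n - 25, replace = FALSE)))
  tab <- trait_table(data.frame(species_id = tr$tip.label,
                                topt_c = as.numeric(topt),
                                arrays = rpois(n, 2)))
  sc <- segmental_pgls(tab, tr, "arrays", window = W)
  ord_topt <- sort(topt)
  n_const <- sum(vapply(seq_len(n - W + 1), function(s)
    length(unique(ord_topt[s:(s + W - 1)])) == 1, logical(1)))
  expect_gt(n_const, 0)
  expect_equal(nrow(sc), (n - W + 1) - n_const)
  expect_equal(attr(sc, "n_skipped"), n_const)
  # each window is a contiguous block of the sorted order with W species
  expect_true(all(sc$n == W))
  expect_true(all(diff(sc$window_index) >= 1))
  # significance flags are consistent with the p-values
  expect_equal(sc$significant_05, sc$slope_p < 0.05)
  expect_equal(sc$significant_01, sc$slope_p < 0.01)
})

test_that("all-identical Topt yields zero windows with an explicit report", {
  tr <- simulate_tree(30, seed = 52)
  tab <- trait_table(data.frame(species_id = tr$tip.label, topt_c = 37,
                                arrays = rpois(30, 2)))
  expect_message(sc <- segmental_pgls(tab, tr, "arrays", window = 30),
                 "all windows skipped")
  expect_equal(nrow(sc), 0)
  expect_error(segmental_pgls(tab, tr, "arrays", window = 31), "smaller")
})

test_that("windows detect a planted slope where categories are flat", {
  set.seed(53)
  n <- 120
  tr <- simulate_tree(n, seed = 53)
  topt <- sort(sample(4:85, n, replace = TRUE))
  mu <- 1 + 4 * plogis((topt - 45) / 2)
  tab <- trait_table(data.frame(species_id = tr$tip.label,
                                topt_c = as.numeric(topt),
                                arrays = rpois(n, mu)))
  sc <- segmental_pgls(tab, tr, "arrays", window = 40, stride = 5)
  mid <- sc[sc$mean_topt > 35 & sc$mean_topt < 55, ]
  expect_gt(nrow(mid), 0)
  expect_true(any(mid$positive_slope & mid$significant_05))
})

test_that("a single category spanning the data equals the plain full fit", {
  set.seed(54)
  n <- 60
  tr <- simulate_tree(n, seed = 54)
  topt <- rtrait_lambda(tr, 0.9, mean = 45, sd = 12, seed = 55)
  tab <- trait_table(data.frame(species_id = tr$tip.label,
                                topt_c = round(as.numeric(topt)),
                                arrays = rpois(n, 2)))
  cats <- data.frame(name = "span", topt_low = min(tab$topt_c),
                     topt_high = max(tab$topt_c))
  res <- category_pgls(tab, tr, cats, measures = "arrays")
  expect_equal(nrow(res), 2)  # "span" plus the whole-range fit
  direct <- pgls_fit(setNames(as.numeric(tab$arrays), tab$species_id),
                     setNames(as.numeric(tab$topt_c), tab$species_id), tr)
  for (lbl in c("span", "all")) {
    row <- res[res$category == lbl, ]
    expect_equal(row$slope, direct$slope, tolerance = 1e-6)
    expect_equal(row$n, direct$n)
  }
  # categories partition the species count
  tert <- tertile_split(tab)
  res3 <- category_pgls(tab, tr, tert, measures = "arrays")
  expect_equal(sum(res3$n[res3$category != "all"]), n)
  expect_error(category_pgls(tab, tr, data.frame(name = c("a", "b"),
                                                 topt_low = c(0, 10),
                                                 topt_high = c(20, 30))),
               "overlap")
})

test_that("tertile split balances groups and never divides tied Topt", {
  nine <- tertile_split(data.frame(species_id = letters[1:9],
                                   topt_c = c(5, 10, 20, 30, 40, 50, 60, 70, 80),
                                   arrays = 0L) |> trait_table())
  expect_equal(nine$n, c(3L, 3L, 3L))

  tied <- tertile_split(trait_table(data.frame(
    species_id = letters[1:6], topt_c = c(10, 10, 10, 20, 20, 30), arrays = 0L)))
  expect_equal(tied$n, c(3L, 2L, 1L))
  expect_equal(tied$topt_low, c(10, 20, 30))
  expect_equal(tied$topt_high, c(10, 20, 30))

  expect_error(tertile_split(trait_table(data.frame(
    species_id = letters[1:6], topt_c = c(1, 1, 1, 2, 2, 2), arrays = 0L))),
    "distinct")
})

test_that("paired domain comparison averages shared Topt and matches the exact oracle", {
  bac <- trait_table(data.frame(
    species_id = paste0("b", 1:8),
    topt_c = c(20, 20, 30, 40, 50, 60, 70, 80),
    arrays = c(6L, 4L, 2L, 6L, 3L, 9L, 7L, 9L)))
  arc <- trait_table(data.frame(
    species_id = paste0("a", 1:7),
    topt_c = c(20, 30, 40, 50, 60, 70, 95),
    arrays = c(2L, 3L, 2L, 5L, 3L, 2L, 8L)))
  cmp <- paired_domain_comparison(bac, arc, "arrays")
  expect_equal(cmp$n_pairs, 6)  # 20,30,40,50,60,70 shared; 80/95 not
  expect_equal(cmp$pairs$mean_bacteria[1], 5)  # (6+4)/2 at 20 degC
  d <- cmp$pairs$mean_bacteria - cmp$pairs$mean_archaea
  expect_equal(cmp$p_value, signed_rank_exact_p(d), tolerance = 1e-12)

  # swapping the domains mirrors the statistic around its mean
  rev <- paired_domain_comparison(arc, bac, "arrays")
  m <- cmp$n_informative
  expect_equal(rev$statistic, m * (m + 1) / 2 - cmp$statistic)
  expect_equal(rev$p_value, cmp$p_value, tolerance = 1e-12)

  same <- paired_domain_comparison(bac, bac, "arrays")
  expect_equal(same$p_value, 1)
  expect_equal(same$n_informative, 0)

  cold <- trait_table(data.frame(species_id = "z", topt_c = 5, arrays = 1L))
  expect_error(paired_domain_comparison(bac, cold, "arrays"), "no shared")
})
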