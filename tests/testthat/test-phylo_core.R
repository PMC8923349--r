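test_that("phylogenetic covariance matches closed forms and a path-summing oracle", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  Cs <- phylo_covariance(star)$C
  expect_equal(unname(Cs), diag(3))

  two <- ape::read.tree(text = "(A:0.3,B:0.7);")
  C2 <- phylo_covariance(two)$C
  expect_equal(unname(C2), matrix(c(0.3, 0, 0, 0.7), 2))

  bal <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,D:0.5):1);")
  C4 <- phylo_covariance(bal)$C
  expect_equal(C4, brute_force_vcv(bal), tolerance = 1e-12)

  neg <- two
  neg$edge.length[1] <- -0.1
  expect_error(phylo_covariance(neg), "negative")
})

test_that("lambda transform scales off-diagonals only and checks bounds", {
  C <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(lambda_transform(C, 0), diag(2))
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0.5), matrix(c(1, 0.2, 0.2, 1), 2))
  expect_error(lambda_transform(C, 1.2), "lambda")
  expect_error(lambda_transform(C, -0.1), "lambda")
})

test_that("PGLS on a star tree reduces to ordinary least squares at any lambda", {
  set.seed(21)
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:12, ":1", collapse = ","), ");"))
  x <- setNames(rnorm(12, 40, 10), star$tip.label)
  y <- setNames(1 + 0.2 * x + rnorm(12), star$tip.label)
  ols <- lm(y ~ x)
  for (lam in c(0, 0.5, 1)) {
    f <- pgls_fit(y, x, star, lambda = lam)
    expect_equal(f$slope, unname(coef(ols)[2]), tolerance = 1e-8)
    expect_equal(f$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  }
})

test_that("profile maximum dominates a dense lambda grid (oracle equivalence)", {
  set.seed(31)
  tr <- simulate_tree(6, seed = 31)
  x <- setNames(c(12, 35, 41, 47, 60, 72), tr$tip.label)
  y <- setNames(c(0, 1, 3, 2, 6, 5), tr$tip.label)
  f <- pgls_fit(y, x, tr)
  C <- phylo_covariance(tr)$C
  X <- cbind(1, as.numeric(x))
  grid_ll <- vapply(seq(0, 1, by = 0.05), function(l)
    gls_oracle(as.numeric(y), X, C, l)$loglik, numeric(1))
  expect_gte(f$loglik, max(grid_ll) - 1e-6)
})

test_that("fixed-lambda endpoints reproduce OLS and explicit GLS", {
  set.seed(41)
  for (r in 1:5) {
    n <- sample(10:50, 1)
    tr <- simulate_tree(n, seed = 100 + r)
    x <- rtrait_lambda(tr, 0.8, mean = 40, sd = 10, seed = 200 + r)
    y <- setNames(2 + 0.1 * as.numeric(x) +
                    as.numeric(rtrait_lambda(tr, 0.8, sd = 1, seed = 300 + r)),
                  names(x))
    C <- phylo_covariance(tr)$C
    X <- cbind(1, as.numeric(x))

    f0 <- pgls_fit(y, x, tr, lambda = 0)
    ols <- lm(as.numeric(y) ~ as.numeric(x))
    expect_equal(f0$slope, unname(coef(ols)[2]), tolerance = 1e-8)
    expect_equal(f0$sigma2_hat, sum(residuals(ols)^2) / n, tolerance = 1e-8)

    f1 <- pgls_fit(y, x, tr, lambda = 1)
    or <- gls_oracle(as.numeric(y), X, C, 1)
    expect_equal(unname(f1$slope), unname(or$beta[2]), tolerance = 1e-8)
    expect_equal(f1$sigma2_hat, or$sigma2, tolerance = 1e-8)
    expect_equal(f1$loglik, or$loglik, tolerance = 1e-6)
  }
})

test_that("fits are invariant to a joint permutation of tip order", {
  tr <- simulate_tree(20, seed = 77)
  x <- rtrait_lambda(tr, 0.9, mean = 40, sd = 10, seed = 78)
  y <- setNames(1 + 0.1 * as.numeric(x) +
                  as.numeric(rtrait_lambda(tr, 0.5, sd = 1, seed = 79)), names(x))
  f1 <- pgls_fit(y, x, tr)
  s1 <- estimate_lambda_signal(y, tr)
  perm <- sample(length(y))
  f2 <- pgls_fit(y[perm], x[perm], tr)
  s2 <- estimate_lambda_signal(y[perm], tr)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f1$lambda_hat, f2$lambda_hat, tolerance = 1e-8)
  expect_equal(s1$lambda_hat, s2$lambda_hat, tolerance = 1e-8)
})

test_that("engine agrees with independent lambda-model implementations", {
  tr <- simulate_tree(40, seed = 91)
  x <- rtrait_lambda(tr, 0.9, mean = 40, sd = 10, seed = 92)
  y <- setNames(2 + 0.1 * as.numeric(x) +
                  as.numeric(rtrait_lambda(tr, 0.7, sd = 2, seed = 93)), names(x))
  f <- pgls_fit(y, x, tr)
  d <- data.frame(y = as.numeric(y), x = as.numeric(x), row.names = names(y))
  g <- suppressWarnings(nlme::gls(y ~ x, data = d,
                                  correlation = ape::corPagel(0.5, tr, form = ~1),
                                  method = "ML"))
  expect_equal(f$slope, unname(coef(g)[2]), tolerance = 1e-5)
  expect_equal(f$lambda_hat, unname(g$modelStruct$corStruct[1]), tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-5)

  s <- estimate_lambda_signal(y, tr)
  ps <- phytools::phylosig(tr, y, method = "lambda", test = TRUE)
  expect_equal(s$lambda_hat, ps$lambda, tolerance = 1e-4)
  expect_equal(s$loglik_at_hat, ps$logL, tolerance = 1e-5)
})

test_that("signal estimates separate independent noise from Brownian traits", {
  tr <- simulate_tree(300, seed = 11)
  noise <- rtrait_lambda(tr, 0, sd = 1, seed = 12)
  bm <- rtrait_lambda(tr, 1, sd = 1, seed = 13)
  expect_lt(estimate_lambda_signal(noise, tr)$lambda_hat, 0.2)
  expect_gt(estimate_lambda_signal(bm, tr)$lambda_hat, 0.8)
  expect_error(estimate_lambda_signal(setNames(rep(1, 300), tr$tip.label), tr),
               "zero-variance")
  expect_error(pgls_fit(noise, setNames(rep(2, 300), tr$tip.label), tr),
               "constant covariate")
})

test_that("joint estimation recovers lambda and slope on simulated data", {
  # 100 datasets, n = 300 tips, lambda_true = 0.8, slope_true = 0.1
  n_rep <- 100
  lams <- numeric(n_rep)
  slopes <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    tr <- simulate_tree(300, seed = 5000 + r)
    x <- rtrait_lambda(tr, 0.9, mean = 40, sd = 10, seed = 6000 + r)
    eps <- rtrait_lambda(tr, 0.8, sd = 1, seed = 7000 + r)
    y <- setNames(1 + 0.1 * as.numeric(x) + as.numeric(eps), names(x))
    f <- pgls_fit(y, x, tr)
    lams[r] <- f$lambda_hat
    slopes[r] <- f$slope
  }
  expect_lt(abs(mean(lams) - 0.8), 0.1)
  expect_lt(abs(mean(slopes) - 0.1) / 0.1, 0.2)
})
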