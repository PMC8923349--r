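#' Phylogenetic covariance matrix of a tree
#'
#' Under Brownian trait evolution the covariance between two tips equals the
#' branch-length distance from the root to their most recent common
#' ancestor; the variance of a tip is its root-to-tip path length. This is
#' the matrix every lambda-model computation starts from.
#'
#' @param tree an [ape::phylo] phylogeny with branch lengths.
#' @return object of class `phylo_cov`: list with `C` (n x n matrix, rows
#'   and columns named and ordered by tip label) and `tip_order`.
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  structure(list(C = C, tip_order = rownames(C)), class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat(sprintf("Phylogenetic covariance: %d tips, tree depth range [%g, %g]\n",
              nrow(x$C), min(diag(x$C)), max(diag(x$C))))
  invisible(x)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda` while leaving the
#' diagonal untouched. `lambda = 0` removes all shared history
#' (independence), `lambda = 1` returns the Brownian covariance unchanged.
#'
#' @param C a `phylo_cov` object or a bare covariance matrix.
#' @param lambda scalar in \[0, 1\].
#' @return transformed covariance matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (inherits(C, "phylo_cov")) C <- C$C
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop_ct("lambda must be a single value in [0, 1]")
  }
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

# ---- internal GLS engine ----------------------------------------------------

# Cholesky of V(lambda) with a jitter fallback of 1e-10 * mean diagonal.
chol_lambda <- function(C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) {
    jit <- 1e-10 * mean(diag(C))
    L <- tryCatch(chol(V + diag(jit, nrow(V))), error = function(e) NULL)
    if (is.null(L)) stop_ct("V(lambda) not positive definite at lambda = %g", lambda)
  }
  L
}

# ML profile log-likelihood and GLS coefficients at fixed lambda.
# Returns loglik, beta, sigma2 (ML), XtViX inverse, residual quadratic form.
gls_at_lambda <- function(y, X, C, lambda) {
  n <- length(y)
  R <- chol_lambda(C, lambda)              # V = R'R
  z <- backsolve(R, y, transpose = TRUE)   # R^-T y
  W <- backsolve(R, X, transpose = TRUE)   # R^-T X
  XtViX <- crossprod(W)
  bet <- tryCatch(solve(XtViX, crossprod(W, z)), error = function(e)
    stop_ct("singular design in GLS at lambda = %g", lambda))
  r <- z - W %*% bet
  rss <- sum(r^2)                          # r' V^-1 r
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  list(loglik = ll, beta = drop(bet), sigma2 = sigma2,
       XtViX = XtViX, rss = rss, n = n)
}

# Maximize the profile likelihood over lambda in [0, 1]: coarse grid then
# local refinement; deterministic and robust to flat profiles.
optimize_lambda <- function(y, X, C, grid_n = 21) {
  grid <- seq(0, 1, length.out = grid_n)
  ll_grid <- vapply(grid, function(l) gls_at_lambda(y, X, C, l)$loglik, numeric(1))
  i <- which.max(ll_grid)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(grid_n, i + 1)]
  best_l <- grid[i]
  best_ll <- ll_grid[i]
  if (hi > lo) {
    op <- optimize(function(l) gls_at_lambda(y, X, C, l)$loglik,
                   interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
    if (op$objective > best_ll) {
      best_l <- op$maximum
      best_ll <- op$objective
    }
  }
  list(lambda = best_l, loglik = best_ll)
}

#' Estimate Pagel's lambda phylogenetic signal of a trait
#'
#' Fits the intercept-only lambda model y ~ Normal(mu, sigma^2 V(lambda))
#' by maximum likelihood, profiling (mu, sigma^2) out analytically per
#' candidate lambda, and tests lambda = 0 with a likelihood-ratio test
#' against chi-square(1). Because lambda = 0 sits on the boundary of the
#' parameter space, the default null is the 50:50 mixture of a point mass
#' at zero and chi-square(1); `boundary = "chisq"` gives the plain
#' chi-square(1) reference.
#'
#' @param y named numeric trait vector, or unnamed in tree tip order.
#' @param tree an [ape::phylo] phylogeny.
#' @param boundary null distribution at the boundary: `"mixture"` (default)
#'   or `"chisq"`.
#' @return object of class `signal_estimate`: `lambda_hat`, `loglik_at_hat`,
#'   `loglik_at_zero`, `lr_stat`, `p_value`, `n`.
#' @export
estimate_lambda_signal <- function(y, tree, boundary = c("mixture", "chisq")) {
  boundary <- match.arg(boundary)
  validate_phylogeny(tree)
  y <- align_to_tips(y, tree)
  n <- length(y)
  if (n < 4) stop_ct("need at least 4 tips to estimate a phylogenetic signal")
  if (var(y) == 0) stop_ct("zero-variance trait")
  C <- phylo_covariance(tree)$C
  X <- matrix(1, n, 1)
  opt <- optimize_lambda(y, X, C)
  ll0 <- gls_at_lambda(y, X, C, 0)$loglik
  if (ll0 > opt$loglik) {  # boundary can win exactly
    opt <- list(lambda = 0, loglik = ll0)
  }
  lr <- 2 * (opt$loglik - ll0)
  lr <- max(lr, 0)
  p <- if (lr == 0) 1 else pchisq(lr, df = 1, lower.tail = FALSE)
  if (boundary == "mixture" && lr > 0) p <- p / 2
  structure(list(lambda_hat = opt$lambda, loglik_at_hat = opt$loglik,
                 loglik_at_zero = ll0, lr_stat = lr, p_value = p, n = n,
                 boundary = boundary, method = "ML"),
            class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat(sprintf("Pagel's lambda signal: lambda_hat = %.4f (n = %d)\n",
              x$lambda_hat, x$n))
  cat(sprintf("  logLik %.3f vs lambda=0 %.3f; LR = %.3f, p = %.3g (%s null)\n",
              x$loglik_at_hat, x$loglik_at_zero, x$lr_stat, x$p_value, x$boundary))
  invisible(x)
}

#' Phylogenetic generalized least squares under the lambda model
#'
#' Fits y = b0 + b1 x + e with e ~ Normal(0, sigma^2 V(lambda)) by joint
#' maximum likelihood: closed-form GLS for the coefficients at each
#' candidate lambda, profile search over lambda in \[0, 1\]. The slope
#' p-value comes from a t statistic with n - 2 degrees of freedom using the
#' (n - 2)-denominator variance estimate.
#'
#' @param y response vector (named, or in tip order).
#' @param x covariate vector (named, or in tip order).
#' @param tree an [ape::phylo] phylogeny.
#' @param lambda fix lambda at this value instead of estimating it
#'   (`NULL`, the default, estimates it).
#' @return object of class `pgls_fit`: `intercept`, `slope`, `slope_se`,
#'   `slope_t`, `slope_p`, `lambda_hat`, `sigma2_hat` (ML), `loglik`, `n`,
#'   `lambda_fixed`.
#' @export
pgls_fit <- function(y, x, tree, lambda = NULL) {
  validate_phylogeny(tree)
  y <- align_to_tips(y, tree)
  x <- align_to_tips(x, tree)
  n <- length(y)
  if (n < 4) stop_ct("need at least 4 tips for PGLS")
  if (var(x) == 0) stop_ct("constant covariate: PGLS slope undefined")
  C <- phylo_covariance(tree)$C
  X <- cbind(`(Intercept)` = 1, x = x)
  if (is.null(lambda)) {
    opt <- optimize_lambda(y, X, C)
    lam <- opt$lambda
  } else {
    if (lambda < 0 || lambda > 1) stop_ct("lambda must be in [0, 1]")
    lam <- lambda
  }
  g <- gls_at_lambda(y, X, C, lam)
  s2_df <- g$rss / (n - 2)
  covb <- s2_df * solve(g$XtViX)
  se <- sqrt(diag(covb))
  tstat <- g$beta / se
  pval <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(list(intercept = unname(g$beta[1]), slope = unname(g$beta[2]),
                 slope_se = unname(se[2]), slope_t = unname(tstat[2]),
                 slope_p = unname(pval[2]), lambda_hat = lam,
                 sigma2_hat = g$sigma2, loglik = g$loglik, n = n,
                 lambda_fixed = !is.null(lambda), method = "ML"),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (lambda model%s): n = %d\n",
              if (x$lambda_fixed) ", lambda fixed" else "", x$n))
  cat(sprintf("  slope = %.4g (SE %.3g, t = %.3g, p = %.3g)\n",
              x$slope, x$slope_se, x$slope_t, x$slope_p))
  cat(sprintf("  intercept = %.4g, lambda_hat = %.4f, sigma2 = %.4g, logLik = %.3f\n",
              x$intercept, x$lambda_hat, x$sigma2_hat, x$loglik))
  invisible(x)
}

#' Serialize PGLS fits to a flat TSV
#'
#' One row per fit: measure, subset, n, slope, p, lambda_hat, sigma2, loglik.
#'
#' @param fits named list of `pgls_fit` objects; names become `subset`
#'   labels, or supply a data.frame of extra columns via `meta`.
#' @param path output TSV path.
#' @param meta optional data.frame (one row per fit) of leading columns,
#'   e.g. measure and subset labels.
#' @export
write_pgls_fits <- function(fits, path, meta = NULL) {
  rows <- do.call(rbind, lapply(fits, function(f)
    data.frame(n = f$n, slope = f$slope, p = f$slope_p,
               lambda_hat = f$lambda_hat, sigma2 = f$sigma2_hat,
               loglik = f$loglik)))
  if (is.null(meta)) meta <- data.frame(subset = names(fits) %||%
                                          as.character(seq_along(fits)))
  write_tsv_fixed(cbind(meta, rows), path)
}

# align a possibly named vector to tip order; unnamed vectors must already
# be in tip order and of matching length
align_to_tips <- function(v, tree) {
  tips <- tree$tip.label
  if (!is.null(names(v))) {
    miss <- setdiff(tips, names(v))
    if (length(miss)) stop_ct("trait values missing for tip(s): %s",
                              paste(head(miss, 5), collapse = ", "))
    v <- v[tips]
  } else if (length(v) != length(tips)) {
    stop_ct("unnamed trait vector length (%d) != number of tips (%d)",
            length(v), length(tips))
  }
  if (any(!is.finite(v))) stop_ct("trait vector contains non-finite values")
  as.numeric(v)
}
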