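#' Penalized-spline smooth of abundance against temperature
#'
#' Fits a cubic regression spline (basis dimension `basis_dim`, knots at
#' quantiles of the observed temperatures) with a second-derivative
#' wiggliness penalty, the smoothing parameter chosen by generalized
#' cross-validation over a log-spaced grid. The non-linearity of the fit is
#' summarised by its effective degrees of freedom (trace of the influence
#' matrix); a straight-line relationship gives edf near 2.
#'
#' When several grid points achieve the minimal GCV score (as happens when
#' the data are fitted exactly), the largest smoothing parameter among them
#' is taken, and the grid is extended upward while the optimum sits on its
#' upper edge, so degenerate inputs resolve to the smoothest model that
#' explains them.
#'
#' @param topt temperature vector (degC; need not be integer).
#' @param abundance response vector.
#' @param basis_dim spline basis dimension (default 10).
#' @param family `"gaussian"` (default, identity link on the untransformed
#'   counts) or `"poisson"` (log link).
#' @param grid_step resolution of the prediction grid in degC (default 0.1).
#' @param sp_grid log10 range and length of the GCV grid; default
#'   `c(-4, 4, 81)`.
#' @return object of class `smooth_fit`: `gam` (the underlying
#'   [mgcv::gam()] fit at the selected smoothing parameter), `knots`,
#'   `coefficients`, `smoothing_parameter`, `edf`, `gcv_score`,
#'   `fitted_grid` (data.frame `temperature`, `fit`), `family`.
#' @export
fit_smooth <- function(topt, abundance, basis_dim = 10,
                       family = c("gaussian", "poisson"),
                       grid_step = 0.1, sp_grid = c(-4, 4, 81)) {
  family <- match.arg(family)
  stopifnot(length(topt) == length(abundance))
  n <- length(topt)
  if (n < basis_dim + 2) {
    stop_ct("need at least basis_dim + 2 = %d observations (have %d); reduce basis_dim",
            basis_dim + 2, n)
  }
  if (length(unique(topt)) < 2) stop_ct("topt is constant: nothing to smooth")
  fam <- if (family == "gaussian") stats::gaussian() else stats::poisson()
  dat <- data.frame(x = as.numeric(topt), y = as.numeric(abundance))
  fit_at <- function(sp) mgcv::gam(y ~ s(x, k = basis_dim, bs = "cr"),
                                   data = dat, family = fam, sp = sp,
                                   method = "GCV.Cp")
  sps <- 10^seq(sp_grid[1], sp_grid[2], length.out = sp_grid[3])
  fits <- lapply(sps, fit_at)
  gcvs <- vapply(fits, function(f) as.numeric(f$gcv.ubre), numeric(1))
  # ties at the minimum resolve to the largest (smoothest) sp; the
  # tolerance is on the scale of the response variance so that exact fits
  # (GCV = 0 up to rounding) are recognized as ties
  tol <- 1e-7 * max(stats::var(dat$y), abs(min(gcvs)), 1e-8)
  best <- max(which(gcvs <= min(gcvs) + tol))
  sp_best <- sps[best]
  f_best <- fits[[best]]
  gcv_best <- gcvs[best]
  # extend upward by decades while the optimum sits on the grid's upper
  # edge (a single-point grid is taken as a fixed smoothing parameter)
  while (length(sps) > 1 && best == length(sps) && log10(sp_best) < 14) {
    sp_try <- sp_best * 10
    f_try <- fit_at(sp_try)
    if (as.numeric(f_try$gcv.ubre) <= gcv_best + tol) {
      sp_best <- sp_try
      f_best <- f_try
      gcv_best <- min(gcv_best, as.numeric(f_try$gcv.ubre))
    } else break
  }
  grid <- seq(min(dat$x), max(dat$x), by = grid_step)
  if (grid[length(grid)] < max(dat$x)) grid <- c(grid, max(dat$x))
  pred <- as.numeric(predict(f_best, newdata = data.frame(x = grid),
                             type = "response"))
  sm <- f_best$smooth[[1]]
  structure(list(gam = f_best,
                 knots = as.numeric(sm$xp),
                 coefficients = coef(f_best),
                 smoothing_parameter = sp_best,
                 edf = sum(f_best$edf),
                 gcv_score = gcv_best,
                 fitted_grid = data.frame(temperature = grid, fit = pred),
                 family = family, basis_dim = basis_dim),
            class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("Penalized-spline smooth (%s, k = %d): edf = %.2f, sp = %.3g, GCV = %.4g\n",
              x$family, x$basis_dim, x$edf, x$smoothing_parameter, x$gcv_score))
  invisible(x)
}

#' First derivative of a fitted smooth and the transition temperature
#'
#' Differentiates the fitted curve by finite differences on the prediction
#' grid (central differences in the interior, one-sided at the ends). The
#' transition temperature is the grid argmax of the derivative, reported as
#' an integer degC with ties broken toward the smaller temperature.
#'
#' @param fit a [fit_smooth()] result.
#' @return object of class `derivative_curve`: data.frame-like list with
#'   `grid` (data.frame `temperature`, `derivative`) and
#'   `argmax_temperature` (integer degC).
#' @export
smooth_derivative <- function(fit) {
  stopifnot(inherits(fit, "smooth_fit"))
  g <- fit$fitted_grid
  x <- g$temperature
  y <- g$fit
  n <- length(x)
  if (n < 3) stop_ct("fitted grid too short to differentiate")
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  # ties within numerical noise of the maximum resolve to the smallest
  # temperature, so a flat derivative reports the grid start deterministically
  dmax <- max(d)
  tol <- 1e-8 * max(abs(dmax), 1e-12)
  j <- which(d >= dmax - tol)[1]
  structure(list(grid = data.frame(temperature = x, derivative = d),
                 argmax_temperature = as.integer(round_half_away(x[j]))),
            class = "derivative_curve")
}

#' @export
print.derivative_curve <- function(x, ...) {
  cat(sprintf("Derivative curve: steepest increase at %d degC (max slope %.4g per degC)\n",
              x$argmax_temperature, max(x$grid$derivative)))
  invisible(x)
}

#' Write smooth-fit outputs to disk
#'
#' Writes the fitted grid and derivative grid as fixed-precision TSVs and a
#' JSON summary (`edf`, `gcv`, `argmax_temperature`).
#'
#' @param fit a [fit_smooth()] result.
#' @param deriv a [smooth_derivative()] result for `fit`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_smooth_outputs <- function(fit, deriv, dir, prefix = "smooth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_fitted.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_derivative.tsv"))
  p3 <- file.path(dir, paste0(prefix, "_summary.json"))
  write_tsv_fixed(fit$fitted_grid, p1)
  write_tsv_fixed(deriv$grid, p2)
  jsonlite::write_json(list(edf = fit$edf, gcv = fit$gcv_score,
                            argmax_temperature = deriv$argmax_temperature),
                       p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
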