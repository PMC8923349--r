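#' Five-degree temperature bin summaries
#'
#' Bins integer temperatures into fixed-width bins aligned at zero
#' (\[0,4\], \[5,9\], ... for the default width 5) and reports per-bin
#' counts, medians and means of an abundance measure. Medians are the
#' headline summary because most genomes lack the systems entirely and the
#' mean is sensitive to high-count outliers. Empty bins are omitted.
#'
#' @param topt integer temperature vector (degC, pre-rounded).
#' @param abundance abundance vector aligned with `topt`.
#' @param width bin width in degC (default 5).
#' @return data.frame: `bin_low`, `bin_high`, `n`, `median_abundance`,
#'   `mean_abundance`, ordered by `bin_low`.
#' @export
bin_summaries <- function(topt, abundance, width = 5) {
  stopifnot(length(topt) == length(abundance))
  if (any(topt != floor(topt))) stop_ct("topt must be integer-rounded (see round_topt)")
  b <- floor(topt / width)
  ub <- sort(unique(b))
  out <- data.frame(
    bin_low = ub * width,
    bin_high = ub * width + (width - 1),
    n = vapply(ub, function(k) sum(b == k), integer(1)),
    median_abundance = vapply(ub, function(k) median(abundance[b == k]), numeric(1)),
    mean_abundance = vapply(ub, function(k) mean(abundance[b == k]), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Above/below mean-abundance ratio along the temperature axis
#'
#' For every integer temperature i strictly above the minimum observed Topt
#' and up to the maximum, computes
#' D_i = mean(abundance of species with Topt >= i) /
#' mean(abundance of species with Topt < i). A flat relationship gives
#' D_i = 1 everywhere; a step up at some temperature inflates D_i near the
#' step. A zero denominator with a positive numerator is flagged as
#' infinite rather than dropped.
#'
#' @param topt integer temperature vector.
#' @param abundance non-negative abundance vector.
#' @param at `"all"` (default) evaluates every integer i in
#'   (min(topt), max(topt)\]; `"observed"` only the observed Topt values in
#'   that interval. The restricted-range maximum is identical whenever the
#'   window contains observed values.
#' @return object of class `d_curve`: data.frame with `i`, `d`, `n_lower`,
#'   `n_upper`, `finite`.
#' @export
d_curve <- function(topt, abundance, at = c("all", "observed")) {
  at <- match.arg(at)
  stopifnot(length(topt) == length(abundance))
  if (any(topt != floor(topt))) stop_ct("topt must be integer-rounded")
  if (any(abundance < 0)) stop_ct("abundance must be non-negative")
  if (length(unique(topt)) < 2) stop_ct("degenerate temperature axis: all Topt equal")
  ord <- order(topt)
  st <- topt[ord]
  sa <- abundance[ord]
  n <- length(st)
  is <- seq.int(min(st) + 1L, max(st))
  if (at == "observed") is <- is[is %in% st]
  nl <- findInterval(is - 0.5, st)      # count of topt < i
  nu <- n - nl
  cs <- cumsum(sa)
  sum_lower <- cs[nl]
  sum_upper <- cs[n] - sum_lower
  mean_lower <- sum_lower / nl
  mean_upper <- sum_upper / nu
  d <- mean_upper / mean_lower
  finite <- is.finite(d)
  structure(data.frame(i = as.integer(is), d = d, n_lower = nl, n_upper = nu,
                       finite = finite),
            class = c("d_curve", "data.frame"))
}

#' Maximum of the D curve over a temperature window
#'
#' The ratio is noisy near both ends of the axis where one of the two means
#' is taken over a handful of species, so the maximum is taken over a
#' restricted window (default 20-64 degC). Infinite ratios are excluded
#' from the maximum and counted; ties are broken toward the smallest
#' temperature.
#'
#' @param curve a [d_curve()] result.
#' @param lo,hi inclusive window bounds in degC (defaults 20 and 64).
#' @return object of class `d_max`: list with `d_max`, `argmax_i`,
#'   `window`, `n_infinite`.
#' @export
d_max <- function(curve, lo = 20, hi = 64) {
  stopifnot(inherits(curve, "d_curve"))
  w <- curve[curve$i >= lo & curve$i <= hi, , drop = FALSE]
  if (!nrow(w)) stop_ct("window [%g, %g] disjoint from the D curve support", lo, hi)
  n_inf <- sum(!w$finite)
  wf <- w[w$finite, , drop = FALSE]
  if (!nrow(wf)) stop_ct("no finite D value in window [%g, %g]", lo, hi)
  j <- which.max(wf$d)  # which.max takes the first maximum: smallest i
  structure(list(d_max = wf$d[j], argmax_i = wf$i[j], window = c(lo, hi),
                 n_infinite = n_inf), class = "d_max")
}

#' @export
print.d_max <- function(x, ...) {
  cat(sprintf("D_max = %.4g at %d degC (window %d-%d degC%s)\n", x$d_max,
              x$argmax_i, x$window[1], x$window[2],
              if (x$n_infinite) sprintf(", %d infinite value(s) excluded", x$n_infinite) else ""))
  invisible(x)
}

#' Permutation test for a step in abundance along the temperature axis
#'
#' The null hypothesis is that species are randomly arranged along the
#' temperature axis, i.e. abundance is exchangeable with respect to Topt.
#' Each replicate permutes the abundance vector against the fixed Topt
#' values (equivalent to shuffling species along the axis), recomputes the
#' restricted-window maximum of the D curve, and the p-value is the
#' fraction of replicates strictly exceeding the observed maximum.
#' `p_variant = "conservative"` uses (k + 1) / (n_perm + 1) instead.
#'
#' @param topt integer temperature vector.
#' @param abundance non-negative, non-constant abundance vector.
#' @param n_perm number of random shuffles (default 1000).
#' @param lo,hi window passed to [d_max()].
#' @param seed integer seed; required for reproducibility.
#' @param p_variant `"strict"` (default) or `"conservative"`.
#' @return object of class `permutation_test`: `observed` (a `d_max`
#'   object), `null_dmax` (length `n_perm`, `NA` where a replicate had no
#'   finite value in the window), `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(topt, abundance, n_perm = 1000, lo = 20, hi = 64,
                             seed = 1L, p_variant = c("strict", "conservative")) {
  p_variant <- match.arg(p_variant)
  if (var(abundance) == 0) stop_ct("constant abundance: permutation test undefined")
  obs_curve <- d_curve(topt, abundance)
  obs <- d_max(obs_curve, lo, hi)

  ord <- order(topt)
  st <- topt[ord]
  sa <- abundance[ord]
  n <- length(st)
  is <- seq.int(min(st) + 1L, max(st))
  keep <- is >= lo & is <= hi
  is <- is[keep]
  if (!length(is)) stop_ct("window [%g, %g] disjoint from the D curve support", lo, hi)
  nl <- findInterval(is - 0.5, st)
  nu <- n - nl
  total <- sum(sa)

  set.seed(as.integer(seed))
  null_dmax <- rep(NA_real_, n_perm)
  if (n_perm > 0) {
    for (r in seq_len(n_perm)) {
      cs <- cumsum(sa[sample.int(n)])
      sl <- cs[nl]
      d <- ((total - sl) / nu) / (sl / nl)
      d <- d[is.finite(d)]
      if (length(d)) null_dmax[r] <- max(d)
    }
  }
  k <- sum(null_dmax > obs$d_max, na.rm = TRUE)
  p <- switch(p_variant,
              strict = k / n_perm,
              conservative = (k + 1) / (n_perm + 1))
  structure(list(observed = obs, null_dmax = null_dmax, p_value = p,
                 n_perm = n_perm, seed = as.integer(seed),
                 p_variant = p_variant),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (%d shuffles, seed %d): observed D_max = %.4g, p = %.4g\n",
              x$n_perm, x$seed, x$observed$d_max, x$p_value))
  invisible(x)
}
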