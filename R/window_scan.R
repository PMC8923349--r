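#' Sliding-window PGLS along the temperature axis
#'
#' Sorts species by (Topt, species_id) — the secondary key makes window
#' membership deterministic when many species share a Topt — and fits a
#' PGLS of the chosen measure against Topt in every window of `window`
#' consecutive species, re-estimating lambda per window on the pruned
#' subtree. Windows whose Topt values are all identical carry no slope
#' information and are skipped.
#'
#' @param table a [trait_table()].
#' @param tree an [ape::phylo] phylogeny covering the table's species.
#' @param measure abundance column to regress (e.g. `"arrays"`).
#' @param window window size W in species (default 200).
#' @param stride step between successive window starts (default 1).
#' @return data.frame of class `window_scan`: one row per fitted window
#'   with `window_index` (start position in the sorted order), `n`,
#'   `mean_topt`, `slope`, `slope_p`, `lambda_hat`, `sigma2`, `loglik`,
#'   `significant_05`, `significant_01`, `positive_slope`. Attributes
#'   `n_skipped` (constant-Topt windows) and `order` (sorted species ids).
#' @export
segmental_pgls <- function(table, tree, measure, window = 200, stride = 1) {
  stopifnot(inherits(table, "trait_table"))
  if (!measure %in% names(table)) stop_ct("measure '%s' not in table", measure)
  m <- match_tree_table(tree, table)
  tab <- m$table
  tr <- m$tree
  n <- nrow(tab)
  if (n < window) stop_ct("n = %d smaller than window = %d", n, window)
  ord <- order(tab$topt_c, tab$species_id)
  tab <- tab[ord, , drop = FALSE]
  starts <- seq.int(1L, n - window + 1L, by = stride)
  rows <- vector("list", length(starts))
  n_skipped <- 0L
  for (k in seq_along(starts)) {
    s <- starts[k]
    block <- tab[s:(s + window - 1L), , drop = FALSE]
    if (length(unique(block$topt_c)) < 2) {
      n_skipped <- n_skipped + 1L
      next
    }
    sub <- ape::keep.tip(tr, block$species_id)
    y <- setNames(block[[measure]], block$species_id)
    x <- setNames(as.numeric(block$topt_c), block$species_id)
    f <- pgls_fit(y, x, sub)
    rows[[k]] <- data.frame(window_index = s, n = window,
                            mean_topt = mean(block$topt_c),
                            slope = f$slope, slope_p = f$slope_p,
                            lambda_hat = f$lambda_hat, sigma2 = f$sigma2_hat,
                            loglik = f$loglik)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(window_index = integer(0), n = integer(0),
                      mean_topt = numeric(0), slope = numeric(0),
                      slope_p = numeric(0), lambda_hat = numeric(0),
                      sigma2 = numeric(0), loglik = numeric(0))
    message("segmental_pgls: all windows skipped (constant Topt)")
  }
  out$significant_05 <- out$slope_p < 0.05
  out$significant_01 <- out$slope_p < 0.01
  out$positive_slope <- out$slope > 0
  rownames(out) <- NULL
  structure(out, class = c("window_scan", "data.frame"),
            n_skipped = n_skipped, order = tab$species_id,
            measure = measure, window = window, stride = stride)
}

#' PGLS within fixed temperature categories
#'
#' Fits a PGLS of each measure against Topt inside each named temperature
#' category (inclusive integer bounds), plus one whole-range fit labelled
#' `"all"`. Categories with fewer than 4 species are skipped with a
#' warning.
#'
#' @param table a [trait_table()].
#' @param tree an [ape::phylo] phylogeny.
#' @param categories data.frame with columns `name`, `topt_low`,
#'   `topt_high` (non-overlapping), e.g. from [tertile_split()].
#' @param measures character vector of abundance columns (default: all
#'   measures present).
#' @return data.frame: `category`, `measure`, `n`, `slope`, `slope_p`,
#'   `lambda_hat`, `loglik`.
#' @export
category_pgls <- function(table, tree, categories, measures = NULL) {
  stopifnot(inherits(table, "trait_table"))
  measures <- measures %||% attr(table, "measures")
  if (!all(measures %in% names(table))) stop_ct("unknown measure column(s)")
  check_categories(categories)
  m <- match_tree_table(tree, table)
  tab <- m$table
  tr <- m$tree
  specs <- rbind(categories[, c("name", "topt_low", "topt_high")],
                 data.frame(name = "all", topt_low = min(tab$topt_c),
                            topt_high = max(tab$topt_c)))
  rows <- list()
  for (ci in seq_len(nrow(specs))) {
    sel <- tab$topt_c >= specs$topt_low[ci] & tab$topt_c <= specs$topt_high[ci]
    if (sum(sel) < 4) {
      warn_ct("category '%s' has %d species (< 4): skipped", specs$name[ci], sum(sel))
      next
    }
    block <- tab[sel, , drop = FALSE]
    if (length(unique(block$topt_c)) < 2) {
      warn_ct("category '%s' has constant Topt: skipped", specs$name[ci])
      next
    }
    sub <- ape::keep.tip(tr, block$species_id)
    for (me in measures) {
      y <- setNames(block[[me]], block$species_id)
      x <- setNames(as.numeric(block$topt_c), block$species_id)
      f <- pgls_fit(y, x, sub)
      rows[[length(rows) + 1L]] <- data.frame(
        category = specs$name[ci], measure = me, n = f$n, slope = f$slope,
        slope_p = f$slope_p, lambda_hat = f$lambda_hat, loglik = f$loglik)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

check_categories <- function(categories) {
  need <- c("name", "topt_low", "topt_high")
  if (!is.data.frame(categories) || !all(need %in% names(categories))) {
    stop_ct("categories must be a data.frame with columns name, topt_low, topt_high")
  }
  if (nrow(categories) > 1) {
    o <- order(categories$topt_low)
    lo <- categories$topt_low[o]
    hi <- categories$topt_high[o]
    if (any(lo[-1] <= hi[-length(hi)])) stop_ct("categories overlap")
  }
  invisible(categories)
}

#' Split a table into three nearly equal-sized temperature groups
#'
#' Chooses two cut points at Topt order statistics so the three groups are
#' as close to n/3 as the ties allow; species sharing a Topt are never
#' split across groups.
#'
#' @param table a [trait_table()] (or a numeric Topt vector).
#' @return data.frame of three rows: `name` (`"low"`, `"mid"`, `"high"`),
#'   `topt_low`, `topt_high` (observed bounds), `n`.
#' @export
tertile_split <- function(table) {
  topt <- if (inherits(table, "trait_table")) table$topt_c else as.numeric(table)
  n <- length(topt)
  if (n < 6) stop_ct("need at least 6 species for a tertile split")
  vals <- sort(unique(topt))
  if (length(vals) < 3) stop_ct("fewer than 3 distinct Topt values")
  cnt <- vapply(vals, function(v) sum(topt == v), integer(1))
  cum <- cumsum(cnt)
  # first boundary: cumulative count closest to n/3 (not exhausting the rest)
  c1 <- which.min(abs(cum - n / 3))
  c1 <- min(c1, length(vals) - 2L)
  # second: closest to 2n/3 among boundaries after c1
  cand <- (c1 + 1L):(length(vals) - 1L)
  c2 <- cand[which.min(abs(cum[cand] - 2 * n / 3))]
  groups <- list(vals[1:c1], vals[(c1 + 1):c2], vals[(c2 + 1):length(vals)])
  out <- data.frame(
    name = c("low", "mid", "high"),
    topt_low = vapply(groups, min, numeric(1)),
    topt_high = vapply(groups, max, numeric(1)),
    n = vapply(groups, function(g) sum(topt %in% g), integer(1)))
  rownames(out) <- NULL
  out
}

#' Paired comparison of two domains at shared temperatures
#'
#' For every integer Topt that occurs in both tables, averages the measure
#' within each domain, then applies the Wilcoxon signed-rank test to the
#' paired averages. Zero differences are dropped; with 25 or fewer
#' informative pairs and untied ranks the exact null is used, otherwise the
#' tie-corrected normal approximation. If every difference is zero the
#' p-value is 1 by convention.
#'
#' @param bacteria,archaea two [trait_table()]s (any two groups work; the
#'   names reflect the motivating comparison).
#' @param measure abundance column present in both tables.
#' @return list: `n_pairs` (shared temperatures), `n_informative`
#'   (non-zero differences), `statistic` (signed-rank V for
#'   bacteria - archaea), `p_value`, `pairs` (data.frame of the paired
#'   averages).
#' @export
paired_domain_comparison <- function(bacteria, archaea, measure) {
  for (tb in list(bacteria, archaea)) {
    stopifnot(inherits(tb, "trait_table"))
    if (!measure %in% names(tb)) stop_ct("measure '%s' not in both tables", measure)
  }
  tb_mean <- function(tb) {
    tapply(tb[[measure]], as.integer(tb$topt_c), mean)
  }
  mb <- tb_mean(bacteria)
  ma <- tb_mean(archaea)
  shared <- intersect(names(mb), names(ma))
  if (!length(shared)) stop_ct("no shared integer Topt between the two tables")
  shared <- shared[order(as.integer(shared))]
  xb <- as.numeric(mb[shared])
  xa <- as.numeric(ma[shared])
  dif <- xb - xa
  informative <- sum(dif != 0)
  if (informative == 0) {
    w <- list(statistic = c(V = 0), p.value = 1)
  } else {
    use_exact <- informative <= 25 && !any(duplicated(abs(dif[dif != 0])))
    w <- suppressWarnings(wilcox.test(xb, xa, paired = TRUE,
                                      exact = use_exact, correct = TRUE))
  }
  list(n_pairs = length(shared), n_informative = informative,
       statistic = unname(w$statistic), p_value = w$p.value,
       pairs = data.frame(topt_c = as.integer(shared), mean_bacteria = xb,
                          mean_archaea = xa))
}
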