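#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic tree/trait
#' generator. The defaults emulate the headline structure of the real
#' bacterial data: ~1500 species spanning 4-85 degC, strong phylogenetic
#' signal in growth temperature, zero-heavy overdispersed counts whose mean
#' steps from about 0.5 to about 4 across a transition near 45 degC.
#'
#' @param n_tips number of species (default 1500).
#' @param birth_rate pure-birth speciation rate (default 1; only the shape
#'   of the tree matters, depths are rescaled).
#' @param lambda_topt phylogenetic signal of the temperature trait in
#'   \[0, 1\] (default 0.95).
#' @param topt_range temperature range in degC (default `c(4, 85)`).
#' @param transition_t_star transition temperature in degC (default 45).
#' @param step_delta increase of the marginal mean abundance across the
#'   step (default 3.5).
#' @param step_scale sigmoid softness s in degC (default 1); the mean is
#'   `baseline_mu + step_delta * plogis((T - t_star) / s)`.
#' @param baseline_mu marginal mean abundance well below the step (0.5).
#' @param dispersion negative-binomial size parameter (default 1, which
#'   keeps the count tail in the tens as in real per-genome annotation
#'   data; `Inf` gives Poisson counts).
#' @param zero_inflation probability that a count is forced to zero
#'   (default 0.55, matching the sparsity of the systems across genomes).
#' @param lambda_abund phylogenetic signal of the abundance noise in
#'   \[0, 1\] (default 0.8).
#' @param phylo_sd standard deviation of the latent phylogenetic effect on
#'   the log-mean scale (default 0.5); 0 switches the effect off.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 1500, birth_rate = 1, lambda_topt = 0.95,
                       topt_range = c(4, 85), transition_t_star = 45,
                       step_delta = 3.5, step_scale = 1, baseline_mu = 0.5,
                       dispersion = 1, zero_inflation = 0.55,
                       lambda_abund = 0.8, phylo_sd = 0.5) {
  stopifnot(n_tips >= 2, birth_rate > 0,
            lambda_topt >= 0, lambda_topt <= 1,
            length(topt_range) == 2, topt_range[1] < topt_range[2],
            step_delta >= 0, step_scale > 0, baseline_mu > 0,
            dispersion > 0, zero_inflation >= 0, zero_inflation < 1,
            lambda_abund >= 0, lambda_abund <= 1, phylo_sd >= 0)
  structure(list(n_tips = n_tips, birth_rate = birth_rate,
                 lambda_topt = lambda_topt, topt_range = topt_range,
                 transition_t_star = transition_t_star,
                 step_delta = step_delta, step_scale = step_scale,
                 baseline_mu = baseline_mu, dispersion = dispersion,
                 zero_inflation = zero_inflation, lambda_abund = lambda_abund,
                 phylo_sd = phylo_sd), class = "sim_config")
}

#' Simulate a pure-birth phylogeny
#'
#' Grows a binary pure-birth tree to `n_tips` tips and rescales all branch
#' lengths so the median root-to-tip depth is 1, which puts the covariance
#' (and hence the trait variances) on a common scale across replicates.
#'
#' @param n_tips number of tips.
#' @param birth_rate speciation rate.
#' @param seed integer seed.
#' @return an [ape::phylo] tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  stopifnot(n_tips >= 2)
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  depths <- ape::node.depth.edgelength(tr)[seq_len(n_tips)]
  tr$edge.length <- tr$edge.length / median(depths)
  tr
}

# draw one MVN vector with covariance sd^2 * Vcorr(lambda) on the tree,
# where Vcorr is the Brownian covariance rescaled to unit diagonal
rtrait_lambda_raw <- function(tree, lambda, sd = 1) {
  n <- length(tree$tip.label)
  if (lambda == 0) return(rnorm(n) * sd)  # independence: no covariance needed
  C <- ape::vcv.phylo(tree)
  s <- sqrt(diag(C))
  Ccor <- C / tcrossprod(s)
  V <- Ccor * lambda
  diag(V) <- 1
  R <- chol(V + diag(1e-10, nrow(V)))
  drop(crossprod(R, rnorm(nrow(V)))) * sd
}

#' Simulate a trait under the lambda model
#'
#' Draws a Gaussian trait with covariance `sd^2 * V(lambda)` on the tree
#' (Brownian covariance rescaled to unit diagonal before the lambda
#' transform, so the marginal variance is `sd^2` at every tip).
#'
#' @param tree an [ape::phylo] phylogeny.
#' @param lambda signal strength in \[0, 1\].
#' @param mean,sd marginal mean and standard deviation.
#' @param seed integer seed.
#' @return named numeric vector in tip order.
#' @export
rtrait_lambda <- function(tree, lambda, mean = 0, sd = 1, seed = 1L) {
  validate_phylogeny(tree)
  set.seed(as.integer(seed))
  z <- mean + rtrait_lambda_raw(tree, lambda, sd)
  setNames(z, tree$tip.label)
}

#' Simulate phylogenetically autocorrelated growth temperatures
#'
#' Draws a latent Gaussian with covariance `V(lambda_topt)` on the tree,
#' maps each tip through its own normal CDF to \[0, 1\] (so the marginal is
#' exactly uniform and the target range is respected exactly, unlike
#' truncating a Brownian walk), affine-maps into `range` and rounds to
#' integer degC.
#'
#' @param tree an [ape::phylo] phylogeny.
#' @param lambda_topt signal strength in \[0, 1\].
#' @param range temperature range `c(lo, hi)` in degC.
#' @param seed integer seed.
#' @return named integer vector of temperatures in tip order.
#' @export
simulate_topt <- function(tree, lambda_topt = 0.95, range = c(4, 85), seed = 1L) {
  validate_phylogeny(tree)
  set.seed(as.integer(seed))
  z <- rtrait_lambda_raw(tree, lambda_topt, sd = 1)
  u <- pnorm(z)
  topt <- round_half_away(range[1] + u * (range[2] - range[1]))
  setNames(as.integer(topt), tree$tip.label)
}

#' Simulate zero-inflated overdispersed abundance counts with a step
#'
#' The marginal mean abundance follows the sigmoid
#' `mu(T) = baseline_mu + step_delta * plogis((T - t_star) / s)`.
#' A latent phylogenetic effect (Gaussian on the tree with signal
#' `lambda_abund`, standard deviation `phylo_sd`, centred so its
#' exponential has mean one) multiplies the mean on the log scale. Counts
#' are negative binomial with size `dispersion`, then forced to zero with
#' probability `zero_inflation`; the negative-binomial mean is inflated by
#' `1 / (1 - zero_inflation)` so the *marginal* mean after zeroing equals
#' `mu(T)` — bin means below the step approach `baseline_mu` and above it
#' `baseline_mu + step_delta`.
#'
#' @param tree an [ape::phylo] phylogeny.
#' @param topt temperature vector aligned to tips (named or in tip order).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return named integer count vector in tip order.
#' @export
simulate_abundance <- function(tree, topt, config, seed = 1L) {
  validate_phylogeny(tree)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(names(topt))) topt <- topt[tree$tip.label]
  stopifnot(length(topt) == length(tree$tip.label))
  set.seed(as.integer(seed))
  n <- length(topt)
  mu_t <- config$baseline_mu + config$step_delta *
    stats::plogis((as.numeric(topt) - config$transition_t_star) / config$step_scale)
  if (config$phylo_sd > 0) {
    g <- rtrait_lambda_raw(tree, config$lambda_abund, sd = config$phylo_sd)
    eff <- exp(g - config$phylo_sd^2 / 2)
  } else {
    eff <- rep(1, n)
  }
  mu_nb <- mu_t * eff / (1 - config$zero_inflation)
  counts <- if (is.finite(config$dispersion)) {
    rnbinom(n, size = config$dispersion, mu = mu_nb)
  } else {
    rpois(n, lambda = mu_nb)
  }
  counts[runif(n) < config$zero_inflation] <- 0L
  setNames(as.integer(counts), tree$tip.label)
}

#' Simulate a complete dataset (tree + trait table)
#'
#' Composes [simulate_tree()], [simulate_topt()] and [simulate_abundance()]
#' with seeds derived deterministically from `seed`, one abundance column
#' per requested measure.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @param measures names of the abundance columns to generate
#'   (default `"arrays"`).
#' @return list of class `sim_dataset`: `tree`, `table` (a
#'   [trait_table()] in tip order, domain `"Bacteria"`), `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L,
                             measures = "arrays") {
  stopifnot(inherits(config, "sim_config"),
            all(measures %in% MEASURE_COLS))
  tree <- simulate_tree(config$n_tips, config$birth_rate,
                        seed = child_seed(seed, 1))
  topt <- simulate_topt(tree, config$lambda_topt, config$topt_range,
                        seed = child_seed(seed, 2))
  df <- data.frame(species_id = tree$tip.label,
                   topt_c = as.numeric(topt),
                   domain = "Bacteria", stringsAsFactors = FALSE)
  for (k in seq_along(measures)) {
    df[[measures[k]]] <- as.integer(
      simulate_abundance(tree, topt, config, seed = child_seed(seed, 2 + k)))
  }
  structure(list(tree = tree,
                 table = trait_table(df, topt_range = c(0, 110)),
                 config = config, seed = as.integer(seed)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d tips, seed %d, t* = %g degC, step %g -> %g\n",
              length(x$tree$tip.label), x$seed, x$config$transition_t_star,
              x$config$baseline_mu, x$config$baseline_mu + x$config$step_delta))
  invisible(x)
}

#' Write a simulated dataset in the formats the readers consume
#'
#' Emits `traits.tsv` (consumed by [read_trait_table()]), `tree.nwk`
#' (consumed by [read_phylogeny()]) and `config.yaml`.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "traits.tsv")
  p2 <- file.path(dir, "tree.nwk")
  p3 <- file.path(dir, "config.yaml")
  write_trait_table(dataset$table, p1)
  ape::write.tree(dataset$tree, p2)
  yaml::write_yaml(c(unclass(dataset$config), seed = dataset$seed), p3)
  invisible(c(p1, p2, p3))
}
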