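#' Read a pipeline run configuration from YAML
#'
#' Fills unspecified fields with the analysis defaults: all measures
#' present, bin width 5, D-window 20-64 degC, 1000 permutations, window
#' size 200, smooth basis dimension 10, strict permutation p-value,
#' Gaussian smooth family. A seed is mandatory because the permutation
#' stage is stochastic.
#'
#' @param path YAML file with at least `trait_table`, `tree` and `out_dir`
#'   paths plus a `seed`.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  need <- c("trait_table", "tree", "out_dir", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop_ct("run config missing field(s): %s", paste(miss, collapse = ", "))
  defaults <- list(measures = NULL, bin_width = 5, d_window = c(20, 64),
                   n_perm = 1000, window = 200, stride = 1,
                   categories = NULL, basis_dim = 10,
                   p_variant = "strict", smooth_family = "gaussian",
                   column_map = NULL, annotations = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the full temperature-transition analysis
#'
#' Executes, for each abundance measure: bin summaries, the D statistic
#' with its permutation test (skipped, not failed, when `n_perm = 0`),
#' phylogenetic-signal estimation, whole-range and category PGLS, the
#' segmental sliding-window PGLS scan, and the penalized-spline smooth
#' with its derivative. Each stage writes a fixed-precision TSV (or JSON)
#' into `out_dir` and reports into a machine-readable manifest; a failing
#' stage is recorded as `"failed"` with its message and independent stages
#' continue.
#'
#' @param config a `run_config` (from [read_run_config()]) or a list with
#'   the same fields; `trait_table`/`tree` may also be passed as in-memory
#'   objects.
#' @return the manifest (list), invisibly written to
#'   `out_dir/manifest.json` as well.
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  t_all <- Sys.time()

  note <- function(stage, status, detail = NULL, n = NA) {
    manifest$stages[[stage]] <<- list(status = status, n = n,
                                      detail = detail)
    message(sprintf("[%s] %s%s", stage, status,
                    if (!is.null(detail)) paste0(": ", detail) else ""))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      note(stage, "failed", conditionMessage(e))
      NULL
    })
  }

  # -- load inputs
  table <- run_stage("load_table", {
    tab <- if (inherits(config$trait_table, "trait_table")) config$trait_table
           else read_trait_table(config$trait_table, column_map = config$column_map)
    tab <- round_topt(tab)
    note("load_table", "ok", n = nrow(tab))
    tab
  })
  tree <- run_stage("load_tree", {
    tr <- if (inherits(config$tree, "phylo")) config$tree
          else read_phylogeny(config$tree)
    note("load_tree", "ok", n = length(tr$tip.label))
    tr
  })
  if (is.null(table) || is.null(tree)) {
    manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(manifest))
  }
  mt <- match_tree_table(tree, table)
  manifest$dropped <- list(tree_only = length(mt$dropped_tree),
                           table_only = length(mt$dropped_table))
  table <- mt$table
  tree <- mt$tree
  measures <- config$measures %||% attr(table, "measures")

  for (me in measures) {
    ab <- table[[me]]
    pre <- paste0(me, "_")

    run_stage(paste0(pre, "bins"), {
      bins <- bin_summaries(table$topt_c, ab, width = config$bin_width)
      write_tsv_fixed(bins, file.path(config$out_dir, paste0(pre, "bins.tsv")))
      note(paste0(pre, "bins"), "ok", n = nrow(bins))
    })

    run_stage(paste0(pre, "dtest"), {
      dc <- d_curve(table$topt_c, ab)
      write_tsv_fixed(as.data.frame(dc),
                      file.path(config$out_dir, paste0(pre, "dcurve.tsv")))
      if (config$n_perm > 0) {
        pt <- permutation_test(table$topt_c, ab, n_perm = config$n_perm,
                               lo = config$d_window[1], hi = config$d_window[2],
                               seed = child_seed(config$seed, match(me, measures)),
                               p_variant = config$p_variant)
        write_tsv_fixed(data.frame(null_dmax = pt$null_dmax),
                        file.path(config$out_dir, paste0(pre, "null_dmax.tsv")))
        jsonlite::write_json(
          list(d_max = pt$observed$d_max, argmax = pt$observed$argmax_i,
               p = pt$p_value, n_perm = pt$n_perm, seed = pt$seed,
               window = pt$observed$window),
          file.path(config$out_dir, paste0(pre, "dtest.json")),
          auto_unbox = TRUE, digits = NA)
        note(paste0(pre, "dtest"), "ok", n = pt$n_perm)
      } else {
        dm <- d_max(dc, config$d_window[1], config$d_window[2])
        jsonlite::write_json(
          list(d_max = dm$d_max, argmax = dm$argmax_i, p = NULL,
               n_perm = 0, window = dm$window),
          file.path(config$out_dir, paste0(pre, "dtest.json")),
          auto_unbox = TRUE, digits = NA, null = "null")
        note(paste0(pre, "dtest"), "skipped", "n_perm = 0")
      }
    })

    run_stage(paste0(pre, "signal"), {
      sig <- estimate_lambda_signal(setNames(ab, table$species_id), tree)
      write_tsv_fixed(data.frame(measure = me, lambda_hat = sig$lambda_hat,
                                 loglik = sig$loglik_at_hat,
                                 loglik_lambda0 = sig$loglik_at_zero,
                                 p = sig$p_value, n = sig$n),
                      file.path(config$out_dir, paste0(pre, "signal.tsv")))
      note(paste0(pre, "signal"), "ok", n = sig$n)
    })

    run_stage(paste0(pre, "pgls"), {
      cats <- config$categories
      if (is.null(cats)) cats <- tertile_split(table)[, c("name", "topt_low", "topt_high")]
      res <- category_pgls(table, tree, cats, measures = me)
      write_tsv_fixed(res, file.path(config$out_dir, paste0(pre, "pgls.tsv")))
      note(paste0(pre, "pgls"), "ok", n = nrow(res))
    })

    run_stage(paste0(pre, "scan"), {
      if (nrow(table) < config$window) {
        note(paste0(pre, "scan"), "skipped",
             sprintf("n = %d < window = %d", nrow(table), config$window))
      } else {
        sc <- segmental_pgls(table, tree, me, window = config$window,
                             stride = config$stride)
        write_tsv_fixed(as.data.frame(sc),
                        file.path(config$out_dir, paste0(pre, "scan.tsv")))
        note(paste0(pre, "scan"), "ok", n = nrow(sc))
      }
    })

    run_stage(paste0(pre, "smooth"), {
      fit <- fit_smooth(table$topt_c, ab, basis_dim = config$basis_dim,
                        family = config$smooth_family)
      der <- smooth_derivative(fit)
      write_smooth_outputs(fit, der, config$out_dir, prefix = paste0(me, "_smooth"))
      note(paste0(pre, "smooth"), "ok", n = nrow(fit$fitted_grid))
    })
  }

  manifest$n_species <- nrow(table)
  manifest$measures <- measures
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
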