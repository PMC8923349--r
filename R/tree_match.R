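#' Read a phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' covariance construction needs: unique tip labels, at least two tips, and
#' finite non-negative branch lengths. Polytomies are accepted as given.
#'
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
read_phylogeny <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop_ct("could not parse Newick file: %s", path)
  validate_phylogeny(tr)
  tr
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop_ct("tree must be an ape 'phylo' object")
  if (length(tree$tip.label) < 2) stop_ct("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) stop_ct("tree tip labels must be unique")
  if (is.null(tree$edge.length)) stop_ct("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length))) stop_ct("all branch lengths must be finite")
  if (any(tree$edge.length < 0)) stop_ct("negative branch length in tree")
  invisible(tree)
}

#' Match a phylogeny against a trait table
#'
#' Prunes the tree to the species shared with the table (suppressing the
#' degree-2 nodes that pruning creates, with adjacent branch lengths summed,
#' so surviving root-to-tip path lengths are preserved) and restricts and
#' reorders the table rows to the pruned tip order.
#'
#' @param tree an [ape::phylo] phylogeny.
#' @param table a [trait_table()].
#' @return list with elements `tree`, `table` (row order = tip order),
#'   `dropped_tree` and `dropped_table` (names present on one side only).
#' @export
match_tree_table <- function(tree, table) {
  validate_phylogeny(tree)
  stopifnot(inherits(table, "trait_table"))
  shared <- intersect(tree$tip.label, table$species_id)
  if (length(shared) < 2) stop_ct("fewer than 2 species shared between tree and table")
  dropped_tree <- setdiff(tree$tip.label, shared)
  dropped_table <- setdiff(table$species_id, shared)
  pruned <- if (length(dropped_tree)) ape::keep.tip(tree, shared) else tree
  idx <- match(pruned$tip.label, table$species_id)
  tab <- restore_trait_table(table[idx, , drop = FALSE], table)
  rownames(tab) <- NULL
  list(tree = pruned, table = tab,
       dropped_tree = dropped_tree, dropped_table = dropped_table)
}

#' Select isolation-source strata suitable for a transition analysis
#'
#' A source category is informative about a mid-range abundance transition
#' only if it is well sampled and its temperature span brackets the range of
#' interest. A source is kept iff it has more than `min_species` species,
#' its maximum Topt is at least `min_upper_c`, and its minimum Topt is at
#' most `max_lower_c`.
#'
#' @param table a [trait_table()] with an `isolation_sources` column
#'   (semicolon-separated labels per species).
#' @param min_species retain sources with more than this many species (150).
#' @param min_upper_c required upper temperature reach in degC (60).
#' @param max_lower_c required lower temperature reach in degC (30).
#' @return named list of [trait_table()] subsets, one per retained source.
#' @export
select_isolation_sources <- function(table, min_species = 150,
                                     min_upper_c = 60, max_lower_c = 30) {
  stopifnot(inherits(table, "trait_table"))
  if (!"isolation_sources" %in% names(table)) {
    stop_ct("table has no isolation_sources column")
  }
  labs <- strsplit(as.character(table$isolation_sources), ";", fixed = TRUE)
  labs <- lapply(labs, function(v) unique(trimws(v[nzchar(trimws(v))])))
  if (!any(lengths(labs) > 0)) stop_ct("isolation_sources populated for no species")
  all_src <- sort(unique(unlist(labs)))
  out <- list()
  for (s in all_src) {
    in_s <- vapply(labs, function(v) s %in% v, logical(1))
    sub <- table[in_s, , drop = FALSE]
    if (sum(in_s) > min_species &&
        max(sub$topt_c) >= min_upper_c &&
        min(sub$topt_c) <= max_lower_c) {
      out[[s]] <- restore_trait_table(sub, table)
    }
  }
  out
}
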