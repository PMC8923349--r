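# Shared fixtures and independent oracles for the suite.

# small trait table used across io/scan tests
tiny_table <- function() {
  trait_table(data.frame(
    species_id = c("A", "B", "C", "D"),
    topt_c = c(10, 20, 50, 60),
    arrays = c(1L, 1L, 3L, 5L),
    domain = "Bacteria",
    stringsAsFactors = FALSE))
}

# write a trait table TSV and return the path
write_tmp_tsv <- function(df, ...) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

# brute-force covariance oracle: shared root-to-MRCA path length per pair,
# computed by walking edge paths, independent of ape::vcv
brute_force_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  path_nodes <- function(tip) {
    v <- tip
    cur <- tip
    while (cur != root) {
      cur <- parent_of[cur]
      v <- c(cur, v)
    }
    v
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in 1:n) for (j in 1:n) {
    shared <- intersect(path_nodes(i), path_nodes(j))
    shared <- setdiff(shared, root)
    C[i, j] <- sum(len_of[shared])
  }
  C
}

# independent GLS oracle at fixed lambda: explicit solve, no Cholesky tricks
gls_oracle <- function(y, X, C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  n <- length(y)
  s2 <- drop(t(r) %*% Vi %*% r) / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) +
                  determinant(V, logarithm = TRUE)$modulus + n)
  list(beta = drop(beta), sigma2 = s2, loglik = as.numeric(ll))
}

# exhaustive signed-rank oracle: exact two-sided p over all sign assignments
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  vs <- apply(expand.grid(rep(list(c(0, 1)), m)), 1,
              function(s) sum(rk[s == 1]))
  ev <- m * (m + 1) / 4
  mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12)
}

root_to_tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}
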