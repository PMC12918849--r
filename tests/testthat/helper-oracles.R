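# Shared fixtures and independent brute-force oracles used across the
# suite. Oracles deliberately take different routes than the package code
# (ape::prop.part tip sets, direct matrix algebra, exhaustive tallies).

random_rooted_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)  # rooted, random branch lengths
  tr
}

# rooted clade tip-sets of a tree via ape::prop.part (independent of
# rooted_clades' own traversal)
oracle_clade_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  lapply(pp, function(ix) sort(labs[ix], method = "radix"))
}

# is `taxa` a rooted clade of `tree`?
oracle_is_clade <- function(tree, taxa) {
  key <- paste(sort(taxa, method = "radix"), collapse = "|")
  any(vapply(oracle_clade_sets(tree), function(s)
    paste(s, collapse = "|") == key, logical(1)))
}

# unrooted bipartitions of a tree as canonical keys (smaller side)
oracle_biparts <- function(tree) {
  all_tips <- sort(tree$tip.label, method = "radix")
  n <- length(all_tips)
  keys <- vapply(oracle_clade_sets(tree), function(s) {
    comp <- setdiff(all_tips, s)
    if (length(s) <= 1 || length(comp) <= 1) return(NA_character_)
    a <- paste(s, collapse = "|"); b <- paste(comp, collapse = "|")
    if (a < b) a else b
  }, character(1))
  unique(keys[!is.na(keys)])
}

# GLS pPCA by direct dense matrix algebra
oracle_ppca <- function(X, C) {
  n <- nrow(X)
  Ci <- solve(C)
  one <- rep(1, n)
  a <- drop(t(one) %*% Ci %*% X) / drop(t(one) %*% Ci %*% one)
  Xc <- sweep(X, 2, a)
  R <- t(Xc) %*% Ci %*% Xc / (n - 1)
  list(a = a, R = R, lambda = eigen((R + t(R)) / 2, symmetric = TRUE)$values)
}

two_area_fixture <- function() {
  sp <- dec_state_space(c("X", "Y"))
  tr <- parse_newick("(A:1,B:1);")
  rg <- matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("A", "B"), c("X", "Y")))
  list(space = sp, tree = tr, ranges = rg)
}

# dense independent DEC likelihood for the 2-tip case: enumerate root
# states and cladogenetic outcomes, transition by Matrix::expm directly
oracle_2tip_loglik <- function(tree, ranges, params, space) {
  Q <- build_dec_q(params, space)
  t1 <- tree$edge.length[1]
  P <- as.matrix(Matrix::expm(Q * t1))
  idx <- function(lbl) {
    m <- sum(2^(which(ranges[lbl, ] == 1) - 1))
    space$index_of_mask[m + 1]
  }
  ia <- idx(tree$tip.label[tree$edge[1, 2]])
  ib <- idx(tree$tip.label[tree$edge[2, 2]])
  nonnull <- which(space$masks != 0)
  lik <- 0
  for (rs in nonnull) {
    ev <- cladogenesis_events(rs, space, params$j)
    lik <- lik + sum(ev$prob * P[ev$left, ia] * P[ev$right, ib]) /
      length(nonnull)
  }
  log(lik)
}

fixture <- fixture_deuterocohnia(seed = 1)
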