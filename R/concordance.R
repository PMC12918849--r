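# Scoring a reference tree's clades against gene-tree sets, gene
# concordance factors, the ILS-attribution rule, and the genus-embedding
# scan.

#' Frequency of reference clades in a tree set
#'
#' For each internal non-root clade S of the rooted reference tree, the
#' frequency is the number of gene trees in which S forms a clade (after
#' pruning each gene tree to its own taxa) divided by the number of gene
#' trees containing all of S plus at least one taxon outside S. Gene trees
#' may miss taxa. In `"bipartition"` mode a gene tree supports S if either
#' S or its complement is a clade, appropriate for arbitrarily rooted gene
#' trees.
#'
#' @param reference Rooted `phylo`.
#' @param trees `multiPhylo` or list of `phylo`.
#' @param mode `"rooted"` (default) or `"bipartition"`.
#' @return Data frame with one row per reference clade: `clade`
#'   (comma-joined taxa), `frequency`, `n_support`, `n_decisive`.
#' @export
clade_support <- function(reference, trees, mode = c("rooted", "bipartition")) {
  mode <- match.arg(mode)
  if (length(trees) == 0L) stop("empty tree set")
  clades <- rooted_clades(reference)
  tree_tips <- lapply(trees, function(tr) tr$tip.label)
  nsup <- integer(length(clades))
  ndec <- integer(length(clades))
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    tips <- tree_tips[[k]]
    for (i in seq_along(clades)) {
      S <- clades[[i]]
      if (!all(S %in% tips) || length(setdiff(tips, S)) == 0L) next
      ndec[i] <- ndec[i] + 1L
      ok <- is_monophyletic(tr, S)
      if (!ok && mode == "bipartition") {
        comp <- setdiff(tips, S)
        ok <- is_monophyletic(tr, comp)
      }
      if (ok) nsup[i] <- nsup[i] + 1L
    }
  }
  data.frame(clade = vapply(clades, paste, character(1), collapse = ","),
             frequency = ifelse(ndec > 0, nsup / ndec, NA_real_),
             n_support = nsup, n_decisive = ndec,
             stringsAsFactors = FALSE)
}

#' Attribute cytonuclear discordance to ILS or beyond
#'
#' Clades whose frequency among coalescent-simulated gene trees exceeds
#' the threshold (strictly, matching the ">0.9" convention) are labeled
#' ILS-consistent: incomplete lineage sorting alone plausibly explains
#' observing them in a conflicting organellar tree. Lower frequencies are
#' labeled conflict-beyond-ILS, pointing to processes such as
#' hybridization or plastome capture.
#'
#' @param report Data frame from [clade_support()].
#' @param threshold Support threshold in (0, 1); default 0.9.
#' @return The report with an added `label` column.
#' @export
attribute_discordance <- function(report, threshold = 0.9) {
  stopifnot(is.data.frame(report), "frequency" %in% names(report),
            threshold > 0, threshold < 1)
  report$label <- ifelse(is.na(report$frequency), NA_character_,
                         ifelse(report$frequency > threshold,
                                "ILS-consistent", "conflict-beyond-ILS"))
  report
}

# unrooted bipartitions of a tree as a list of tip-subset keys; each
# bipartition stored as the lexicographically smaller side's sorted key
bipartition_keys <- function(tree) {
  n <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label, method = "radix")
  sets <- clade_tip_sets(tree)
  keys <- character(0)
  for (s in sets) {
    if (length(s) <= 1L || length(s) >= n - 1L) next
    a <- sort(s, method = "radix")
    b <- setdiff(all_tips, a)
    key <- if (paste(a, collapse = "|") < paste(b, collapse = "|"))
      paste(a, collapse = "|") else paste(b, collapse = "|")
    keys <- c(keys, key)
  }
  unique(keys)
}

#' Gene concordance factors
#'
#' For each internal branch b of the reference tree, gCF(b) is 100 times
#' the number of gene trees containing bipartition b (after restriction to
#' the taxa they share with b) divided by the number of decisive gene
#' trees: those retaining at least one taxon in each of the four subtrees
#' b induces. Branches with no decisive gene tree get NA.
#'
#' @param reference `phylo`; internal branches are scored as unrooted
#'   bipartitions.
#' @param gene_trees `multiPhylo` or list of `phylo`, possibly with
#'   missing taxa.
#' @return Data frame: `bipartition` (smaller side, |-joined), `gcf`
#'   (percent), `n_concordant`, `n_decisive`.
#' @export
gene_concordance_factor <- function(reference, gene_trees) {
  n <- length(reference$tip.label)
  all_ref <- sort(reference$tip.label, method = "radix")
  sets <- clade_tip_sets(reference)
  # four blocks per internal branch: the two child clades of the tipward
  # node, and the complement split by the branch's rootward side
  kids <- split(reference$edge[, 2L], reference$edge[, 1L])
  root <- n + 1L
  branches <- list()
  for (nd in seq.int(n + 1L, n + reference$Nnode)) {
    if (nd == root) next
    S <- sets[[nd - n]]
    if (length(S) <= 1L || length(S) >= n - 1L) next
    ch <- kids[[as.character(nd)]]
    side1 <- lapply(ch, function(c2)
      if (c2 <= n) reference$tip.label[c2] else sets[[c2 - n]])
    par <- reference$edge[match(nd, reference$edge[, 2L]), 1L]
    sibs <- setdiff(kids[[as.character(par)]], nd)
    sib_tips <- unique(unlist(lapply(sibs, function(c2)
      if (c2 <= n) reference$tip.label[c2] else sets[[c2 - n]])))
    rest <- setdiff(reference$tip.label, c(S, sib_tips))
    side2 <- list(sib_tips, rest)
    side2 <- side2[vapply(side2, length, integer(1)) > 0]
    if (length(side2) < 2L) {
      # branch adjacent to the root of a binary tree: in the unrooted
      # tree its far side splits into the other root-child's child clades
      other <- setdiff(kids[[as.character(root)]], nd)
      side2 <- list()
      for (o in other) {
        if (o <= n) side2 <- c(side2, list(reference$tip.label[o]))
        else {
          och <- kids[[as.character(o)]]
          side2 <- c(side2, lapply(och, function(c2)
            if (c2 <= n) reference$tip.label[c2] else sets[[c2 - n]]))
        }
      }
      if (length(side2) < 2L) side2 <- list(unlist(side2), character(0))
    }
    branches[[length(branches) + 1L]] <-
      list(S = sort(S, method = "radix"), blocks = c(side1, side2))
  }
  # dedupe branches mapping to the same bipartition (the two root edges)
  bip_key <- vapply(branches, function(b) {
    a <- b$S; cmp <- setdiff(all_ref, a)
    if (paste(a, collapse = "|") < paste(cmp, collapse = "|"))
      paste(a, collapse = "|") else paste(cmp, collapse = "|")
  }, character(1))
  keepb <- !duplicated(bip_key)
  branches <- branches[keepb]
  bip_key <- bip_key[keepb]

  gt_bips <- lapply(gene_trees, bipartition_keys)
  gt_tips <- lapply(gene_trees, function(tr) tr$tip.label)
  ncon <- integer(length(branches))
  ndec <- integer(length(branches))
  for (k in seq_along(gene_trees)) {
    tips <- gt_tips[[k]]
    bips <- gt_bips[[k]]
    tsort <- sort(tips, method = "radix")
    for (i in seq_along(branches)) {
      blocks <- branches[[i]]$blocks
      if (!all(vapply(blocks, function(bl) any(bl %in% tips), logical(1))))
        next
      ndec[i] <- ndec[i] + 1L
      S <- intersect(branches[[i]]$S, tips)
      Ss <- sort(S, method = "radix")
      comp <- setdiff(tsort, Ss)
      key <- if (paste(Ss, collapse = "|") < paste(comp, collapse = "|"))
        paste(Ss, collapse = "|") else paste(comp, collapse = "|")
      hit <- key %in% bips ||
        length(Ss) <= 1L || length(comp) <= 1L  # trivial after restriction
      if (hit) ncon[i] <- ncon[i] + 1L
    }
  }
  data.frame(bipartition = bip_key,
             gcf = ifelse(ndec > 0, 100 * ncon / ndec, NA_real_),
             n_concordant = ncon, n_decisive = ndec,
             stringsAsFactors = FALSE)
}

#' Fraction of gene trees embedding one group inside another
#'
#' Scans gene trees for tips of group B falling inside the smallest clade
#' containing group A (e.g. species of a sister genus embedded within a
#' focal genus). Each gene tree is rooted on its first available outgroup
#' taxon; trees lacking an outgroup tip, fewer than two A-tips, or any
#' B-tip are skipped. "Some embedded" requires at least one present B-tip
#' inside MRCA(A); "all embedded" requires every present B-tip inside.
#'
#' @param gene_trees `multiPhylo` or list of `phylo`.
#' @param group_a,group_b,outgroup Disjoint character vectors of tip
#'   labels.
#' @return List: `some_embedded`, `all_embedded` (fractions over eligible
#'   trees), `n_eligible`.
#' @export
embedding_fraction <- function(gene_trees, group_a, group_b, outgroup) {
  if (length(intersect(group_a, group_b)) ||
      length(intersect(group_a, outgroup)) ||
      length(intersect(group_b, outgroup)))
    stop("group_a, group_b and outgroup must be disjoint")
  some <- 0L; all_ <- 0L; elig <- 0L
  for (tr in gene_trees) {
    tips <- tr$tip.label
    A <- intersect(group_a, tips)
    B <- intersect(group_b, tips)
    og <- intersect(outgroup, tips)
    if (length(A) < 2L || length(B) < 1L || length(og) < 1L) next
    elig <- elig + 1L
    tr2 <- tryCatch(ape::root(tr, outgroup = og[1], resolve.root = TRUE),
                    error = function(e) NULL)
    if (is.null(tr2)) next
    mrca <- ape::getMRCA(tr2, A)
    inside <- ape::extract.clade(tr2, mrca)$tip.label
    nb <- sum(B %in% inside)
    if (nb >= 1L) some <- some + 1L
    if (nb == length(B)) all_ <- all_ + 1L
  }
  if (elig == 0L) stop("no eligible gene trees")
  list(some_embedded = some / elig, all_embedded = all_ / elig,
       n_eligible = elig)
}
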