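# Target-capture locus triage: support-based branch collapsing,
# informativeness classification, pairwise divergence screening, and
# candidate intersection.

#' Locus filter configuration
#'
#' Defaults follow the target-capture screening convention: collapse
#' internal branches below 70% ultrafast bootstrap support, call a locus
#' informative when strictly more than four surviving nodes have support
#' 90 or more, and call its sequence divergent when the p-distance to the
#' reference is >= 0.15 (inclusive).
#'
#' @param collapse_threshold Support below which internal branches are
#'   collapsed (0-100).
#' @param strong_threshold Support defining a strongly supported node.
#' @param min_strong_nodes Exclusive lower bound on strong nodes for the
#'   informative class ("more than four").
#' @param divergence_threshold Inclusive p-distance bound in `[0, 1)`.
#' @param unlabeled_support Support value assumed for unlabeled internal
#'   branches (conservative default 0: collapsed).
#' @return List of class `locus_filter_config`.
#' @export
locus_filter_config <- function(collapse_threshold = 70,
                                strong_threshold = 90,
                                min_strong_nodes = 4,
                                divergence_threshold = 0.15,
                                unlabeled_support = 0) {
  stopifnot(collapse_threshold >= 0, collapse_threshold <= 100,
            strong_threshold >= 0, strong_threshold <= 100,
            collapse_threshold <= strong_threshold,
            divergence_threshold >= 0, divergence_threshold < 1)
  structure(list(collapse_threshold = collapse_threshold,
                 strong_threshold = strong_threshold,
                 min_strong_nodes = min_strong_nodes,
                 divergence_threshold = divergence_threshold,
                 unlabeled_support = unlabeled_support),
            class = "locus_filter_config")
}

#' Collapse poorly supported branches into polytomies
#'
#' Every internal (non-root, non-terminal) branch whose tipward node
#' support is below `threshold` is contracted; its length is added to
#' nothing (the polytomy absorbs it) and tip branches are untouched.
#' Collapsing is idempotent.
#'
#' @param tree `phylo` with numeric internal node labels as supports
#'   (0-100).
#' @param threshold Strictly-below collapse bound; default 70.
#' @param unlabeled_support Support assumed for unlabeled internal nodes.
#' @return `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold = 70, unlabeled_support = 0) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  sup <- node_supports(tree, unlabeled = unlabeled_support)
  root <- n + 1L
  # internal non-root nodes whose subtending branch is contracted
  drop_nodes <- which(sup < threshold) + n
  drop_nodes <- drop_nodes[drop_nodes != root &
                           drop_nodes %in% tree$edge[, 2L]]
  if (!length(drop_nodes)) return(tree)
  contract_nodes(tree, drop_nodes)
}

# contract the branches above the given internal nodes: their children are
# reattached (with unchanged branch lengths) to the nearest surviving
# ancestor, producing polytomies
contract_nodes <- function(tree, drop_nodes) {
  n <- length(tree$tip.label)
  root <- n + 1L
  nnode <- tree$Nnode
  par <- integer(n + nnode)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- rep(NA_real_, n + nnode)
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2L]] <- tree$edge.length
  dropped <- logical(n + nnode)
  dropped[drop_nodes] <- TRUE
  survivors <- c(seq_len(n), setdiff(seq.int(n + 1L, n + nnode),
                                     drop_nodes))
  keep_int <- sort(setdiff(seq.int(n + 1L, n + nnode), drop_nodes))
  newid <- integer(n + nnode)
  newid[seq_len(n)] <- seq_len(n)
  newid[keep_int] <- n + seq_along(keep_int)  # old root stays node n+1
  edge <- matrix(0L, length(survivors) - 1L, 2L)
  el <- numeric(nrow(edge))
  r <- 0L
  for (v in survivors) {
    if (v == root) next
    p <- par[v]
    while (dropped[p]) p <- par[p]
    r <- r + 1L
    edge[r, ] <- c(newid[p], newid[v])
    el[r] <- elen[v]
  }
  out <- list(edge = edge, Nnode = length(keep_int),
              tip.label = tree$tip.label)
  if (!is.null(tree$edge.length)) out$edge.length <- el
  if (!is.null(tree$node.label))
    out$node.label <- tree$node.label[keep_int - n]
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' Classify a locus tree's informativeness
#'
#' The tree is first collapsed at the low-support threshold; it is
#' `unresolved` if no internal (non-root) branch survives, `informative`
#' if strictly more than `min_strong_nodes` surviving internal nodes have
#' support at or above the strong threshold, and `neither` otherwise.
#'
#' @param tree `phylo` with support labels.
#' @param config [locus_filter_config()].
#' @return List: `class`, `n_nodes` (surviving internal non-root nodes),
#'   `n_strong`.
#' @export
classify_locus <- function(tree, config = locus_filter_config()) {
  coll <- collapse_low_support(tree, config$collapse_threshold,
                               config$unlabeled_support)
  n <- length(coll$tip.label)
  sup <- node_supports(coll, unlabeled = config$unlabeled_support)
  internal <- coll$edge[, 2L][coll$edge[, 2L] > n]  # non-root internal nodes
  n_nodes <- length(internal)
  n_strong <- sum(sup[internal - n] >= config$strong_threshold)
  cls <- if (n_nodes == 0L) "unresolved"
         else if (n_strong > config$min_strong_nodes) "informative"
         else "neither"
  list(class = cls, n_nodes = n_nodes, n_strong = n_strong)
}

#' Uncorrected pairwise distance between aligned sequences
#'
#' Proportion of mismatches over comparable columns; columns with a gap or
#' ambiguity code in either sequence are excluded. NA when no column is
#' comparable.
#'
#' @param a,b Equal-length character strings (or character vectors of
#'   single residues).
#' @return Numeric in `[0, 1]`, or NA.
#' @export
p_distance <- function(a, b) {
  av <- if (length(a) == 1L) strsplit(a, "")[[1]] else a
  bv <- if (length(b) == 1L) strsplit(b, "")[[1]] else b
  if (length(av) != length(bv))
    stop("sequences differ in length (", length(av), " vs ", length(bv), ")")
  av <- toupper(av); bv <- toupper(bv)
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  sum(av[ok] != bv[ok]) / sum(ok)
}

#' Select candidate loci by informativeness and divergence
#'
#' A locus is selected iff it is classified informative and its p-distance
#' to the reference is at or above the divergence threshold (inclusive).
#'
#' @param reports Data frame with one row per locus: columns `locus`,
#'   `class`, `p_dist` (see [classify_locus()] and [p_distance()]).
#' @param config [locus_filter_config()].
#' @return The data frame with logical columns `informative`, `divergent`,
#'   `selected` added, plus a `summary` attribute with the class counts.
#' @export
select_candidates <- function(reports, config = locus_filter_config()) {
  stopifnot(all(c("locus", "class", "p_dist") %in% names(reports)))
  reports$informative <- reports$class == "informative"
  reports$divergent <- !is.na(reports$p_dist) &
    reports$p_dist >= config$divergence_threshold
  reports$selected <- reports$informative & reports$divergent
  attr(reports, "summary") <- c(
    n_loci = nrow(reports),
    n_unresolved = sum(reports$class == "unresolved"),
    n_informative = sum(reports$informative),
    n_divergent = sum(reports$divergent),
    n_selected = sum(reports$selected))
  reports
}

#' Run the full locus triage on trees and sequence pairs
#'
#' @param trees Named list of `phylo` locus trees with support labels.
#' @param ref_seqs,query_seqs Named character vectors of aligned sequences
#'   (names matching `trees`).
#' @param config [locus_filter_config()].
#' @return Selected-locus report as from [select_candidates()].
#' @export
screen_loci <- function(trees, ref_seqs, query_seqs,
                        config = locus_filter_config()) {
  loci <- names(trees)
  stopifnot(!is.null(loci), all(loci %in% names(ref_seqs)),
            all(loci %in% names(query_seqs)))
  cls <- vapply(trees, function(tr) classify_locus(tr, config)$class,
                character(1))
  pd <- vapply(loci, function(l) p_distance(ref_seqs[[l]], query_seqs[[l]]),
               numeric(1))
  select_candidates(data.frame(locus = loci, class = unname(cls),
                               p_dist = unname(pd),
                               stringsAsFactors = FALSE), config)
}
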