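#' @useDynLib phylodiscord, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize optim setNames rexp runif rnorm quantile var sd
#'   pchisq aggregate complete.cases as.formula lm coef terms model.matrix
#'   rbinom
#' @importFrom utils combn head
NULL

#' Parse a Newick string into a rooted phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that validates the result and
#' normalizes internal-node support labels to the 0-100 scale used
#' throughout the package (the ultrafast-bootstrap convention). Numeric
#' internal labels are interpreted as branch support.
#'
#' @param text Newick string (single tree, terminated by `;`).
#' @param support_scale `"percent"` (labels already 0-100) or `"fraction"`
#'   (labels in 0-1, rescaled to 0-100 on read).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text, support_scale = c("percent", "fraction")) {
  support_scale <- match.arg(support_scale)
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    # locate first structural problem for the error message
    bal <- cumsum((strsplit(text, "")[[1]] == "(") -
                  (strsplit(text, "")[[1]] == ")"))
    off <- if (any(bal < 0)) which(bal < 0)[1] else nchar(text)
    stop("malformed Newick near character offset ", off, call. = FALSE)
  }
  if (any(duplicated(tr$tip.label)))
    stop("duplicated tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (!is.null(tr$node.label) && support_scale == "fraction") {
    lab <- suppressWarnings(as.numeric(tr$node.label))
    tr$node.label <- ifelse(is.na(lab), tr$node.label,
                            as.character(lab * 100))
  }
  tr
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return Newick string. Round-trips with [parse_newick()] up to label
#'   quoting and floating-point formatting.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Internal support labels as numbers
#'
#' @param tree `phylo` with (possibly empty) `node.label`.
#' @param unlabeled Value assigned to unlabeled/non-numeric internal nodes.
#' @return Numeric vector of length `tree$Nnode` (root included).
#' @export
node_supports <- function(tree, unlabeled = NA_real_) {
  if (is.null(tree$node.label)) return(rep(unlabeled, tree$Nnode))
  s <- suppressWarnings(as.numeric(tree$node.label))
  s[is.na(s) | tree$node.label == ""] <- unlabeled
  if (length(s) < tree$Nnode) s <- c(s, rep(unlabeled, tree$Nnode - length(s)))
  s
}

#' Rooted clades of a tree
#'
#' One entry per internal non-root node: the set of tip labels descending
#' from it. These are the units scored by [clade_support()].
#'
#' @param tree Rooted `phylo`.
#' @return Named list of character vectors (sorted tip labels); names are
#'   internal node numbers.
#' @export
rooted_clades <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it (e.g. with ape::root) first")
  n <- length(tree$tip.label)
  root <- n + 1L
  internal <- setdiff(seq.int(n + 1L, n + tree$Nnode), root)
  desc <- clade_tip_sets(tree)
  out <- lapply(internal, function(nd) sort(desc[[nd - n]], method = "radix"))
  names(out) <- internal
  out
}

# tip-label sets for every internal node (index 1 = root = node n+1)
clade_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  sets <- vector("list", m)
  tr <- ape::reorder.phylo(tree, "postorder")
  acc <- vector("list", n + m)
  for (i in seq_len(n)) acc[[i]] <- tree$tip.label[i]
  for (r in seq_len(nrow(tr$edge))) {
    p <- tr$edge[r, 1L]; ch <- tr$edge[r, 2L]
    acc[[p]] <- c(acc[[p]], acc[[ch]])
  }
  for (k in seq_len(m)) sets[[k]] <- acc[[n + k]]
  sets
}

#' Test monophyly of a taxon set
#'
#' TRUE iff the most recent common ancestor of `taxa` has no other tips
#' among its descendants (rooted sense).
#'
#' @param tree Rooted `phylo`.
#' @param taxa Character vector of tip labels, non-empty.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"), length(taxa) >= 1L)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) %in% c(1L, length(tree$tip.label))) return(TRUE)
  ape::is.monophyletic(tree, taxa)
}

#' Phylogenetic covariance matrix
#'
#' `C[i, j]` = depth (shared root-to-MRCA path length) of tips i and j; the
#' diagonal holds root-to-tip distances. This is the Brownian-motion
#' covariance structure used by [ppca()], [fit_pmm()] and [bm_ancestral()].
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @return Symmetric positive semi-definite matrix, tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  ape::vcv(tree)
}

#' Prune a tree to a subset of tips
#'
#' Induced subtree on `keep`; suppressed degree-2 nodes have their branch
#' lengths summed, so all pairwise patristic distances among kept tips are
#' preserved.
#'
#' @param tree `phylo`.
#' @param keep Character vector of tip labels to retain.
#' @return `phylo` on `keep`.
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- intersect(tree$tip.label, keep)
  if (!length(keep)) stop("'keep' shares no tips with the tree")
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) {
    # single-tip tree preserving the root-to-tip path length
    d <- ape::node.depth.edgelength(tree)[match(keep, tree$tip.label)]
    tr <- list(edge = matrix(c(2L, 1L), 1L, 2L), edge.length = d,
               Nnode = 1L, tip.label = keep)
    class(tr) <- "phylo"
    return(tr)
  }
  ape::keep.tip(tree, keep)
}

#' Canonical topology string
#'
#' Label-sorted parenthetical encoding of a rooted topology (branch lengths
#' and supports dropped). Two trees have equal strings iff they are
#' identical rooted topologies. Matches the encoding used by the C-level
#' coalescent simulator, so simulated and empirical tree sets can be
#' tabulated together.
#'
#' @param tree Rooted `phylo` (polytomies allowed).
#' @return Character scalar.
#' @export
canonical_topology <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(nd) {
    if (nd <= n) return(tree$tip.label[nd])
    parts <- vapply(kids[[as.character(nd)]], rec, character(1))
    paste0("(", paste(sort(parts, method = "radix"), collapse = ","), ")")
  }
  rec(n + 1L)
}

#' Topology frequency table
#'
#' @param trees `multiPhylo`, list of `phylo`, or character vector of
#'   canonical topology strings.
#' @return Named numeric vector of relative frequencies, summing to 1.
#' @export
topology_frequencies <- function(trees) {
  keys <- if (is.character(trees)) trees
          else vapply(trees, canonical_topology, character(1))
  tab <- table(keys)
  out <- as.numeric(tab) / length(keys)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

# height (max root-to-tip distance) of a tree
tree_height <- function(tree) max(ape::node.depth.edgelength(tree))
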