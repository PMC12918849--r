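# Multispecies-coalescent simulation on species trees and networks.
#
# The species tree (or network) is digested into "populations": time
# segments bounded by speciation and reticulation events, measured in
# coalescent units before the present. The C-level censored coalescent
# then runs over the population graph. This one code path serves both the
# plain-tree and the network simulator; a tree is simply a network with no
# reticulation edges.

# node times before present; tips at 0 (ultrametric within tolerance)
node_times <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth)
  tt <- h - depth
  n <- length(tree$tip.label)
  if (max(abs(tt[seq_len(n)])) > tol * h)
    stop("species tree is not ultrametric (tip-depth spread exceeds ",
         "tolerance); use terminal_policy = \"extend\" if terminal branch ",
         "lengths are arbitrary")
  tt[seq_len(n)] <- 0
  tt
}

# Build the population-graph arrays consumed by the C simulator.
# events: data.frame(donor_node, recipient_node, time, gamma) where the
# *_node columns give the tipward node of the edge carrying the event.
population_graph <- function(tree, events = NULL, samples_per_species = 1,
                             tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree))
  if (is.null(tree$edge.length)) stop("species tree needs branch lengths")
  if (any(tree$edge.length <= 0))
    stop("species-tree branch lengths must be positive")
  n <- length(tree$tip.label)
  root <- n + 1L
  tt <- node_times(tree, tol)

  # one population per edge, keyed by tipward node, plus the root population
  pop_start <- tt[tree$edge[, 2L]]
  pop_end <- tt[tree$edge[, 1L]]
  npop <- nrow(tree$edge) + 1L
  rootpop <- npop
  pop_start <- c(pop_start, tt[root])
  pop_end <- c(pop_end, Inf)
  edge_of_node <- match(seq_len(n + tree$Nnode), tree$edge[, 2L])
  route1 <- integer(npop)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]
    route1[e] <- if (par == root) rootpop else edge_of_node[par]
  }
  route1[rootpop] <- -1L
  route2 <- rep(-1L, npop)
  prob2 <- rep(0, npop)
  # chain of population indices per original edge, tipward-first
  chains <- as.list(seq_len(nrow(tree$edge)))

  split_at <- function(edge, tau, state) {
    # return (state, index of population starting at tau on this edge)
    ch <- state$chains[[edge]]
    starts <- state$pop_start[ch]
    ends <- state$pop_end[ch]
    hit <- which(starts <= tau & tau <= ends)[1]
    if (is.na(hit)) stop("reticulation time ", tau,
                         " lies outside edge ", edge)
    p <- ch[hit]
    if (abs(state$pop_start[p] - tau) < 1e-12) return(list(state, p))
    if (abs(state$pop_end[p] - tau) < 1e-12) {
      nxt <- if (hit < length(ch)) ch[hit + 1L] else state$route1[p]
      return(list(state, nxt))
    }
    newp <- length(state$pop_start) + 1L
    state$pop_start[newp] <- tau
    state$pop_end[newp] <- state$pop_end[p]
    state$route1[newp] <- state$route1[p]
    state$route2[newp] <- state$route2[p]
    state$prob2[newp] <- state$prob2[p]
    state$pop_end[p] <- tau
    state$route1[p] <- newp
    state$route2[p] <- -1L
    state$prob2[p] <- 0
    state$chains[[edge]] <- append(ch, newp, after = hit)
    list(state, newp)
  }

  state <- list(pop_start = pop_start, pop_end = pop_end, route1 = route1,
                route2 = route2, prob2 = prob2, chains = chains)
  if (!is.null(events) && nrow(events)) {
    for (k in order(events$time)) {
      tau <- events$time[k]
      gam <- events$gamma[k]
      de <- edge_of_node[events$donor_node[k]]
      re <- edge_of_node[events$recipient_node[k]]
      if (is.na(de) || is.na(re)) stop("reticulation edge not found")
      res <- split_at(de, tau, state); state <- res[[1]]; dup <- res[[2]]
      res <- split_at(re, tau, state); state <- res[[1]]; rup <- res[[2]]
      # the population just below tau on the recipient edge gets the split
      rch <- state$chains[[re]]
      rlow <- rch[which(abs(state$pop_end[rch] - tau) < 1e-12)[1]]
      if (is.na(rlow)) stop("internal error: recipient segment not found")
      state$route1[rlow] <- rup
      state$route2[rlow] <- dup
      state$prob2[rlow] <- gam
    }
  }

  # per-lineage starting populations
  if (length(samples_per_species) == 1L)
    samples_per_species <- setNames(rep(samples_per_species, n),
                                    tree$tip.label)
  samples_per_species <- samples_per_species[tree$tip.label]
  lineage_pop <- integer(0)
  lineage_label <- character(0)
  for (i in seq_len(n)) {
    k <- samples_per_species[i]
    lab <- if (k == 1L) tree$tip.label[i]
           else paste0(tree$tip.label[i], "_", seq_len(k))
    lineage_pop <- c(lineage_pop, rep(edge_of_node[i], k))
    lineage_label <- c(lineage_label, lab)
  }

  # topological processing order over the routing DAG (sources first)
  np <- length(state$pop_start)
  indeg <- integer(np)
  for (p in seq_len(np)) {
    if (state$route1[p] > 0) indeg[state$route1[p]] <- indeg[state$route1[p]] + 1L
    if (state$route2[p] > 0) indeg[state$route2[p]] <- indeg[state$route2[p]] + 1L
  }
  ord <- integer(0)
  frontier <- which(indeg == 0L)
  frontier <- frontier[order(state$pop_start[frontier])]
  while (length(frontier)) {
    p <- frontier[1]; frontier <- frontier[-1]
    ord <- c(ord, p)
    for (tg in c(state$route1[p], state$route2[p])) {
      if (tg > 0) {
        indeg[tg] <- indeg[tg] - 1L
        if (indeg[tg] == 0L) {
          frontier <- c(frontier, tg)
          frontier <- frontier[order(state$pop_start[frontier])]
        }
      }
    }
  }
  if (length(ord) != np) stop("population graph has a cycle; check events")

  list(pop_start = state$pop_start, pop_end = state$pop_end,
       route1 = state$route1 - 1L,  # 0-based for C
       route2 = ifelse(state$route2 > 0, state$route2 - 1L, -1L),
       prob2 = state$prob2, order = ord - 1L,
       lineage_pop = lineage_pop - 1L, lineage_label = lineage_label)
}

phylo_from_sim <- function(rec, tip_label) {
  tr <- list(edge = rec$edge, edge.length = rec$edge.length,
             Nnode = rec$Nnode, tip.label = tip_label)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Censored coalescent on a species tree with branch lengths in coalescent
#' units (2N generations): within each species-tree branch carrying k
#' lineages the next coalescence waits Exp(k(k-1)/2); lineages that fail to
#' coalesce are passed rootward, and coalescence continues above the root
#' until a single lineage remains. Gene-tree branch lengths are in
#' coalescent units.
#'
#' @param species_tree Rooted ultrametric `phylo`, coalescent units.
#' @param n_reps Number of gene trees (the reference analysis used 5000).
#' @param samples_per_species Integer scalar or named vector; default 1,
#'   matching a one-accession-per-species design.
#' @param terminal_policy `"as_is"` requires an ultrametric input;
#'   `"extend"` stretches terminal branches so all tips reach the present,
#'   for species trees (e.g. quartet-based) whose terminal lengths are
#'   arbitrary. With one sample per species the choice does not affect the
#'   topology distribution.
#' @param seed Optional integer seed.
#' @param topology_only If TRUE return canonical topology strings instead
#'   of `phylo` objects (fast path for frequency work).
#' @return `multiPhylo` (or character vector when `topology_only = TRUE`).
#' @export
simulate_gene_trees <- function(species_tree, n_reps = 5000,
                                samples_per_species = 1,
                                terminal_policy = c("as_is", "extend"),
                                seed = NULL, topology_only = FALSE) {
  terminal_policy <- match.arg(terminal_policy)
  stopifnot(n_reps >= 1)
  if (terminal_policy == "extend") species_tree <- extend_tips(species_tree)
  pg <- population_graph(species_tree, NULL, samples_per_species)
  if (!is.null(seed)) set.seed(seed)
  run_sim(pg, n_reps, topology_only)
}

run_sim <- function(pg, n_reps, topology_only) {
  if (topology_only) {
    msc_sim_topologies(pg$pop_start, pg$pop_end, pg$route1, pg$route2,
                       pg$prob2, pg$order, pg$lineage_pop, pg$lineage_label,
                       as.integer(n_reps))
  } else {
    raw <- msc_sim_trees(pg$pop_start, pg$pop_end, pg$route1, pg$route2,
                         pg$prob2, pg$order, pg$lineage_pop, pg$lineage_label,
                         as.integer(n_reps))
    out <- lapply(raw, phylo_from_sim, tip_label = pg$lineage_label)
    class(out) <- "multiPhylo"
    out
  }
}

# stretch terminal branches so every tip reaches time 0
extend_tips <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth)
  n <- length(tree$tip.label)
  term <- tree$edge[, 2L] <= n
  tree$edge.length[term] <- tree$edge.length[term] +
    (h - depth[tree$edge[term, 2L]])
  tree
}

#' Species network: tree plus reticulation edges
#'
#' A rooted ultrametric species tree with one or more gene-flow edges.
#' Each edge sends lineages sitting on the recipient branch at `time`
#' (coalescent units before present) to the donor branch with probability
#' `gamma`, the inheritance probability of the minor parent.
#'
#' @param tree Rooted ultrametric `phylo`, coalescent units.
#' @param donor,recipient Character vectors of tip labels; the branch
#'   carrying the event is the one above the MRCA of the given tips (a
#'   single label names a terminal branch).
#' @param time Event time(s), before present; must lie within the time
#'   spans of both branches.
#' @param gamma Inheritance probabilities, each in (0, 1).
#' @return Object of class `retic_network`.
#' @export
retic_network <- function(tree, donor, recipient, time, gamma) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.list(donor)) donor <- list(donor)
  if (!is.list(recipient)) recipient <- list(recipient)
  k <- length(donor)
  stopifnot(length(recipient) == k, length(time) == k, length(gamma) == k)
  if (any(gamma <= 0 | gamma >= 1))
    stop("gamma must lie strictly in (0, 1)")
  tt <- node_times(tree)
  nodeof <- function(taxa) {
    unknown <- setdiff(taxa, tree$tip.label)
    if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
    if (length(taxa) == 1L) match(taxa, tree$tip.label)
    else ape::getMRCA(tree, taxa)
  }
  dn <- vapply(donor, nodeof, integer(1))
  rn <- vapply(recipient, nodeof, integer(1))
  parent_of <- function(nd) tree$edge[match(nd, tree$edge[, 2L]), 1L]
  for (i in seq_len(k)) {
    for (nd in c(dn[i], rn[i])) {
      if (is.na(match(nd, tree$edge[, 2L])))
        stop("event ", i, ": branch not found (root cannot carry an event)")
      lo <- tt[nd]; hi <- tt[parent_of(nd)]
      if (time[i] <= lo || time[i] >= hi)
        stop("event ", i, ": time ", time[i],
             " outside branch span (", signif(lo, 6), ", ", signif(hi, 6), ")")
    }
  }
  structure(list(tree = tree,
                 events = data.frame(donor_node = dn, recipient_node = rn,
                                     time = time, gamma = gamma)),
            class = "retic_network")
}

#' @export
print.retic_network <- function(x, ...) {
  cat("Species network:", length(x$tree$tip.label), "tips,",
      nrow(x$events), "reticulation edge(s)\n")
  print(x$events)
  invisible(x)
}

#' Simulate gene trees on a species network
#'
#' As [simulate_gene_trees()], but each lineage present on a recipient
#' branch at a reticulation time independently follows the minor (donor)
#' parent with probability gamma; conditional on those choices the censored
#' coalescent proceeds unchanged.
#'
#' @param network `retic_network`.
#' @inheritParams simulate_gene_trees
#' @return `multiPhylo` (or character vector when `topology_only = TRUE`).
#' @export
simulate_on_network <- function(network, n_reps = 5000,
                                samples_per_species = 1, seed = NULL,
                                topology_only = FALSE) {
  stopifnot(inherits(network, "retic_network"))
  pg <- population_graph(network$tree, network$events, samples_per_species)
  if (!is.null(seed)) set.seed(seed)
  run_sim(pg, n_reps, topology_only)
}

#' Grid estimate of the inheritance probability gamma
#'
#' Given observed gene trees and a network whose gamma is unknown, the
#' estimate is the grid point minimizing the L2 distance between observed
#' topology frequencies and simulation-estimated frequencies at that gamma
#' (fixed simulation seed per grid point, so the objective is
#' deterministic). A nonparametric bootstrap over the observed trees gives
#' the confidence interval.
#'
#' @param observed `multiPhylo`/list of `phylo` or canonical topology
#'   strings.
#' @param network `retic_network`; its `gamma` column is ignored.
#' @param grid Candidate gamma values.
#' @param nsim Simulated replicates per grid point.
#' @param n_boot Bootstrap resamples (0 to skip the CI).
#' @param conf CI level.
#' @param seed Integer seed for the per-grid-point simulations and the
#'   bootstrap.
#' @return List with `gamma_hat`, `ci`, `grid`, `objective`.
#' @export
estimate_gamma <- function(observed, network,
                           grid = seq(0.01, 0.99, by = 0.02),
                           nsim = 5000, n_boot = 200, conf = 0.95,
                           seed = 1L) {
  keys <- if (is.character(observed)) observed
          else vapply(observed, canonical_topology, character(1))
  if (length(keys) == 0L) stop("no observed gene trees")
  if (length(keys) < 100L)
    warning("fewer than 100 observed gene trees; the estimate will be noisy")
  stopifnot(inherits(network, "retic_network"))
  nets <- lapply(grid, function(g) {
    nw <- network
    nw$events$gamma <- g
    nw
  })
  sim_freq <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    sim_freq[[i]] <- topology_frequencies(
      simulate_on_network(nets[[i]], n_reps = nsim, seed = seed + i,
                          topology_only = TRUE))
  }
  all_keys <- unique(c(unlist(lapply(sim_freq, names)), keys))
  simmat <- vapply(sim_freq, function(f) {
    v <- setNames(numeric(length(all_keys)), all_keys)
    v[names(f)] <- f
    v
  }, numeric(length(all_keys)))
  obj_for <- function(kk) {
    obs <- setNames(numeric(length(all_keys)), all_keys)
    tab <- table(kk) / length(kk)
    obs[names(tab)] <- as.numeric(tab)
    colSums((simmat - obs)^2)
  }
  objective <- obj_for(keys)
  gamma_hat <- grid[which.min(objective)]
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      grid[which.min(obj_for(sample(keys, replace = TRUE)))]
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(a, 1 - a)))
  }
  list(gamma_hat = gamma_hat, ci = ci, grid = grid, objective = objective)
}
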