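# Dispersal-extinction-cladogenesis (DEC) likelihood on discrete
# area/habitat ranges, ML fitting, AIC comparison, and stochastic mapping
# with between-area dispersal counts.
#
# Ranges are subsets of A areas encoded as bitmasks. The observable state
# space holds the 2^A - 1 non-empty subsets; the null (empty) range exists
# only internally, as the absorbing state reached when a single-area range
# goes extinct.

#' DEC state space
#'
#' @param areas Character vector of area (habitat) labels, length >= 2.
#' @param max_range_size Optional cap on range sizes (default: none).
#' @return List of class `dec_state_space`: `areas`, `masks` (state 1 is
#'   the null range), `sets`, `sizes`, `index_of_mask`, `n_states`
#'   (observable states, excluding null).
#' @export
dec_state_space <- function(areas, max_range_size = NULL) {
  A <- length(areas)
  stopifnot(A >= 2)
  masks <- 0:(2^A - 1)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(A - 1))) > 0),
                  numeric(1))
  if (!is.null(max_range_size))
    masks <- masks[sizes <= max_range_size | masks == 0]
  sizes <- sizes[masks + 1]
  o <- order(sizes, masks)
  masks <- masks[o]; sizes <- sizes[o]
  sets <- lapply(masks, function(m) which(bitwAnd(m, 2^(0:(A - 1))) > 0))
  idx <- integer(2^A)
  idx[masks + 1] <- seq_along(masks)
  structure(list(areas = areas, masks = masks, sets = sets, sizes = sizes,
                 index_of_mask = idx, n_states = length(masks) - 1L),
            class = "dec_state_space")
}

#' @export
print.dec_state_space <- function(x, ...) {
  cat("DEC state space:", length(x$areas), "areas,", x$n_states,
      "observable states (+ null)\n")
  invisible(x)
}

range_mask <- function(space, area_idx) sum(2^(area_idx - 1))

#' Drop autapomorphic areas from a range matrix
#'
#' Iteratively removes every area occupied by exactly one species when
#' that species also occupies at least one other retained area (such
#' single-species habitats are unlikely to have been ancestral and
#' inflate the state space). An area that is a species' only habitat is
#' never removed.
#'
#' @param ranges Binary species-by-areas matrix (dimnames required).
#' @return The reduced matrix.
#' @export
reduce_areas <- function(ranges) {
  ranges <- as.matrix(ranges)
  stopifnot(all(ranges %in% c(0, 1)), !is.null(colnames(ranges)))
  if (any(rowSums(ranges) == 0)) stop("every species must occupy an area")
  repeat {
    occ <- colSums(ranges)
    drop <- NULL
    for (a in which(occ == 1)) {
      sp <- which(ranges[, a] == 1)
      if (sum(ranges[sp, ]) > 1) { drop <- a; break }
    }
    if (is.null(drop)) break
    ranges <- ranges[, -drop, drop = FALSE]
  }
  ranges
}

#' DEC parameters
#'
#' @param d Dispersal (area-gain) rate per source area per time.
#' @param e Extinction (area-loss) rate per area per time.
#' @param j Founder-event (jump) cladogenesis weight; 0 gives plain DEC.
#' @return List of class `dec_params`.
#' @export
dec_params <- function(d, e, j = 0) {
  stopifnot(d >= 0, e >= 0, j >= 0)
  structure(list(d = d, e = e, j = j), class = "dec_params")
}

#' Anagenetic DEC rate matrix
#'
#' Off-diagonal rates: range r gains area a at rate d * |r| (every area in
#' r is an equally weighted source); r loses area a at rate e, single-area
#' ranges passing to the null range. Rows sum to zero; the null range is
#' absorbing.
#'
#' @param params [dec_params()].
#' @param space [dec_state_space()].
#' @return Dense rate matrix over the full state list (null included).
#' @export
build_dec_q <- function(params, space) {
  ns <- length(space$masks)
  A <- length(space$areas)
  Q <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    m <- space$masks[i]
    if (m == 0) next
    r <- space$sets[[i]]
    for (a in seq_len(A)) {
      bit <- 2^(a - 1)
      if (bitwAnd(m, bit) > 0) {                # loss of a
        tgt <- space$index_of_mask[bitwXor(m, bit) + 1]
        if (tgt > 0) Q[i, tgt] <- Q[i, tgt] + params$e
      } else {                                  # gain of a
        tgt <- space$index_of_mask[bitwOr(m, bit) + 1]
        if (tgt > 0) Q[i, tgt] <- Q[i, tgt] + params$d * length(r)
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Cladogenetic event table for a parent range
#'
#' Ordered daughter-range pairs with weights: sympatric duplication for
#' single-area parents; subset sympatry (one daughter a single area of r,
#' the other all of r) and single-area vicariance for wider parents; and,
#' with weight j, founder-event jumps to an area outside r. Probabilities
#' are normalized to sum to one within the parent state.
#'
#' @param range_index State index of the (non-null) parent range.
#' @param space [dec_state_space()].
#' @param j Jump weight.
#' @return Data frame: `left`, `right` (state indices), `weight`, `prob`,
#'   `type`.
#' @export
cladogenesis_events <- function(range_index, space, j = 0) {
  m <- space$masks[range_index]
  if (m == 0) stop("null range cannot speciate")
  r <- space$sets[[range_index]]
  A <- length(space$areas)
  idx <- function(mask) space$index_of_mask[mask + 1]
  left <- integer(0); right <- integer(0); w <- numeric(0); ty <- character(0)
  add <- function(l, rr, wt, type) {
    left <<- c(left, l); right <<- c(right, rr)
    w <<- c(w, wt); ty <<- c(ty, type)
  }
  if (length(r) == 1L) {
    add(range_index, range_index, 1, "sympatry")
  } else {
    for (a in r) {
      am <- 2^(a - 1)
      ai <- idx(am)
      add(ai, range_index, 1, "subset_sympatry")
      add(range_index, ai, 1, "subset_sympatry")
      rest <- idx(bitwXor(m, am))
      if (rest > 0) {
        add(ai, rest, 1, "vicariance")
        add(rest, ai, 1, "vicariance")
      }
    }
  }
  if (j > 0) {
    for (b in setdiff(seq_len(A), r)) {
      bi <- idx(2^(b - 1))
      add(bi, range_index, j, "jump")
      add(range_index, bi, j, "jump")
    }
  }
  # a 2-area parent yields each vicariance pair twice (once per choice of
  # the single-area daughter); keep each ordered event once
  dup <- duplicated(data.frame(left, right, ty))
  left <- left[!dup]; right <- right[!dup]; w <- w[!dup]; ty <- ty[!dup]
  data.frame(left = left, right = right, weight = w, prob = w / sum(w),
             type = ty, stringsAsFactors = FALSE)
}

# tip conditional-likelihood matrix (states x tips)
tip_likelihoods <- function(tree, ranges, space) {
  ranges <- as.matrix(ranges)
  stopifnot(!is.null(rownames(ranges)),
            setequal(rownames(ranges), tree$tip.label),
            identical(colnames(ranges), space$areas))
  ns <- length(space$masks)
  n <- length(tree$tip.label)
  L <- matrix(0, ns, n)
  for (i in seq_len(n)) {
    rr <- ranges[tree$tip.label[i], ]
    mask <- sum(2^(which(rr == 1) - 1))
    st <- space$index_of_mask[mask + 1]
    if (st == 0 || mask == 0)
      stop("tip '", tree$tip.label[i], "' has a range outside the state space")
    L[st, i] <- 1
  }
  L
}

# full pruning pass; returns per-node state likelihoods and per-branch
# rootward-transported likelihoods, for reuse by the stochastic mapper
dec_prune <- function(tree, ranges, params, space) {
  n <- length(tree$tip.label)
  ns <- length(space$masks)
  Q <- build_dec_q(params, space)
  Ltip <- tip_likelihoods(tree, ranges, space)
  clado <- lapply(seq_len(ns), function(i)
    if (space$masks[i] == 0) NULL else cladogenesis_events(i, space, params$j))
  Lnode <- matrix(0, ns, n + tree$Nnode)
  Lnode[, seq_len(n)] <- Ltip
  Lup <- matrix(0, ns, nrow(tree$edge))  # indexed by edge (original order)
  P <- vector("list", nrow(tree$edge))
  kids_edges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  combine_node <- function(nd) {
    edges <- kids_edges[[as.character(nd)]]
    stopifnot(length(edges) == 2L)  # binary trees only
    v <- numeric(ns)
    for (i in seq_len(ns)) {
      ev <- clado[[i]]
      if (is.null(ev)) next
      v[i] <- sum(ev$prob * Lup[ev$left, edges[1]] * Lup[ev$right, edges[2]])
    }
    v
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  eo <- match(paste(tr$edge[, 1], tr$edge[, 2]),
              paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(nrow(tr$edge))) {
    e <- eo[k]
    ch <- tree$edge[e, 2L]
    if (ch > n && all(Lnode[, ch] == 0))
      Lnode[, ch] <- combine_node(ch)  # child edges already transported
    Pe <- as.matrix(Matrix::expm(Q * tree$edge.length[e]))
    P[[e]] <- Pe
    Lup[, e] <- Pe %*% Lnode[, ch]
  }
  root <- n + 1L
  Lnode[, root] <- combine_node(root)
  list(Q = Q, P = P, Lnode = Lnode, Lup = Lup, clado = clado,
       kids_edges = kids_edges)
}

#' DEC log-likelihood
#'
#' Felsenstein pruning over the range state space: anagenetic transitions
#' along branches by the matrix exponential of Q t, cladogenetic
#' combination at internal nodes through the normalized event
#' probabilities, and a flat root prior over non-null ranges.
#'
#' @param tree Rooted binary `phylo`, time-scaled branch lengths.
#' @param ranges Binary species-by-areas matrix (rownames = tips,
#'   colnames = `space$areas`).
#' @param params [dec_params()].
#' @param space [dec_state_space()].
#' @param root_prior `"flat"` (default) over non-null states.
#' @return Log-likelihood (scalar).
#' @export
dec_loglik <- function(tree, ranges, params, space, root_prior = "flat") {
  pr <- dec_prune(tree, ranges, params, space)
  root <- length(tree$tip.label) + 1L
  ns <- length(pr$Lnode[, root])
  nonnull <- which(space$masks != 0)
  prior <- numeric(ns)
  prior[nonnull] <- 1 / length(nonnull)
  lik <- sum(prior * pr$Lnode[, root])
  if (lik <= 0) return(-Inf)
  log(lik)
}

#' Fit a DEC or DEC+J model by maximum likelihood
#'
#' Bounded optimization of (d, e) (and j for DEC+J) on the log scale from
#' several seeded starting points; AIC uses k = 2 (DEC) or 3 (DEC+J).
#'
#' @inheritParams dec_loglik
#' @param model `"DEC"` or `"DEC+J"`.
#' @param n_starts Number of random restarts.
#' @param seed Integer seed for the restarts.
#' @return List of class `dec_fit`: `params`, `loglik`, `aic`, `model`,
#'   `convergence`.
#' @export
fit_dec <- function(tree, ranges, space, model = c("DEC", "DEC+J"),
                    n_starts = 3, seed = 1) {
  model <- match.arg(model)
  has_j <- model == "DEC+J"
  negll <- function(lp) {
    p <- exp(lp)
    par <- dec_params(p[1], p[2], if (has_j) p[3] else 0)
    ll <- dec_loglik(tree, ranges, par, space)
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  h <- tree_height(tree)
  starts <- lapply(seq_len(n_starts), function(i) {
    s <- log(c(runif(1, 0.01, 2), runif(1, 0.005, 1)) / h)
    if (has_j) s <- c(s, log(runif(1, 0.01, 1))) else s
  })
  best <- NULL
  for (s in starts) {
    op <- tryCatch(
      optim(s, negll, method = "L-BFGS-B",
            lower = rep(log(1e-8), length(s)),
            upper = rep(log(50), length(s)),
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) stop("all optimization starts failed")
  p <- exp(best$par)
  k <- if (has_j) 3L else 2L
  ll <- -best$value
  structure(list(params = dec_params(p[1], p[2], if (has_j) p[3] else 0),
                 loglik = ll, aic = 2 * k - 2 * ll, k = k, model = model,
                 convergence = best$convergence), class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf("%s fit: d = %.4g, e = %.4g%s\n", x$model, x$params$d,
              x$params$e,
              if (x$params$j > 0) sprintf(", j = %.4g", x$params$j) else ""))
  cat(sprintf("logLik = %.3f  AIC = %.3f\n", x$loglik, x$aic))
  invisible(x)
}

#' Compare fitted DEC-family models by AIC
#'
#' @param ... `dec_fit` objects (externally computed likelihoods may be
#'   supplied as `list(model=, loglik=, k=)`).
#' @return Data frame sorted by AIC with delta-AIC column.
#' @export
dec_model_compare <- function(...) {
  fits <- list(...)
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model, loglik = f$loglik, k = f$k,
               aic = 2 * f$k - 2 * f$loglik, stringsAsFactors = FALSE)))
  df <- df[order(df$aic), ]
  df$delta_aic <- df$aic - df$aic[1]
  df
}

# --- endpoint-conditioned CTMC path sampling ------------------------------

# rejection sampler: forward-simulate from `from`; accept when the end
# state matches
sample_path_reject <- function(Q, from, to, t_len, max_try = 50) {
  ns <- nrow(Q)
  for (tryi in seq_len(max_try)) {
    s <- from; t <- 0; path <- list()
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      dt <- rexp(1, rate)
      if (t + dt >= t_len) break
      t <- t + dt
      probs <- Q[s, ]; probs[s] <- 0
      s2 <- sample.int(ns, 1, prob = probs)
      path[[length(path) + 1]] <- c(time = t, from = s, to = s2)
      s <- s2
    }
    if (s == to) return(path)
  }
  NULL
}

# uniformization sampler (fallback); exact conditional on endpoints
sample_path_unif <- function(Q, P_t, from, to, t_len, max_jumps = 200) {
  ns <- nrow(Q)
  lam <- max(-diag(Q)) * 1.05 + 1e-12
  R <- diag(ns) + Q / lam
  pt <- P_t[from, to]
  if (pt <= 0) stop("impossible endpoint pair in path sampling")
  # sample number of uniformized jumps
  Rpow <- vector("list", max_jumps + 1)
  Rpow[[1]] <- diag(ns)
  u <- runif(1)
  cum <- 0; njump <- NA
  for (m in 0:max_jumps) {
    if (m > 0) Rpow[[m + 1]] <- Rpow[[m]] %*% R
    pm <- exp(-lam * t_len + m * log(lam * t_len) - lfactorial(m)) *
      Rpow[[m + 1]][from, to] / pt
    cum <- cum + pm
    if (u <= cum) { njump <- m; break }
  }
  if (is.na(njump)) njump <- max_jumps
  if (njump == 0) return(list())
  times <- sort(runif(njump, 0, t_len))
  states <- integer(njump + 1)
  states[1] <- from
  for (i in seq_len(njump)) {
    remain <- njump - i
    probs <- R[states[i], ] * Rpow[[remain + 1]][, to]
    states[i + 1] <- sample.int(ns, 1, prob = probs)
  }
  path <- list()
  for (i in seq_len(njump)) {
    if (states[i + 1] != states[i])
      path[[length(path) + 1]] <- c(time = times[i], from = states[i],
                                    to = states[i + 1])
  }
  path
}

# add anagenetic and jump dispersal events to a count matrix, with the
# 1/|source-range| fractional attribution
count_dispersal <- function(counts, from_set, gained_area) {
  w <- 1 / length(from_set)
  for (a in from_set)
    counts[a, gained_area] <- counts[a, gained_area] + w
  counts
}

#' Stochastic mapping of DEC range histories
#'
#' Samples complete range histories conditional on the tip ranges and
#' fitted parameters: node states from the conditional likelihoods,
#' cladogenetic events from their posterior weights, and branch histories
#' endpoint-conditioned by rejection sampling with a uniformization
#' fallback. Every anagenetic gain of area b by a range r adds 1/|r| to
#' each (a in r -> b) cell of the dispersal-count matrix; cladogenetic
#' jumps are attributed the same way. Cell means over replicates are
#' returned.
#'
#' @inheritParams dec_loglik
#' @param n_maps Number of stochastic maps (the reference analysis
#'   used 50).
#' @param seed Integer seed.
#' @param max_try Rejection-sampling retry cap per branch before falling
#'   back to uniformization.
#' @return List: `mean_counts` (areas x areas matrix of mean dispersal
#'   counts), `per_map` (list of per-replicate matrices), `node_states`
#'   (matrix of sampled state indices, nodes x maps).
#' @export
dec_stochastic_map <- function(tree, ranges, params, space, n_maps = 50,
                               seed = 1, max_try = 50) {
  set.seed(seed)
  pr <- dec_prune(tree, ranges, params, space)
  n <- length(tree$tip.label)
  root <- n + 1L
  ns <- length(space$masks)
  A <- length(space$areas)
  nonnull <- which(space$masks != 0)
  prior <- numeric(ns); prior[nonnull] <- 1 / length(nonnull)
  kids_edges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  per_map <- vector("list", n_maps)
  node_states <- matrix(NA_integer_, n + tree$Nnode, n_maps)
  for (mp in seq_len(n_maps)) {
    counts <- matrix(0, A, A, dimnames = list(space$areas, space$areas))
    # root state
    wroot <- prior * pr$Lnode[, root]
    st <- integer(n + tree$Nnode)
    st[root] <- sample.int(ns, 1, prob = wroot)
    # preorder: at each internal node sample the cladogenetic event, then
    # each child's endpoint and branch history
    ord <- rev(ape::reorder.phylo(tree, "postorder")$edge[, 1L])
    visit <- unique(c(root, ord))
    for (nd in visit) {
      edges <- kids_edges[[as.character(nd)]]
      if (is.null(edges)) next
      ev <- pr$clado[[st[nd]]]
      wev <- ev$prob * pr$Lup[ev$left, edges[1]] * pr$Lup[ev$right, edges[2]]
      pick <- ev[sample.int(nrow(ev), 1, prob = wev), ]
      if (pick$type == "jump") {
        jd <- if (pick$left == st[nd]) pick$right else pick$left
        counts <- count_dispersal(counts, space$sets[[st[nd]]],
                                  space$sets[[jd]][1])
      }
      starts <- c(pick$left, pick$right)
      for (ci in 1:2) {
        e <- edges[ci]
        ch <- tree$edge[e, 2L]
        from <- starts[ci]
        Pe <- pr$P[[e]]
        wend <- Pe[from, ] * pr$Lnode[, ch]
        to <- sample.int(ns, 1, prob = wend)
        st[ch] <- to
        path <- sample_path_reject(pr$Q, from, to, tree$edge.length[e],
                                   max_try)
        if (is.null(path))
          path <- sample_path_unif(pr$Q, Pe, from, to, tree$edge.length[e])
        for (step in path) {
          mf <- space$masks[step["from"]]; mt <- space$masks[step["to"]]
          gained <- bitwAnd(mt, bitwNot(mf))
          if (gained > 0) {
            ga <- which(bitwAnd(gained, 2^(0:(A - 1))) > 0)
            counts <- count_dispersal(counts,
                                      space$sets[[step[["from"]]]], ga[1])
          }
        }
      }
    }
    node_states[, mp] <- st
    per_map[[mp]] <- counts
  }
  mean_counts <- Reduce(`+`, per_map) / n_maps
  list(mean_counts = mean_counts, per_map = per_map,
       node_states = node_states)
}
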