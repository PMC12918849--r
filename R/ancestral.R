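# Continuous-character ancestral reconstruction under Brownian motion and
# geographic-centroid utilities.

#' Geographic centroid of a species' occurrence records
#'
#' Arithmetic mean latitude and longitude (decimal degrees, south and west
#' negative) over unexcluded records. The genus analyzed here spans a
#' small, connected region well away from the antimeridian, so plain
#' averaging is free of wrap-around artifacts.
#'
#' @param occurrences Data frame with columns `species`, `lat`, `lon` and
#'   optionally logical `exclude` (misidentified records etc.).
#' @param species Species to summarize (default: all present).
#' @param dedup Drop duplicated (lat, lon) pairs per species first.
#' @return Data frame `species`, `lat`, `lon`, `n_records`.
#' @export
sp_centroid <- function(occurrences, species = NULL, dedup = FALSE) {
  stopifnot(all(c("species", "lat", "lon") %in% names(occurrences)))
  if (any(abs(occurrences$lat) > 90) || any(abs(occurrences$lon) > 180))
    stop("coordinates outside valid ranges")
  if (is.null(species)) species <- unique(occurrences$species)
  occ <- occurrences
  if (!is.null(occ$exclude)) occ <- occ[!occ$exclude, , drop = FALSE]
  out <- lapply(species, function(sp) {
    rec <- occ[occ$species == sp, , drop = FALSE]
    if (dedup) rec <- rec[!duplicated(rec[, c("lat", "lon")]), , drop = FALSE]
    if (!nrow(rec)) stop("no unexcluded records for species '", sp, "'")
    data.frame(species = sp, lat = mean(rec$lat), lon = mean(rec$lon),
               n_records = nrow(rec), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# covariance between internal nodes and tips under BM: shared path length
# from the root to the MRCA of each (node, tip) pair
anc_tip_cov <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)  # (n+m) x (n+m) node numbers
  idx_anc <- seq.int(n + 1L, n + m)
  Cat <- matrix(0, m, n)
  for (i in seq_len(m))
    Cat[i, ] <- depth[mr[idx_anc[i], seq_len(n)]]
  rownames(Cat) <- idx_anc
  colnames(Cat) <- tree$tip.label
  Cat
}

#' ML ancestral states of a continuous character under Brownian motion
#'
#' Point estimates are the GLS/kriging values: the root state is the
#' phylogenetic mean mu = (1'C^-1 1)^-1 1'C^-1 x and each internal node's
#' state is mu + c_k' C^-1 (x - mu), with c_k the vector of shared path
#' lengths between node k and the tips. These coincide with the
#' re-rooted-GLS (maximum likelihood) reconstruction. Variances are the
#' kriging variances with the uncertainty of the estimated mean added,
#' scaled by the ML rate estimate.
#'
#' @param tree Rooted `phylo` with positive branch lengths.
#' @param x Named numeric vector of tip values (names = tip labels).
#' @return Data frame with one row per internal node: `node`, `estimate`,
#'   `variance`; plus attributes `sigma2` (ML BM rate) and `root_state`.
#' @export
bm_ancestral <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (is.null(names(x))) {
    stopifnot(length(x) == n)
    names(x) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("tips without values: ", paste(miss, collapse = ", "))
  x <- x[tree$tip.label]
  if (!is.null(tree$edge.length) && any(tree$edge.length <= 0) &&
      any(tree$edge.length[tree$edge[, 2L] <= n] <= 0))
    stop("zero-length pendant branch makes the system singular; ",
         "jitter those branches")
  C <- phylo_vcv(tree)[tree$tip.label, tree$tip.label]
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance; jitter zero-length branches",
         call. = FALSE))
  one <- rep(1, n)
  denom <- drop(crossprod(one, Cinv %*% one))
  mu <- drop(crossprod(one, Cinv %*% x)) / denom
  r <- x - mu
  s2 <- drop(crossprod(r, Cinv %*% r)) / n  # ML rate
  Cat <- anc_tip_cov(tree)
  est <- mu + drop(Cat %*% (Cinv %*% r))
  depth <- ape::node.depth.edgelength(tree)
  vars <- numeric(tree$Nnode)
  for (k in seq_len(tree$Nnode)) {
    ck <- Cat[k, ]
    q <- drop(crossprod(ck, Cinv %*% ck))
    mean_adj <- (1 - drop(crossprod(ck, Cinv %*% one)))^2 / denom
    vars[k] <- s2 * (depth[n + k] - q + mean_adj)
  }
  out <- data.frame(node = seq.int(n + 1L, n + tree$Nnode),
                    estimate = unname(est), variance = pmax(vars, 0))
  attr(out, "sigma2") <- s2
  attr(out, "root_state") <- unname(est[1])
  out
}

#' Ancestral geographic centroids
#'
#' Latitude and longitude are reconstructed independently as two
#' univariate Brownian characters over the centroid of each species
#' ([sp_centroid()]); the root estimate is the inferred area of origin.
#'
#' @param tree Rooted `phylo`.
#' @param centroids Data frame from [sp_centroid()] (columns `species`,
#'   `lat`, `lon`), one row per tip.
#' @return List: `lat`, `lon` (each a [bm_ancestral()] data frame) and
#'   `origin` (named vector, root latitude/longitude).
#' @export
ancestral_centroids <- function(tree, centroids) {
  stopifnot(all(c("species", "lat", "lon") %in% names(centroids)))
  lat <- setNames(centroids$lat, centroids$species)
  lon <- setNames(centroids$lon, centroids$species)
  rl <- bm_ancestral(tree, lat)
  rg <- bm_ancestral(tree, lon)
  list(lat = rl, lon = rg,
       origin = c(lat = attr(rl, "root_state"),
                  lon = attr(rg, "root_state")))
}
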