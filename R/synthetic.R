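# Seeded generators for every input the pipeline consumes, with the
# statistical structure the downstream analyses assume: birth-death
# species trees, traits with Brownian phylogenetic covariance plus linear
# environmental effects, occurrence clouds drifting on the tree,
# forward-simulated DEC range histories, and locus panels with planted
# bootstrap supports and controlled p-distances. Every generator records
# its ground truth so recovery tests never peek at internals.

#' Deterministic substream seeds
#'
#' Expands the scenario master seed into independent per-generator
#' substreams, so adding a generator never perturbs the draws of another.
#' Fixed offsets: species tree 1, traits 2, occurrences 3, ranges 4,
#' loci 5. The result always lies below 2^31.
#'
#' @param seed Master seed (integer).
#' @param stream Substream index (integer).
#' @return Integer seed.
#' @export
substream_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147483647L
}

#' Scenario configuration for the synthetic-data generators
#'
#' Defaults emulate the study system the package targets: a radiation of
#' 17 Andean rosette-plant species spanning 0-3900 m of elevation, 10
#' quantitative traits, one reticulation with inheritance probability
#' 0.254, ranges over 7 habitats, and target-capture locus panels.
#'
#' @param n_species Number of species.
#' @param birth,death Birth-death rates (per unit time) for the species
#'   tree.
#' @param tree_height Crown height of the conditioned species tree (time
#'   units; 5.6 mirrors the genus' crown age in Myr).
#' @param gamma Reticulation inheritance probability in (0, 1).
#' @param beta0,beta_elev,beta_temp,beta_prec Trait model intercept and
#'   slopes (per m, per degree C, per mm/yr).
#' @param sigma2_bm Brownian rate of the phylogenetic trait deviation.
#' @param elev_root,elev_sigma2 Root value (m) and BM rate of the
#'   elevation character; values are clamped to `[0, 3900]` m after
#'   simulation.
#' @param n_records Occurrence records per species.
#' @param dispersion Gaussian scatter (degrees) of records about the true
#'   centroid.
#' @param root_lat,root_lon Root centroid (decimal degrees; southern
#'   latitudes negative).
#' @param centroid_sigma2 BM rate (squared degrees per unit time) of
#'   centroid drift.
#' @param n_areas,d,e,j DEC range simulation: number of areas and rates.
#' @param n_loci,seq_length Locus panel size and alignment length.
#' @param target_pdist Target p-distance of each locus' reference/query
#'   pair (scalar or per-locus vector).
#' @param seed Master seed; all generators derive fixed substreams from
#'   it.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 17, birth = 0.55, death = 0.05,
                            tree_height = 5.6, gamma = 0.254,
                            beta0 = 50, beta_elev = -0.5, beta_temp = 0,
                            beta_prec = 0, sigma2_bm = 25,
                            elev_root = 2000, elev_sigma2 = 4e5,
                            n_records = 50, dispersion = 0.5,
                            root_lat = -21.9, root_lon = -64.8,
                            centroid_sigma2 = 1.5,
                            n_areas = 7, d = 0.05, e = 0.01, j = 0,
                            n_loci = 500, seq_length = 1000,
                            target_pdist = 0.15, seed = 1) {
  stopifnot(n_species >= 2, birth >= 0, death >= 0,
            gamma > 0, gamma < 1, sigma2_bm >= 0,
            n_areas >= 2, d >= 0, e >= 0, j >= 0,
            all(target_pdist >= 0), all(target_pdist < 1))
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate a species tree
#'
#' A rooted ultrametric birth-death tree conditioned on the number of
#' tips (via [ape::rphylo()]), rescaled to the configured crown height;
#' or, with `mode = "time"`, an unconditioned forward simulation stopped
#' at `tree_height` (lineage count then varies and the tree may go
#' extinct, returned as NULL).
#'
#' @param config [scenario_config()].
#' @param mode `"fixed_n"` (default) or `"time"`.
#' @return `phylo` with tips `sp01`, `sp02`, ... (or NULL for an extinct
#'   `"time"` run).
#' @export
gen_species_tree <- function(config = scenario_config(),
                             mode = c("fixed_n", "time")) {
  mode <- match.arg(mode)
  if (config$n_species <= 0) stop("n_species must be positive")
  set.seed(substream_seed(config$seed, 1L))
  if (mode == "fixed_n") {
    tr <- ape::rphylo(config$n_species, birth = config$birth,
                      death = config$death)
    tr$edge.length <- tr$edge.length * config$tree_height / tree_height(tr)
    tr$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
    return(tr)
  }
  forward_bd(config$birth, config$death, config$tree_height)
}

# unconditioned forward birth-death from a single lineage; NULL if extinct
forward_bd <- function(birth, death, t_max) {
  # alive lineages: birth time of each pendant edge
  alive <- data.frame(id = 1L, start = 0)
  splits <- list()  # (parent id, child ids, time)
  nextid <- 2L
  t <- 0
  repeat {
    k <- nrow(alive)
    if (k == 0L) return(NULL)
    rate <- k * (birth + death)
    t <- t + rexp(1, rate)
    if (t >= t_max) break
    i <- sample.int(k, 1)
    if (runif(1) < birth / (birth + death)) {
      splits[[length(splits) + 1]] <-
        list(id = alive$id[i], kids = c(nextid, nextid + 1L), time = t)
      alive <- rbind(alive[-i, ],
                     data.frame(id = c(nextid, nextid + 1L), start = t))
      nextid <- nextid + 2L
    } else {
      alive <- alive[-i, , drop = FALSE]
    }
  }
  n_tip <- nrow(alive)
  if (n_tip == 0L) return(NULL)
  # build newick recursively from the split records
  kid_of <- list(); time_of <- c()
  for (s in splits) {
    kid_of[[as.character(s$id)]] <- s$kids
    time_of[as.character(s$id)] <- s$time
  }
  tipno <- 0L
  rec <- function(id, start) {
    kk <- kid_of[[as.character(id)]]
    if (is.null(kk)) {
      if (!(id %in% alive$id)) return(NULL)  # extinct before t_max
      tipno <<- tipno + 1L
      return(sprintf("t%d:%g", tipno, t_max - start))
    }
    tsp <- time_of[as.character(id)]
    parts <- Filter(Negate(is.null),
                    lapply(kk, function(k2) rec(k2, tsp)))
    if (!length(parts)) return(NULL)
    if (length(parts) == 1L) {
      # splice through the extinct side, extending the branch
      child <- parts[[1]]
      lab <- sub(":[^:]*$", "", child)
      len <- as.numeric(sub("^.*:", "", child))
      return(sprintf("%s:%g", lab, len + tsp - start))
    }
    sprintf("(%s):%g", paste(unlist(parts), collapse = ","), tsp - start)
  }
  nwk <- rec(1L, 0)
  if (is.null(nwk)) return(NULL)
  if (!grepl("\\(", nwk)) return(NULL)  # single surviving lineage
  ape::read.tree(text = paste0(sub(":[^:]*$", "", nwk), ";"))
}

#' Simulate traits with phylogenetic covariance and environmental effects
#'
#' Elevation evolves by Brownian motion on the tree (clamped to
#' `[0, 3900]` m); temperature follows a lapse-rate relation with elevation
#' and precipitation an independent Brownian character. Each trait is
#' beta0 + beta_elev elev + beta_temp temp + beta_prec prec + u with
#' u ~ MVN(0, sigma2_bm C). True parameters travel with the result as the
#' `truth` attribute.
#'
#' @param tree Species tree (tips define the species list).
#' @param config [scenario_config()].
#' @param n_traits Number of replicate trait columns.
#' @param elev Optional named vector of fixed tip elevations (m); by
#'   default elevation is simulated by clamped BM.
#' @return Data frame (rownames = species) with `elev`, `temp`, `prec`
#'   and trait columns `trait1`...; attribute `truth` holds the
#'   generating parameters and the raw phylogenetic deviations.
#' @export
gen_traits <- function(tree, config = scenario_config(), n_traits = 10,
                       elev = NULL) {
  if (config$sigma2_bm < 0) stop("sigma2_bm must be non-negative")
  set.seed(substream_seed(config$seed, 2L))
  n <- length(tree$tip.label)
  C <- phylo_vcv(tree)[tree$tip.label, tree$tip.label]
  if (is.null(elev)) {
    elev_raw <- config$elev_root +
      drop(chol_mvn(C * config$elev_sigma2 / tree_height(tree)))
    elev <- pmin(pmax(elev_raw, 0), 3900)
  } else {
    elev <- unname(elev[tree$tip.label])
  }
  temp <- 26 - 0.0055 * elev + rnorm(n, 0, 0.5)      # lapse ~5.5 C/km
  prec <- pmax(200, 600 + drop(chol_mvn(C * 4e4 / tree_height(tree))))
  L <- if (config$sigma2_bm > 0) t(chol(config$sigma2_bm * C)) else NULL
  # per-trait slopes: scalar configs apply to every trait, vectors are
  # recycled, so panels can mix elevation-driven and temperature-driven
  # traits as real morphology panels do
  b0 <- rep(config$beta0, length.out = n_traits)
  be <- rep(config$beta_elev, length.out = n_traits)
  bt <- rep(config$beta_temp, length.out = n_traits)
  bp <- rep(config$beta_prec, length.out = n_traits)
  traits <- matrix(0, n, n_traits)
  u <- matrix(0, n, n_traits)
  for (k in seq_len(n_traits)) {
    if (!is.null(L)) u[, k] <- drop(L %*% rnorm(n))
    traits[, k] <- b0[k] + be[k] * elev + bt[k] * temp + bp[k] * prec +
      u[, k]
  }
  colnames(traits) <- paste0("trait", seq_len(n_traits))
  out <- data.frame(elev = elev, temp = temp, prec = prec, traits)
  rownames(out) <- tree$tip.label
  attr(out, "truth") <- list(beta0 = b0, beta_elev = be, beta_temp = bt,
                             beta_prec = bp,
                             sigma2_bm = config$sigma2_bm, u = u)
  out
}

chol_mvn <- function(Sigma) {
  if (all(Sigma == 0)) return(rep(0, nrow(Sigma)))
  t(chol(Sigma)) %*% rnorm(nrow(Sigma))
}

#' Simulate occurrence records around drifting centroids
#'
#' Each species' true centroid evolves by independent bivariate Brownian
#' motion from the configured root location (southern latitudes
#' negative); records scatter around it with isotropic Gaussian noise.
#'
#' @param tree Species tree.
#' @param config [scenario_config()].
#' @return Data frame `species`, `lat`, `lon`; attribute `truth` holds
#'   the per-species true centroids and the root location.
#' @export
gen_occurrences <- function(tree, config = scenario_config()) {
  if (config$dispersion < 0) stop("dispersion must be positive")
  set.seed(substream_seed(config$seed, 3L))
  C <- phylo_vcv(tree)[tree$tip.label, tree$tip.label]
  Cs <- C * config$centroid_sigma2 / tree_height(tree)
  lat <- config$root_lat + drop(chol_mvn(Cs))
  lon <- config$root_lon + drop(chol_mvn(Cs))
  lat <- pmin(pmax(lat, -90), 90)
  lon <- pmin(pmax(lon, -180), 180)
  n <- length(tree$tip.label)
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(species = tree$tip.label[i],
               lat = rnorm(config$n_records, lat[i], config$dispersion),
               lon = rnorm(config$n_records, lon[i], config$dispersion),
               stringsAsFactors = FALSE)
  }))
  recs$lat <- pmin(pmax(recs$lat, -90), 90)
  recs$lon <- pmin(pmax(recs$lon, -180), 180)
  attr(recs, "truth") <- list(
    centroids = data.frame(species = tree$tip.label, lat = lat, lon = lon),
    root = c(lat = config$root_lat, lon = config$root_lon))
  recs
}

#' Forward-simulate DEC range histories
#'
#' Ranges evolve root-to-tips under exactly the anagenetic rates and
#' cladogenetic event weights of the DEC likelihood ([build_dec_q()],
#' [cladogenesis_events()]): Gillespie simulation along branches, event
#' sampling at nodes. Trees whose simulation leaves any lineage rangeless
#' are resimulated up to `max_retry` times. Every dispersal (anagenetic
#' gain or cladogenetic jump) is logged for mapping-recovery tests.
#'
#' @param tree Time-scaled species tree.
#' @param config [scenario_config()] (fields `n_areas`, `d`, `e`, `j`).
#' @param root_range Integer vector of area indices at the root (default
#'   a single random area).
#' @param max_retry Resimulation cap.
#' @return List: `ranges` (binary species x areas matrix), `event_log`
#'   (data.frame: map of every dispersal with source areas and gained
#'   area), `node_states` (range index per node), `n_retries`, `space`.
#' @export
gen_ranges <- function(tree, config = scenario_config(), root_range = NULL,
                       max_retry = 100) {
  stopifnot(config$d >= 0, config$e >= 0, config$n_areas >= 2)
  set.seed(substream_seed(config$seed, 4L))
  space <- dec_state_space(paste0("H", seq_len(config$n_areas)))
  params <- dec_params(config$d, config$e, config$j)
  Q <- build_dec_q(params, space)
  ns <- length(space$masks)
  n <- length(tree$tip.label)
  root <- n + 1L
  kids_edges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  clado <- lapply(seq_len(ns), function(i)
    if (space$masks[i] == 0) NULL
    else cladogenesis_events(i, space, config$j))
  for (attempt in seq_len(max_retry)) {
    log_rows <- list()
    st <- integer(n + tree$Nnode)
    st[root] <- if (is.null(root_range))
      space$index_of_mask[2^(sample.int(config$n_areas, 1) - 1) + 1]
    else space$index_of_mask[range_mask(space, root_range) + 1]
    ok <- TRUE
    # preorder over internal nodes
    visit <- unique(rev(ape::reorder.phylo(tree, "postorder")$edge[, 1L]))
    for (nd in visit) {
      edges <- kids_edges[[as.character(nd)]]
      ev <- clado[[st[nd]]]
      pick <- ev[sample.int(nrow(ev), 1, prob = ev$prob), ]
      if (pick$type == "jump") {
        jd <- if (pick$left == st[nd]) pick$right else pick$left
        log_rows[[length(log_rows) + 1]] <- data.frame(
          node = nd, type = "jump",
          source = paste(space$sets[[st[nd]]], collapse = "+"),
          gained = space$sets[[jd]][1])
      }
      starts <- c(pick$left, pick$right)
      for (ci in 1:2) {
        e <- edges[ci]
        ch <- tree$edge[e, 2L]
        s <- starts[ci]
        t <- 0; t_len <- tree$edge.length[e]
        repeat {
          rate <- -Q[s, s]
          if (rate <= 0) break
          t <- t + rexp(1, rate)
          if (t >= t_len) break
          probs <- Q[s, ]; probs[s] <- 0
          s2 <- sample.int(ns, 1, prob = probs)
          gained <- bitwAnd(space$masks[s2], bitwNot(space$masks[s]))
          if (gained > 0)
            log_rows[[length(log_rows) + 1]] <- data.frame(
              node = ch, type = "dispersal",
              source = paste(space$sets[[s]], collapse = "+"),
              gained = which(bitwAnd(gained,
                                     2^(0:(config$n_areas - 1))) > 0)[1])
          s <- s2
        }
        if (space$masks[s] == 0) { ok <- FALSE; break }
        st[ch] <- s
      }
      if (!ok) break
    }
    if (ok) {
      ranges <- t(vapply(seq_len(n), function(i) {
        as.integer(seq_len(config$n_areas) %in% space$sets[[st[i]]])
      }, integer(config$n_areas)))
      dimnames(ranges) <- list(tree$tip.label, space$areas)
      ev_log <- if (length(log_rows)) do.call(rbind, log_rows)
        else data.frame(node = integer(0), type = character(0),
                        source = character(0), gained = integer(0))
      return(list(ranges = ranges, event_log = ev_log, node_states = st,
                  n_retries = attempt - 1L, space = space))
    }
  }
  stop("lineages kept going extinct after ", max_retry,
       " attempts; lower e (or raise d)")
}

#' True dispersal-count matrix from a forward-simulation event log
#'
#' Applies the same fractional attribution rule as the stochastic mapper:
#' a gain of area b from source range r adds 1/|r| to each (a in r -> b)
#' cell.
#'
#' @param event_log From [gen_ranges()].
#' @param areas Area labels.
#' @return areas x areas numeric matrix.
#' @export
dispersal_counts_from_log <- function(event_log, areas) {
  A <- length(areas)
  counts <- matrix(0, A, A, dimnames = list(areas, areas))
  for (i in seq_len(nrow(event_log))) {
    src <- as.integer(strsplit(event_log$source[i], "\\+")[[1]])
    counts <- count_dispersal(counts, src, event_log$gained[i])
  }
  counts
}

#' Generate a target-capture locus panel with planted supports
#'
#' Each locus gets (i) a random topology on `n_species` tips whose
#' internal-node supports are drawn from a planted per-locus support
#' distribution (a high-support and a low-support regime mixed in
#' configurable proportion), and (ii) a reference/query sequence pair of
#' length `seq_length` whose realized p-distance equals
#' round(target * L)/L, within 0.5/L of the per-locus target. Sequence
#' divergence uses a two-taxon Jukes-Cantor-style substitution at the
#' planted sites.
#'
#' @param config [scenario_config()].
#' @param n_taxa Tips per locus tree.
#' @param p_high Proportion of loci in the high-support regime.
#' @param high_range,low_range Support ranges (0-100) of the two regimes.
#' @return List: `trees` (named list of `phylo` with support labels),
#'   `ref_seqs`, `query_seqs` (named character vectors), `truth`
#'   (data frame of planted regime and target distance per locus).
#' @export
gen_loci <- function(config = scenario_config(), n_taxa = 10,
                     p_high = 0.7, high_range = c(90, 100),
                     low_range = c(0, 69)) {
  set.seed(substream_seed(config$seed, 5L))
  L <- config$seq_length
  targets <- rep(config$target_pdist, length.out = config$n_loci)
  if (any(round(targets * L) / L > 1))
    stop("target p-distance unreachable at sequence length ", L)
  loci <- sprintf("locus%04d", seq_len(config$n_loci))
  regime <- ifelse(runif(config$n_loci) < p_high, "high", "low")
  trees <- vector("list", config$n_loci)
  ref <- character(config$n_loci); qry <- character(config$n_loci)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(config$n_loci)) {
    tr <- ape::rtree(n_taxa)
    rng <- if (regime[i] == "high") high_range else low_range
    tr$node.label <- c("", as.character(round(
      runif(tr$Nnode - 1L, rng[1], rng[2]))))
    trees[[i]] <- tr
    s <- sample(bases, L, replace = TRUE)
    q <- s
    nmut <- round(targets[i] * L)
    pos <- sample.int(L, nmut)
    for (p in pos) q[p] <- sample(setdiff(bases, s[p]), 1)
    ref[i] <- paste(s, collapse = "")
    qry[i] <- paste(q, collapse = "")
  }
  names(trees) <- loci
  list(trees = trees,
       ref_seqs = setNames(ref, loci), query_seqs = setNames(qry, loci),
       truth = data.frame(locus = loci, regime = regime,
                          target_pdist = targets,
                          realized_pdist = round(targets * L) / L,
                          stringsAsFactors = FALSE))
}

#' Packaged 17-species study fixture
#'
#' A stylized ultrametric phylogeny of the 17 species of a high-Andean
#' terrestrial bromeliad radiation, with the six strongly supported
#' clades (A-F) in their published backbone order (F, then E, then D
#' sister to the remainder), crown height 5.6, tip elevations drawn from
#' the species' published elevational ranges, and synthetic traits,
#' occurrences and habitat ranges keyed to the tree. Branch lengths and
#' within-clade resolution are synthetic stand-ins.
#'
#' @param seed Master seed for the attached synthetic data.
#' @return List: `tree` (`phylo`, 17 tips), `clades` (named list A-F),
#'   `elevations` (named vector, m), `traits`, `occurrences`, `ranges`,
#'   `network` (the single published-style reticulation, gamma = 0.254).
#' @export
fixture_deuterocohnia <- function(seed = 1) {
  nwk <- paste0(
    "((((((recurvipetala:0.8,longipetala:0.8):0.5,",
    "(haumanii:0.9,glandulosa:0.9):0.4):1.2,",
    "(sanctae_crucis:1.6,(gableana:1.0,scapigera:1.0):0.6):0.9):0.7,",
    "(lotteae:1.9,(abstrusa:1.2,brevifolia:1.2):0.7):1.3):0.9,",
    "((schreiteri:1.4,digitata:1.4):1.5,",
    "(chrysantha:2.0,strobilifera:2.0):0.9):1.2):1.5,",
    "(brevispicata:2.4,(meziana:1.5,seramisiana:1.5):0.9):3.2);")
  tree <- parse_newick(nwk)
  clades <- list(
    A = c("recurvipetala", "longipetala", "haumanii", "glandulosa"),
    B = c("sanctae_crucis", "gableana", "scapigera"),
    C = c("lotteae", "abstrusa", "brevifolia"),
    D = c("schreiteri", "digitata"),
    E = c("chrysantha", "strobilifera"),
    F = c("brevispicata", "meziana", "seramisiana"))
  # mid-range elevations (m) consistent with the published spans, e.g.
  # 200-2200 (meziana), 1200-2200 (brevispicata), 2000-2400 (seramisiana),
  # coastal-desert chrysantha lowest, strobilifera highest
  elevations <- c(
    recurvipetala = 800, longipetala = 1500, haumanii = 1800,
    glandulosa = 2000, sanctae_crucis = 1900, gableana = 2100,
    scapigera = 2900, lotteae = 3000, abstrusa = 2800, brevifolia = 3100,
    schreiteri = 2400, digitata = 3200, chrysantha = 400,
    strobilifera = 3500, brevispicata = 1700, meziana = 1200,
    seramisiana = 2200)
  # vegetative/inflorescence traits (1-5) decline with elevation, floral
  # traits (6-8) track temperature, traits 9-10 carry only phylogenetic
  # signal -- the qualitative structure of the published trait panel
  cfg <- scenario_config(seed = seed,
                         beta_elev = c(rep(-0.5, 5), rep(0, 5)),
                         beta_temp = c(rep(0, 5), 2, 2, 2, 0, 0))
  traits <- gen_traits(tree, cfg, elev = elevations)
  occ <- gen_occurrences(tree, cfg)
  rng <- gen_ranges(tree, cfg)
  # gene flow from the sanctae_crucis lineage into the stem of clade F,
  # placed at the most recent time where both host branches co-exist
  # (the donor lineage is then part of the clade-B stem)
  net <- retic_network(coalescent_rescale(tree),
                       donor = clades$B,
                       recipient = clades$F,
                       time = 2.2, gamma = 0.254)
  list(tree = tree, clades = clades, elevations = elevations,
       traits = traits, occurrences = occ, ranges = rng, network = net)
}

#' Rescale a time tree to coalescent units
#'
#' Maps the crown height to a chosen depth in coalescent units so a dated
#' tree can drive the MSC simulator.
#'
#' @param tree Ultrametric `phylo`.
#' @param height_cu Target crown height in coalescent units.
#' @return `phylo` with rescaled branch lengths.
#' @export
coalescent_rescale <- function(tree, height_cu = 5) {
  tree$edge.length <- tree$edge.length * height_cu / tree_height(tree)
  tree
}

#' Write a scenario bundle to plain-text files
#'
#' Newick for trees, CSV for tables, FASTA for sequences, and a JSON
#' sidecar holding every ground-truth parameter, so downstream recovery
#' tests can read truth without touching generator internals.
#'
#' @param bundle List from [fixture_deuterocohnia()] (or a compatible
#'   assembly of generator outputs).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wf <- function(path) { files <<- c(files, path); path }
  ape::write.tree(bundle$tree, wf(file.path(dir, "species_tree.nwk")))
  utils::write.csv(bundle$traits, wf(file.path(dir, "traits.csv")))
  utils::write.csv(bundle$occurrences,
                   wf(file.path(dir, "occurrences.csv")), row.names = FALSE)
  utils::write.csv(bundle$ranges$ranges, wf(file.path(dir, "ranges.csv")))
  truth <- list(trait_truth = attr(bundle$traits, "truth")[
                  c("beta0", "beta_elev", "beta_temp", "beta_prec",
                    "sigma2_bm")],
                centroid_truth = attr(bundle$occurrences, "truth"),
                range_events = bundle$ranges$event_log,
                elevations = as.list(bundle$elevations))
  jsonlite::write_json(truth, wf(file.path(dir, "truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}
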