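test_that("generators are deterministic under the scenario seed", {
  cfg <- scenario_config(n_species = 8, seed = 42)
  t1 <- gen_species_tree(cfg)
  t2 <- gen_species_tree(cfg)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_identical(gen_traits(t1, cfg), gen_traits(t1, cfg))
  expect_identical(gen_occurrences(t1, cfg), gen_occurrences(t1, cfg))
  r1 <- gen_ranges(t1, cfg)
  r2 <- gen_ranges(t1, cfg)
  expect_identical(r1$ranges, r2$ranges)
  expect_identical(r1$event_log, r2$event_log)
  l1 <- gen_loci(scenario_config(n_loci = 5, seed = 42))
  l2 <- gen_loci(scenario_config(n_loci = 5, seed = 42))
  expect_identical(l1$ref_seqs, l2$ref_seqs)
  # substreams: changing one generator's consumption leaves others alone
  cfgb <- scenario_config(n_species = 8, seed = 42, n_loci = 99)
  expect_identical(write_newick(gen_species_tree(cfgb)), write_newick(t1))
})

test_that("species trees are rooted ultrametric with the configured size", {
  cfg <- scenario_config(n_species = 17, seed = 3)
  tr <- gen_species_tree(cfg)
  expect_equal(length(tr$tip.label), 17L)
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(tr)), cfg$tree_height)
  expect_error(gen_species_tree(scenario_config(n_species = 0)),
               "n_species")
})

test_that("unconditioned birth-death mean tip count matches E[N(t)]", {
  # E[N(t)] = exp((b - d) t) from one founder lineage
  b <- 0.9; d <- 0.3; tmax <- 2
  cfg <- scenario_config(n_species = 5, birth = b, death = d,
                         tree_height = tmax, seed = 99)
  set.seed(substream_seed(cfg$seed, 1L))
  counts <- vapply(1:1000, function(i) {
    tr <- phylodiscord:::forward_bd(b, d, tmax)
    if (is.null(tr)) 0 else length(tr$tip.label)
  }, numeric(1))
  expected <- exp((b - d) * tmax)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("trait generator honors degenerate and near-deterministic cases", {
  cfg0 <- scenario_config(n_species = 10, seed = 5, sigma2_bm = 0,
                          beta_elev = 0, beta_temp = 0, beta_prec = 0,
                          beta0 = 7)
  tr <- gen_species_tree(cfg0)
  tt <- gen_traits(tr, cfg0, n_traits = 3)
  expect_true(all(tt[, paste0("trait", 1:3)] == 7))
  expect_true(all(tt$elev >= 0 & tt$elev <= 3900))

  # tiny noise: OLS slope on elevation ~ planted value
  cfg1 <- scenario_config(n_species = 40, seed = 6, sigma2_bm = 1e-8,
                          beta_elev = -0.5)
  tr1 <- gen_species_tree(cfg1)
  t1 <- gen_traits(tr1, cfg1, n_traits = 1)
  sl <- coef(lm(trait1 ~ elev, data = t1))["elev"]
  expect_equal(unname(sl), -0.5, tolerance = 1e-3)
  expect_error(gen_traits(tr1, scenario_config(sigma2_bm = -1)),
               "sigma2_bm|not")
})

test_that("phylogenetic trait deviations have covariance proportional to C", {
  cfg <- scenario_config(n_species = 8, seed = 7, sigma2_bm = 4,
                         beta_elev = 0)
  tr <- gen_species_tree(cfg)
  C <- phylo_vcv(tr)[tr$tip.label, tr$tip.label]
  U <- do.call(cbind, lapply(1:400, function(r) {
    attr(gen_traits(tr, scenario_config(n_species = 8, seed = 7000 + r,
                                        sigma2_bm = 4, beta_elev = 0),
                    n_traits = 1), "truth")$u[, 1]
  }))
  Chat <- U %*% t(U) / ncol(U)
  # elementwise within 3 SE of 4C (SE of a cross-moment estimate)
  for (i in 1:8) for (j in 1:8) {
    se <- sqrt((4 * C[i, i] * 4 * C[j, j] + (4 * C[i, j])^2) / ncol(U))
    expect_lt(abs(Chat[i, j] - 4 * C[i, j]), 4 * se)
  }
})

test_that("occurrence clouds center on the true centroids", {
  cfg <- scenario_config(n_species = 5, seed = 8, n_records = 4000,
                         dispersion = 0.4)
  tr <- gen_species_tree(cfg)
  occ <- gen_occurrences(tr, cfg)
  truth <- attr(occ, "truth")$centroids
  cen <- sp_centroid(occ)
  m <- merge(cen, truth, by = "species")
  se <- 0.4 / sqrt(4000)
  expect_true(all(abs(m$lat.x - m$lat.y) < 4 * se))
  expect_true(all(abs(m$lon.x - m$lon.y) < 4 * se))

  tiny <- scenario_config(n_species = 5, seed = 8, n_records = 10,
                          dispersion = 1e-9)
  occ0 <- gen_occurrences(tr, tiny)
  cen0 <- sp_centroid(occ0)
  t0 <- attr(occ0, "truth")$centroids
  expect_equal(cen0$lat, t0$lat[match(cen0$species, t0$species)],
               tolerance = 1e-6)
})

test_that("range simulation respects degenerate rates and logs events", {
  cfg <- scenario_config(n_species = 6, seed = 9, d = 0, e = 0, n_areas = 3)
  tr <- gen_species_tree(cfg)
  rr <- gen_ranges(tr, cfg, root_range = 1)
  expect_true(all(rr$ranges[, 1] == 1))
  expect_true(all(rr$ranges[, 2:3] == 0))
  expect_equal(nrow(rr$event_log), 0L)

  # strong dispersal, no extinction: ranges tend to the full area set
  cfg2 <- scenario_config(n_species = 6, seed = 10, d = 3, e = 0,
                          n_areas = 3)
  rr2 <- gen_ranges(tr, cfg2, root_range = 1)
  expect_gt(mean(rr2$ranges), 0.9)
  expect_gt(nrow(rr2$event_log), 0)
})

test_that("locus panel distances hit their targets", {
  cfg <- scenario_config(n_loci = 10, seq_length = 10000, seed = 11,
                         target_pdist = 0.15)
  panel <- gen_loci(cfg)
  pd <- mapply(p_distance, panel$ref_seqs, panel$query_seqs)
  expect_true(all(pd >= 0.14 & pd <= 0.16))
  cfg0 <- scenario_config(n_loci = 3, seed = 11, target_pdist = 0)
  p0 <- gen_loci(cfg0)
  expect_identical(p0$ref_seqs, p0$query_seqs)
})

test_that("study fixture has the published structure", {
  fx <- fixture
  expect_equal(length(fx$tree$tip.label), 17L)
  expect_true(ape::is.ultrametric(fx$tree, tol = 1e-8))
  # clade F sister to everything else
  expect_true(is_monophyletic(fx$tree, fx$clades$F))
  rest <- setdiff(fx$tree$tip.label, fx$clades$F)
  expect_true(is_monophyletic(fx$tree, rest))
  for (cl in fx$clades) expect_true(is_monophyletic(fx$tree, cl))
  expect_true(all(fx$elevations >= 0 & fx$elevations <= 3900))
  expect_equal(nrow(fx$traits), 17L)
  expect_equal(fx$network$events$gamma, 0.254)
})

test_that("write_scenario emits plain-text files with a truth sidecar", {
  dir <- tempfile("scen")
  files <- write_scenario(fixture, dir)
  expect_true(all(file.exists(files)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$trait_truth$sigma2_bm, 25)
  tr <- parse_newick(paste(readLines(file.path(dir, "species_tree.nwk")),
                           collapse = ""))
  expect_equal(length(tr$tip.label), 17L)
})
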