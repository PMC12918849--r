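test_that("state space enumerates all non-empty subsets plus null", {
  sp <- dec_state_space(paste0("H", 1:7))
  expect_equal(sp$n_states, 127L)
  expect_equal(length(sp$masks), 128L)
  expect_equal(sp$masks[1], 0)
  sp3 <- dec_state_space(c("a", "b", "c"), max_range_size = 2)
  expect_equal(sp3$n_states, 6L)
  expect_error(dec_state_space("one"), ">= 2")
})

test_that("reduce_areas drops autapomorphic habitats with the guard", {
  m <- matrix(c(1, 1, 0, 0,
                0, 1, 1, 0,
                0, 0, 1, 1), 3, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("H", 1:4)))
  # H1 only in s1 (which also has H2); H4 only in s3 (which has H3)
  out <- reduce_areas(m)
  expect_equal(colnames(out), c("H2", "H3"))
  # species occupying only an autapomorphic area keeps it
  m2 <- matrix(c(1, 0,
                 0, 1,
                 0, 1), 3, 2, byrow = TRUE,
               dimnames = list(paste0("s", 1:3), c("H1", "H2")))
  expect_identical(reduce_areas(m2), m2)
  m3 <- matrix(1, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
  expect_identical(reduce_areas(m3), m3)  # nothing autapomorphic
})

test_that("rate matrix has DEC structure and conserves probability", {
  sp <- dec_state_space(c("X", "Y"))
  Q <- build_dec_q(dec_params(0.3, 0.1), sp)
  iX <- sp$index_of_mask[1 + 1]; iY <- sp$index_of_mask[2 + 1]
  iXY <- sp$index_of_mask[3 + 1]
  expect_equal(Q[iX, iXY], 0.3)           # {X} -> {X,Y} at d|r| = d
  expect_equal(Q[iXY, iX], 0.1)           # {X,Y} -> {X} at e
  expect_equal(Q[iX, 1], 0.1)             # {X} -> null at e
  expect_true(all(Q[1, ] == 0))           # null absorbing
  for (i in 1:20) {
    set.seed(i)
    sp5 <- dec_state_space(paste0("H", 1:5))
    Q5 <- build_dec_q(dec_params(runif(1, 0, 2), runif(1, 0, 1)), sp5)
    expect_true(all(abs(rowSums(Q5)) < 1e-12))
    expect_equal(build_dec_q(dec_params(0, 0), sp5),
                 matrix(0, 32, 32))
  }
})

test_that("cladogenesis tables are normalized with the expected events", {
  sp <- dec_state_space(c("X", "Y", "Z"))
  single <- sp$index_of_mask[1 + 1]
  ev1 <- cladogenesis_events(single, sp, j = 0)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$prob, 1)
  expect_equal(ev1$type, "sympatry")

  pair <- sp$index_of_mask[3 + 1]  # {X,Y}
  ev2 <- cladogenesis_events(pair, sp, j = 0)
  expect_equal(nrow(ev2), 6L)
  expect_equal(ev2$prob, rep(1 / 6, 6))
  expect_equal(sum(ev2$type == "subset_sympatry"), 4L)
  expect_equal(sum(ev2$type == "vicariance"), 2L)

  # jump weight dominates as j grows
  evj <- cladogenesis_events(single, sp, j = 1000)
  expect_gt(sum(evj$prob[evj$type == "jump"]), 0.99)
  # normalization across all ranges up to 7 areas
  sp7 <- dec_state_space(paste0("H", 1:7))
  for (i in sample(which(sp7$masks != 0), 15)) {
    ev <- cladogenesis_events(i, sp7, j = 0.5)
    expect_equal(sum(ev$prob), 1, tolerance = 1e-12)
  }
  expect_error(cladogenesis_events(1, sp, 0), "null")
})

test_that("likelihood matches the dense oracle over a (d, e) grid", {
  fx <- two_area_fixture()
  for (d in c(0.05, 0.2, 0.5, 1, 2)) {
    for (e in c(0.01, 0.1, 0.3, 0.6, 1)) {
      par <- dec_params(d, e)
      expect_equal(dec_loglik(fx$tree, fx$ranges, par, fx$space),
                   oracle_2tip_loglik(fx$tree, fx$ranges, par, fx$space),
                   tolerance = 1e-8)
    }
  }
})

test_that("degenerate and symmetric likelihood cases behave", {
  sp <- dec_state_space(c("X", "Y"))
  tr <- parse_newick("(A:1,B:1);")
  rgX <- matrix(c(1, 1, 0, 0), 2, 2,
                dimnames = list(c("A", "B"), c("X", "Y")))
  # d = e = 0: nothing moves, likelihood is the root prior of {X}
  ll <- dec_loglik(tr, rgX, dec_params(0, 0), sp)
  expect_equal(ll, log(1 / 3), tolerance = 1e-10)
  # relabeling areas permutes nothing observable
  rgY <- rgX[, c(2, 1)]
  colnames(rgY) <- c("X", "Y")
  expect_equal(dec_loglik(tr, rgY, dec_params(0.3, 0.1), sp),
               dec_loglik(tr, rgX, dec_params(0.3, 0.1), sp),
               tolerance = 1e-10)
})

test_that("DEC+J at j = 0 reproduces plain DEC exactly", {
  fx <- two_area_fixture()
  par0 <- dec_params(0.4, 0.1, j = 0)
  expect_equal(dec_loglik(fx$tree, fx$ranges, par0, fx$space),
               dec_loglik(fx$tree, fx$ranges, dec_params(0.4, 0.1),
                          fx$space), tolerance = 1e-10)
  cfg <- scenario_config(n_species = 8, n_areas = 3, d = 0.4, e = 0.05,
                         seed = 21)
  tr <- gen_species_tree(cfg)
  rr <- gen_ranges(tr, cfg)
  fit0 <- fit_dec(tr, rr$ranges, rr$space, "DEC", n_starts = 2, seed = 1)
  fitj <- fit_dec(tr, rr$ranges, rr$space, "DEC+J", n_starts = 2, seed = 1)
  expect_gte(fitj$loglik, fit0$loglik - 1e-6)  # nesting
  cmp <- dec_model_compare(fit0, fitj)
  expect_equal(cmp$delta_aic[1], 0)
})

test_that("ML fitting is seeded-reproducible and rank-recovers d", {
  cfg <- scenario_config(n_species = 20, n_areas = 3, d = 0.3, e = 0.03,
                         seed = 31)
  tr <- gen_species_tree(cfg)
  rr <- gen_ranges(tr, cfg)
  f1 <- fit_dec(tr, rr$ranges, rr$space, "DEC", n_starts = 2, seed = 5)
  f2 <- fit_dec(tr, rr$ranges, rr$space, "DEC", n_starts = 2, seed = 5)
  expect_identical(f1$params, f2$params)
  # d-hat rank-correlates with the planted d across a 3-point grid
  dhat <- vapply(c(0.05, 0.3, 1.2), function(d_true) {
    est <- vapply(1:3, function(r) {
      cfg2 <- scenario_config(n_species = 20, n_areas = 3, d = d_true,
                              e = 0.03, seed = 100 * d_true + r + 40)
      tr2 <- gen_species_tree(cfg2)
      rr2 <- gen_ranges(tr2, cfg2)
      fit_dec(tr2, rr2$ranges, rr2$space, "DEC", n_starts = 2,
              seed = r)$params$d
    }, numeric(1))
    median(est)
  }, numeric(1))
  expect_true(all(diff(dhat) > 0))
})

test_that("stochastic mapping is seeded and silent when d = 0", {
  sp <- dec_state_space(c("X", "Y"))
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  rg <- matrix(c(1, 1, 1, 0, 0, 0), 3, 2,
               dimnames = list(c("A", "B", "C"), c("X", "Y")))
  sm <- dec_stochastic_map(tr, rg, dec_params(0, 0.0), sp, n_maps = 10,
                           seed = 2)
  expect_true(all(sm$mean_counts == 0))
  cfg <- scenario_config(n_species = 8, n_areas = 3, d = 0.4, e = 0.02,
                         seed = 61)
  tr2 <- gen_species_tree(cfg)
  rr <- gen_ranges(tr2, cfg)
  a <- dec_stochastic_map(tr2, rr$ranges, dec_params(0.4, 0.02),
                          rr$space, n_maps = 5, seed = 9)
  b <- dec_stochastic_map(tr2, rr$ranges, dec_params(0.4, 0.02),
                          rr$space, n_maps = 5, seed = 9)
  expect_identical(a$mean_counts, b$mean_counts)
  expect_true(all(a$mean_counts >= 0))
})

test_that("mapped dispersal counts track forward-simulated truth", {
  true_tot <- NULL; map_tot <- NULL
  for (ds in 1:5) {
    cfg <- scenario_config(n_species = 12, n_areas = 3, d = 0.25,
                           e = 0.02, seed = 500 + ds)
    tr <- gen_species_tree(cfg)
    rr <- gen_ranges(tr, cfg)
    tc <- dispersal_counts_from_log(rr$event_log, rr$space$areas)
    sm <- dec_stochastic_map(tr, rr$ranges, dec_params(0.25, 0.02),
                             rr$space, n_maps = 25, seed = ds)
    if (is.null(true_tot)) {
      true_tot <- tc; map_tot <- sm$mean_counts
    } else {
      true_tot <- true_tot + tc; map_tot <- map_tot + sm$mean_counts
    }
  }
  cells <- which(true_tot >= 5, arr.ind = TRUE)
  expect_gt(nrow(cells), 0)
  relerr <- abs(map_tot[cells] - true_tot[cells]) / true_tot[cells]
  expect_lt(mean(relerr), 0.35)
})
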