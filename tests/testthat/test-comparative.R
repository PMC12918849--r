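test_that("standardization z-scores and inverts exactly", {
  df <- data.frame(a = rnorm(10, 5, 2), b = runif(10, 0, 100))
  z <- standardize_traits(df)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(vapply(z, sd, 1)), c(1, 1), tolerance = 1e-12)
  back <- sweep(sweep(as.matrix(z), 2, attr(z, "scale"), `*`), 2,
                -attr(z, "center"))
  expect_equal(unname(back), unname(as.matrix(df)), tolerance = 1e-12)
  # location invariance of the standardized values
  z2 <- standardize_traits(transform(df, a = a + 100))
  expect_equal(z2$a, z$a, tolerance = 1e-12)
  expect_error(standardize_traits(data.frame(a = rep(1, 5))),
               "zero variance")
})

test_that("ppca matches the direct GLS matrix-algebra oracle", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  set.seed(1)
  X <- matrix(rnorm(9), 3, 3,
              dimnames = list(c("A", "B", "C"), paste0("x", 1:3)))
  C <- phylo_vcv(tr)[rownames(X), rownames(X)]
  got <- ppca(X, tr)
  want <- oracle_ppca(X, C)
  expect_equal(unname(got$ancestral_mean), unname(want$a),
               tolerance = 1e-10)
  expect_equal(unname(got$evo_cov), unname(want$R), tolerance = 1e-10)
  expect_equal(got$eigenvalues, pmax(want$lambda, 0), tolerance = 1e-10)
  expect_equal(sum(got$percent_var), 100)
  # scores reproduce (X - 1a) V
  expect_equal(got$scores,
               sweep(X, 2, got$ancestral_mean) %*% got$loadings)
})

test_that("ppca on a star tree equals ordinary PCA", {
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1.7, 6)
  star$tip.label <- paste0("s", 1:6)
  set.seed(2)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(star$tip.label, NULL))
  p1 <- ppca(X, star)
  p2 <- pca(X)
  expect_equal(p1$eigenvalues / sum(p1$eigenvalues),
               p2$eigenvalues / sum(p2$eigenvalues), tolerance = 1e-8)
  expect_equal(abs(p1$loadings), abs(p2$loadings), tolerance = 1e-8)
  # single trait: PC1 carries all variance
  expect_equal(ppca(X[, 1, drop = FALSE], star)$percent_var, 100)
})

test_that("pca matches the SVD route", {
  set.seed(3)
  X <- matrix(rnorm(40), 8, 5)
  got <- pca(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  expect_equal(got$eigenvalues, sv$d^2 / (nrow(X) - 1), tolerance = 1e-10)
  expect_equal(sum(got$eigenvalues), sum(apply(X, 2, var)),
               tolerance = 1e-10)
})

test_that("fit_pmm reduces to OLS without phylogenetic variance", {
  set.seed(4)
  n <- 20
  X <- cbind(1, x = rnorm(n))
  y <- drop(X %*% c(2, -1)) + rnorm(n)
  f_np <- fit_pmm(y, X, random = "NP")
  ols <- lm(y ~ X[, 2])
  expect_equal(unname(f_np$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(f_np$loglik, as.numeric(logLik(ols)), tolerance = 1e-8)
  # P model on a star tree is the same model: equal maximized likelihoods
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  C <- phylo_vcv(star)
  f_p <- fit_pmm(y, X, C, "P")
  expect_equal(f_p$loglik, f_np$loglik, tolerance = 1e-8)
  expect_error(fit_pmm(y, cbind(X, X[, 2]), random = "NP"),
               "rank deficient")
})

test_that("fit_pmm recovers a planted elevation effect", {
  C <- phylo_vcv(fixture$tree)
  b <- vapply(1:60, function(r) {
    cfg <- scenario_config(seed = 5000 + r, beta_elev = -0.5,
                           sigma2_bm = 25)
    tt <- gen_traits(fixture$tree, cfg, n_traits = 1)
    f <- fit_pmm(tt$trait1, cbind(1, elev = tt$elev), C, "P")
    f$coefficients["elev"]
  }, numeric(1))
  se <- sd(b) / sqrt(length(b))
  expect_lt(abs(mean(b) + 0.5), 3 * se)
})

test_that("backward elimination respects AIC and marginality", {
  set.seed(6)
  n <- 50
  tr <- ape::rphylo(n, 1, 0)
  dat <- data.frame(elev = runif(n, 0, 3000), prec = runif(n, 200, 1500),
                    temp = runif(n, 5, 25))
  rownames(dat) <- tr$tip.label
  dat$y <- 3 - 0.4 * dat$elev + rnorm(n, 0, 50)
  sel <- backward_eliminate(dat, "y", tree = tr, random = "NP")
  expect_true("elev" %in% sel$terms)
  # marginality: an interaction never outlives a missing main effect
  for (tm in sel$terms) {
    vars <- strsplit(tm, ":")[[1]]
    if (length(vars) > 1) expect_true(all(vars %in% sel$terms))
  }
  full <- fit_pmm(dat$y,
                  phylodiscord:::design_matrix(
                    dat, phylodiscord:::all_interaction_terms(
                      c("elev", "prec", "temp"))), random = "NP")
  expect_lte(sel$fit$aic, full$aic)

  # pure noise: the empty model is the modal choice (AIC is permissive,
  # so noise terms survive individually with probability ~0.16)
  sizes <- vapply(1:60, function(r) {
    set.seed(700 + r)
    dat$y <- rnorm(n)
    length(backward_eliminate(dat, "y", tree = tr, random = "NP")$terms)
  }, numeric(1))
  tab <- table(sizes)
  expect_equal(names(which.max(tab)), "0")

  # a strongly planted single effect is retained nearly always
  kept <- vapply(1:40, function(r) {
    set.seed(800 + r)
    dat$y <- 1 - 2 * dat$elev / 1000 + rnorm(n, 0, 0.5)
    "elev" %in% backward_eliminate(dat, "y", tree = tr,
                                   random = "NP")$terms
  }, logical(1))
  expect_gte(mean(kept), 0.95)
})

test_that("k-fold CV is seeded, near-zero on noiseless data, and flags
           overfit models", {
  set.seed(8)
  n <- 24
  tr <- ape::rphylo(n, 1, 0)
  dat <- data.frame(elev = runif(n, 0, 3000), prec = runif(n, 200, 1500),
                    temp = runif(n, 5, 25))
  rownames(dat) <- tr$tip.label
  dat$y <- 2 + 0.001 * dat$elev
  mse <- kfold_cv(dat, "y", "elev", tr, random = "NP", k = 3, seed = 1)
  expect_lt(mse, 1e-10)
  expect_identical(kfold_cv(dat, "y", "elev", tr, "NP", k = 4, seed = 2),
                   kfold_cv(dat, "y", "elev", tr, "NP", k = 4, seed = 2))
  expect_error(kfold_cv(dat, "y", "elev", tr, "NP", k = 99), "exceeds")

  wins <- vapply(1:40, function(r) {
    set.seed(900 + r)
    dat$y <- 2 - 0.4 * dat$elev / 1000 + rnorm(n, 0, 0.6)
    m_true <- kfold_cv(dat, "y", "elev", tr, "NP", k = 3, seed = r)
    m_over <- kfold_cv(dat, "y",
                       phylodiscord:::all_interaction_terms(
                         c("elev", "prec", "temp")),
                       tr, "NP", k = 3, seed = r)
    m_true < m_over
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("random-effect choice follows the boundary-mixture LRT", {
  # closed form at LR = 0
  f0 <- list(loglik = -10, X = cbind(1), coefficients = 1)
  class(f0) <- "pmm_fit"
  f1 <- list(loglik = -10, X = cbind(1), coefficients = 1)
  class(f1) <- "pmm_fit"
  colnames(f0$X) <- colnames(f1$X) <- "(Intercept)"
  ch <- choose_random_effect(f0, f1)
  expect_equal(ch$p_value, 0.5)
  expect_equal(ch$choice, "NP")

  # strong phylogenetic signal on a large tree picks P nearly always
  picks <- vapply(1:30, function(r) {
    cfg <- scenario_config(n_species = 40, seed = 1100 + r, beta_elev = 0,
                           sigma2_bm = 25)
    tr <- gen_species_tree(cfg)
    tt <- gen_traits(tr, cfg, n_traits = 1)
    X <- matrix(1, 40, 1, dimnames = list(NULL, "(Intercept)"))
    fp <- fit_pmm(tt$trait1, X, phylo_vcv(tr), "P")
    fn <- fit_pmm(tt$trait1, X, random = "NP")
    choose_random_effect(fp, fn)$choice == "P"
  }, logical(1))
  expect_gte(mean(picks), 0.9)
  expect_error(choose_random_effect(f0, structure(list(
    loglik = 1, X = cbind(z = 1), coefficients = 1), class = "pmm_fit")),
    "different fixed-effect")
})

test_that("likelihood R-squared follows its closed form", {
  expect_equal(r2_lik(-5, -5, n = 10), 0)
  expect_equal(r2_lik(0, -10, n = 20), 1 - exp(-1))
  expect_lt(r2_lik(0, -100, n = 20), 1)
  expect_lte(r2_lik(0, -1e6, n = 20), 1)
  expect_error(r2_lik(-10, -5, n = 10), "nested|converge")
})

test_that("BY adjustment matches hand evaluation and p.adjust", {
  expect_equal(by_adjust(0.03), 0.03)  # c(1) = 1
  got <- by_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(min(got), 0.01 * 4 * (25 / 12), tolerance = 1e-12)
  expect_true(all(got >= c(0.01, 0.02, 0.03, 0.04)))
  expect_true(all(diff(got[order(c(0.01, 0.02, 0.03, 0.04))]) >= 0))
  set.seed(10)
  for (i in 1:25) {
    p <- runif(sample(2:30, 1))
    expect_equal(by_adjust(p), p.adjust(p, "BY"), tolerance = 1e-12)
    expect_equal(by_adjust(p, c_method = "unit"), p.adjust(p, "BH"),
                 tolerance = 1e-12)
  }
  expect_error(by_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("trait regression pipeline produces a coherent table", {
  fx <- fixture
  dat <- fx$traits
  tab <- trait_regression(dat, c("trait1", "trait6", "trait9"),
                          tree = fx$tree)
  expect_true(all(tab$r2_total >= 0 & tab$r2_total < 1, na.rm = TRUE))
  ok <- !is.na(tab$p_raw)
  expect_true(all(tab$p_adj[ok] >= tab$p_raw[ok]))
  expect_true(all(tab$p_adj[ok] <= 1))
  # trait1 is elevation-driven by construction
  t1 <- tab[tab$trait == "trait1", ]
  expect_true("elev" %in% t1$term)
  expect_equal(t1$slope_sign[t1$term == "elev"], "-")
})
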