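# Trait-vs-environment machinery: phylogenetically structured PCA,
# ML phylogenetic mixed models with backward elimination and k-fold CV,
# likelihood-based R-squared, and Benjamini-Yekutieli FDR control.

#' Z-score trait columns
#'
#' @param table Data frame, one row per species.
#' @param cols Columns to standardize (default: all numeric columns).
#' @return The data frame with the chosen columns centered and scaled;
#'   attributes `center` and `scale` allow exact destandardization.
#' @export
standardize_traits <- function(table, cols = NULL) {
  if (is.null(cols))
    cols <- names(table)[vapply(table, is.numeric, logical(1))]
  ctr <- numeric(0); scl <- numeric(0)
  for (cn in cols) {
    x <- table[[cn]]
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      stop("trait '", cn, "' has zero variance; cannot standardize")
    ctr[cn] <- mean(x); scl[cn] <- s
    table[[cn]] <- (x - ctr[cn]) / scl[cn]
  }
  attr(table, "center") <- ctr
  attr(table, "scale") <- scl
  table
}

pca_core <- function(X, Cinv) {
  n <- nrow(X)
  one <- matrix(1, n, 1)
  denom <- drop(crossprod(one, Cinv %*% one))
  a <- drop(crossprod(one, Cinv %*% X)) / denom      # GLS ancestral mean
  Xc <- sweep(X, 2L, a)
  R <- crossprod(Xc, Cinv %*% Xc) / (n - 1)          # evolutionary covariance
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  V <- eg$vectors
  colnames(V) <- paste0("PC", seq_along(lam))
  rownames(V) <- colnames(X)
  S <- Xc %*% V
  rownames(S) <- rownames(X)
  structure(list(ancestral_mean = a, evo_cov = R, eigenvalues = lam,
                 loadings = V, scores = S,
                 percent_var = 100 * lam / sum(lam)),
            class = "ppca_result")
}

#' @export
print.ppca_result <- function(x, ...) {
  k <- min(5L, length(x$percent_var))
  cat("Principal components of the evolutionary covariance matrix\n")
  cat("  variance explained (%):",
      paste(sprintf("PC%d %.1f", seq_len(k), x$percent_var[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Phylogenetically structured PCA
#'
#' Principal components of the evolutionary (rate) covariance matrix
#' estimated by GLS with the Brownian phylogenetic covariance C: the
#' ancestral mean is a = (1'C^-1 1)^-1 1'C^-1 X, the rate matrix is
#' R = (X - 1a)' C^-1 (X - 1a) / (n - 1), and scores are (X - 1a)V where V
#' holds R's eigenvectors. On a star tree with equal branch lengths this
#' reduces to ordinary covariance PCA.
#'
#' @param X Numeric matrix or data frame, species in rows (rownames must
#'   match the tree tips); standardize first with [standardize_traits()]
#'   unless raw units are wanted.
#' @param tree Rooted `phylo` with branch lengths covering the rows of X.
#' @return `ppca_result`: ancestral mean, evolutionary covariance,
#'   eigenvalues, loadings, scores, percent variance per axis.
#' @export
ppca <- function(X, tree) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), !is.null(rownames(X)))
  miss <- setdiff(rownames(X), tree$tip.label)
  if (length(miss)) stop("species missing from tree: ",
                         paste(miss, collapse = ", "))
  C <- phylo_vcv(prune_tree(tree, rownames(X)))[rownames(X), rownames(X)]
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("phylogenetic covariance is singular; jitter zero-length branches",
         call. = FALSE))
  pca_core(X, Cinv)
}

#' Ordinary PCA in the same format
#'
#' [ppca()] with identity phylogenetic covariance (no structure).
#'
#' @inheritParams ppca
#' @return `ppca_result`.
#' @export
pca <- function(X) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- seq_len(nrow(X))
  pca_core(X, diag(nrow(X)))
}

#' Fit a phylogenetic mixed model by maximum likelihood
#'
#' Model: y = X beta + b + e with b ~ N(0, sigma2_b * Ct) and
#' e ~ N(0, sigma2_e * I), where Ct is the Brownian covariance scaled to
#' maximum diagonal 1 (random = "P"). With one observation per species the
#' species-iid random effect ("NP") is confounded with the residual, so
#' that model collapses to OLS with a single variance. ML (not REML)
#' throughout, so AIC is comparable across fixed-effect structures;
#' the variance ratio is profiled out and optimized on the unit interval.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (including intercept).
#' @param C Phylogenetic covariance for the rows of y (from
#'   [phylo_vcv()]), required when `random = "P"`.
#' @param random `"P"` (phylogenetic) or `"NP"` (species-iid / OLS).
#' @param scale_C Scale C to maximum diagonal 1 (default TRUE; set FALSE
#'   when passing a pre-scaled submatrix, e.g. in cross-validation).
#' @return `pmm_fit`: coefficients, variance components, log-likelihood,
#'   AIC (k counts coefficients plus variance parameters), convergence
#'   flag.
#' @export
fit_pmm <- function(y, X, C = NULL, random = c("P", "NP"), scale_C = TRUE) {
  random <- match.arg(random)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  p <- ncol(X)
  if (n <= p + 1) stop("too few observations (", n, ") for ", p,
                       " fixed-effect coefficients")
  if (random == "NP") {
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    s2 <- rss / n
    ll <- -n / 2 * (log(2 * pi * s2) + 1)
    k <- p + 1
    vc <- rss / (n - p) * chol2inv(qr.R(qr(X)))
    dimnames(vc) <- list(colnames(X), colnames(X))
    out <- list(coefficients = setNames(fit$coefficients, colnames(X)),
                sigma2_phylo = 0, sigma2_resid = s2, h = 0,
                loglik = ll, aic = 2 * k - 2 * ll, k = k, n = n,
                beta_vcov = vc, df_resid = n - p,
                random = "NP", converged = TRUE, X = X, y = y, C = NULL)
    class(out) <- "pmm_fit"
    return(out)
  }
  if (is.null(C)) stop("random = \"P\" requires a phylogenetic covariance C")
  if (scale_C) C <- C / max(diag(C))
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  prof <- function(h) {
    w <- h * d + (1 - h)
    if (any(w < 1e-12)) return(list(ll = -Inf))
    sw <- 1 / sqrt(w)
    fit <- lm.fit(Xs * sw, ys * sw)
    s2 <- sum(fit$residuals^2) / n
    ll <- -n / 2 * log(2 * pi * s2) - 0.5 * sum(log(w)) - n / 2
    list(ll = ll, beta = fit$coefficients, s2 = s2)
  }
  op <- optimize(function(h) prof(h)$ll, c(0, 1), maximum = TRUE,
                 tol = 1e-9)
  cand <- c(0, op$maximum, 1)
  lls <- vapply(cand, function(h) prof(h)$ll, numeric(1))
  h <- cand[which.max(lls)]
  best <- prof(h)
  k <- p + 2
  # Wald covariance of beta from the REML variance ratio: ML
  # underestimates the phylogenetic variance share at small n, which
  # makes ML-based intervals anticonservative; REML for the dispersion is
  # the standard mixed-model remedy (the reported coefficients, logLik
  # and AIC stay ML so fixed-effect model comparison remains valid)
  remll <- function(h2) {
    w <- h2 * d + (1 - h2)
    if (any(w < 1e-12)) return(-Inf)
    sw <- 1 / sqrt(w)
    fr <- lm.fit(Xs * sw, ys * sw)
    s2 <- sum(fr$residuals^2) / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
              determinant(crossprod(Xs * sw))$modulus + (n - p))
  }
  opr <- optimize(remll, c(0, 1), maximum = TRUE, tol = 1e-9)
  candr <- c(0, opr$maximum, 1)
  h_reml <- candr[which.max(vapply(candr, remll, numeric(1)))]
  wr <- h_reml * d + (1 - h_reml)
  swr <- 1 / sqrt(wr)
  fr <- lm.fit(Xs * swr, ys * swr)
  s2_reml <- sum(fr$residuals^2) / (n - p)
  vc <- s2_reml * chol2inv(qr.R(qr(Xs * swr)))  # QR: robust near saturation
  dimnames(vc) <- list(colnames(X), colnames(X))
  out <- list(coefficients = setNames(best$beta, colnames(X)),
              sigma2_phylo = h * best$s2, sigma2_resid = (1 - h) * best$s2,
              h = h, loglik = best$ll, aic = 2 * k - 2 * best$ll, k = k,
              n = n, beta_vcov = vc, df_resid = n - p, h_reml = h_reml,
              coefficients_reml = setNames(fr$coefficients, colnames(X)),
              random = "P", converged = is.finite(best$ll),
              X = X, y = y, C = C)
  class(out) <- "pmm_fit"
  out
}

#' Wald confidence intervals for fixed effects
#'
#' t-intervals with n - p degrees of freedom, computed from the REML fit
#' (REML coefficients and dispersion) when a phylogenetic random effect
#' is present; ML-based intervals are anticonservative at the sample
#' sizes typical of species-level analyses.
#'
#' @param object `pmm_fit`.
#' @param parm Coefficient names (default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix of lower/upper bounds.
#' @export
confint.pmm_fit <- function(object, parm = NULL, level = 0.95, ...) {
  cf <- if (!is.null(object$coefficients_reml)) object$coefficients_reml
        else object$coefficients
  if (is.null(parm)) parm <- names(cf)
  se <- sqrt(diag(object$beta_vcov))[parm]
  q <- stats::qt(1 - (1 - level) / 2, df = object$df_resid)
  out <- cbind(lower = cf[parm] - q * se, upper = cf[parm] + q * se)
  rownames(out) <- parm
  out
}

#' @export
print.pmm_fit <- function(x, ...) {
  cat("Phylogenetic mixed model (", x$random, " random effect), ML\n",
      sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("sigma2_phylo = %.4g  sigma2_resid = %.4g\n",
              x$sigma2_phylo, x$sigma2_resid))
  cat(sprintf("logLik = %.3f  AIC = %.3f (k = %d, n = %d)\n",
              x$loglik, x$aic, x$k, x$n))
  invisible(x)
}

# design matrix for a set of model terms (":"-joined variable names);
# always includes an intercept
design_matrix <- function(data, terms_vec) {
  rhs <- if (length(terms_vec)) paste(terms_vec, collapse = " + ") else "1"
  model.matrix(as.formula(paste("~", rhs)), data = data)
}

all_interaction_terms <- function(covariates) {
  unlist(lapply(seq_along(covariates), function(k)
    apply(combn(covariates, k), 2L, paste, collapse = ":")))
}

# a term is removable iff no other remaining term strictly contains it
removable_terms <- function(terms_vec) {
  vars <- lapply(strsplit(terms_vec, ":"), sort)
  keep <- vapply(seq_along(vars), function(i) {
    !any(vapply(seq_along(vars), function(j) {
      i != j && all(vars[[i]] %in% vars[[j]])
    }, logical(1)))
  }, logical(1))
  terms_vec[keep]
}

#' Backward elimination over fixed effects by AIC
#'
#' Starts from the full model with all covariate interactions (by default
#' elevation, precipitation, temperature and every interaction among
#' them), repeatedly removes the term whose removal lowers AIC the most
#' while respecting marginality (a main effect stays while any containing
#' interaction remains), and stops when no removal improves AIC.
#'
#' @param data Data frame, one row per species, rownames = species.
#' @param response Response column name.
#' @param covariates Covariate column names.
#' @param tree Phylogeny (used when `random = "P"`).
#' @param random Random-effect structure passed to [fit_pmm()].
#' @return List: `fit` (best `pmm_fit`), `terms` (retained fixed terms),
#'   `trace` (data frame of steps).
#' @export
backward_eliminate <- function(data, response,
                               covariates = c("elev", "prec", "temp"),
                               tree = NULL, random = "P") {
  y <- data[[response]]
  C <- if (random == "P") {
    stopifnot(!is.null(tree))
    phylo_vcv(prune_tree(tree, rownames(data)))[rownames(data),
                                                rownames(data)]
  } else NULL
  terms_vec <- all_interaction_terms(covariates)
  if (nrow(data) <= length(terms_vec) + 2L)
    warning("full interaction model is near-saturated at n = ", nrow(data),
            "; assess the selected model with kfold_cv()")
  fit_terms <- function(tv) fit_pmm(y, design_matrix(data, tv), C, random)
  cur <- fit_terms(terms_vec)
  trace <- data.frame(step = 0L, removed = "", aic = cur$aic,
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    cand <- removable_terms(terms_vec)
    if (!length(cand)) break
    fits <- lapply(cand, function(tm) fit_terms(setdiff(terms_vec, tm)))
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    if (min(aics) >= cur$aic) break
    j <- which.min(aics)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = cand[j],
                                     aic = aics[j]))
    terms_vec <- setdiff(terms_vec, cand[j])
    cur <- fits[[j]]
  }
  list(fit = cur, terms = terms_vec, trace = trace)
}

#' k-fold cross-validation of a phylogenetic mixed model
#'
#' Species are partitioned into k folds by a seeded shuffle; each fold is
#' predicted from the model fit to the remainder. Under the phylogenetic
#' random effect, held-out species are predicted by the conditional
#' Brownian expectation given the training species (fixed effects plus
#' sigma2_b * Ct(test, train) V_train^-1 residuals); under "NP" by fixed
#' effects alone.
#'
#' @inheritParams backward_eliminate
#' @param terms_vec Fixed-effect terms of the model being assessed.
#' @param k Number of folds (3 and 4 are the conventional choices here).
#' @param seed Integer seed for the fold shuffle.
#' @return Mean squared prediction error averaged over folds.
#' @export
kfold_cv <- function(data, response, terms_vec, tree = NULL, random = "P",
                     k = 3, seed = 1) {
  n <- nrow(data)
  if (k > n) stop("k exceeds the number of species")
  y <- data[[response]]
  X <- design_matrix(data, terms_vec)
  Ct <- if (random == "P") {
    C <- phylo_vcv(prune_tree(tree, rownames(data)))[rownames(data),
                                                     rownames(data)]
    C / max(diag(C))
  } else NULL
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  errs <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    tr <- !te
    fit <- fit_pmm(y[tr], X[tr, , drop = FALSE],
                   C = if (random == "P") Ct[tr, tr] else NULL,
                   random = random, scale_C = FALSE)
    pred <- drop(X[te, , drop = FALSE] %*% fit$coefficients)
    if (random == "P" && fit$sigma2_phylo > 0) {
      Vtr <- fit$sigma2_phylo * Ct[tr, tr] +
        diag(fit$sigma2_resid, sum(tr))
      resid_tr <- y[tr] - drop(X[tr, , drop = FALSE] %*% fit$coefficients)
      pred <- pred + drop(fit$sigma2_phylo * Ct[te, tr, drop = FALSE] %*%
                            solve(Vtr, resid_tr))
    }
    errs[f] <- mean((y[te] - pred)^2)
  }
  mean(errs)
}

#' Choose between phylogenetic and non-phylogenetic random effects
#'
#' Likelihood-ratio test of sigma2_phylo > 0 against the boundary null,
#' using the 50:50 mixture of chi-squared(0) and chi-squared(1) reference:
#' p = 0.5 * P(chi2_1 >= LR), which equals 0.5 exactly at LR = 0. The
#' phylogenetic model is chosen iff p < cutoff (default 0.5, a permissive
#' cutoff that retains any phylogenetic structure present).
#'
#' @param fit_p,fit_np `pmm_fit` objects with identical fixed effects.
#' @param cutoff Decision threshold on the p-value.
#' @return List: `choice` ("P"/"NP"), `p_value`, `lr`.
#' @export
choose_random_effect <- function(fit_p, fit_np, cutoff = 0.5) {
  stopifnot(inherits(fit_p, "pmm_fit"), inherits(fit_np, "pmm_fit"))
  if (!identical(colnames(fit_p$X), colnames(fit_np$X)))
    stop("fits have different fixed-effect structures")
  lr <- max(0, 2 * (fit_p$loglik - fit_np$loglik))
  p <- 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  list(choice = if (p < cutoff) "P" else "NP", p_value = p, lr = lr)
}

#' Likelihood-based R-squared
#'
#' R2 = 1 - exp(-(2/n) (l_full - l_reduced)) for a reduced model nested in
#' the full one. The total R2 of a fit uses the intercept-only model with
#' no random effect as the reduced model; a partial R2 for a term refits
#' the full model without that term.
#'
#' @param full,reduced `pmm_fit` objects, or numeric log-likelihoods.
#' @param n Number of observations (taken from `full` if a fit).
#' @return Numeric in `[0, 1)`.
#' @export
r2_lik <- function(full, reduced, n = NULL) {
  lf <- if (inherits(full, "pmm_fit")) full$loglik else full
  lr <- if (inherits(reduced, "pmm_fit")) reduced$loglik else reduced
  if (is.null(n)) {
    if (!inherits(full, "pmm_fit")) stop("n must be given")
    n <- full$n
  }
  if (lf < lr - 1e-8)
    stop("full model log-likelihood below reduced model; models are not ",
         "nested or a fit failed to converge")
  max(0, 1 - exp(-(2 / n) * (lf - lr)))
}

#' Trait-vs-environment regression table
#'
#' The full per-trait pipeline: backward elimination of the fixed effects
#' under the phylogenetic random effect, the P-vs-NP random-effect choice
#' at the permissive 0.5 cutoff, likelihood-based total and partial
#' R-squared for the selected model, per-term likelihood-ratio p-values,
#' and Benjamini-Yekutieli adjustment across all tests.
#'
#' @param data Data frame (rownames = species) holding responses and
#'   covariates.
#' @param responses Character vector of response column names.
#' @param covariates Covariate columns fed to [backward_eliminate()].
#' @param tree Phylogeny.
#' @param cutoff Random-effect choice cutoff (see
#'   [choose_random_effect()]).
#' @return Data frame, one row per (trait, retained term): columns
#'   `trait`, `model`, `random`, `r2_total`, `term`, `r2_partial`,
#'   `p_raw`, `p_adj`, `slope_sign`.
#' @export
trait_regression <- function(data, responses,
                             covariates = c("elev", "prec", "temp"),
                             tree, cutoff = 0.5) {
  rows <- list()
  for (resp in responses) {
    sel <- backward_eliminate(data, resp, covariates, tree, random = "P")
    y <- data[[resp]]
    X <- design_matrix(data, sel$terms)
    C <- phylo_vcv(prune_tree(tree, rownames(data)))[rownames(data),
                                                     rownames(data)]
    fit_p <- fit_pmm(y, X, C, "P")
    fit_np <- fit_pmm(y, X, random = "NP")
    ch <- choose_random_effect(fit_p, fit_np, cutoff)
    fit <- if (ch$choice == "P") fit_p else fit_np
    null_fit <- fit_pmm(y, design_matrix(data, character(0)), random = "NP")
    r2t <- r2_lik(fit, null_fit)
    model_str <- paste("~", if (length(sel$terms))
      paste(sel$terms, collapse = " + ") else "1", "+", ch$choice)
    if (!length(sel$terms)) {
      rows[[length(rows) + 1]] <- data.frame(
        trait = resp, model = model_str, random = ch$choice,
        r2_total = r2t, term = NA_character_, r2_partial = NA_real_,
        p_raw = NA_real_, p_adj = NA_real_, slope_sign = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    for (tm in sel$terms) {
      red_terms <- setdiff(sel$terms, tm)
      red <- fit_pmm(y, design_matrix(data, red_terms),
                     C = if (ch$choice == "P") C else NULL,
                     random = ch$choice)
      r2p <- r2_lik(fit, red)
      lr <- max(0, 2 * (fit$loglik - red$loglik))
      p <- pchisq(lr, df = 1, lower.tail = FALSE)
      cf <- fit$coefficients[tm]
      rows[[length(rows) + 1]] <- data.frame(
        trait = resp, model = model_str, random = ch$choice,
        r2_total = r2t, term = tm, r2_partial = r2p, p_raw = p,
        p_adj = NA_real_,
        slope_sign = if (is.na(cf)) NA_character_
                     else if (cf >= 0) "+" else "-",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj[!is.na(out$p_raw)] <- by_adjust(out$p_raw[!is.na(out$p_raw)])
  out
}

#' Benjamini-Yekutieli step-up FDR adjustment
#'
#' Sorted ascending, adjusted p_(i) = min(1, min_{j >= i} m c(m) p_(j)/j)
#' with c(m) = sum_{k=1}^m 1/k (the correction valid under arbitrary
#' dependence); original order is restored. With `c_method = "unit"`
#' (c(m) = 1) the procedure is exactly Benjamini-Hochberg.
#'
#' @param pvals Numeric vector in `[0, 1]` (NAs passed through).
#' @param c_method `"by"` (harmonic c(m), default) or `"unit"`.
#' @return Adjusted p-values in the original order.
#' @export
by_adjust <- function(pvals, c_method = c("by", "unit")) {
  c_method <- match.arg(c_method)
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(pvals)
  cm <- if (c_method == "by") sum(1 / seq_len(m)) else 1
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, rev(cummin(rev(m * cm * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  res <- pvals
  res[ok] <- out
  res
}
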