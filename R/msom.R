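#' Community-level priors
#'
#' Priors for the community layer of the multi-species occupancy model.
#' Every coefficient family (occupancy intercept, each occupancy slope,
#' each detection intercept and slope) has a community mean with prior
#' Normal(0, variance 2.72) -- on the logit scale this implies a close to
#' uniform prior on the probability scale -- and a community variance with
#' prior Inverse-Gamma(shape 0.1, rate 0.1), i.e. the community precision
#' is Gamma(0.1, rate 0.1).
#'
#' @param mean_mu Prior mean of every community mean.
#' @param mean_var Prior variance of every community mean (logit scale).
#' @param var_shape,var_rate Shape and rate of the Inverse-Gamma prior on
#'   every community variance.
#' @return An object of class `community_priors`.
#' @export
community_priors <- function(mean_mu = 0, mean_var = 2.72,
                             var_shape = 0.1, var_rate = 0.1) {
  stopifnot(mean_var > 0, var_shape > 0, var_rate > 0)
  structure(list(mean_mu = mean_mu, mean_var = mean_var,
                 var_shape = var_shape, var_rate = var_rate),
            class = "community_priors")
}

#' MCMC configuration
#'
#' Defaults reproduce the reference protocol: three chains of 54,000
#' iterations with a 10,000-iteration burn-in and thinning of 10, which
#' retains 3 x 4,400 = 13,200 posterior draws.
#'
#' @param n_chains Number of chains.
#' @param n_iterations Total iterations per chain (burn-in included).
#' @param burn_in Iterations discarded per chain.
#' @param thin Thinning interval.
#' @param seed Master seed; per-chain seeds are derived from it
#'   deterministically.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iterations = 54000L,
                        burn_in = 10000L, thin = 10L, seed = 1L) {
  stopifnot(n_chains >= 1L, n_iterations > burn_in, thin >= 1L)
  retained <- n_chains * ((n_iterations - burn_in) %/% thin)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), retained = retained),
            class = "mcmc_config")
}

# Assemble sampler inputs from a detection history and covariate table.
# "Active" cells are site-primary combinations with >= 1 conducted visit;
# only those carry a modeled z. Detection design: one intercept column per
# primary period plus the visit covariates.
build_model_data <- function(det_hist, covariates = NULL) {
  stopifnot(inherits(det_hist, "detection_history"))
  y <- det_hist$y; mask <- det_hist$mask
  N <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]; Tm <- dim(y)[4]
  if (!is.null(covariates)) {
    stopifnot(inherits(covariates, "covariate_table"))
    if (!isTRUE(covariates$standardized))
      stop("covariates must be standardized before fitting")
    if (!all(is.finite(covariates$site)))
      stop("non-finite site covariate")
    Xocc <- cbind(`(Intercept)` = 1, covariates$site)
    varr <- covariates$visit[[det_hist$season]]
    if (is.null(varr) && !is.null(covariates$visit))
      stop("no visit covariates for season ", det_hist$season)
  } else {
    Xocc <- matrix(1, J, 1, dimnames = list(det_hist$site_ids,
                                            "(Intercept)"))
    varr <- NULL
  }
  cells <- which(apply(mask, c(1, 2), any), arr.ind = TRUE)
  cells <- cells[order(cells[, 2], cells[, 1]), , drop = FALSE]
  ncell <- nrow(cells)
  cell_of <- matrix(NA_integer_, J, K)
  cell_of[cells] <- seq_len(ncell)

  vidx <- which(mask, arr.ind = TRUE)
  vidx <- vidx[order(vidx[, 2], vidx[, 1], vidx[, 3]), , drop = FALSE]
  nobs <- nrow(vidx)
  visit_cell <- cell_of[vidx[, 1:2, drop = FALSE]]
  per <- matrix(0, nobs, K)
  per[cbind(seq_len(nobs), vidx[, 2])] <- 1
  colnames(per) <- paste0("p_intercept_", seq_len(K))
  if (!is.null(varr)) {
    nv <- dim(varr)[4]
    W <- matrix(NA_real_, nobs, nv, dimnames = list(NULL,
                                                    dimnames(varr)[[4]]))
    for (v in seq_len(nv))
      W[, v] <- varr[cbind(vidx, v)]
    if (!all(is.finite(W))) stop("non-finite visit covariate")
    Bdet <- cbind(per, W)
  } else {
    Bdet <- per
  }
  Y <- vapply(seq_len(N), function(i)
    y[cbind(i, vidx[, 1], vidx[, 2], vidx[, 3])], numeric(nobs))
  Y <- matrix(as.integer(Y), nobs, N)
  list(Xocc = Xocc, Bdet = Bdet, Y = Y,
       cell_site = as.integer(cells[, 1] - 1L),
       visit_cell = as.integer(visit_cell - 1L),
       cells = cells, cell_of = cell_of, vidx = vidx,
       N = N, J = J, K = K, Tm = Tm, ncell = ncell,
       occ_names = colnames(Xocc), det_names = colnames(Bdet))
}

#' Log joint density of the multi-species occupancy model
#'
#' Evaluates the log of prior x Bernoulli(z | psi) x Bernoulli(y | z p) for
#' a full parameter and latent assignment. Masked visits contribute zero;
#' any observed detection with z = 0 makes the state impossible (-Inf).
#'
#' @param state List with elements `alpha` (species x occupancy coefficients,
#'   intercept first), `beta` (species x detection coefficients, one
#'   intercept per primary period first), `z` (species x site x primary),
#'   and, for the hierarchical model, `mu_alpha`, `sigma2_alpha`, `mu_beta`,
#'   `sigma2_beta`.
#' @param det_hist A [detection_history].
#' @param covariates Standardized [covariate_table] or NULL for an
#'   intercept-only model.
#' @param priors A [community_priors].
#' @param hierarchical If FALSE, species coefficients get independent
#'   Normal(0, `priors$mean_var`) priors and no community layer is evaluated.
#' @return Log joint density (scalar; may be -Inf).
#' @export
log_joint <- function(state, det_hist, covariates = NULL,
                      priors = community_priors(), hierarchical = TRUE) {
  md <- build_model_data(det_hist, covariates)
  alpha <- as.matrix(state$alpha); beta <- as.matrix(state$beta)
  stopifnot(nrow(alpha) == md$N, ncol(alpha) == ncol(md$Xocc),
            nrow(beta) == md$N, ncol(beta) == ncol(md$Bdet))
  z <- state$z
  lp <- 0
  if (hierarchical) {
    for (nm in c("alpha", "beta")) {
      mu <- state[[paste0("mu_", nm)]]
      s2 <- state[[paste0("sigma2_", nm)]]
      co <- if (nm == "alpha") alpha else beta
      lp <- lp + sum(dnorm(mu, priors$mean_mu, sqrt(priors$mean_var),
                           log = TRUE))
      lp <- lp + sum(dinvgamma_log(s2, priors$var_shape, priors$var_rate))
      lp <- lp + sum(dnorm(co, rep(mu, each = md$N),
                           rep(sqrt(s2), each = md$N), log = TRUE))
    }
  } else {
    lp <- lp + sum(dnorm(alpha, 0, sqrt(priors$mean_var), log = TRUE)) +
      sum(dnorm(beta, 0, sqrt(priors$mean_var), log = TRUE))
  }
  # z layer over active cells
  psi_site <- plogis(md$Xocc %*% t(alpha))        # J x N
  for (c in seq_len(md$ncell)) {
    j <- md$cells[c, 1]
    zc <- z[, j, md$cells[c, 2]]
    lp <- lp + sum(dbinom(zc, 1, psi_site[j, ], log = TRUE))
  }
  # y layer over observed visits
  p_vis <- plogis(md$Bdet %*% t(beta))            # nobs x N
  zv <- matrix(0L, md$ncell, md$N)
  for (c in seq_len(md$ncell))
    zv[c, ] <- z[, md$cells[c, 1], md$cells[c, 2]]
  zvis <- zv[md$visit_cell + 1L, , drop = FALSE]  # nobs x N
  pr <- zvis * p_vis
  ll <- ifelse(md$Y == 1, log(pr), log1p(-pr))
  lp + sum(ll)
}

dinvgamma_log <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

#' Fit the seasonal multi-species occupancy model by MCMC
#'
#' Polya-Gamma augmented Gibbs sampling targeting the exact posterior of the
#' robust-design multi-species occupancy model: per species,
#' logit(psi_ijk) = alpha0_i + alpha_i' X_j (site covariates constant within
#' a season, incidence conditionally independent across primary periods) and
#' logit(p_ijkt) = beta0_ik + beta_i' X_jkt with a separate detection
#' intercept per primary period. Species coefficients are exchangeable draws
#' from community normal distributions whose means and variances get the
#' priors in [community_priors()]. Incidence is fixed to 1 wherever the
#' species was detected. Each season is fitted independently.
#'
#' After sampling, the Gelman-Rubin statistic is computed for every scalar
#' parameter; a warning names any parameter with R-hat >= 1.1 (samples are
#' still returned).
#'
#' @param det_hist A [detection_history] for one season.
#' @param covariates Standardized [covariate_table], or NULL for an
#'   intercept-only (no covariate) model.
#' @param priors A [community_priors].
#' @param config An [mcmc_config].
#' @param hierarchical If FALSE the community layer is dropped and species
#'   coefficients get fixed independent Normal(0, `priors$mean_var`) priors
#'   (useful for single-species fits and validation against quadrature).
#' @return An object of class `msom_fit`: arrays `alpha`
#'   (draw x species x coefficient), `beta`, `z` (draw x species x site x
#'   primary), hyperparameter draws, chain ids, convergence summary, and the
#'   model data needed by downstream diagnostics.
#' @export
fit_msom <- function(det_hist, covariates = NULL,
                     priors = community_priors(), config = mcmc_config(),
                     hierarchical = TRUE) {
  md <- build_model_data(det_hist, covariates)
  if (md$J < 2L) stop("need at least 2 sites")
  n_store <- (config$n_iterations - config$burn_in) %/% config$thin
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    chains[[ch]] <- .msom_gibbs_chain(
      md$Xocc, md$cell_site, md$Y, md$Bdet, md$visit_cell,
      config$n_iterations, config$burn_in, config$thin,
      hierarchical, priors$mean_var, priors$var_shape, priors$var_rate,
      priors$mean_var)
  }

  P <- ncol(md$Xocc); Q <- ncol(md$Bdet); N <- md$N
  S <- n_store * config$n_chains
  glue <- function(field, d1, d2) {
    # chain output cubes are (d1 x d2 x n_store); combine to draw-major
    out <- array(NA_real_, c(S, d2, d1))
    for (ch in seq_len(config$n_chains)) {
      a <- chains[[ch]][[field]]
      idx <- (ch - 1L) * n_store + seq_len(n_store)
      out[idx, , ] <- aperm(a, c(3, 2, 1))
    }
    out
  }
  alpha <- glue("alpha", P, N)      # S x N x P
  beta <- glue("beta", Q, N)        # S x N x Q
  zcell <- glue("z", md$ncell, N)   # S x N x ncell
  gmat <- function(field, d) {
    out <- matrix(NA_real_, S, d)
    for (ch in seq_len(config$n_chains)) {
      idx <- (ch - 1L) * n_store + seq_len(n_store)
      out[idx, ] <- t(chains[[ch]][[field]])
    }
    out
  }
  mu_alpha <- gmat("mu_alpha", P); sigma2_alpha <- gmat("sigma2_alpha", P)
  mu_beta <- gmat("mu_beta", Q); sigma2_beta <- gmat("sigma2_beta", Q)
  colnames(mu_alpha) <- colnames(sigma2_alpha) <- md$occ_names
  colnames(mu_beta) <- colnames(sigma2_beta) <- md$det_names
  dimnames(alpha) <- list(NULL, det_hist$species_ids, md$occ_names)
  dimnames(beta) <- list(NULL, det_hist$species_ids, md$det_names)

  # full incidence array; inactive site-primaries (no conducted visits) get
  # posterior-predictive draws z ~ Bernoulli(psi) from each retained draw
  z <- array(NA_integer_, c(S, N, md$J, md$K),
             dimnames = list(NULL, det_hist$species_ids,
                             det_hist$site_ids, NULL))
  for (c in seq_len(md$ncell))
    z[, , md$cells[c, 1], md$cells[c, 2]] <- zcell[, , c]
  inactive <- which(is.na(md$cell_of), arr.ind = TRUE)
  if (nrow(inactive)) {
    set.seed(chain_seeds[1] %% 1000003L + 7L)
    for (r in seq_len(nrow(inactive))) {
      j <- inactive[r, 1]
      xj <- md$Xocc[j, ]
      psi <- plogis(matrix(alpha, S * N, P) %*% xj)
      psi <- matrix(psi, S, N)
      z[, , j, inactive[r, 2]] <- (matrix(runif(S * N), S, N) < psi) * 1L
    }
  }

  chain_id <- rep(seq_len(config$n_chains), each = n_store)
  fit <- structure(list(
    alpha = alpha, beta = beta, z = z,
    mu_alpha = mu_alpha, sigma2_alpha = sigma2_alpha,
    mu_beta = mu_beta, sigma2_beta = sigma2_beta,
    chain = chain_id, n_retained = S, season = det_hist$season,
    species_ids = det_hist$species_ids, site_ids = det_hist$site_ids,
    occ_names = md$occ_names, det_names = md$det_names,
    hierarchical = hierarchical, priors = priors, config = config,
    model_data = md,
    standardization = if (!is.null(covariates))
      list(center = covariates$center, scale = covariates$scale,
           site_raw = covariates$site_raw)
  ), class = "msom_fit")

  fit$rhat <- rhat_all(fit)
  bad <- names(fit$rhat)[fit$rhat >= 1.1 & !is.na(fit$rhat)]
  if (length(bad))
    warning("Gelman-Rubin statistic >= 1.1 for: ",
            paste(utils::head(bad, 20), collapse = ", "),
            if (length(bad) > 20) " ...", call. = FALSE)
  fit
}

# R-hat for every scalar parameter of a fit
rhat_all <- function(fit) {
  if (fit$config$n_chains < 2L) return(NA_real_)
  split_chains <- function(v) matrix(v, ncol = fit$config$n_chains)
  out <- c()
  for (f in seq_along(fit$occ_names))
    for (i in seq_along(fit$species_ids))
      out[paste0("alpha[", fit$species_ids[i], ",", fit$occ_names[f], "]")] <-
        gelman_rubin(split_chains(fit$alpha[, i, f]))
  for (f in seq_along(fit$det_names))
    for (i in seq_along(fit$species_ids))
      out[paste0("beta[", fit$species_ids[i], ",", fit$det_names[f], "]")] <-
        gelman_rubin(split_chains(fit$beta[, i, f]))
  if (fit$hierarchical) {
    for (f in seq_along(fit$occ_names)) {
      out[paste0("mu_alpha[", fit$occ_names[f], "]")] <-
        gelman_rubin(split_chains(fit$mu_alpha[, f]))
      out[paste0("sigma2_alpha[", fit$occ_names[f], "]")] <-
        gelman_rubin(split_chains(fit$sigma2_alpha[, f]))
    }
    for (f in seq_along(fit$det_names)) {
      out[paste0("mu_beta[", fit$det_names[f], "]")] <-
        gelman_rubin(split_chains(fit$mu_beta[, f]))
      out[paste0("sigma2_beta[", fit$det_names[f], "]")] <-
        gelman_rubin(split_chains(fit$sigma2_beta[, f]))
    }
  }
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Standard between/within-chain variance ratio for one scalar parameter.
#' Values near 1 indicate well-mixed chains; the conventional convergence
#' rule is R-hat < 1.1.
#'
#' @param draws Matrix of draws with one column per chain, or a list of
#'   equal-length per-chain draw vectors.
#' @return The potential scale reduction factor.
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2L) stop("need at least 2 chains")
  if (n < 10L) stop("need at least 10 draws per chain")
  W <- mean(apply(draws, 2, var))
  B <- n * var(colMeans(draws))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Exact single-species posterior by grid quadrature
#'
#' For a one-species, no-covariate occupancy model (constant psi and p),
#' integrates the posterior over a 2-D grid of (psi, p). The latent
#' incidence is marginalized analytically: a site with d detections out of
#' m visits contributes psi p^d (1-p)^(m-d) + (1-psi) 1(d = 0). Priors are
#' independent Normal(0, `prior_var`) on logit(psi) and logit(p). This is a
#' quadrature oracle, fully independent of the Gibbs sampler.
#'
#' @param y Matrix (sites x visits) of binary detections.
#' @param mask Logical matrix of conducted visits (default: all conducted).
#' @param prior_var Prior variance on the logit scale.
#' @param n_grid Grid points per dimension.
#' @return List with grids, the joint posterior matrix (normalized), and
#'   posterior means `mean_psi`, `mean_p`.
#' @export
single_species_grid_posterior <- function(y, mask = NULL, prior_var = 2.72,
                                          n_grid = 400L) {
  y <- as.matrix(y)
  if (is.null(mask)) mask <- !is.na(y)
  d <- rowSums(y * mask, na.rm = TRUE)
  m <- rowSums(mask)
  grid <- (seq_len(n_grid) - 0.5) / n_grid
  lpri <- dnorm(qlogis(grid), 0, sqrt(prior_var), log = TRUE) -
    log(grid) - log1p(-grid)
  logpost <- matrix(0, n_grid, n_grid)   # psi rows, p cols
  for (j in seq_along(d)) {
    lik <- outer(grid, grid, function(psi, p)
      psi * p^d[j] * (1 - p)^(m[j] - d[j]) + (1 - psi) * (d[j] == 0))
    logpost <- logpost + log(lik)
  }
  logpost <- logpost + lpri + rep(lpri, each = n_grid)
  post <- exp(logpost - max(logpost))
  post <- post / sum(post)
  list(psi_grid = grid, p_grid = grid, posterior = post,
       mean_psi = sum(rowSums(post) * grid),
       mean_p = sum(colSums(post) * grid),
       d = d, m = m)
}

#' Sample from a grid posterior, including latent incidence
#'
#' Draws (psi, p) pairs from the quadrature posterior of
#' [single_species_grid_posterior()] and, for each draw, latent incidence
#' z_j from its exact conditional: z = 1 with certainty at sites with a
#' detection, otherwise with probability
#' psi (1-p)^m / (psi (1-p)^m + 1 - psi).
#'
#' @param gp Result of [single_species_grid_posterior()].
#' @param n_draws Number of posterior draws.
#' @return List with vectors `psi`, `p` and matrix `z` (draw x site).
#' @export
draw_from_grid_posterior <- function(gp, n_draws) {
  idx <- sample.int(length(gp$posterior), n_draws, replace = TRUE,
                    prob = as.vector(gp$posterior))
  n <- length(gp$psi_grid)
  psi <- gp$psi_grid[(idx - 1L) %% n + 1L]
  p <- gp$p_grid[(idx - 1L) %/% n + 1L]
  J <- length(gp$d)
  z <- matrix(0L, n_draws, J)
  for (j in seq_len(J)) {
    if (gp$d[j] > 0) {
      z[, j] <- 1L
    } else {
      num <- psi * (1 - p)^gp$m[j]
      z[, j] <- (runif(n_draws) < num / (num + 1 - psi)) * 1L
    }
  }
  list(psi = psi, p = p, z = z)
}
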