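# Small fixtures built in code.

# single-species detection history: y is sites x visits (one primary period)
dh_single <- function(y, mask = NULL, season = "spring") {
  y <- as.matrix(y)
  J <- nrow(y); Tm <- ncol(y)
  if (is.null(mask)) mask <- matrix(TRUE, J, Tm)
  detection_history(array(y, c(1, J, 1, Tm)), array(mask, c(J, 1, Tm)),
                    "sp1", paste0("s", seq_len(J)), season)
}

# random multi-species instance with covariates, ragged mask, and a random
# hierarchical parameter state (for likelihood oracles)
random_instance <- function(seed, N = 3, J = 4, K = 2, Tm = 2,
                            n_occ = 2, n_det = 1) {
  set.seed(seed)
  mask <- array(runif(J * K * Tm) < 0.85, c(J, K, Tm))
  mask[1, 1, 1] <- TRUE   # keep at least one visit
  y <- array(NA_real_, c(N, J, K, Tm))
  for (i in 1:N) y[i, , , ][mask] <- rbinom(sum(mask), 1, 0.4)
  # ensure every species has a detection somewhere
  for (i in 1:N) if (!any(y[i, , , ] == 1, na.rm = TRUE))
    y[i, , , ][which(mask)[1]] <- 1
  dh <- detection_history(y, mask, paste0("sp", 1:N), paste0("s", 1:J),
                          "spring")
  occ <- matrix(rnorm(J * n_occ), J,
                dimnames = list(NULL, paste0("x", 1:n_occ)))
  visit <- array(rnorm(J * K * Tm * n_det), c(J, K, Tm, n_det),
                 dimnames = list(NULL, NULL, NULL, paste0("w", 1:n_det)))
  ct <- covariate_table(scale(occ, scale = apply(occ, 2, function(v)
    sqrt(mean((v - mean(v))^2)))), site_ids = paste0("s", 1:J))
  ct$visit <- list(spring = visit)
  ct$standardized <- TRUE
  ct$center <- c(colMeans(occ), setNames(rep(0, n_det), paste0("w", 1:n_det)))
  ct$scale <- c(apply(occ, 2, function(v) sqrt(mean((v - mean(v))^2))),
                setNames(rep(1, n_det), paste0("w", 1:n_det)))
  state <- list(
    alpha = matrix(rnorm(N * (1 + n_occ), 0, 0.8), N),
    beta = matrix(rnorm(N * (K + n_det), 0, 0.8), N),
    z = array(0L, c(N, J, K)),
    mu_alpha = rnorm(1 + n_occ, 0, 0.5),
    sigma2_alpha = rgamma(1 + n_occ, 3, 3) + 0.2,
    mu_beta = rnorm(K + n_det, 0, 0.5),
    sigma2_beta = rgamma(K + n_det, 3, 3) + 0.2)
  # z consistent with detections
  for (i in 1:N) for (j in 1:J) for (k in 1:K) {
    det <- any(y[i, j, k, ] == 1, na.rm = TRUE)
    state$z[i, j, k] <- if (det) 1L else rbinom(1, 1, 0.5)
  }
  list(dh = dh, ct = ct, state = state)
}

# explicit-loop brute-force evaluation of the model's log joint density;
# deliberately unvectorized and independent of the package implementation
brute_force_log_joint <- function(state, dh, ct, priors) {
  N <- dim(dh$y)[1]; J <- dim(dh$y)[2]; K <- dim(dh$y)[3]
  Tm <- dim(dh$y)[4]
  Xocc <- cbind(1, ct$site)
  lp <- 0
  # hyperpriors
  for (f in seq_along(state$mu_alpha)) {
    lp <- lp + dnorm(state$mu_alpha[f], 0, sqrt(priors$mean_var), log = TRUE)
    s2 <- state$sigma2_alpha[f]
    lp <- lp + priors$var_shape * log(priors$var_rate) -
      lgamma(priors$var_shape) - (priors$var_shape + 1) * log(s2) -
      priors$var_rate / s2
  }
  for (f in seq_along(state$mu_beta)) {
    lp <- lp + dnorm(state$mu_beta[f], 0, sqrt(priors$mean_var), log = TRUE)
    s2 <- state$sigma2_beta[f]
    lp <- lp + priors$var_shape * log(priors$var_rate) -
      lgamma(priors$var_shape) - (priors$var_shape + 1) * log(s2) -
      priors$var_rate / s2
  }
  for (i in 1:N) {
    for (f in seq_along(state$mu_alpha))
      lp <- lp + dnorm(state$alpha[i, f], state$mu_alpha[f],
                       sqrt(state$sigma2_alpha[f]), log = TRUE)
    for (f in seq_along(state$mu_beta))
      lp <- lp + dnorm(state$beta[i, f], state$mu_beta[f],
                       sqrt(state$sigma2_beta[f]), log = TRUE)
    for (j in 1:J) for (k in 1:K) {
      if (!any(dh$mask[j, k, ])) next
      psi <- 1 / (1 + exp(-sum(Xocc[j, ] * state$alpha[i, ])))
      z <- state$z[i, j, k]
      lp <- lp + log(if (z == 1) psi else 1 - psi)
      for (t in 1:Tm) {
        if (!dh$mask[j, k, t]) next
        eta <- state$beta[i, k] +
          sum(ct$visit$spring[j, k, t, ] *
                state$beta[i, (K + 1):ncol(state$beta)])
        p <- 1 / (1 + exp(-eta)) * z
        yv <- dh$y[i, j, k, t]
        lp <- lp + log(if (yv == 1) p else 1 - p)
      }
    }
  }
  lp
}

# toy msom_fit-like object with prescribed coefficient draws, for testing
# derived-quantity functions without running MCMC
fake_fit <- function(alpha_draws, occ_names, scale = NULL,
                     species = paste0("sp", seq_len(dim(alpha_draws)[2]))) {
  dimnames(alpha_draws) <- list(NULL, species, occ_names)
  structure(list(
    alpha = alpha_draws, n_retained = dim(alpha_draws)[1],
    species_ids = species, occ_names = occ_names,
    standardization = if (!is.null(scale)) list(scale = scale)
  ), class = "msom_fit")
}
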