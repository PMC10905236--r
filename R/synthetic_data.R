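# Synthetic survey generator. Emulates the study conditions the models
# assume: ~45 one-hectare sites a few kilometers apart, ~80 bird species
# per season on a 3 primary x 3 secondary robust design (9 roughly weekly
# visits), species-level logit-linear occupancy and detection responses
# drawn from community normal distributions, correlated site covariates at
# three spatial scales, and Poisson pollinator richness counts.

#' Generator configuration
#'
#' Defaults mirror the assumed field conditions: 45 sites, 80 species,
#' 3 x 3 robust design in four seasons, community hyperparameters tuned to
#' mean occupancy near 0.5 and cumulative detection probability (p-star)
#' near 0.7-0.85 over 9 visits, mildly correlated covariates, and
#' missingness leaving 35-44 of 45 sites surveyed per season.
#'
#' @param n_sites,n_species Community size.
#' @param seasons Season labels.
#' @param n_primary,n_secondary Robust design per season.
#' @param extent_m Side of the square site extent in meters (6700 m makes
#'   the mean pairwise spacing about 3.5 km).
#' @param occ_mu,occ_sd Community means and standard deviations for the
#'   occupancy intercept and the ten slopes (model scale).
#' @param det_mu,det_sd Community means/sds for the per-primary detection
#'   intercepts and the four visit-covariate slopes.
#' @param cov_corr Correlation matrix for the ten site covariates (Gaussian
#'   copula); must be positive semi-definite.
#' @param pollinator_beta True Poisson log-linear coefficients (intercept
#'   plus ten covariates) for pollinator richness.
#' @param missing_sites Range (min, max) of surveyed sites per season; use
#'   `c(n_sites, n_sites)` for complete surveys.
#' @param seed Master seed; the same seed yields bit-identical datasets.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_sites = 45L, n_species = 80L,
                             seasons = SEASON_LEVELS,
                             n_primary = 3L, n_secondary = 3L,
                             extent_m = 6700,
                             occ_mu = c(`(Intercept)` = 0,
                                        canopy_local = 0.4,
                                        native_tree_prop = 0.1,
                                        impervious_local = -0.3,
                                        shrub_total = 0.1,
                                        shrub_native = 0.1,
                                        vertical_complexity = 0.1,
                                        canopy_neigh = 0.2,
                                        impervious_neigh = -0.2,
                                        dist_bay_km = -0.3,
                                        dist_stream_km = -0.5),
                             occ_sd = c(1, rep(0.5, 10)),
                             det_mu = c(rep(-1.6, n_primary),
                                        julian_day = 0.1,
                                        julian_day_sq = -0.1,
                                        min_after_sunrise = -0.2,
                                        noise_leq = -0.2),
                             det_sd = c(rep(0.5, n_primary), rep(0.25, 4)),
                             cov_corr = default_cov_corr(),
                             pollinator_beta = c(`(Intercept)` = 1.1,
                                                 canopy_local = -0.25,
                                                 native_tree_prop = 0.15,
                                                 impervious_local = -0.25,
                                                 shrub_total = 0,
                                                 shrub_native = 0,
                                                 vertical_complexity = 0,
                                                 canopy_neigh = 0,
                                                 impervious_neigh = 0,
                                                 dist_bay_km = -0.4,
                                                 dist_stream_km = 0),
                             missing_sites = c(35L, 44L),
                             seed = 1L) {
  stopifnot(length(occ_mu) == 11L, length(occ_sd) == 11L,
            length(det_mu) == n_primary + 4L,
            length(det_sd) == n_primary + 4L)
  names(occ_mu) <- c("(Intercept)", OCC_COVARIATES)
  names(occ_sd) <- names(occ_mu)
  names(det_mu) <- c(paste0("p_intercept_", seq_len(n_primary)),
                     DET_COVARIATES)
  names(det_sd) <- names(det_mu)
  stopifnot(all(occ_sd > 0), all(det_sd > 0))
  ev <- eigen(cov_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("covariate correlation matrix is not positive semi-definite")
  if (n_sites < missing_sites[2]) missing_sites <- c(n_sites, n_sites)
  structure(list(
    n_sites = as.integer(n_sites), n_species = as.integer(n_species),
    seasons = seasons, n_primary = as.integer(n_primary),
    n_secondary = as.integer(n_secondary), extent_m = extent_m,
    occ_mu = occ_mu, occ_sd = occ_sd, det_mu = det_mu, det_sd = det_sd,
    cov_corr = cov_corr, pollinator_beta = pollinator_beta,
    missing_sites = as.integer(missing_sites), seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default covariate correlation structure
#'
#' Identity apart from canopy/impervious trade-offs within and across the
#' local and neighborhood scales and a mild bay/stream distance
#' correlation.
#'
#' @return A 10 x 10 correlation matrix over the occupancy covariates.
#' @export
default_cov_corr <- function() {
  R <- diag(10)
  dimnames(R) <- list(OCC_COVARIATES, OCC_COVARIATES)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("canopy_local", "canopy_neigh", 0.5)
  set_r("impervious_local", "impervious_neigh", 0.5)
  set_r("canopy_local", "impervious_local", -0.4)
  set_r("canopy_neigh", "impervious_neigh", -0.4)
  set_r("canopy_local", "impervious_neigh", -0.2)
  set_r("canopy_neigh", "impervious_local", -0.2)
  set_r("dist_bay_km", "dist_stream_km", 0.3)
  R
}

# marginal quantile functions for the raw covariates
COV_MARGINALS <- list(
  canopy_local = function(u) 100 * qbeta(u, 2, 2),
  native_tree_prop = function(u) qbeta(u, 2, 2),
  impervious_local = function(u) 100 * qbeta(u, 2, 3),
  shrub_total = function(u) 100 * qbeta(u, 2, 4),
  shrub_native = function(u) 100 * qbeta(u, 2, 5),
  vertical_complexity = function(u) qbeta(u, 2, 2),
  canopy_neigh = function(u) 100 * qbeta(u, 2, 2),
  impervious_neigh = function(u) 100 * qbeta(u, 3, 2),
  dist_bay_km = function(u) qunif(u, 0.2, 12),
  dist_stream_km = function(u) qunif(u, 0.05, 3)
)

#' Generate correlated site covariates and coordinates
#'
#' Draws site covariates through a Gaussian copula (multivariate normal
#' scores mapped through realistic marginals: scaled Beta for covers and
#' fractions, uniform for distances) and uniform planar coordinates over a
#' square extent.
#'
#' @param config A [generator_config]. Seed from the config's current RNG
#'   state; call inside `set.seed()` or use [simulate_dataset()].
#' @return List with `covariates` (raw-scale [covariate_table]) and
#'   `coords` (n_sites x 2, meters).
#' @export
gen_sites <- function(config) {
  J <- config$n_sites
  R <- config$cov_corr
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  Z <- matrix(rnorm(J * ncol(R)), J) %*% L
  U <- pnorm(Z)
  X <- vapply(seq_along(OCC_COVARIATES), function(c)
    COV_MARGINALS[[OCC_COVARIATES[c]]](U[, c]), numeric(J))
  colnames(X) <- OCC_COVARIATES
  site_ids <- sprintf("site_%02d", seq_len(J))
  rownames(X) <- site_ids
  coords <- cbind(x_m = runif(J, 0, config$extent_m),
                  y_m = runif(J, 0, config$extent_m))
  rownames(coords) <- site_ids
  list(covariates = covariate_table(X, site_ids = site_ids),
       coords = coords)
}

#' Draw true species coefficients from the community layer
#'
#' @param config A [generator_config].
#' @return List with matrices `alpha` (species x occupancy coefficients)
#'   and `beta` (species x detection coefficients), plus the community
#'   means/sds used.
#' @export
gen_community <- function(config) {
  N <- config$n_species
  alpha <- vapply(seq_along(config$occ_mu), function(f)
    rnorm(N, config$occ_mu[f], config$occ_sd[f]), numeric(N))
  beta <- vapply(seq_along(config$det_mu), function(f)
    rnorm(N, config$det_mu[f], config$det_sd[f]), numeric(N))
  colnames(alpha) <- names(config$occ_mu)
  colnames(beta) <- names(config$det_mu)
  rownames(alpha) <- rownames(beta) <- sprintf("sp_%03d", seq_len(N))
  list(alpha = alpha, beta = beta,
       occ_mu = config$occ_mu, occ_sd = config$occ_sd,
       det_mu = config$det_mu, det_sd = config$det_sd)
}

SEASON_START <- c(winter = "2015-11-01", spring = "2016-03-01",
                  summer = "2016-05-01", fall = "2016-08-01")

# raw visit covariates + dates for one season (approximately weekly visits)
gen_visit_schedule <- function(config, season, surveyed) {
  J <- config$n_sites
  K <- config$n_primary; Tm <- config$n_secondary
  base <- as.Date(SEASON_START[[season]])
  varr <- array(NA_real_, c(J, K, Tm, length(DET_COVARIATES_RAW)),
                dimnames = list(NULL, NULL, NULL, DET_COVARIATES_RAW))
  dates <- array(as.Date(NA), c(J, K, Tm))
  mask <- array(FALSE, c(J, K, Tm))
  for (j in which(surveyed)) {
    v <- 0L
    for (k in seq_len(K)) for (t in seq_len(Tm)) {
      v <- v + 1L
      dt <- base + 7L * (v - 1L) + sample.int(5L, 1L) - 3L
      dates[j, k, t] <- dt
      mask[j, k, t] <- TRUE
      varr[j, k, t, "julian_day"] <- as.integer(format(dt, "%j"))
      varr[j, k, t, "min_after_sunrise"] <- runif(1, 0, 240)
      varr[j, k, t, "noise_leq"] <- runif(1, 45, 70)
    }
  }
  list(visit = varr, dates = dates, mask = mask)
}

#' Simulate robust-design detection histories from known truth
#'
#' The generative direction of the fitted model: per species, site and
#' primary period z ~ Bernoulli(psi) with
#' logit(psi) = alpha0 + alpha' X_j, and per conducted visit
#' y ~ Bernoulli(z p) with logit(p) = beta0_k + beta' X_jkt. Species with
#' no detection in the season are dropped from the returned history, as in
#' the seasonal species-list rule.
#'
#' @param truth Output of [gen_community()].
#' @param covariates Standardized [covariate_table] with visit covariates
#'   for `season`.
#' @param config A [generator_config].
#' @param season Season label.
#' @param mask Logical visit mask (site x primary x secondary).
#' @return List: `det_hist` (a [detection_history]), `z_true`
#'   (species x site x primary), `psi`, and the retained species index.
#' @export
simulate_surveys <- function(truth, covariates, config, season, mask) {
  J <- config$n_sites; K <- config$n_primary; Tm <- config$n_secondary
  N <- nrow(truth$alpha)
  Xocc <- cbind(1, covariates$site)
  psi <- plogis(Xocc %*% t(truth$alpha))           # J x N
  z <- array(rbinom(N * J * K, 1, rep(t(psi), K)), c(N, J, K))
  varr <- covariates$visit[[season]]
  y <- array(NA_real_, c(N, J, K, Tm))
  for (k in seq_len(K)) {
    b0 <- truth$beta[, k]                          # species intercepts
    for (t in seq_len(Tm)) {
      obs <- which(mask[, k, t])
      if (!length(obs)) next
      W <- matrix(varr[obs, k, t, DET_COVARIATES], length(obs))
      eta <- matrix(b0, length(obs), N, byrow = TRUE) +
        W %*% t(truth$beta[, DET_COVARIATES, drop = FALSE])
      p <- plogis(eta)                             # obs x N
      zz <- t(z[, obs, k])                         # obs x N
      y[, obs, k, t] <- t((matrix(runif(length(p)), nrow(p)) < p * zz) * 1)
    }
  }
  detected <- apply(y == 1, 1, any, na.rm = TRUE)
  species <- rownames(truth$alpha)
  dh <- detection_history(y[detected, , , , drop = FALSE], mask,
                          species[detected], covariates$site_ids, season)
  list(det_hist = dh, z_true = z, psi = psi, retained = which(detected))
}

#' Simulate pollinator richness counts
#'
#' richness ~ Poisson(exp(beta0 + beta' X_j)) per site.
#'
#' @param beta Named true coefficient vector (intercept first).
#' @param covariates Standardized [covariate_table].
#' @param season Season label attached to the output.
#' @return Data frame site_id, season, richness plus the covariates.
#' @export
simulate_pollinators <- function(beta, covariates,
                                 season = "early_summer") {
  X <- cbind(1, covariates$site[, names(beta)[-1], drop = FALSE])
  lambda <- exp(as.numeric(X %*% beta))
  data.frame(site_id = covariates$site_ids, season = season,
             richness = rpois(length(lambda), lambda),
             covariates$site, row.names = NULL)
}

#' Simulate monthly urban-tolerance scores
#'
#' Species-level latent tolerance with small monthly variation; a few
#' species are left unscored to exercise the exclusion rule.
#'
#' @param species_ids Species identifiers.
#' @param n_unscored Number of species with no score data.
#' @return Data frame species_id, month, score.
#' @export
simulate_tolerance_scores <- function(species_ids, n_unscored = 3L) {
  latent <- runif(length(species_ids))
  # keep at least three scored species so tertiles remain defined
  n_unscored <- min(n_unscored, max(0L, length(species_ids) - 3L))
  unscored <- if (n_unscored > 0)
    sample(seq_along(species_ids), n_unscored) else integer(0)
  out <- do.call(rbind, lapply(seq_along(species_ids), function(i) {
    if (i %in% unscored) return(NULL)
    data.frame(species_id = species_ids[i], month = 1:12,
               score = pmin(pmax(latent[i] + rnorm(12, 0, 0.03), 0), 1))
  }))
  if (is.null(out))
    out <- data.frame(species_id = character(0), month = integer(0),
                      score = numeric(0))
  attr(out, "unscored") <- species_ids[unscored]
  out
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates [gen_sites()], [gen_community()], [simulate_surveys()] per
#' season (with missing-completely-at-random site-season gaps),
#' [simulate_pollinators()] and [simulate_tolerance_scores()], all from the
#' config's master seed (bit-reproducible).
#'
#' @param config A [generator_config].
#' @return List with `design`, `detections` (per season), `covariates`
#'   (standardized, with raw retained), `truth` (community coefficients and
#'   per-season true z), `pollinators`, `tolerance_scores`, `config`.
#' @export
simulate_dataset <- function(config = generator_config()) {
  set.seed(config$seed)
  sites <- gen_sites(config)
  truth <- gen_community(config)
  schedules <- list()
  visit_raw <- list()
  masks <- list()
  for (s in config$seasons) {
    n_surv <- if (config$missing_sites[1] == config$missing_sites[2])
      config$missing_sites[1]
    else
      sample(config$missing_sites[1]:config$missing_sites[2], 1)
    surveyed <- rep(FALSE, config$n_sites)
    surveyed[sample.int(config$n_sites, n_surv)] <- TRUE
    sch <- gen_visit_schedule(config, s, surveyed)
    schedules[[s]] <- sch
    visit_raw[[s]] <- sch$visit
    masks[[s]] <- sch$mask
  }
  ct_raw <- covariate_table(sites$covariates$site, visit = visit_raw,
                            site_ids = sites$covariates$site_ids)
  ct <- standardize_covariates(ct_raw)
  detections <- list(); z_true <- list()
  for (s in config$seasons) {
    sim <- simulate_surveys(truth, ct, config, s, masks[[s]])
    detections[[s]] <- sim$det_hist
    z_true[[s]] <- sim$z_true
  }
  design <- survey_design(ct$site_ids, sites$coords,
                          seasons = config$seasons,
                          n_primary = config$n_primary,
                          n_secondary = config$n_secondary)
  poll <- do.call(rbind, lapply(c("spring", "early_summer", "late_summer"),
                                function(s)
    simulate_pollinators(config$pollinator_beta, ct, season = s)))
  all_spp <- sort(unique(unlist(lapply(detections,
                                       function(d) d$species_ids))))
  tol <- simulate_tolerance_scores(all_spp)
  list(design = design, detections = detections, covariates = ct,
       truth = c(truth, list(z = z_true)), pollinators = poll,
       tolerance_scores = tol, schedules = schedules, config = config)
}

#' Write a simulated dataset to the survey CSV schemas
#'
#' Emits `detections.csv`, `site_covariates.csv` and `visit_covariates.csv`
#' (raw scale) so that [load_survey_tables()] round-trips the simulated
#' detections, masks and covariates.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_survey_csvs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  sc <- data.frame(site_id = sim$design$site_ids, sim$design$coords,
                   sim$covariates$site_raw, row.names = NULL)
  det_rows <- list(); vc_rows <- list()
  for (s in cfg$seasons) {
    sch <- sim$schedules[[s]]
    dh <- sim$detections[[s]]
    for (j in seq_len(cfg$n_sites)) for (k in seq_len(cfg$n_primary))
      for (t in seq_len(cfg$n_secondary)) {
        if (!sch$mask[j, k, t]) next
        dt <- as.Date(sch$dates[j, k, t], origin = "1970-01-01")
        vc_rows[[length(vc_rows) + 1L]] <- data.frame(
          site_id = sim$design$site_ids[j], season = s,
          visit_date = format(dt),
          julian_day = sch$visit[j, k, t, "julian_day"],
          min_after_sunrise = sch$visit[j, k, t, "min_after_sunrise"],
          noise_leq = sch$visit[j, k, t, "noise_leq"])
        hit <- which(dh$y[, j, k, t] == 1)
        if (length(hit))
          det_rows[[length(det_rows) + 1L]] <- data.frame(
            site_id = sim$design$site_ids[j], season = s,
            visit_date = format(dt), species_id = dh$species_ids[hit],
            detected = 1L)
      }
  }
  paths <- file.path(dir, c("detections.csv", "site_covariates.csv",
                            "visit_covariates.csv"))
  write.csv(do.call(rbind, det_rows), paths[1], row.names = FALSE)
  write.csv(sc, paths[2], row.names = FALSE)
  write.csv(do.call(rbind, vc_rows), paths[3], row.names = FALSE)
  invisible(paths)
}
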