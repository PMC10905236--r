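#' Per-draw occupancy probabilities at new covariate vectors
#'
#' @param fit An [msom_fit].
#' @param newdata Matrix (new sites x occupancy covariates, model scale) or
#'   a single named vector. All fitted occupancy covariates must be present.
#' @return Array (draw x species x new site) of psi.
#' @export
predict_psi <- function(fit, newdata) {
  X <- resolve_newdata(fit, newdata)
  S <- fit$n_retained; N <- length(fit$species_ids); P <- ncol(X)
  out <- array(NA_real_, c(S, N, nrow(X)),
               dimnames = list(NULL, fit$species_ids, rownames(X)))
  am <- matrix(fit$alpha, S * N, P)
  for (s in seq_len(nrow(X)))
    out[, , s] <- matrix(plogis(am %*% X[s, ]), S, N)
  out
}

resolve_newdata <- function(fit, newdata) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  covs <- setdiff(fit$occ_names, "(Intercept)")
  miss <- setdiff(covs, colnames(newdata))
  if (length(miss))
    stop("missing covariate(s): ", paste(miss, collapse = ", "))
  cbind(`(Intercept)` = 1, newdata[, covs, drop = FALSE])
}

#' Predict latent incidence at new sites
#'
#' For each retained draw, computes psi from that draw's species
#' coefficients and samples a Bernoulli incidence, so estimation uncertainty
#' propagates draw by draw. Use the `psi` element for expected-richness
#' variants that average psi instead of sampling z.
#'
#' @inheritParams predict_psi
#' @param seed Optional seed for the incidence stream.
#' @return List of class `incidence_pred` with arrays `z` and `psi`
#'   (draw x species x new site).
#' @export
predict_incidence <- function(fit, newdata, seed = NULL) {
  psi <- predict_psi(fit, newdata)
  if (!is.null(seed)) set.seed(seed)
  z <- array((array(runif(length(psi)), dim(psi)) < psi) * 1L, dim(psi),
             dimnames = dimnames(psi))
  structure(list(z = z, psi = psi), class = "incidence_pred")
}

#' Species richness posterior from incidence draws
#'
#' Sums latent incidence over a chosen species subset, draw by draw.
#'
#' @param incidence Matrix (draw x species) of 0/1 incidence with species
#'   names as column names, or an `incidence_pred` (then `site` selects the
#'   new-site slice).
#' @param subset Character vector of species to count (default all).
#' @param site New-site index when `incidence` is an `incidence_pred`.
#' @param mass HDI mass for the summary.
#' @return Object of class `richness_posterior`: `draws`, `mean`, `hdi`.
#' @export
richness_posterior <- function(incidence, subset = NULL, site = 1L,
                               mass = 0.95) {
  if (inherits(incidence, "incidence_pred"))
    incidence <- incidence$z[, , site, drop = TRUE]
  incidence <- as.matrix(incidence)
  if (is.null(subset)) subset <- colnames(incidence)
  if (length(subset) == 0L) stop("empty species subset")
  miss <- setdiff(subset, colnames(incidence))
  if (length(miss))
    stop("subset species not modeled: ", paste(miss, collapse = ", "))
  draws <- rowSums(incidence[, subset, drop = FALSE])
  structure(list(draws = draws, mean = mean(draws), hdi = hdi(draws, mass),
                 n_species = length(subset)),
            class = "richness_posterior")
}

#' @export
print.richness_posterior <- function(x, ...) {
  cat(sprintf("Richness posterior over %d species: mean %.1f, 95%% HDI %.1f-%.1f\n",
              x$n_species, x$mean, x$hdi[1], x$hdi[2]))
  invisible(x)
}

# The six scenario-driving covariates and the sign of their assumed
# association with community occupancy (+1: more is better).
SCENARIO_DRIVERS <- list(
  local = c(canopy_local = +1, impervious_local = -1),
  neighborhood = c(canopy_neigh = +1, impervious_neigh = -1),
  landscape = c(dist_bay_km = -1, dist_stream_km = -1)
)

#' Hypothetical good/poor site scenarios by spatial scale
#'
#' Builds covariate vectors for hypothetical sites: at each scale the
#' driving covariates are set to their observed maximum (positive
#' association) or minimum (negative association) for "good" conditions and
#' to the opposite extreme for "poor"; every non-driving covariate is held
#' at its standardized mean (0). All 2^3 combinations of good/poor across
#' the local, neighborhood and landscape scales are returned.
#'
#' @param covariates Standardized [covariate_table] with raw values retained
#'   (as produced by [standardize_covariates()]).
#' @param directions Named list per scale of signed driving covariates;
#'   the default uses maximum canopy / minimum impervious cover (local and
#'   neighborhood) and minimum distances to bay and stream (landscape) as
#'   "good".
#' @return Data frame with one row per scenario (columns `local`,
#'   `neighborhood`, `landscape` holding "good"/"poor") and an attached
#'   matrix attribute `x` of model-scale covariate vectors.
#' @export
build_scenarios <- function(covariates, directions = SCENARIO_DRIVERS) {
  if (!isTRUE(covariates$standardized) || is.null(covariates$site_raw))
    stop("need a standardized covariate table with raw values retained")
  for (sc in names(directions))
    if (is.null(directions[[sc]]) || !length(directions[[sc]]))
      stop("direction missing for scale ", sc)
  all_drivers <- unlist(unname(lapply(directions, names)))
  covs <- colnames(covariates$site)
  miss <- setdiff(all_drivers, covs)
  if (length(miss))
    stop("direction given for unknown covariate(s): ",
         paste(miss, collapse = ", "))
  grid <- expand.grid(local = c("good", "poor"),
                      neighborhood = c("good", "poor"),
                      landscape = c("good", "poor"),
                      stringsAsFactors = FALSE)
  X <- matrix(0, nrow(grid), length(covs), dimnames = list(NULL, covs))
  for (r in seq_len(nrow(grid))) {
    for (sc in names(directions)) {
      quality <- grid[r, sc]
      for (v in names(directions[[sc]])) {
        sgn <- directions[[sc]][[v]]
        raw <- covariates$site_raw[, v]
        want_max <- (sgn > 0) == (quality == "good")
        val <- if (want_max) max(raw) else min(raw)
        X[r, v] <- cov_to_model_scale(covariates, v, val)
      }
    }
  }
  rownames(X) <- paste(substr(grid$local, 1, 4), substr(grid$neighborhood, 1, 4),
                       substr(grid$landscape, 1, 4), sep = "_")
  grid$scenario <- rownames(X)
  attr(grid, "x") <- X
  grid
}

#' Annual richness by matching seasonal posterior draws
#'
#' Seasonal models are fitted independently, so their posteriors are
#' independent; draws are matched by retained-draw index (chains
#' concatenated in a fixed order) and a species counts once if present in
#' at least one season's draw. Species absent from a season's model
#' contribute nothing for that season.
#'
#' @param seasonal_incidence Named list (by season) of draw x species
#'   incidence matrices with species names as column names; equal draw
#'   counts required.
#' @param species Union species list (default: union over seasons).
#' @param mass HDI mass for the summary.
#' @return A `richness_posterior` for annual richness.
#' @export
annual_richness <- function(seasonal_incidence, species = NULL,
                            mass = 0.95) {
  ns <- vapply(seasonal_incidence, nrow, 0L)
  if (length(unique(ns)) != 1L)
    stop("seasonal posteriors have mismatched draw counts: ",
         paste(ns, collapse = ", "))
  if (is.null(species))
    species <- Reduce(union, lapply(seasonal_incidence, colnames))
  S <- ns[[1]]
  present <- matrix(0L, S, length(species), dimnames = list(NULL, species))
  for (zs in seasonal_incidence) {
    common <- intersect(colnames(zs), species)
    present[, common] <- pmax(present[, common, drop = FALSE],
                              zs[, common, drop = FALSE])
  }
  richness_posterior(present, subset = species, mass = mass)
}

#' Cumulative detection probability over repeated visits
#'
#' p-star is the probability that an occupying species is detected at least
#' once across all visits at a site: 1 - prod(1 - p_t).
#'
#' @param p_draws Matrix (draw x visit) of per-visit detection
#'   probabilities, or a vector for a single draw.
#' @param n_visits Optional check on the number of visits.
#' @return Vector of per-draw p-star values.
#' @export
pstar <- function(p_draws, n_visits = NULL) {
  if (is.null(dim(p_draws))) p_draws <- t(as.matrix(p_draws))
  p_draws <- as.matrix(p_draws)
  if (any(p_draws < 0 | p_draws > 1, na.rm = TRUE))
    stop("detection probabilities must lie in [0, 1]")
  if (!is.null(n_visits) && ncol(p_draws) != n_visits)
    stop("expected ", n_visits, " visits, got ", ncol(p_draws))
  1 - apply(1 - p_draws, 1, prod, na.rm = TRUE)
}

#' Community summary of cumulative detection probability
#'
#' Computes p-star per species and site over all conducted visits in the
#' fitted season (using each draw's detection coefficients), then averages
#' over species and sites per draw.
#'
#' @param fit An [msom_fit].
#' @return List with `mean` (posterior mean of the community average
#'   p-star), `hdi`, and `draws`.
#' @export
community_pstar <- function(fit) {
  md <- fit$model_data
  S <- fit$n_retained; N <- length(fit$species_ids)
  acc <- matrix(0, S, N)
  site_of_visit <- md$cell_site[md$visit_cell + 1L] + 1L
  sites <- sort(unique(site_of_visit))
  for (i in seq_len(N)) {
    P <- plogis(md$Bdet %*% t(fit$beta[, i, ]))   # nobs x S
    logq <- rowsum(log1p(-P), site_of_visit)      # per site: sum log(1-p)
    acc[, i] <- colMeans(1 - exp(logq))           # mean over sites
  }
  draws <- rowMeans(acc)
  list(mean = mean(draws), hdi = hdi(draws, 0.95), draws = draws)
}

#' Classify species responses to a covariate by HDI rule
#'
#' A species responds positively (negatively) to a covariate when the
#' level-HDI of its slope lies entirely above (below) zero. The
#' conventional "strong response" level is 0.75; "significant" is 0.95.
#'
#' @param fit An [msom_fit].
#' @param covariate Occupancy covariate name.
#' @param level HDI mass in (0, 1).
#' @return Data frame (species, mean, hdi_low, hdi_high, direction) with
#'   attribute `fractions` giving community fractions positive/negative.
#' @export
species_response_summary <- function(fit, covariate, level = 0.75) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (!covariate %in% fit$occ_names)
    stop("covariate not among fitted slopes: ", covariate)
  f <- match(covariate, fit$occ_names)
  out <- lapply(seq_along(fit$species_ids), function(i) {
    d <- fit$alpha[, i, f]
    h <- hdi(d, level)
    dir <- if (h[1] > 0) "positive" else if (h[2] < 0) "negative" else "neither"
    data.frame(species = fit$species_ids[i], mean = mean(d),
               hdi_low = h[1], hdi_high = h[2], direction = dir)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "fractions") <- c(
    positive = mean(out$direction == "positive"),
    negative = mean(out$direction == "negative"),
    neither = mean(out$direction == "neither"))
  out
}

#' Expected richness change for a raw-unit covariate shift
#'
#' For each retained draw, sums over species the change in occupancy
#' probability when one covariate moves by `delta_raw` raw units from a
#' baseline site (default: the average site, all covariates at their
#' standardized mean). Positive values are species gained, negative species
#' lost. The raw-to-model conversion uses the standardization record stored
#' with the fit and is therefore specific to the fitted data.
#'
#' @param fit An [msom_fit] fitted with covariates.
#' @param covariate Occupancy covariate name.
#' @param delta_raw Shift in raw units (e.g. 10 for "+10% canopy cover",
#'   0.5 for "+0.5 km").
#' @param baseline Named model-scale covariate vector (default all zeros).
#' @param mass HDI mass for the summary.
#' @return List with `mean`, `hdi`, `draws` of the richness change.
#' @export
richness_delta <- function(fit, covariate, delta_raw, baseline = NULL,
                           mass = 0.95) {
  covs <- setdiff(fit$occ_names, "(Intercept)")
  if (!covariate %in% covs) stop("unknown covariate: ", covariate)
  if (is.null(fit$standardization))
    stop("fit has no standardization record")
  x0 <- setNames(numeric(length(covs)), covs)
  if (!is.null(baseline)) x0[names(baseline)] <- baseline
  x1 <- x0
  x1[covariate] <- x1[covariate] +
    delta_raw / fit$standardization$scale[[covariate]]
  psi0 <- predict_psi(fit, x0)[, , 1, drop = TRUE]
  psi1 <- predict_psi(fit, x1)[, , 1, drop = TRUE]
  if (is.null(dim(psi0))) { psi0 <- as.matrix(psi0); psi1 <- as.matrix(psi1) }
  draws <- rowSums(psi1) - rowSums(psi0)
  list(mean = mean(draws), hdi = hdi(draws, mass), draws = draws)
}
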