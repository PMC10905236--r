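#' Highest-density interval from posterior draws
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws.
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass in (0, 1).
#' @return Numeric vector `c(low, high)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n == 0L) stop("no draws")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Chi-square posterior predictive check
#'
#' For each retained draw, replicate detections y_rep are simulated from
#' that draw's incidence and detection probabilities; observed and
#' replicated detection counts are summed per site (over species, primary
#' periods and visits) and compared through
#' T = sum_sites (O - E)^2 / (E + eps) with E the site total of z * p.
#' The Bayesian p-value is the proportion of draws with T_rep >= T_obs;
#' values near 0 or 1 signal misfit.
#'
#' @param fit An [msom_fit].
#' @param seed Optional seed for the replication stream.
#' @param eps Guard added to E in the denominator.
#' @return List with `p_value`, and per-draw `T_obs`, `T_rep`.
#' @export
ppc_chisq <- function(fit, seed = NULL, eps = 1e-6) {
  md <- fit$model_data
  S <- fit$n_retained
  if (S < 1L) stop("no retained draws")
  if (!is.null(seed)) set.seed(seed)
  N <- length(fit$species_ids)
  site_of_visit <- md$cell_site[md$visit_cell + 1L] + 1L
  sites <- sort(unique(site_of_visit))
  grp <- match(site_of_visit, sites)
  G <- length(sites)
  ind <- matrix(0, length(grp), G)
  ind[cbind(seq_along(grp), grp)] <- 1
  O_tot <- numeric(G)
  E_tot <- matrix(0, S, G)
  Orep_tot <- matrix(0, S, G)
  for (i in seq_len(N)) {
    P <- plogis(md$Bdet %*% t(fit$beta[, i, ]))          # nobs x S
    zc <- fit$z[, i, , , drop = FALSE]                   # S x 1 x J x K
    zvis <- vapply(seq_len(md$ncell), function(c)
      zc[, 1, md$cells[c, 1], md$cells[c, 2]], numeric(S))  # S x ncell
    zv <- zvis[, md$visit_cell + 1L, drop = FALSE]       # S x nobs
    Ev <- zv * t(P)                                      # S x nobs
    O_tot <- O_tot + as.numeric(md$Y[, i] %*% ind)
    E_tot <- E_tot + Ev %*% ind
    yrep <- (matrix(runif(S * nrow(ind)), S) < Ev) * 1
    Orep_tot <- Orep_tot + yrep %*% ind
  }
  Om <- matrix(O_tot, S, G, byrow = TRUE)
  T_obs <- rowSums((Om - E_tot)^2 / (E_tot + eps))
  T_rep <- rowSums((Orep_tot - E_tot)^2 / (E_tot + eps))
  list(p_value = mean(T_rep >= T_obs), T_obs = T_obs, T_rep = T_rep)
}

#' Moran's I for one set of values under binary band weights
#'
#' I = (n / W) * sum_{j != l} w_jl r_j r_l / sum_j r_j^2 with values
#' mean-centered first and w_jl = 1 iff the pair distance falls in
#' (lower, upper].
#'
#' @param values Numeric vector per site.
#' @param coords Site coordinates (n x 2, meters).
#' @param lower,upper Band edges in meters.
#' @return List with `I` (NA when the band has no pairs or the values have
#'   zero variance), `n_pairs`, and `W`.
#' @export
morans_i <- function(values, coords, lower, upper) {
  d <- as.matrix(dist(coords))
  w <- (d > lower & d <= upper) * 1
  diag(w) <- 0
  W <- sum(w)
  r <- values - mean(values)
  ss <- sum(r^2)
  if (W == 0 || ss == 0)
    return(list(I = NA_real_, n_pairs = W / 2, W = W))
  list(I = (length(values) / W) * as.numeric(t(r) %*% w %*% r) / ss,
       n_pairs = W / 2, W = W)
}

#' Moran's I distance-band summary for a matrix of residual draws
#'
#' Core banding engine: given posterior draws of a site-level residual
#' field, computes Moran's I per draw in each distance band and summarizes
#' with an HDI. Values are mean-centered per draw; draws with zero residual
#' variance are skipped and counted.
#'
#' @param r_draws Matrix (draw x site) of residuals.
#' @param coords Site coordinates (site x 2, meters).
#' @param band_width,max_dist Band width and cap in meters.
#' @param min_pairs Minimum pair count for an unflagged band.
#' @param mass HDI mass.
#' @return Data frame per band: `lower`, `upper`, `n_pairs`, `flagged`,
#'   `mean`, `hdi_low`, `hdi_high`, `excludes_zero`, `n_skipped`.
#' @export
morans_i_bands <- function(r_draws, coords, band_width = 500,
                           max_dist = 5000, min_pairs = 20, mass = 0.95) {
  coords <- as.matrix(coords)
  r <- as.matrix(r_draws)
  J <- ncol(r)
  if (nrow(coords) != J) stop("coords must match residual columns")
  if (J < 3L) stop("need at least 3 sites")
  edges <- seq(0, max_dist, by = band_width)
  d <- as.matrix(dist(coords))
  r <- r - rowMeans(r)
  ss <- rowSums(r^2)
  ok <- ss > 0
  out <- lapply(seq_len(length(edges) - 1L), function(b) {
    w <- (d > edges[b] & d <= edges[b + 1]) * 1
    diag(w) <- 0
    W <- sum(w)
    base <- data.frame(lower = edges[b], upper = edges[b + 1],
                       n_pairs = W / 2, flagged = W / 2 <= min_pairs)
    if (W == 0 || !any(ok)) {
      base$mean <- NA_real_; base$hdi_low <- NA_real_
      base$hdi_high <- NA_real_; base$excludes_zero <- NA
      base$n_skipped <- nrow(r)
      return(base)
    }
    Idraws <- (J / W) * rowSums((r[ok, , drop = FALSE] %*% w) *
                                  r[ok, , drop = FALSE]) / ss[ok]
    h <- hdi(Idraws, mass)
    base$mean <- mean(Idraws); base$hdi_low <- h[1]; base$hdi_high <- h[2]
    base$excludes_zero <- h[1] > 0 || h[2] < 0
    base$n_skipped <- sum(!ok)
    base
  })
  do.call(rbind, out)
}

#' Residual spatial autocorrelation correlogram for an occupancy fit
#'
#' Latent occupancy residuals (discrepancies) r_j = z_j - psi_j are formed
#' per species and draw, averaging over primary periods within the season,
#' mean-centered, and summarized as Moran's I in distance bands (default
#' 500 m bands from 0 to 5 km). Bands with <= `min_pairs` site pairs are
#' flagged and should be excluded from inference. Draws with zero residual
#' variance are skipped and counted.
#'
#' @param fit An [msom_fit].
#' @param coords Site coordinates (sites x 2, meters) in fit site order.
#' @param band_width,max_dist Band width and cap in meters.
#' @param min_pairs Minimum pair count for an unflagged band.
#' @param mass HDI mass per species-band.
#' @return Object of class `correlogram_result`: `bands` (edges, n_pairs,
#'   flagged) and `summary` (species, band, posterior mean, HDI,
#'   excludes_zero, n_skipped).
#' @export
morans_i_residuals <- function(fit, coords, band_width = 500,
                               max_dist = 5000, min_pairs = 20,
                               mass = 0.95) {
  coords <- as.matrix(coords)
  J <- length(fit$site_ids)
  if (nrow(coords) != J) stop("coords must match fitted sites")
  if (J < 3L) stop("need at least 3 sites")
  md <- fit$model_data
  S <- fit$n_retained
  N <- length(fit$species_ids)
  P <- length(fit$occ_names)
  res <- vector("list", N)
  for (i in seq_len(N)) {
    psiJ <- plogis(matrix(fit$alpha[, i, ], S, P) %*% t(md$Xocc))  # S x J
    zmean <- apply(fit$z[, i, , , drop = FALSE], c(1, 3), mean)    # S x J
    bb <- morans_i_bands(zmean - psiJ, coords, band_width = band_width,
                         max_dist = max_dist, min_pairs = min_pairs,
                         mass = mass)
    bb$species <- fit$species_ids[i]
    bb$band <- seq_len(nrow(bb))
    res[[i]] <- bb
  }
  all <- do.call(rbind, res)
  bands <- unique(all[, c("lower", "upper", "n_pairs", "flagged")])
  structure(list(bands = bands,
                 summary = all[, c("species", "band", "mean", "hdi_low",
                                   "hdi_high", "excludes_zero",
                                   "n_skipped")]),
            class = "correlogram_result")
}

#' Moran's I correlogram for site-level counts
#'
#' Distance-class correlogram with the number of classes chosen by the
#' Sturges rule, ceiling(1 + log2(n_pairs)), over the observed distance
#' range, with a seeded permutation test per class.
#'
#' @param values Per-site counts (or any numeric values).
#' @param coords Site coordinates (n x 2, meters).
#' @param n_perm Number of permutations for the p-value.
#' @param seed Optional seed for the permutation stream.
#' @return Data frame per class: `lower`, `upper`, `n_pairs`, `I`,
#'   `p_value`.
#' @export
correlogram_counts <- function(values, coords, n_perm = 999, seed = NULL) {
  coords <- as.matrix(coords)
  n <- length(values)
  if (n < 4L) stop("need at least 4 sites")
  if (length(unique(values)) == 1L) stop("all values identical")
  if (!is.null(seed)) set.seed(seed)
  d <- as.matrix(dist(coords))
  dv <- d[upper.tri(d)]
  n_pairs <- length(dv)
  n_classes <- ceiling(1 + log2(n_pairs))
  edges <- seq(min(dv), max(dv), length.out = n_classes + 1)
  edges[1] <- edges[1] - 1e-9
  mu0 <- -1 / (n - 1)
  out <- lapply(seq_len(n_classes), function(b) {
    obs <- morans_i(values, coords, edges[b], edges[b + 1])
    if (is.na(obs$I))
      return(data.frame(lower = edges[b], upper = edges[b + 1],
                        n_pairs = obs$n_pairs, I = NA_real_,
                        p_value = NA_real_))
    Iperm <- vapply(seq_len(n_perm), function(r)
      morans_i(sample(values), coords, edges[b], edges[b + 1])$I, 0)
    p <- (1 + sum(abs(Iperm - mu0) >= abs(obs$I - mu0), na.rm = TRUE)) /
      (n_perm + 1)
    data.frame(lower = edges[b], upper = edges[b + 1],
               n_pairs = obs$n_pairs, I = obs$I, p_value = p)
  })
  do.call(rbind, out)
}
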