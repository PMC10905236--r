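#' @useDynLib urbanocc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dnorm plogis qlogis quantile rbinom rnorm rpois runif
#'   sd var glm poisson coef vcov model.matrix pnorm qnorm rgamma dgamma dbinom
#'   setNames aggregate na.omit qbeta qunif rexp dist
#' @importFrom utils read.csv write.csv combn
"_PACKAGE"

# Canonical covariate sets. Occupancy covariates are site-level at three
# spatial scales; detection covariates vary by visit. The quadratic Julian
# day term is derived from the standardized linear term, so it appears in
# the model covariate list but not in the raw visit schema.
OCC_COVARIATES <- c(
  "canopy_local", "native_tree_prop", "impervious_local", "shrub_total",
  "shrub_native", "vertical_complexity", "canopy_neigh", "impervious_neigh",
  "dist_bay_km", "dist_stream_km"
)
DET_COVARIATES_RAW <- c("julian_day", "min_after_sunrise", "noise_leq")
DET_COVARIATES <- c("julian_day", "julian_day_sq", "min_after_sunrise",
                    "noise_leq")
SEASON_LEVELS <- c("winter", "spring", "summer", "fall")

#' Survey design description
#'
#' Describes the robust sampling design: sites with planar coordinates and a
#' nested season / primary period / secondary occasion structure. The default
#' design is three primary periods per season, each a triplet of adjacent
#' visits. Occupancy may change between primary periods; closure is assumed
#' within them.
#'
#' @param site_ids Character vector of site identifiers.
#' @param coords Two-column matrix or data frame of planar site coordinates
#'   in meters (projected; the package never reprojects lon/lat).
#' @param seasons Ordered season labels.
#' @param n_primary Primary sampling periods per season.
#' @param n_secondary Secondary occasions per primary period.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(site_ids, coords,
                          seasons = SEASON_LEVELS,
                          n_primary = 3L, n_secondary = 3L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) != length(site_ids))
    stop("coords must be a (n_sites x 2) matrix matching site_ids")
  if (!all(is.finite(coords))) stop("site coordinates must be finite")
  if (n_primary < 1L || n_secondary < 1L)
    stop("n_primary and n_secondary must be >= 1")
  colnames(coords) <- c("x_m", "y_m")
  rownames(coords) <- site_ids
  structure(list(
    n_sites = length(site_ids), site_ids = as.character(site_ids),
    coords = coords, seasons = seasons,
    n_primary = as.integer(n_primary), n_secondary = as.integer(n_secondary)
  ), class = "survey_design")
}

#' Detection history for one season
#'
#' Binary detections `y[i, j, k, t]` for species i, site j, primary period k,
#' secondary occasion t, together with the mask of conducted visits. Entries
#' where `mask` is FALSE are undefined (stored as NA) and never enter any
#' likelihood. Only species with at least one detection in the season belong
#' in a seasonal history.
#'
#' @param y Binary array (species x site x primary x secondary); NA where
#'   masked.
#' @param mask Logical array (site x primary x secondary) of conducted visits.
#' @param species_ids,site_ids Identifiers along the array margins.
#' @param season Season label.
#' @return An object of class `detection_history`.
#' @export
detection_history <- function(y, mask, species_ids, site_ids, season) {
  stopifnot(length(dim(y)) == 4L, length(dim(mask)) == 3L)
  if (!all(dim(y)[2:4] == dim(mask)))
    stop("y and mask dimensions disagree")
  obs <- aperm(array(mask, c(dim(mask), dim(y)[1])), c(4, 1, 2, 3))
  vals <- y[obs]
  if (any(!vals %in% c(0, 1)))
    stop("detection values must be 0/1 wherever visits were conducted")
  y[!obs] <- NA
  dimnames(y) <- list(species_ids, site_ids, NULL, NULL)
  structure(list(
    y = y, mask = mask, species_ids = as.character(species_ids),
    site_ids = as.character(site_ids), season = season
  ), class = "detection_history")
}

#' Partition chronologically ordered visits into a robust design
#'
#' Visits within a site-season are grouped, in date order, into `n_primary`
#' contiguous primary periods of near-equal size. With 9 visits and 3
#' primaries this yields triplets (3,3,3); leftover visits go to the earliest
#' primaries, so 8 visits give (3,3,2).
#'
#' @param visit_dates Vector of visit dates (coercible with `as.Date`).
#' @param n_primary Number of primary periods.
#' @return Data frame with columns `visit_date`, `primary`, `secondary`,
#'   sorted chronologically.
#' @export
partition_robust_design <- function(visit_dates, n_primary = 3L) {
  n <- length(visit_dates)
  if (n < n_primary)
    stop("fewer visits (", n, ") than primary periods (", n_primary, ")")
  dates <- sort(as.Date(visit_dates))
  base <- n %/% n_primary
  extra <- n %% n_primary
  sizes <- rep(base, n_primary)
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  primary <- rep(seq_len(n_primary), sizes)
  secondary <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  data.frame(visit_date = dates, primary = primary, secondary = secondary)
}

#' Load and validate the three survey tables
#'
#' Reads `detections.csv` (site_id, season, visit_date, species_id, detected),
#' `site_covariates.csv` (site_id, x_m, y_m, ten occupancy covariates) and
#' `visit_covariates.csv` (site_id, season, visit_date, julian_day,
#' min_after_sunrise, noise_leq); assembles one [detection_history] per
#' season on the robust design, masking unsurveyed site-visit combinations.
#' Species never detected in a season are dropped from that season's list.
#'
#' @param detections_path,site_covariates_path,visit_covariates_path CSV
#'   paths conforming to the schemas above.
#' @param n_primary Primary periods per season passed to
#'   [partition_robust_design()].
#' @return List with elements `design` ([survey_design]), `detections`
#'   (named list of [detection_history] by season) and `covariates`
#'   (raw-scale [covariate_table]).
#' @export
load_survey_tables <- function(detections_path, site_covariates_path,
                               visit_covariates_path, n_primary = 3L) {
  det <- read.csv(detections_path, stringsAsFactors = FALSE)
  sc <- read.csv(site_covariates_path, stringsAsFactors = FALSE)
  vc <- read.csv(visit_covariates_path, stringsAsFactors = FALSE)

  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("schema violation in ", file, ": missing column(s) ",
           paste(miss, collapse = ", "))
  }
  need(det, c("site_id", "season", "visit_date", "species_id", "detected"),
       "detections.csv")
  need(sc, c("site_id", "x_m", "y_m", OCC_COVARIATES), "site_covariates.csv")
  need(vc, c("site_id", "season", "visit_date", DET_COVARIATES_RAW),
       "visit_covariates.csv")
  if (any(!det$detected %in% c(0, 1)))
    stop("detected values outside {0,1} in detections.csv")
  key <- paste(det$species_id, det$site_id, det$season, det$visit_date)
  if (anyDuplicated(key))
    stop("duplicate (species, site, visit) rows in detections.csv")

  site_ids <- as.character(sc$site_id)
  seasons <- intersect(SEASON_LEVELS, unique(det$season))
  if (!length(seasons)) seasons <- unique(det$season)
  design <- survey_design(site_ids, sc[, c("x_m", "y_m")], seasons = seasons,
                          n_primary = n_primary)

  # visits per site-season from the union of detection and covariate rows
  vis <- unique(rbind(det[, c("site_id", "season", "visit_date")],
                      vc[, c("site_id", "season", "visit_date")]))
  histories <- list()
  visit_arrays <- list()
  n_secondary_max <- 0L
  plan_all <- list()
  for (s in seasons) {
    vs <- vis[vis$season == s, ]
    plans <- lapply(split(vs$visit_date, as.character(vs$site_id)),
                    function(d) partition_robust_design(d, n_primary))
    Tmax <- max(vapply(plans, function(p) max(p$secondary), 1L))
    n_secondary_max <- max(n_secondary_max, Tmax)
    plan_all[[s]] <- plans
  }
  Tmax <- n_secondary_max
  J <- design$n_sites
  K <- as.integer(n_primary)

  for (s in seasons) {
    plans <- plan_all[[s]]
    mask <- array(FALSE, c(J, K, Tmax))
    dimnames(mask) <- list(site_ids, NULL, NULL)
    vmat <- array(NA_real_, c(J, K, Tmax, length(DET_COVARIATES_RAW)),
                  dimnames = list(site_ids, NULL, NULL, DET_COVARIATES_RAW))
    dets <- det[det$season == s, ]
    spp <- sort(unique(dets$species_id[dets$detected == 1]))
    y <- array(NA_real_, c(length(spp), J, K, Tmax),
               dimnames = list(spp, site_ids, NULL, NULL))
    vcs <- vc[vc$season == s, ]
    for (sid in names(plans)) {
      j <- match(sid, site_ids)
      if (is.na(j)) stop("site ", sid, " in detections but not in ",
                         "site_covariates.csv")
      pl <- plans[[sid]]
      for (r in seq_len(nrow(pl))) {
        k <- pl$primary[r]; t <- pl$secondary[r]
        mask[j, k, t] <- TRUE
        y[, j, k, t] <- 0
        dd <- dets[dets$site_id == sid &
                   as.Date(dets$visit_date) == pl$visit_date[r], ]
        if (nrow(dd)) {
          idx <- match(dd$species_id, spp)
          keep <- !is.na(idx)
          y[idx[keep], j, k, t] <- dd$detected[keep]
        }
        vv <- vcs[vcs$site_id == sid &
                  as.Date(vcs$visit_date) == pl$visit_date[r], ]
        if (nrow(vv) == 1L)
          vmat[j, k, t, ] <- as.numeric(vv[1, DET_COVARIATES_RAW])
      }
    }
    histories[[s]] <- detection_history(y, mask, spp, site_ids, s)
    visit_arrays[[s]] <- vmat
  }

  covs <- covariate_table(
    site = as.matrix(sc[, OCC_COVARIATES]),
    visit = visit_arrays, site_ids = site_ids
  )
  list(design = design, detections = histories, covariates = covs)
}

#' Covariate table
#'
#' Holds per-site occupancy covariates (local, neighborhood and landscape
#' scales) and per-visit detection covariates, either on the raw scale or
#' standardized (see [standardize_covariates()]). The standardization record
#' (`center`, `scale`) maps any raw value onto the model scale and back.
#'
#' @param site Numeric matrix (sites x occupancy covariates), raw scale.
#' @param visit Named list (by season) of arrays
#'   (site x primary x secondary x detection covariate), raw scale; may be
#'   NULL for site-only tables.
#' @param site_ids Site identifiers.
#' @return An object of class `covariate_table`.
#' @export
covariate_table <- function(site, visit = NULL, site_ids = rownames(site)) {
  site <- as.matrix(site)
  if (is.null(site_ids)) site_ids <- as.character(seq_len(nrow(site)))
  rownames(site) <- site_ids
  structure(list(
    site = site, visit = visit, site_ids = as.character(site_ids),
    standardized = FALSE, center = NULL, scale = NULL, site_raw = NULL
  ), class = "covariate_table")
}

#' Center and scale covariates onto the model scale
#'
#' Standardizes every site covariate to mean 0 and unit scale across sites
#' (population scaling, divide by n) and every raw detection covariate across
#' all conducted visits, then builds the quadratic Julian day term as the
#' square of the standardized linear term. The raw site values and the
#' center/scale record are retained so raw-unit quantities (observed maxima
#' and minima, "+10% canopy", "+0.5 km") can be mapped exactly onto the model
#' scale and back.
#'
#' @param covariates Raw-scale [covariate_table].
#' @return Standardized [covariate_table].
#' @export
standardize_covariates <- function(covariates) {
  stopifnot(inherits(covariates, "covariate_table"))
  if (isTRUE(covariates$standardized))
    stop("covariates are already standardized")
  pop_sd <- function(x) {
    x <- x[!is.na(x)]
    sqrt(mean((x - mean(x))^2))
  }
  site <- covariates$site
  center <- colMeans(site, na.rm = TRUE)
  scale <- apply(site, 2, pop_sd)
  if (any(scale == 0))
    stop("zero-variance covariate: ",
         paste(colnames(site)[scale == 0], collapse = ", "))
  site_std <- sweep(sweep(site, 2, center), 2, scale, "/")

  visit <- covariates$visit
  if (!is.null(visit)) {
    vals <- lapply(DET_COVARIATES_RAW, function(v) {
      unlist(lapply(visit, function(a) as.vector(a[, , , v])))
    })
    names(vals) <- DET_COVARIATES_RAW
    vcenter <- vapply(vals, function(x) mean(x, na.rm = TRUE), 0)
    vscale <- vapply(vals, pop_sd, 0)
    if (any(vscale == 0))
      stop("zero-variance covariate: ",
           paste(DET_COVARIATES_RAW[vscale == 0], collapse = ", "))
    visit <- lapply(visit, function(a) {
      d <- dim(a)
      out <- array(NA_real_, c(d[1:3], length(DET_COVARIATES)),
                   dimnames = c(dimnames(a)[1:3], list(DET_COVARIATES)))
      for (v in DET_COVARIATES_RAW)
        out[, , , v] <- (a[, , , v] - vcenter[v]) / vscale[v]
      out[, , , "julian_day_sq"] <- out[, , , "julian_day"]^2
      out
    })
    center <- c(center, vcenter)
    scale <- c(scale, vscale)
  }
  out <- covariates
  out$site_raw <- covariates$site
  out$site <- site_std
  out$visit <- visit
  out$center <- center
  out$scale <- scale
  out$standardized <- TRUE
  out
}

#' Map raw covariate values onto the model scale (and back)
#'
#' @param covariates Standardized [covariate_table].
#' @param name Covariate name.
#' @param value Value(s) to transform.
#' @return Transformed value(s).
#' @export
cov_to_model_scale <- function(covariates, name, value) {
  rec <- standardization_record(covariates, name)
  (value - rec$center) / rec$scale
}

#' @rdname cov_to_model_scale
#' @export
cov_to_raw_scale <- function(covariates, name, value) {
  rec <- standardization_record(covariates, name)
  value * rec$scale + rec$center
}

standardization_record <- function(covariates, name) {
  if (!isTRUE(covariates$standardized))
    stop("covariates are not standardized")
  if (!name %in% names(covariates$center))
    stop("unknown covariate: ", name)
  list(center = covariates$center[[name]], scale = covariates$scale[[name]])
}

#' Pairwise collinearity screen
#'
#' Reports all pairwise Pearson correlations among site covariates and flags
#' pairs at or above the threshold. The community occupancy model assumes all
#' retained covariates satisfy |r| < 0.6.
#'
#' @param covariates A [covariate_table].
#' @param threshold Absolute correlation at which a pair is flagged.
#' @return Data frame with columns `var1`, `var2`, `r`, `flagged`.
#' @export
collinearity_screen <- function(covariates, threshold = 0.6) {
  x <- covariates$site
  if (nrow(x) < 3L) stop("need at least 3 sites")
  cm <- cor(x, use = "pairwise.complete.obs")
  pairs <- t(combn(colnames(x), 2))
  r <- cm[pairs]
  data.frame(var1 = pairs[, 1], var2 = pairs[, 2], r = r,
             flagged = abs(r) >= threshold)
}
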