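#' Poisson regression of pollinator taxonomic richness
#'
#' Maximum-likelihood Poisson log-linear regression of per-site pooled
#' taxonomic richness on the standardized site covariates (intercept plus
#' the ten occupancy covariates by default). No exposure offset is used:
#' richness is pooled over the 1-3 visits per site, mirroring the survey
#' protocol; pass `offset_log_visits = TRUE` (with an `n_visits` column)
#' for a sensitivity analysis.
#'
#' @param counts Data frame with a `richness` column of non-negative
#'   integer counts plus covariate columns.
#' @param covariates Covariate column names (default: the ten standard
#'   occupancy covariates present in `counts`).
#' @param offset_log_visits If TRUE, include log(n_visits) as an offset.
#' @return Object of class `pollinator_glm`: the underlying `glm` fit and a
#'   coefficient table (`estimate`, `se`, `ci_low`, `ci_high`,
#'   `significant`, Wald 95% intervals on the log scale).
#' @export
fit_pollinator_glm <- function(counts,
                               covariates = intersect(OCC_COVARIATES,
                                                      names(counts)),
                               offset_log_visits = FALSE) {
  if (!"richness" %in% names(counts)) stop("counts needs a richness column")
  y <- counts$richness
  if (any(y < 0) || any(y != round(y))) stop("non-integer or negative counts")
  X <- as.matrix(counts[, covariates, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    aliased <- c("(Intercept)", covariates)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("rank-deficient design; aliased covariate(s): ",
         paste(aliased, collapse = ", "))
  }
  if (nrow(counts) < length(covariates) + 2L)
    stop("need at least p + 2 sites with counts")
  dat <- data.frame(richness = y, X)
  fmla <- if (length(covariates))
    paste("richness ~", paste(covariates, collapse = " + "))
  else "richness ~ 1"
  if (offset_log_visits) {
    if (!"n_visits" %in% names(counts)) stop("offset needs n_visits")
    dat$n_visits <- counts$n_visits
    fmla <- paste(fmla, "+ offset(log(n_visits))")
  }
  fit <- glm(stats::as.formula(fmla), family = poisson(), data = dat)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  tab <- data.frame(term = names(est), estimate = est, se = se,
                    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                    row.names = NULL)
  tab$significant <- tab$ci_low > 0 | tab$ci_high < 0
  structure(list(glm = fit, coefficients = tab, n = nrow(counts),
                 p = length(est)), class = "pollinator_glm")
}

#' @export
print.pollinator_glm <- function(x, ...) {
  cat("Poisson richness regression (n =", x$n, ")\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Pearson dispersion check for a Poisson fit
#'
#' phi = Pearson chi-square / (n - p). For a correctly specified Poisson
#' model phi is near 1; the fit is flagged "overdispersed" when phi exceeds
#' the threshold.
#'
#' @param fit A `pollinator_glm`.
#' @param threshold Dispersion above which the verdict is "overdispersed".
#' @return List with `phi`, `verdict`, `df`.
#' @export
dispersion_check <- function(fit, threshold = 1.5) {
  stopifnot(inherits(fit, "pollinator_glm"))
  df <- fit$glm$df.residual
  if (df <= 0) stop("no residual degrees of freedom (n <= p)")
  phi <- sum(stats::residuals(fit$glm, type = "pearson")^2) / df
  list(phi = phi,
       verdict = if (phi > threshold) "overdispersed" else "ok",
       df = df)
}
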