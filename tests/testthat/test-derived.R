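# prescribed-coefficient fits for closed-form checks
occ_names2 <- c("(Intercept)", "canopy_local", "dist_stream_km")

test_that("predicted incidence matches occupancy probability in expectation", {
  set.seed(4)
  S <- 4000
  alpha <- array(rnorm(S * 2 * 3, 0, 0.7), c(S, 2, 3))
  fit <- fake_fit(alpha, occ_names2)
  x <- c(canopy_local = 0.5, dist_stream_km = -1)
  pred <- predict_incidence(fit, x, seed = 8)
  # Rao-Blackwell: mean of sampled z equals mean of psi within MC error
  for (i in 1:2)
    expect_equal(mean(pred$z[, i, 1]), mean(pred$psi[, i, 1]),
                 tolerance = 4 / sqrt(S))
  # all-zero coefficients give psi = 0.5 anywhere
  fit0 <- fake_fit(array(0, c(10, 1, 3)), occ_names2)
  expect_true(all(predict_psi(fit0, x) == 0.5))
  # a huge intercept saturates incidence
  fitI <- fake_fit(array(rep(c(50, 0, 0), each = 10), c(10, 1, 3)),
                   occ_names2)
  expect_true(all(predict_incidence(fitI, x)$z == 1L))
  expect_error(predict_psi(fit, c(canopy_local = 1)), "dist_stream_km")
})

test_that("occupancy is monotone in a positive-slope covariate", {
  fit <- fake_fit(array(rep(c(0.2, 0.8, -0.3), each = 50), c(50, 1, 3)),
                  occ_names2)
  grid <- seq(-2, 2, length.out = 9)
  psi <- vapply(grid, function(g)
    mean(predict_psi(fit, c(canopy_local = g, dist_stream_km = 0))), 0)
  expect_true(all(diff(psi) > 0))
})

test_that("richness sums incidence over subsets additively", {
  set.seed(9)
  z <- matrix(rbinom(300 * 6, 1, 0.5), 300, 6,
              dimnames = list(NULL, paste0("sp", 1:6)))
  r_all <- richness_posterior(z)
  r_a <- richness_posterior(z, paste0("sp", 1:3))
  r_b <- richness_posterior(z, paste0("sp", 4:6))
  expect_equal(r_a$draws + r_b$draws, r_all$draws)
  expect_equal(richness_posterior(matrix(1, 50, 5,
    dimnames = list(NULL, paste0("sp", 1:5))))$hdi, c(5, 5))
  # independent incidence 0.5 over 10 species has mean about 5
  z10 <- matrix(rbinom(5000 * 10, 1, 0.5), 5000, 10,
                dimnames = list(NULL, paste0("sp", 1:10)))
  expect_equal(richness_posterior(z10)$mean, 5, tolerance = 0.15)
  expect_error(richness_posterior(z, character(0)), "empty")
  expect_error(richness_posterior(z, "nope"), "not modeled")
})

test_that("annual richness unions seasonal draws by index", {
  # disjoint certain sets count 3 + 4 = 7
  zs <- matrix(1L, 20, 3, dimnames = list(NULL, paste0("a", 1:3)))
  zf <- matrix(1L, 20, 4, dimnames = list(NULL, paste0("b", 1:4)))
  expect_equal(annual_richness(list(spring = zs, fall = zf))$draws,
               rep(7, 20))
  # a species present in several seasons counts once
  both <- list(spring = zs, fall = zs)
  expect_equal(annual_richness(both)$draws, rep(3, 20))
  # brute-force per-draw set union on a random toy posterior
  set.seed(3)
  za <- matrix(rbinom(40 * 3, 1, 0.4), 40, 3,
               dimnames = list(NULL, c("x", "y", "w")))
  zb <- matrix(rbinom(40 * 2, 1, 0.6), 40, 2,
               dimnames = list(NULL, c("y", "v")))
  got <- annual_richness(list(a = za, b = zb))$draws
  want <- vapply(1:40, function(s) {
    pres <- union(colnames(za)[za[s, ] == 1], colnames(zb)[zb[s, ] == 1])
    length(pres)
  }, 0)
  expect_equal(got, want)
  expect_error(annual_richness(list(a = za, b = zb[1:10, ])), "mismatched")
})

test_that("cumulative detection probability follows its closed form", {
  expect_equal(pstar(c(0.5, 0.5, 0.5)), 0.875)
  expect_equal(pstar(c(0.3, 1, 0.2)), 1)
  p <- matrix(runif(50 * 6, 0.1, 0.6), 50, 6)
  # non-decreasing in the number of visits
  ps <- vapply(2:6, function(k) pstar(p[, 1:k]), numeric(50))
  expect_true(all(diff(t(ps)) >= 0))
  expect_equal(pstar(p), 1 - apply(1 - p, 1, prod))
  expect_error(pstar(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("species responses are classified by HDI sign exclusion", {
  S <- 500
  al <- array(0, c(S, 3, 3))
  al[, 1, 2] <- abs(rnorm(S)) + 0.01        # all positive draws
  al[, 2, 2] <- rnorm(S)                    # centered
  al[, 3, 2] <- -abs(rnorm(S)) - 0.01       # all negative
  fit <- fake_fit(al, occ_names2)
  for (lv in c(0.75, 0.95)) {
    out <- species_response_summary(fit, "canopy_local", level = lv)
    expect_equal(out$direction, c("positive", "neither", "negative"))
  }
  fr <- attr(species_response_summary(fit, "canopy_local"), "fractions")
  expect_equal(unname(fr["positive"]), 1 / 3)
  expect_error(species_response_summary(fit, "canopy_local", level = 1.2),
               "level")
  expect_error(species_response_summary(fit, "nope"), "not among")
})

test_that("richness change matches the closed-form logistic difference", {
  # a single species with known intercept/slope, delta in raw units
  a0 <- 0.4; b <- 0.9; sc <- c(canopy_local = 12, dist_stream_km = 0.8)
  al <- array(rep(c(a0, b, 0), each = 3), c(3, 1, 3))
  fit <- fake_fit(al, occ_names2, scale = sc)
  out <- richness_delta(fit, "canopy_local", delta_raw = 10)
  want <- plogis(a0 + b * 10 / 12) - plogis(a0)
  expect_equal(out$mean, want, tolerance = 1e-12)
  # zero slopes give exactly zero change
  fit0 <- fake_fit(array(rep(c(1, 0, 0), each = 3), c(3, 1, 3)),
                   occ_names2, scale = sc)
  expect_equal(richness_delta(fit0, "dist_stream_km", 0.5)$mean, 0)
  expect_error(richness_delta(fit, "nope", 1), "unknown covariate")
})

test_that("good/poor scenarios use observed extremes and mean baselines", {
  set.seed(6)
  raw <- vapply(urbanocc:::OCC_COVARIATES, function(v) runif(20, 1, 9),
                numeric(20))
  ct <- standardize_covariates(covariate_table(raw))
  sc <- build_scenarios(ct)
  X <- attr(sc, "x")
  expect_equal(nrow(X), 8)
  g <- X[sc$local == "good" & sc$neighborhood == "good" &
           sc$landscape == "good", ]
  p <- X[sc$local == "poor" & sc$neighborhood == "poor" &
           sc$landscape == "poor", ]
  expect_equal(g[["canopy_local"]],
               cov_to_model_scale(ct, "canopy_local",
                                  max(raw[, "canopy_local"])))
  expect_equal(g[["dist_bay_km"]],
               cov_to_model_scale(ct, "dist_bay_km",
                                  min(raw[, "dist_bay_km"])))
  # impervious cover is adverse: poor conditions take its observed maximum
  expect_equal(p[["impervious_local"]],
               cov_to_model_scale(ct, "impervious_local",
                                  max(raw[, "impervious_local"])))
  expect_equal(g[["impervious_local"]],
               cov_to_model_scale(ct, "impervious_local",
                                  min(raw[, "impervious_local"])))
  # non-driving covariates sit at the standardized mean in every scenario
  expect_true(all(X[, "shrub_total"] == 0))
  expect_true(all(X[, "vertical_complexity"] == 0))
  # good and poor are reflections only if the observed range is symmetric,
  # which a skewed sample is not: assert true extremes are used, not +/-
  expect_false(isTRUE(all.equal(g[["canopy_local"]],
                                -p[["canopy_local"]])))
  expect_error(build_scenarios(ct, directions = list(local = NULL)),
               "direction missing")
})
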