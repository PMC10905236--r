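test_that("generator configuration validates its inputs", {
  cfg <- generator_config()
  expect_equal(cfg$n_sites, 45L)
  expect_equal(cfg$n_species, 80L)
  expect_equal(cfg$n_primary, 3L)
  bad <- default_cov_corr()
  bad[1, 2] <- bad[2, 1] <- 0.999
  bad[1, 3] <- bad[3, 1] <- 0.999
  bad[2, 3] <- bad[3, 2] <- -0.999
  expect_error(generator_config(cov_corr = bad), "positive semi-definite")
})

test_that("copula site generation honors the correlation structure", {
  cfg <- generator_config(n_sites = 500, seed = 41)
  set.seed(cfg$seed)
  # identity correlation: sample correlations stay small
  s1 <- gen_sites(generator_config(n_sites = 500, cov_corr = diag(10)))
  cm <- cor(s1$covariates$site)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.2)
  # requested correlation 0.7 comes out within +/- 0.1 (on copula scale
  # the rank correlation is preserved; Pearson on the marginals is close)
  R <- diag(10)
  dimnames(R) <- list(urbanocc:::OCC_COVARIATES, urbanocc:::OCC_COVARIATES)
  R["canopy_local", "canopy_neigh"] <- 0.7
  R["canopy_neigh", "canopy_local"] <- 0.7
  set.seed(42)
  s2 <- gen_sites(generator_config(n_sites = 500, cov_corr = R))
  expect_equal(cor(s2$covariates$site[, "canopy_local"],
                   s2$covariates$site[, "canopy_neigh"]), 0.7,
               tolerance = 0.1)
})

test_that("community draws concentrate at their means as spread vanishes", {
  cfg <- generator_config(n_species = 200,
                          occ_sd = c(1e-8, rep(1e-8, 10)))
  set.seed(43)
  com <- gen_community(cfg)
  expect_equal(unname(apply(com$alpha, 2, sd)), rep(0, 11),
               tolerance = 1e-6)
  expect_equal(unname(com$alpha[1, ]), unname(cfg$occ_mu),
               tolerance = 1e-6)
  # zero means, unit spread: about half the slopes are positive
  cfg2 <- generator_config(n_species = 10000,
                           occ_mu = setNames(rep(0, 11),
                                             names(cfg$occ_mu)),
                           occ_sd = rep(1, 11))
  set.seed(44)
  com2 <- gen_community(cfg2)
  expect_equal(mean(com2$alpha[, "canopy_local"] > 0), 0.5,
               tolerance = 0.02)
  # sample mean within 3 standard errors of the community mean
  expect_lt(abs(mean(com2$alpha[, 1]) - 0), 3 / sqrt(10000))
})

test_that("survey simulation respects the Bernoulli layers", {
  cfg <- generator_config(n_sites = 40, n_species = 3,
                          seasons = "summer",
                          missing_sites = c(40L, 40L), seed = 45)
  sim <- simulate_dataset(cfg)
  # saturation: huge intercepts mean everything present and detected
  cfg_sat <- generator_config(n_sites = 10, n_species = 3,
                              seasons = "summer",
                              occ_mu = c(50, rep(0, 10)),
                              occ_sd = c(1e-6, rep(1e-6, 10)),
                              det_mu = c(rep(50, 3), rep(0, 4)),
                              det_sd = rep(1e-6, 7),
                              missing_sites = c(10L, 10L), seed = 46)
  sim_sat <- simulate_dataset(cfg_sat)
  y <- sim_sat$detections$summer$y
  expect_true(all(y[!is.na(y)] == 1))
  expect_true(all(sim_sat$truth$z$summer == 1))
  # absence: psi = 0 gives no incidence and no species retained
  cfg_abs <- generator_config(n_sites = 10, n_species = 3,
                              seasons = "summer",
                              occ_mu = c(-50, rep(0, 10)),
                              occ_sd = c(1e-6, rep(1e-6, 10)),
                              missing_sites = c(10L, 10L), seed = 47)
  sim_abs <- simulate_dataset(cfg_abs)
  expect_equal(length(sim_abs$detections$summer$species_ids), 0)
  expect_true(all(sim_abs$truth$z$summer == 0))
})

test_that("simulated incidence frequencies match occupancy probabilities", {
  cfg <- generator_config(n_sites = 45, n_species = 40, seasons = "spring",
                          missing_sites = c(45L, 45L), seed = 48)
  sim <- simulate_dataset(cfg)
  # z has K = 3 independent layers per species-site; compare frequencies
  z <- sim$truth$z$spring               # species x site x primary
  psi_true <- plogis(cbind(1, sim$covariates$site) %*%
                       t(sim$truth$alpha))    # site x species
  emp <- apply(z, 1, mean)
  want <- colMeans(psi_true)
  # binomial error over 45 x 3 draws per species
  expect_true(all(abs(emp - want) < 4 * sqrt(0.25 / (45 * 3))))
})

test_that("pollinator counts follow the Poisson log-linear model", {
  cfg <- generator_config(n_sites = 2000, seed = 49)
  set.seed(49)
  sites <- gen_sites(cfg)
  ct <- standardize_covariates(sites$covariates)
  beta <- c(`(Intercept)` = log(5), setNames(rep(0, 10),
                                             urbanocc:::OCC_COVARIATES))
  set.seed(50)
  pc <- simulate_pollinators(beta, ct)
  expect_equal(mean(pc$richness), 5, tolerance = 0.15)
  # a very negative intercept produces almost all zeros
  beta0 <- beta; beta0[1] <- -8
  set.seed(51)
  expect_true(mean(simulate_pollinators(beta0, ct)$richness == 0) > 0.99)
})

test_that("the master seed makes whole datasets bit-reproducible", {
  cfg <- generator_config(n_sites = 8, n_species = 10,
                          seasons = c("spring", "fall"), seed = 52)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$covariates$site, s2$covariates$site)
  expect_identical(s1$pollinators, s2$pollinators)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_survey_csvs(s1, d1); p2 <- write_survey_csvs(s2, d2)
  for (i in 1:3)
    expect_identical(readLines(p1[i]), readLines(p2[i]))
})
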