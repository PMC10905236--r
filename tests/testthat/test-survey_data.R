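test_that("visits are partitioned into near-equal chronological primaries", {
  d <- as.Date("2016-03-01") + 7 * (0:8)
  p9 <- partition_robust_design(sample(d), n_primary = 3)
  expect_equal(as.integer(table(p9$primary)), c(3L, 3L, 3L))
  expect_equal(p9$visit_date, sort(d))

  p8 <- partition_robust_design(d[1:8], n_primary = 3)
  expect_equal(as.integer(table(p8$primary)), c(3L, 3L, 2L))

  p10 <- partition_robust_design(c(d, max(d) + 7), n_primary = 3)
  expect_equal(as.integer(table(p10$primary)), c(4L, 3L, 3L))

  expect_error(partition_robust_design(d[1:2], n_primary = 3),
               "fewer visits")
})

test_that("standardization is population-scaled and exactly invertible", {
  ct <- covariate_table(cbind(a = c(1, 2, 3), b = c(10, 0, 5)))
  std <- standardize_covariates(ct)
  expect_equal(std$site[, "a"], c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(mean(std$site[, "b"]), 0)
  expect_equal(sqrt(mean(std$site[, "b"]^2)), 1)
  # round trip through the standardization record
  for (v in c("a", "b")) {
    raw <- ct$site[, v]
    expect_equal(cov_to_raw_scale(std, v, cov_to_model_scale(std, v, raw)),
                 raw, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(
    standardize_covariates(covariate_table(cbind(a = c(5, 5, 5),
                                                 b = 1:3))),
    "zero-variance covariate: a")
})

test_that("collinearity screen reports and flags pairwise Pearson r", {
  x <- cbind(u = c(1, -1, 0), v = c(1, 1, -2), w = c(1, -1, 0))
  ct <- covariate_table(x)
  rep <- collinearity_screen(ct, threshold = 0.6)
  expect_equal(rep$r[rep$var1 == "u" & rep$var2 == "v"], 0)
  expect_equal(rep$r[rep$var1 == "u" & rep$var2 == "w"], 1)
  expect_true(rep$flagged[rep$var1 == "u" & rep$var2 == "w"])
  expect_false(rep$flagged[rep$var1 == "u" & rep$var2 == "v"])
  expect_error(collinearity_screen(covariate_table(x[1:2, ])), "3 sites")
})

make_toy_csvs <- function(dir) {
  dates <- format(as.Date("2016-03-01") + 7 * (0:2))
  det <- expand.grid(site_id = c("A", "B"), visit_date = dates,
                     species_id = c("wren", "junco"),
                     stringsAsFactors = FALSE)
  det$season <- "spring"
  det$detected <- as.integer(det$site_id == "A" & det$species_id == "wren")
  det$detected[det$species_id == "junco" & det$visit_date == dates[2]] <- 1L
  sc <- data.frame(site_id = c("A", "B"), x_m = c(0, 1000), y_m = c(0, 0))
  for (v in urbanocc:::OCC_COVARIATES) sc[[v]] <- c(1, 2)
  vc <- expand.grid(site_id = c("A", "B"), visit_date = dates,
                    stringsAsFactors = FALSE)
  vc$season <- "spring"
  vc$julian_day <- as.integer(format(as.Date(vc$visit_date), "%j"))
  vc$min_after_sunrise <- 30
  vc$noise_leq <- 55
  paths <- file.path(dir, c("det.csv", "site.csv", "visit.csv"))
  write.csv(det, paths[1], row.names = FALSE)
  write.csv(sc, paths[2], row.names = FALSE)
  write.csv(vc, paths[3], row.names = FALSE)
  paths
}

test_that("loading builds the robust design with per-season species lists", {
  dir <- withr::local_tempdir()
  paths <- make_toy_csvs(dir)
  out <- load_survey_tables(paths[1], paths[2], paths[3], n_primary = 1)
  dh <- out$detections$spring
  expect_equal(dim(dh$y), c(2, 2, 1, 3))
  expect_equal(sort(dh$species_ids), c("junco", "wren"))
  expect_true(all(out$covariates$site[, "canopy_local"] == c(1, 2)))

  # a species never detected is dropped from the season's list
  det <- read.csv(paths[1])
  det$detected[det$species_id == "junco"] <- 0L
  write.csv(det, paths[1], row.names = FALSE)
  out2 <- load_survey_tables(paths[1], paths[2], paths[3], n_primary = 1)
  expect_equal(out2$detections$spring$species_ids, "wren")

  # a site absent from the season is fully masked
  det <- det[det$site_id != "B", ]
  write.csv(det, paths[1], row.names = FALSE)
  vc <- read.csv(paths[3]); vc <- vc[vc$site_id != "B", ]
  write.csv(vc, paths[3], row.names = FALSE)
  out3 <- load_survey_tables(paths[1], paths[2], paths[3], n_primary = 1)
  expect_false(any(out3$detections$spring$mask[2, , ]))
  expect_true(all(is.na(out3$detections$spring$y[, 2, , ])))
})

test_that("schema and value violations are rejected with clear errors", {
  dir <- withr::local_tempdir()
  paths <- make_toy_csvs(dir)
  det <- read.csv(paths[1])
  det$detected[1] <- 2
  write.csv(det, paths[1], row.names = FALSE)
  expect_error(load_survey_tables(paths[1], paths[2], paths[3]),
               "outside \\{0,1\\}")
  det$detected[1] <- 1
  write.csv(rbind(det, det[1, ]), paths[1], row.names = FALSE)
  expect_error(load_survey_tables(paths[1], paths[2], paths[3]),
               "duplicate")
  sc <- read.csv(paths[2]); sc$canopy_local <- NULL
  write.csv(sc, paths[2], row.names = FALSE)
  write.csv(det, paths[1], row.names = FALSE)
  expect_error(load_survey_tables(paths[1], paths[2], paths[3]),
               "canopy_local")
})

test_that("simulated datasets round-trip through the CSV schemas", {
  cfg <- generator_config(n_sites = 8, n_species = 12,
                          seasons = c("spring", "fall"),
                          missing_sites = c(7L, 8L), seed = 4)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_survey_csvs(sim, dir)
  out <- load_survey_tables(paths[1], paths[2], paths[3])
  for (s in cfg$seasons) {
    a <- sim$detections[[s]]; b <- out$detections[[s]]
    expect_equal(b$species_ids, sort(a$species_ids))
    expect_equal(b$mask, a$mask, ignore_attr = TRUE)
    expect_equal(b$y[b$species_ids, , , ], a$y[b$species_ids, , , ],
                 ignore_attr = TRUE)
  }
  expect_equal(unname(out$covariates$site),
               unname(sim$covariates$site_raw), tolerance = 1e-9)
})

test_that("masked visits contribute nothing to the likelihood", {
  # the same data with a visit masked out equals the data with that visit
  # physically absent
  y3 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0), c(1, 1, 1))
  mask3 <- matrix(TRUE, 4, 3); mask3[, 3] <- FALSE
  dh_masked <- dh_single(y3, mask3)
  dh_short <- dh_single(y3[, 1:2])
  state <- list(alpha = matrix(0.3), beta = matrix(-0.2),
                z = array(c(1L, 1L, 0L, 1L), c(1, 4, 1)))
  lj_masked <- log_joint(state, dh_masked, NULL, hierarchical = FALSE)
  lj_short <- log_joint(state, dh_short, NULL, hierarchical = FALSE)
  expect_equal(lj_masked, lj_short, tolerance = 1e-12)
})
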