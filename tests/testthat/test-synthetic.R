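test_that("config validation rejects degenerate settings", {
  expect_error(gradient_sim_config(n_bands = 1), "n_bands")
  expect_error(gradient_sim_config(detection_prob = 0), "detection_prob")
  expect_error(gradient_sim_config(range_size_dist = c(0.5, 0.6, 0, 0, 0, 0)),
               "sum to 1")
  expect_error(gradient_sim_config(n_species = 0), "positive")
  expect_error(gradient_sim_config(noise_sd = list(mat = -1, mah = 1,
                                                   ndvi = 0, psr = 0)),
               ">= 0")
})

test_that("identical seed and config give identical datasets", {
  d1 <- generate_dataset(ailao_config(seed = 11))
  d2 <- generate_dataset(ailao_config(seed = 11))
  expect_identical(d1$captures, d2$captures)
  expect_identical(d1$covariates, d2$covariates)
  expect_identical(d1$truth$ranges, d2$truth$ranges)
  d3 <- generate_dataset(ailao_config(seed = 12))
  expect_false(identical(d1$captures, d3$captures))
})

test_that("perfect detection recovers the generating ranges exactly", {
  cfg <- ailao_config(seed = 3, detection_prob = 1, abundance_mean = 60)
  d <- generate_dataset(cfg)
  rg <- build_ranges(d$captures, fixture_bands())
  truth <- d$truth$ranges
  expect_equal(nrow(rg), nrow(truth))
  key_r <- paste(rg$species, rg$slope)
  key_t <- paste(truth$species, truth$slope)
  expect_setequal(key_r, key_t)
  idx <- match(key_t, key_r)
  expect_equal(rg$min_band[idx], truth$start_band)
  expect_equal(rg$max_band[idx], truth$end_band)
  ## observed sets are already contiguous under perfect detection
  expect_true(all(vapply(seq_len(nrow(rg)), function(i)
    identical(rg$observed_bands[[i]], rg$interpolated_bands[[i]]),
    logical(1))))
})

test_that("mde_null placement puts unit ranges uniformly over bands", {
  cfg <- gradient_sim_config(slopes = "west", n_species = 10000L,
                             n_shared = 0L,
                             range_size_dist = c(1, 0, 0, 0, 0, 0),
                             abundance_mean = 1, detection_prob = 0.5,
                             trap_nights_per_band = 10L, seed = 21)
  d <- generate_dataset(cfg)
  freq <- tabulate(d$truth$ranges$start_band, nbins = 6) / 10000
  se <- sqrt((1 / 6) * (5 / 6) / 10000)
  expect_true(all(abs(freq - 1 / 6) <= 3 * se))
})

test_that("empirical band occupancy matches the analytic null expectation", {
  cfg <- gradient_sim_config(slopes = "west", n_species = 5000L,
                             n_shared = 0L, abundance_mean = 1,
                             detection_prob = 0.5,
                             trap_nights_per_band = 10L, seed = 31)
  d <- generate_dataset(cfg)
  tr <- d$truth$ranges
  occ <- vapply(1:6, function(b)
    sum(tr$start_band <= b & tr$end_band >= b), numeric(1))
  expect_equal(sum(occ), sum(tr$range_size))
  exp_occ <- expected_richness_analytic(tr$range_size, 6)
  ## per-band binomial-sum SE from each species' coverage probability
  se <- vapply(1:6, function(b) {
    p <- (pmin(b, 6 - tr$range_size + 1) -
            pmax(1, b - tr$range_size + 1) + 1) / (6 - tr$range_size + 1)
    sqrt(sum(p * (1 - p)))
  }, numeric(1))
  expect_true(all(abs(occ - exp_occ) <= 3 * se))
})

test_that("environmental placement concentrates midpoints at the optimum", {
  cfg <- gradient_sim_config(slopes = "west", n_species = 4000L,
                             n_shared = 0L,
                             range_size_dist = c(1, 0, 0, 0, 0, 0),
                             placement_mode = "environmental",
                             env_optimum_band = 3.5, env_breadth = 0.8,
                             abundance_mean = 1, detection_prob = 0.5,
                             trap_nights_per_band = 10L, seed = 41)
  d <- generate_dataset(cfg)
  freq <- tabulate(d$truth$ranges$start_band, nbins = 6) / 4000
  expect_gt(min(freq[3:4]), max(freq[c(1, 6)]))
})

test_that("generated covariates reproduce the requested sign structure", {
  d <- fixture_dataset(seed = 8)
  cv <- d$covariates
  expect_lt(cor(cv$MAT, cv$elevation), 0)
  expect_lt(cor(cv$MAT, cv$NDVI), -0.84)
  expect_gt(cor(cv$MAH, cv$NDVI), 0.5)
  expect_lt(cor(cv$PSR, cv$elevation), 0)
})

test_that("generate_richness_from_model honours its coefficients", {
  design <- recovery_design()
  expect_equal(generate_richness_from_model(design, c(intercept = 5)),
               rep(5, nrow(design)))
  ## noiseless identifiability: refitting recovers the truth
  y <- generate_richness_from_model(design, c(area = 2, NDVI = 3))
  fit <- fit_model(y, design, c("area", "NDVI"))
  expect_equal(unname(fit$coefficients[c("area", "NDVI")]), c(2, 3),
               tolerance = 1e-10)
  expect_error(generate_richness_from_model(design, c(bogus = 1)),
               "unknown term")
  ## same seed, same noise
  y1 <- generate_richness_from_model(design, c(area = 2), 1, seed = 4)
  y2 <- generate_richness_from_model(design, c(area = 2), 1, seed = 4)
  expect_identical(y1, y2)
})

test_that("refitted coefficients are unbiased over simulation replicates", {
  design <- recovery_design()
  est <- vapply(1:200, function(s) {
    y <- generate_richness_from_model(design, c(area = 4, NDVI = 5),
                                      noise_sd = 1, seed = s)
    unname(fit_model(y, design, c("area", "NDVI"))$coefficients["area"])
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 4), 2 * mc_se + 1e-12)
})
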