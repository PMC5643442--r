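## Shared fixtures, all built in code at test time.

## The packaged "ailao-like" synthetic survey.
fixture_dataset <- function(seed = 1L) {
  generate_dataset(ailao_config(seed = seed))
}

fixture_bands <- function() seq(1800, 2800, by = 200)

## A two-slope, 30-band covariate table plus MDE predictor for
## parameter-recovery experiments (n = 60 rows). Deterministic given seed;
## covariate correlations sit below the 0.7 screen threshold.
recovery_design <- function(seed = 99L) {
  set.seed(seed)
  n_b <- 30L
  elev <- seq(1000, 2900, length.out = n_b)
  cov <- do.call(rbind, lapply(c("west", "east"), function(sl) {
    data.frame(slope = sl, elevation = elev,
               area = exp(4 - 0.0006 * elev + rnorm(n_b, 0, 0.25)),
               NDVI = plogis(-1 + 0.0009 * elev + rnorm(n_b, 0, 0.35)),
               PSR = round(pmax(5, 150 - 0.03 * elev + rnorm(n_b, 0, 12))))
  }))
  mde <- as.vector(replicate(2, simulate_mde(
    sample(1:n_b, 25, replace = TRUE), n_b, 500, seed = seed)$mean_richness))
  build_design(cov, mde = mde)
}

## Truth for the recovery experiments: strong effects on log(area) and
## log(NDVI); noise scaled to a signal-to-noise ratio of ~3.
recovery_truth <- function(design) {
  coefs <- c("(Intercept)" = 10, area = 4, NDVI = 5)
  signal <- coefs[["area"]] * design$area + coefs[["NDVI"]] * design$NDVI
  list(coefs = coefs, noise_sd = sd(signal) / 3)
}

## Two centered, orthogonal, unit-norm vectors of length n (for building
## predictor pairs with an exact sample correlation).
orthonormal_pair <- function(n, seed = 5L) {
  set.seed(seed)
  z1 <- rnorm(n); z1 <- z1 - mean(z1)
  z2 <- rnorm(n); z2 <- z2 - mean(z2)
  z2 <- z2 - sum(z1 * z2) / sum(z1^2) * z1
  list(z1 = z1 / sqrt(sum(z1^2)), z2 = z2 / sqrt(sum(z2^2)))
}

## Brute-force per-band coverage of a size-r range on m bands by
## enumerating every feasible placement (independent oracle for the
## closed-form expectation).
enumerate_coverage <- function(r, m) {
  starts <- seq_len(m - r + 1L)
  cov <- numeric(m)
  for (s in starts) cov[s:(s + r - 1L)] <- cov[s:(s + r - 1L)] + 1
  cov / length(starts)
}
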