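test_that("correlation screen keeps one variable per correlated block", {
  set.seed(1)
  n <- 40
  base <- rnorm(n)
  d <- data.frame(
    MAT = base + rnorm(n, 0, 0.1),
    MAH = -base + rnorm(n, 0, 0.1),
    NDVI = base + rnorm(n, 0, 0.1),
    PSR = rnorm(n),
    area = rnorm(n)
  )
  out <- correlation_screen(d, threshold = 0.7,
                            keep_priority = c("NDVI", "PSR", "MAT", "MAH"))
  expect_setequal(out$retained, c("NDVI", "PSR", "area"))
  expect_setequal(out$dropped, c("MAT", "MAH"))
  expect_equal(out$cor_matrix, t(out$cor_matrix))
  expect_equal(unname(diag(out$cor_matrix)), rep(1, 5))
  ## nothing correlated: everything survives
  d2 <- as.data.frame(matrix(rnorm(40 * 3), 40,
                             dimnames = list(NULL, c("a", "b", "c"))))
  expect_setequal(correlation_screen(d2)$retained, c("a", "b", "c"))
  d$MAT <- 1
  expect_error(correlation_screen(d), "MAT")
})

test_that("model enumeration respects marginality", {
  expect_length(enumerate_models(c("A", "B")), 4)
  m5 <- enumerate_models(c("slope", "X"), "slope:X")
  expect_length(m5, 5)
  labs <- sort(vapply(m5, paste, character(1), collapse = "+"))
  expect_equal(labs, sort(c("", "slope", "X", "slope+X", "slope+X+slope:X")))
  ## full global model versus a brute-force subset filter
  mains <- c("slope", "MDE", "area", "NDVI", "PSR")
  inter <- paste0("slope:", mains[-1])
  got <- enumerate_models(mains, inter)
  all_terms <- c(mains, inter)
  brute <- Filter(function(terms) {
    ints <- grep(":", terms, value = TRUE)
    all(unlist(strsplit(ints, ":")) %in% terms)
  }, lapply(0:(2^9 - 1), function(mask)
    all_terms[as.logical(bitwAnd(mask, 2^(0:8)))]))
  expect_length(got, length(brute))
  expect_setequal(vapply(got, paste, character(1), collapse = "+"),
                  vapply(brute, paste, character(1), collapse = "+"))
  expect_error(enumerate_models("A", "A:B"), "undeclared")
})

test_that("fit_model is exact OLS on the transformed design", {
  design <- recovery_design()
  y <- 2 * design$area
  fit <- fit_model(y, design, "area")
  expect_equal(unname(fit$coefficients["area"]), 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  ## irrelevant terms never decrease R-squared
  set.seed(2)
  y2 <- y + rnorm(length(y))
  f1 <- fit_model(y2, design, "area")
  f2 <- fit_model(y2, design, c("area", "PSR"))
  expect_gte(f2$r_squared, f1$r_squared)
  ## oracle check including a factor and an interaction
  f3 <- fit_model(y2, design, c("slope", "area", "slope:area"))
  X <- model.matrix(~ slope + area + slope:area, design)
  beta <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(unname(f3$coefficients), as.vector(beta), tolerance = 1e-8)
  ## rank-deficient designs are rejected
  design$dup <- design$area
  expect_error(fit_model(y2, design, c("area", "dup")), "rank-deficient")
})

test_that("log transforms are applied to elevational variables only", {
  cov <- data.frame(slope = c("w", "e"), elevation = c(1, 2),
                    area = c(10, 20), NDVI = c(0.5, 0.6), PSR = c(100, 90))
  d <- build_design(cov, mde = c(3, 4))
  expect_equal(d$area, log(c(10, 20)))
  expect_equal(d$NDVI, log(c(0.5, 0.6)))
  expect_equal(d$MDE, c(3, 4))
  expect_s3_class(d$slope, "factor")
  cov$area[1] <- -1
  expect_error(build_design(cov), "area")
})

test_that("best model minimizes AICc and carries the top weight", {
  design <- recovery_design()
  truth <- recovery_truth(design)
  y <- generate_richness_from_model(design, truth$coefs, truth$noise_sd,
                                    seed = 14)
  mains <- c("slope", "MDE", "area", "NDVI", "PSR")
  cms <- candidate_model_set(y, design, mains, paste0("slope:", mains[-1]))
  best <- select_best(cms)
  expect_equal(best$aicc, min(cms$table$aicc))
  expect_equal(which.max(cms$table$weight), 1L)
  expect_equal(cms$table$delta_aicc[1], 0)
  expect_equal(sum(cms$table$weight), 1, tolerance = 1e-12)
  ## confidence set is the smallest prefix reaching 95% cumulative weight
  k <- sum(cms$table$in_conf_set)
  expect_gte(cms$table$cum_weight[k], 0.95)
  if (k > 1) expect_lt(cms$table$cum_weight[k - 1], 0.95)
})

test_that("model averaging importance and coefficients follow the weights", {
  mk_fit <- function(terms, coefs) {
    structure(list(terms = c("(Intercept)", terms),
                   coefficients = coefs), class = "lm_fit")
  }
  cms <- structure(list(
    fits = list(mk_fit("A", c("(Intercept)" = 1, A = 2)),
                mk_fit(c("A", "B"), c("(Intercept)" = 0, A = 3, B = -1))),
    table = data.frame(weight = c(0.7, 0.3))
  ), class = "candidate_model_set")
  av <- model_average(cms, cum_weight = 0.95)
  expect_equal(unname(av$importance["A"]), 1)
  expect_equal(unname(av$importance["B"]), 0.3)
  expect_equal(unname(av$averaged_coefficients["A"]), 0.7 * 2 + 0.3 * 3)
  expect_equal(unname(av$averaged_coefficients["B"]), 0.3 * (-1))
  cond <- model_average(cms, method = "conditional")
  expect_equal(unname(cond$averaged_coefficients["B"]), -1)
  ## full-average magnitude never exceeds conditional for partial terms
  expect_lte(abs(av$averaged_coefficients["B"]),
             abs(cond$averaged_coefficients["B"]))
})

test_that("variable importance ranks terms by |t|", {
  design <- recovery_design()
  truth <- recovery_truth(design)
  y <- generate_richness_from_model(design, truth$coefs, truth$noise_sd,
                                    seed = 15)
  fit <- fit_model(y, design, c("area", "NDVI", "PSR"))
  imp <- variable_importance_best(fit)
  X <- model.matrix(~ area + NDVI + PSR, design)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  oracle <- abs(as.vector(beta) / se)[-1]
  names(oracle) <- c("area", "NDVI", "PSR")
  expect_equal(imp[names(oracle)][order(names(oracle))],
               oracle[order(names(oracle))], tolerance = 1e-8)
  sc <- variable_importance_best(fit, rescale = TRUE)
  expect_equal(max(sc), 100)
})

test_that("VIF matches its closed form and is scale invariant", {
  z <- orthonormal_pair(30)
  ## orthogonal predictors
  expect_equal(as.numeric(vif(data.frame(a = z$z1, b = z$z2))), c(1, 1),
               tolerance = 1e-10)
  ## exact r = 0.8 pair
  x2 <- 0.8 * z$z1 + 0.6 * z$z2
  v <- vif(data.frame(a = z$z1, b = x2))
  expect_equal(as.numeric(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  v_scaled <- vif(data.frame(a = 1000 * z$z1, b = x2 / 50))
  expect_equal(as.numeric(v_scaled), as.numeric(v), tolerance = 1e-8)
  ## perfect collinearity
  v_inf <- vif(data.frame(a = z$z1, b = 2 * z$z1))
  expect_true(all(is.infinite(v_inf)))
  expect_true(all(attr(v_inf, "flagged")))
})

test_that("chain spatial weights are block tridiagonal and row-standard", {
  tab <- data.frame(slope = rep(c("west", "east"), each = 6),
                    elevation = rep(seq(1800, 2800, 200), 2))
  sw <- build_spatial_weights(tab, "chain", row_standardize = FALSE)
  expect_equal(sw$W, t(sw$W))
  expect_equal(sum(sw$W[1:6, 7:12]), 0)     # slopes disconnected
  expect_equal(sum(sw$W[1:6, 1:6] != 0), 10) # 5 adjacent pairs, symmetric
  sw_std <- build_spatial_weights(tab, "chain")
  expect_equal(unname(rowSums(sw_std$W)), rep(1, 12))
})

test_that("Moran's I has the right expectation, sign behavior, and oracle", {
  tab <- data.frame(slope = rep(c("west", "east"), each = 6),
                    elevation = rep(seq(1800, 2800, 200), 2))
  sw <- build_spatial_weights(tab, "chain")
  set.seed(10)
  m <- morans_i(rnorm(12), sw)
  expect_equal(m$expected, -1 / 11, tolerance = 1e-12)
  ## alternating residuals on a chain: strong negative autocorrelation
  alt <- rep(c(1, -1), 6)
  expect_lt(morans_i(alt, sw)$I, m$expected)
  ## smooth gradient: positive autocorrelation
  expect_gt(morans_i(rep(1:6, 2), sw)$I, 0)
  expect_error(morans_i(rep(1, 12), sw), "constant")
  ## independent oracle (ape implements the same statistic)
  skip_if_not_installed("ape")
  x <- rnorm(12)
  ours <- morans_i(x, sw)
  theirs <- ape::Moran.I(x, sw$W)
  expect_equal(ours$I, theirs$observed, tolerance = 1e-10)
  expect_equal(ours$expected, theirs$expected, tolerance = 1e-12)
  expect_equal(sqrt(ours$variance), theirs$sd, tolerance = 1e-10)
  expect_equal(ours$p, theirs$p.value, tolerance = 1e-8)
})

test_that("normal-approximation p agrees with a permutation test", {
  tab <- data.frame(slope = "west", elevation = seq(100, 1500, 100))
  sw <- build_spatial_weights(tab, "chain")
  set.seed(20)
  for (i in 1:3) {
    x <- rnorm(15)
    m <- morans_i(x, sw)
    perm <- vapply(1:999, function(j) morans_i(sample(x), sw)$I, numeric(1))
    p_perm <- (1 + sum(abs(perm - m$expected) >= abs(m$I - m$expected))) / 1000
    expect_lt(abs(p_perm - m$p), 0.05)
  }
})

test_that("null residuals reject at close to the nominal 5% rate", {
  tab <- data.frame(slope = rep(c("west", "east"), each = 6),
                    elevation = rep(seq(1800, 2800, 200), 2))
  sw <- build_spatial_weights(tab, "chain")
  set.seed(30)
  rej <- mean(vapply(1:400, function(i) {
    morans_i(rnorm(12), sw)$p < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 0.04)
})
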