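## Polynomial richness-elevation trends and information-theoretic tools
## (AICc, Akaike weights) shared with the driver-selection module.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1)`, where `K` counts every
#' estimated parameter including the residual variance of a Gaussian fit.
#'
#' @param log_likelihood maximized log-likelihood.
#' @param n number of observations.
#' @param K number of estimated parameters (coefficients + 1 for sigma^2
#'   in Gaussian models).
#' @return the AICc value.
#' @examples
#' aicc(-10, n = 6, K = 3)  # 38
#' @export
aicc <- function(log_likelihood, n, K) {
  stopifnot(is.finite(log_likelihood), n >= 1, K >= 0)
  if (n - K - 1 <= 0) {
    stop("AICc undefined: n - K - 1 must be positive (n = ", n,
         ", K = ", K, ")", call. = FALSE)
  }
  -2 * log_likelihood + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`. Non-finite entries receive weight 0;
#' the weights of the finite entries sum to 1.
#'
#' @param aicc_values numeric vector with at least one finite value.
#' @return weight vector of the same length.
#' @examples
#' akaike_weights(c(100, 102))  # 0.731, 0.269
#' @export
akaike_weights <- function(aicc_values) {
  ok <- is.finite(aicc_values)
  if (!any(ok)) stop("no finite AICc values", call. = FALSE)
  w <- numeric(length(aicc_values))
  d <- aicc_values[ok] - min(aicc_values[ok])
  ew <- exp(-d / 2)
  w[ok] <- ew / sum(ew)
  w
}

## Gaussian log-likelihood of an lm fit with the ML variance estimate
## (RSS/n), the convention under which logLik.lm reports its value.
gaussian_loglik <- function(residuals) {
  n <- length(residuals)
  rss <- sum(residuals^2)
  -n / 2 * (log(2 * pi) + log(rss / n) + 1)
}

## Wrap a fitted lm into the package's model-fit record.
as_lm_fit <- function(fit, term_labels) {
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design: coefficient(s) not estimable (",
         paste(names(cf)[is.na(cf)], collapse = ", "), ")", call. = FALSE)
  }
  n <- length(stats::residuals(fit))
  K <- length(cf) + 1L
  ll <- gaussian_loglik(stats::residuals(fit))
  sm <- summary(fit)
  structure(list(
    terms = term_labels,
    coefficients = cf,
    n = n, K = K,
    log_likelihood = ll,
    r_squared = sm$r.squared,
    ## a perfect (zero-residual) fit has divergent Gaussian likelihood;
    ## report -Inf so it dominates any comparison instead of erroring
    aicc = if (n - K - 1 <= 0) NA_real_
           else if (is.finite(ll)) aicc(ll, n, K) else -Inf,
    aicc_available = n - K - 1 > 0,
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    t_stats = sm$coefficients[, "t value"],
    p_values = sm$coefficients[, "Pr(>|t|)"],
    std_errors = sm$coefficients[, "Std. Error"],
    f_p_value = if (!is.null(sm$fstatistic)) {
      unname(stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                       sm$fstatistic[3L], lower.tail = FALSE))
    } else NA_real_,
    model = fit
  ), class = "lm_fit")
}

#' @export
print.lm_fit <- function(x, ...) {
  cat("<lm_fit> ", paste(x$terms, collapse = " + "), "\n", sep = "")
  cat(sprintf("  n = %d, K = %d, R2 = %.3f, AICc = %s\n", x$n, x$K,
              x$r_squared,
              if (x$aicc_available) sprintf("%.2f", x$aicc) else "unavailable"))
  invisible(x)
}

#' Polynomial richness-elevation fit
#'
#' Ordinary least squares of richness on powers 1..`degree` of centered
#' elevation (centering reduces the collinearity of the raw power basis;
#' fitted values, R-squared and AICc are unaffected). The log-likelihood
#' uses the Gaussian ML variance, and `K` counts the residual variance, so
#' a linear fit has `K = 3`.
#'
#' @param elevation numeric vector of band elevations (distinct values).
#' @param richness numeric richness vector, same length.
#' @param degree polynomial degree, 1, 2 or 3.
#' @return an object of class `lm_fit` (see [compare_polynomials()]).
#'   `aicc` is `NA` with `aicc_available = FALSE` when `n - K - 1 <= 0`.
#' @export
fit_polynomial <- function(elevation, richness, degree) {
  degree <- as.integer(degree)
  stopifnot(degree %in% 1:3, length(elevation) == length(richness))
  if (length(unique(elevation)) < degree + 1L) {
    stop("need more distinct elevations than the polynomial degree",
         call. = FALSE)
  }
  if (length(elevation) <= degree + 1L) {
    stop("need n > degree + 1 observations", call. = FALSE)
  }
  x <- elevation - mean(elevation)
  X <- stats::poly(x, degree = degree, raw = TRUE)
  colnames(X) <- paste0("elev", seq_len(degree))
  d <- data.frame(richness = richness, X)
  fit <- stats::lm(richness ~ ., data = d)
  as_lm_fit(fit, c("(Intercept)", colnames(X)))
}

#' Compare polynomial trends of degree 1-3 by AICc
#'
#' Fits linear, quadratic and cubic richness-elevation models and reports
#' the degree with the lowest AICc (ties resolved toward the lower
#' degree). Because AICc penalizes parameters, the best degree frequently
#' differs from the degree with the highest R-squared.
#'
#' @param elevation,richness numeric vectors (n >= 6).
#' @return list with `fits` (named list of `lm_fit`, degrees 1-3),
#'   `best_degree`, and `table` (degree, r_squared, aicc).
#' @export
compare_polynomials <- function(elevation, richness) {
  stopifnot(length(elevation) >= 6)
  fits <- lapply(1:3, function(d) fit_polynomial(elevation, richness, d))
  names(fits) <- c("linear", "quadratic", "cubic")
  tab <- data.frame(
    degree = 1:3,
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    row.names = NULL
  )
  avail <- which(!is.na(tab$aicc))
  best <- if (length(avail)) avail[which.min(tab$aicc[avail])] else NA_integer_
  list(fits = fits, best_degree = tab$degree[best], table = tab)
}
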