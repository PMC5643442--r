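## Information-theoretic analysis of richness drivers: collinearity
## screen, all-subsets fitting of slope*(MDE + area + NDVI + PSR)-type
## global models, AICc ranking, Akaike-weight model averaging over the 95%
## cumulative-weight confidence set, VIF and Moran's I diagnostics.

#' Pairwise-correlation collinearity screen
#'
#' Computes all pairwise Pearson correlations among numeric covariates and
#' drops redundant ones: within each connected component of the graph
#' whose edges join pairs with `|r| > threshold`, only the
#' highest-priority covariate is retained. Priority is the order of
#' `keep_priority`; covariates not listed rank after listed ones, in
#' column order.
#'
#' @param covariates data frame; only numeric columns are screened.
#' @param threshold absolute-correlation threshold (default 0.7).
#' @param keep_priority character vector, most-preferred first. The
#'   default prefers NDVI over the climate variables it integrates.
#' @return list with `retained`, `dropped` (character vectors) and
#'   `cor_matrix`.
#' @export
correlation_screen <- function(covariates, threshold = 0.7,
                               keep_priority = c("NDVI", "PSR", "MAT", "MAH")) {
  stopifnot(is.data.frame(covariates), nrow(covariates) >= 3)
  num <- covariates[vapply(covariates, is.numeric, logical(1))]
  const <- names(num)[vapply(num, function(x) stats::sd(x) == 0, logical(1))]
  if (length(const)) {
    stop("constant column(s) make correlations undefined: ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  cm <- stats::cor(num)
  vars <- colnames(cm)
  p <- ncol(cm)
  adj <- abs(cm) > threshold
  diag(adj) <- FALSE
  ## connected components by BFS
  comp <- rep(NA_integer_, p)
  cid <- 0L
  for (i in seq_len(p)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  rank_of <- function(v) {
    i <- match(v, keep_priority)
    ifelse(is.na(i), length(keep_priority) + match(v, vars), i)
  }
  retained <- character(0)
  for (k in seq_len(cid)) {
    members <- vars[comp == k]
    retained <- c(retained, members[which.min(rank_of(members))])
  }
  retained <- vars[vars %in% retained]
  list(retained = retained, dropped = setdiff(vars, retained),
       cor_matrix = cm)
}

#' Enumerate candidate model term sets
#'
#' All subsets of the global model's terms, each including the intercept.
#' Under marginality (the default) an interaction `a:b` enters a model
#' only when both `a` and `b` do.
#'
#' @param main_terms character vector of main-effect terms.
#' @param interaction_terms character vector of `"a:b"` interaction terms
#'   whose parents appear in `main_terms`.
#' @param marginality enforce the parent rule.
#' @return list of character vectors of terms; the intercept-only model is
#'   `character(0)`.
#' @export
enumerate_models <- function(main_terms, interaction_terms = character(0),
                             marginality = TRUE) {
  stopifnot(is.character(main_terms), length(main_terms) >= 1)
  parents <- strsplit(interaction_terms, ":", fixed = TRUE)
  bad <- vapply(parents, function(p) !all(p %in% main_terms), logical(1))
  if (any(bad)) {
    stop("interaction(s) with undeclared parents: ",
         paste(interaction_terms[bad], collapse = ", "), call. = FALSE)
  }
  all_terms <- c(main_terms, interaction_terms)
  n <- length(all_terms)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    inc <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    terms <- all_terms[inc]
    if (marginality) {
      ints <- intersect(terms, interaction_terms)
      ok <- all(vapply(strsplit(ints, ":", fixed = TRUE),
                       function(p) all(p %in% terms), logical(1)))
      if (!ok) next
    }
    out[[length(out) + 1L]] <- terms
  }
  out
}

#' Assemble the driver-analysis design table
#'
#' Joins per-band covariates with the MDE-predicted richness and applies
#' the analysis transforms: the elevational variables (`area`, `MAT`,
#' `MAH`, `NDVI`, `PSR`) are natural-log transformed, the MDE predictor
#' enters untransformed, and `slope` becomes a factor. Transformed columns
#' keep their original names; the applied transform is recorded in
#' `attr(, "log_vars")`.
#'
#' @param covariates data frame with one row per slope x band (columns
#'   `slope`, `elevation` and the covariates).
#' @param mde optional numeric vector of MDE-predicted richness, in the
#'   row order of `covariates`.
#' @param log_vars columns to log-transform (intersected with those
#'   present).
#' @return the transformed design data frame.
#' @export
build_design <- function(covariates, mde = NULL,
                         log_vars = c("area", "MAT", "MAH", "NDVI", "PSR")) {
  stopifnot(is.data.frame(covariates))
  d <- covariates
  log_vars <- intersect(log_vars, names(d))
  for (v in log_vars) {
    if (any(d[[v]] <= 0)) {
      stop("cannot log-transform `", v, "`: non-positive values", call. = FALSE)
    }
    d[[v]] <- log(d[[v]])
  }
  if (!is.null(mde)) {
    stopifnot(length(mde) == nrow(d))
    d$MDE <- mde
  }
  if ("slope" %in% names(d)) d$slope <- factor(d$slope)
  attr(d, "log_vars") <- log_vars
  d
}

#' Fit one candidate richness model
#'
#' Gaussian identity-link fit (ordinary least squares) of richness on a
#' term set over a prepared design table (see [build_design()]). A
#' Poisson-log alternative is available for count responses.
#'
#' @param richness numeric response vector, one value per design row.
#' @param design data frame of predictors (already transformed).
#' @param terms character vector of terms (`character(0)` = intercept
#'   only); interactions as `"a:b"`.
#' @param family `"gaussian"` (default) or `"poisson"`.
#' @return an `lm_fit` object (Gaussian) or the fitted `glm` (Poisson).
#' @export
fit_model <- function(richness, design, terms = character(0),
                      family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(design), length(richness) == nrow(design))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  d <- cbind(.y = richness, design)
  f <- stats::as.formula(paste(".y ~", rhs))
  if (family == "poisson") {
    return(stats::glm(f, data = d, family = stats::poisson()))
  }
  fit <- stats::lm(f, data = d)
  as_lm_fit(fit, if (length(terms)) terms else "(Intercept)")
}

#' Fit and rank the all-subsets candidate set
#'
#' Enumerates every sub-model of the global model (marginality enforced),
#' fits each by OLS, and ranks them by AICc. Models whose sample size
#' cannot support the AICc correction (`n - K - 1 <= 0`) are excluded with
#' a warning; at 12 bands this is what removes the richest interaction
#' models from contention.
#'
#' @param richness response vector.
#' @param design prepared design table ([build_design()]).
#' @param main_terms,interaction_terms,marginality passed to
#'   [enumerate_models()].
#' @return an object of class `candidate_model_set`: list with `fits`
#'   (ranked), `table` (terms, K, r_squared, aicc, delta_aicc, weight,
#'   cum_weight, in_conf_set), and `n_excluded`.
#' @export
candidate_model_set <- function(richness, design, main_terms,
                                interaction_terms = character(0),
                                marginality = TRUE) {
  term_sets <- enumerate_models(main_terms, interaction_terms, marginality)
  fits <- lapply(term_sets, function(ts) fit_model(richness, design, ts))
  ok <- vapply(fits, function(f) f$aicc_available, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " model(s) dropped: n - K - 1 <= 0 leaves AICc undefined")
  }
  fits <- fits[ok]
  if (!length(fits)) stop("no candidate model supports AICc at this n",
                          call. = FALSE)
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  nterms <- vapply(fits, function(f) length(setdiff(f$terms, "(Intercept)")),
                   integer(1))
  labels <- vapply(fits, function(f)
    paste(setdiff(f$terms, "(Intercept)"), collapse = "+"), character(1))
  labels[labels == ""] <- "(intercept)"
  ## rank by AICc; ties -> fewer terms, then lexicographic label
  ord <- order(aiccs, nterms, labels)
  fits <- fits[ord]
  aiccs <- aiccs[ord]
  w <- akaike_weights(aiccs)
  cw <- cumsum(w)
  ## smallest prefix of ranked models reaching 95% cumulative weight
  cutoff <- which(cw >= 0.95)[1L]
  in_set <- seq_along(fits) <= cutoff
  tab <- data.frame(
    rank = seq_along(fits),
    terms = labels[ord],
    K = vapply(fits, function(f) f$K, integer(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    aicc = aiccs,
    delta_aicc = aiccs - aiccs[1L],
    weight = w,
    cum_weight = cw,
    in_conf_set = in_set,
    stringsAsFactors = FALSE
  )
  structure(list(fits = fits, table = tab, n_excluded = sum(!ok)),
            class = "candidate_model_set")
}

#' @export
print.candidate_model_set <- function(x, n = 10L, ...) {
  cat("<candidate_model_set>", nrow(x$table), "models")
  if (x$n_excluded) cat(" (", x$n_excluded, " excluded, AICc undefined)", sep = "")
  cat("\n")
  tab <- utils::head(x$table, n)
  tab$r_squared <- round(tab$r_squared, 3)
  tab$aicc <- round(tab$aicc, 2)
  tab$delta_aicc <- round(tab$delta_aicc, 2)
  tab$weight <- round(tab$weight, 3)
  tab$cum_weight <- round(tab$cum_weight, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Best model of a candidate set
#'
#' The lowest-AICc model; ties were already resolved toward fewer terms,
#' then lexicographically, when the set was ranked.
#'
#' @param cms a `candidate_model_set`.
#' @return the rank-1 `lm_fit`.
#' @export
select_best <- function(cms) {
  stopifnot(inherits(cms, "candidate_model_set"))
  cms$fits[[1L]]
}

#' Model averaging over the 95% confidence set
#'
#' Restricts to the smallest top-ranked set whose Akaike weights cumulate
#' to `cum_weight`, renormalizes the weights, and computes (i) per-term
#' relative importance — the summed weight of set members containing the
#' term — and (ii) weight-averaged coefficients, by default the full
#' (zero-substitution) average in which a model lacking a term contributes
#' a zero coefficient; `method = "conditional"` averages only over models
#' containing the term.
#'
#' @param cms a `candidate_model_set`.
#' @param cum_weight cumulative-weight mass of the confidence set.
#' @param method `"full"` or `"conditional"` coefficient averaging.
#' @return an object of class `averaged_model`: list with `importance`
#'   (named, sorted decreasing), `averaged_coefficients`, `method`,
#'   `n_models`, `weights` (renormalized).
#' @export
model_average <- function(cms, cum_weight = 0.95,
                          method = c("full", "conditional")) {
  stopifnot(inherits(cms, "candidate_model_set"))
  method <- match.arg(method)
  w <- cms$table$weight
  cutoff <- which(cumsum(w) >= cum_weight)[1L]
  keep <- seq_len(cutoff)
  fits <- cms$fits[keep]
  wr <- w[keep] / sum(w[keep])
  terms <- unique(unlist(lapply(fits, function(f)
    setdiff(f$terms, "(Intercept)"))))
  importance <- vapply(terms, function(t)
    sum(wr[vapply(fits, function(f) t %in% f$terms, logical(1))]), numeric(1))
  coef_names <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  avg <- vapply(coef_names, function(cn) {
    b <- vapply(fits, function(f) {
      if (cn %in% names(f$coefficients)) f$coefficients[[cn]] else 0
    }, numeric(1))
    present <- vapply(fits, function(f) cn %in% names(f$coefficients),
                      logical(1))
    if (method == "full") sum(wr * b)
    else sum(wr[present] * b[present]) / sum(wr[present])
  }, numeric(1))
  structure(list(
    importance = sort(importance, decreasing = TRUE),
    averaged_coefficients = avg,
    method = method, n_models = length(fits), weights = wr
  ), class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("<averaged_model>", x$n_models, "models in the confidence set;",
      x$method, "averaging\n")
  cat("relative importance:\n")
  print(round(x$importance, 3))
  invisible(x)
}

#' Variable importance within the best model
#'
#' Scores each non-intercept term of a fitted model by the absolute value
#' of its t-statistic, optionally rescaled so the strongest term is 100.
#'
#' @param fit an `lm_fit`.
#' @param rescale rescale scores to `[0, 100]`.
#' @return named numeric vector, sorted decreasing.
#' @export
variable_importance_best <- function(fit, rescale = FALSE) {
  stopifnot(inherits(fit, "lm_fit"))
  t <- fit$t_stats
  t <- t[setdiff(names(t), "(Intercept)")]
  if (!length(t)) stop("model has no non-intercept terms", call. = FALSE)
  imp <- abs(t)
  if (rescale) imp <- 100 * imp / max(imp)
  sort(imp, decreasing = TRUE)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, where `R2_j` is from regressing predictor `j`
#' on all the others. Values of 5 or more are flagged as problematic
#' collinearity. Perfectly collinear predictors yield `Inf`.
#'
#' @param design data frame or matrix of at least two numeric predictors
#'   (no intercept column).
#' @return named numeric vector of VIFs with a logical `flagged` attribute
#'   (`VIF >= 5`).
#' @export
vif <- function(design) {
  X <- as.matrix(as.data.frame(lapply(as.data.frame(design), function(x) {
    if (is.factor(x) || is.character(x)) as.numeric(factor(x)) else x
  })))
  if (ncol(X) < 2) stop("VIF needs at least two predictors", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  attr(out, "flagged") <- out >= 5
  out
}

#' Spatial weights for band transects
#'
#' Builds an n x n spatial weights matrix over the rows of a band table.
#' The default `"chain"` scheme joins consecutive bands within a slope
#' (slopes are disconnected blocks); `"idw"` uses inverse distance on
#' supplied coordinates or on elevation.
#'
#' @param band_table data frame with `slope` and `elevation` (and
#'   optionally `x`/`y` coordinates for `"idw"`).
#' @param scheme `"chain"` or `"idw"`.
#' @param row_standardize divide each row by its sum.
#' @return an object of class `spatial_weights`: list with `W`, `scheme`,
#'   `row_standardized`.
#' @export
build_spatial_weights <- function(band_table, scheme = c("chain", "idw"),
                                  row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(band_table), nrow(band_table) >= 2)
  n <- nrow(band_table)
  W <- matrix(0, n, n)
  if (scheme == "chain") {
    for (sl in unique(band_table$slope)) {
      idx <- which(band_table$slope == sl)
      idx <- idx[order(band_table$elevation[idx])]
      for (k in seq_len(length(idx) - 1L)) {
        W[idx[k], idx[k + 1L]] <- 1
        W[idx[k + 1L], idx[k]] <- 1
      }
    }
  } else {
    if (all(c("x", "y") %in% names(band_table))) {
      d <- as.matrix(stats::dist(band_table[, c("x", "y")]))
    } else {
      d <- as.matrix(stats::dist(band_table$elevation))
    }
    W <- 1 / d
    diag(W) <- 0
    W[!is.finite(W)] <- 0
  }
  zero_rows <- rowSums(W) == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows), " unit(s) have no neighbours under the '",
            scheme, "' scheme")
    if (row_standardize) {
      stop("cannot row-standardize with neighbourless units", call. = FALSE)
    }
  }
  if (row_standardize) W <- W / rowSums(W)
  structure(list(W = W, scheme = scheme, row_standardized = row_standardize),
            class = "spatial_weights")
}

#' Moran's I spatial autocorrelation of residuals
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centered values
#' `z` and `S0 = sum(W)`. The expectation under no autocorrelation is
#' `-1/(n-1)`; the variance uses the randomisation (kurtosis-corrected)
#' formula and the p-value a two-sided normal approximation.
#'
#' @param x numeric vector (typically model residuals), length >= 3.
#' @param weights a `spatial_weights` object or an n x n matrix.
#' @return an object of class `moran_result`: list with `I`, `expected`,
#'   `variance`, `z`, `p`, `n`.
#' @export
morans_i <- function(x, weights) {
  W <- if (inherits(weights, "spatial_weights")) weights$W else as.matrix(weights)
  n <- length(x)
  stopifnot(n >= 3, all(dim(W) == n))
  if (stats::sd(x) == 0) stop("Moran's I undefined for constant input",
                              call. = FALSE)
  z <- x - mean(x)
  S0 <- sum(W)
  I <- (n / S0) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- (sum(z^4) / n) / (sum(z^2) / n)^2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zstat <- (I - EI) / sqrt(VI)
  structure(list(I = I, expected = EI, variance = VI, z = zstat,
                 p = 2 * stats::pnorm(abs(zstat), lower.tail = FALSE), n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("<moran_result> I = %.4f (E = %.4f), z = %.3f, p = %.3g\n",
              x$I, x$expected, x$z, x$p))
  invisible(x)
}
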