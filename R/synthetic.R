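## Synthetic two-slope elevational trapping surveys.
##
## The generator emulates the study design the analysis assumes: a bounded
## discrete domain of elevation bands on each of two slopes, species with
## contiguous elevational ranges, Poisson abundance per occupied band,
## binomial detection over a fixed trapping effort, and band-level
## covariates (area, temperature, humidity, NDVI, plant richness) whose
## sign structure mimics a temperate-subtropical mountain: temperature
## falls with elevation, humidity and NDVI rise, plant richness falls.

#' Configuration for the synthetic gradient generator
#'
#' Builds a validated configuration object for [generate_dataset()]. All
#' defaults describe an "Ailao-like" survey: 6 bands per slope spanning
#' 1,800-2,800 m in 200-m steps, two slopes with 27 and 33 species sharing
#' 23, and roughly 2,200 trap-nights per band (1,100 per season over two
#' seasons).
#'
#' @param n_bands number of elevation bands per slope.
#' @param band_step band width in meters.
#' @param base_elevation elevation (m) of the lowest band.
#' @param slopes character vector of slope labels.
#' @param n_species species pool size per slope; scalar or one value per
#'   slope.
#' @param n_shared number of species occurring on both slopes (the rest are
#'   slope-exclusive). Must not exceed `min(n_species)`.
#' @param range_size_dist probability vector over range sizes `1:n_bands`
#'   (must sum to 1).
#' @param placement_mode `"mde_null"` places range midpoints uniformly over
#'   feasible positions; `"environmental"` weights positions by a Gaussian
#'   kernel around `env_optimum_band`.
#' @param env_optimum_band,env_breadth optimum band index and kernel SD (in
#'   bands) used when `placement_mode = "environmental"`.
#' @param detection_prob per-individual, per-trap-night detection
#'   probability in (0, 1].
#' @param trap_nights_per_band trapping effort per band (trap-nights).
#' @param abundance_mean expected number of individuals of a species in an
#'   occupied band (Poisson mean).
#' @param abundance_dispersion reserved for future negative-binomial noise;
#'   currently must be `Inf` (Poisson).
#' @param covariate_coefs named list of covariate-generating coefficients;
#'   see Details.
#' @param noise_sd named list of Gaussian noise SDs for `mat`, `mah`,
#'   `ndvi`, `psr` (natural covariate scale).
#' @param endemic_prob,insectivore_prob per-species trait probabilities.
#' @param seed integer seed; the whole dataset is reproducible from it.
#'
#' @details
#' `covariate_coefs` components (all on the natural scale; downstream
#' analyses apply their own log transforms):
#' \describe{
#'   \item{mat_base, mat_lapse}{mean annual temperature at the lowest band
#'     (deg C) and change per meter (negative lapse).}
#'   \item{mah_base, mah_trend}{mean annual humidity (%) at the lowest band
#'     and change per meter.}
#'   \item{ndvi_intercept, ndvi_mat, ndvi_mah}{NDVI as a linear function of
#'     MAT and MAH; a negative `ndvi_mat` reproduces the strong negative
#'     MAT-NDVI correlation of humid montane forests.}
#'   \item{psr_base, psr_trend}{plant species richness at the lowest band
#'     and change per meter.}
#'   \item{area}{list of per-slope area profiles (km^2), each of length
#'     `n_bands`.}
#' }
#'
#' @return an object of class `gradient_sim_config` (a validated list).
#' @seealso [generate_dataset()], [ailao_config()]
#' @export
gradient_sim_config <- function(n_bands = 6L,
                                band_step = 200,
                                base_elevation = 1800,
                                slopes = c("west", "east"),
                                n_species = c(27L, 33L),
                                n_shared = 23L,
                                range_size_dist = NULL,
                                placement_mode = c("mde_null", "environmental"),
                                env_optimum_band = NULL,
                                env_breadth = 1.5,
                                detection_prob = 0.001,
                                trap_nights_per_band = 2200L,
                                abundance_mean = 11.4,
                                abundance_dispersion = Inf,
                                covariate_coefs = NULL,
                                noise_sd = NULL,
                                endemic_prob = 0.55,
                                insectivore_prob = 0.43,
                                seed = 1L) {
  placement_mode <- match.arg(placement_mode)
  n_bands <- as.integer(n_bands)
  if (n_bands < 2L) stop("`n_bands` must be >= 2", call. = FALSE)
  if (length(n_species) == 1L) n_species <- rep(n_species, length(slopes))
  if (length(n_species) != length(slopes)) {
    stop("`n_species` must have one value per slope", call. = FALSE)
  }
  n_species <- as.integer(n_species)
  if (any(n_species <= 0L)) stop("`n_species` must be positive", call. = FALSE)
  n_shared <- as.integer(min(n_shared, min(n_species)))
  if (n_shared < 0L) stop("`n_shared` must be >= 0", call. = FALSE)

  if (is.null(range_size_dist)) {
    ## Mildly right-skewed over 1..n_bands: many narrow ranges, a tail of
    ## full-domain species, so a median split lands near half large-ranged.
    w <- c(1.6, rep(1, n_bands - 2L), 1.4)
    range_size_dist <- w / sum(w)
  }
  if (length(range_size_dist) != n_bands) {
    stop("`range_size_dist` must have one probability per range size 1..n_bands",
         call. = FALSE)
  }
  if (any(range_size_dist < 0) || abs(sum(range_size_dist) - 1) > 1e-9) {
    stop("`range_size_dist` must be non-negative and sum to 1 (tol 1e-9)",
         call. = FALSE)
  }
  if (!(detection_prob > 0 && detection_prob <= 1)) {
    stop("`detection_prob` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.infinite(abundance_dispersion)) {
    stop("only Poisson abundance (`abundance_dispersion = Inf`) is implemented",
         call. = FALSE)
  }

  if (is.null(covariate_coefs)) {
    covariate_coefs <- list(
      mat_base = 16, mat_lapse = -0.0055,
      mah_base = 70, mah_trend = 0.008,
      ndvi_intercept = 0.78, ndvi_mat = -0.012, ndvi_mah = 0.001,
      psr_base = 140, psr_trend = -0.04,
      area = NULL
    )
  }
  if (is.null(covariate_coefs$area)) {
    ## Planimetric band area: broadly shrinking toward the summit but
    ## irregular, as real topography is — keeps area only weakly
    ## correlated with the smooth climate covariates.
    covariate_coefs$area <- if (n_bands == 6L && length(slopes) == 2L) {
      stats::setNames(list(c(38, 52, 27, 45, 31, 34),
                           c(45, 30, 48, 26, 42, 28)), slopes)
    } else {
      wiggle <- rep_len(c(0.7, 1.35, 0.85, 1.2), n_bands)
      stats::setNames(lapply(seq_along(slopes), function(i) {
        round((45 - 5 * (i - 1L)) * wiggle *
                seq(1.1, 0.9, length.out = n_bands), 1)
      }), slopes)
    }
  }
  if (is.null(noise_sd)) {
    noise_sd <- list(mat = 0.3, mah = 1.5, ndvi = 0.015, psr = 6)
  }
  if (any(unlist(noise_sd) < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  if (is.null(env_optimum_band)) env_optimum_band <- (n_bands + 1) / 2

  cfg <- structure(list(
    n_bands = n_bands, band_step = band_step, base_elevation = base_elevation,
    slopes = slopes, n_species = stats::setNames(n_species, slopes),
    n_shared = n_shared, range_size_dist = range_size_dist,
    placement_mode = placement_mode, env_optimum_band = env_optimum_band,
    env_breadth = env_breadth, detection_prob = detection_prob,
    trap_nights_per_band = as.integer(trap_nights_per_band),
    abundance_mean = abundance_mean, covariate_coefs = covariate_coefs,
    noise_sd = noise_sd, endemic_prob = endemic_prob,
    insectivore_prob = insectivore_prob, seed = as.integer(seed)
  ), class = "gradient_sim_config")
  cfg
}

#' The packaged "Ailao-like" survey configuration
#'
#' A convenience wrapper around [gradient_sim_config()] whose defaults
#' mirror the dimensions of a two-slope montane small-mammal survey: 6
#' bands (1,800-2,800 m), 27 and 33 species with 23 shared, ~2,200
#' trap-nights per band, and detection parameters giving an overall trap
#' success near 8%.
#'
#' @param seed integer seed passed through.
#' @param ... overrides forwarded to [gradient_sim_config()].
#' @return a `gradient_sim_config` object.
#' @export
ailao_config <- function(seed = 1L, ...) {
  gradient_sim_config(seed = seed, ...)
}

## Draw a contiguous range (start band, size) for one species.
draw_range <- function(cfg) {
  r <- sample.int(cfg$n_bands, 1L, prob = cfg$range_size_dist)
  n_pos <- cfg$n_bands - r + 1L
  if (cfg$placement_mode == "mde_null") {
    start <- sample.int(n_pos, 1L)
  } else {
    mids <- seq_len(n_pos) + (r - 1) / 2
    w <- exp(-0.5 * ((mids - cfg$env_optimum_band) / cfg$env_breadth)^2)
    start <- sample.int(n_pos, 1L, prob = w)
  }
  c(start = start, size = r)
}

#' Generate a synthetic two-slope gradient dataset
#'
#' Simulates species ranges, trapping captures, traits, and band covariates
#' from a [gradient_sim_config()]. Ranges are contiguous band intervals
#' whose size is drawn from `range_size_dist` and whose midpoint is uniform
#' over feasible positions (under `placement_mode = "mde_null"`). In each
#' occupied band a species' abundance is Poisson with mean
#' `abundance_mean`; each individual is detected with probability
#' `1 - (1 - detection_prob)^trap_nights_per_band`, and detections are
#' split evenly at random over two trapping seasons.
#'
#' @param config a `gradient_sim_config`.
#' @return an object of class `synthetic_dataset`: a list with components
#'   `captures` (species, slope, elevation, season, count), `traits`
#'   (species, taxon_group, endemic), `covariates` (one row per slope x
#'   band with area, MAT, MAH, NDVI, PSR, trap_nights), and `truth` (the
#'   generating ranges, coefficients and seed).
#' @examples
#' d <- generate_dataset(ailao_config(seed = 42))
#' head(d$captures)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "gradient_sim_config"))
  cfg <- config
  with_seed(derive_seed(cfg$seed, "simulate"), {
    n_pool <- sum(cfg$n_species) - cfg$n_shared * (length(cfg$slopes) - 1L) *
      (length(cfg$slopes) == 2L)
    if (length(cfg$slopes) != 2L) n_pool <- sum(cfg$n_species)
    pool <- sprintf("sp%02d", seq_len(n_pool))

    ## Slope membership: first n_shared species occur on both slopes.
    members <- if (length(cfg$slopes) == 2L) {
      n1 <- cfg$n_species[[1L]]
      list(
        pool[seq_len(n1)],
        c(pool[seq_len(cfg$n_shared)],
          pool[seq.int(n1 + 1L, length.out = cfg$n_species[[2L]] - cfg$n_shared)])
      )
    } else {
      split_sizes <- cfg$n_species
      idx <- split(seq_len(n_pool), rep(seq_along(split_sizes), split_sizes))
      lapply(idx, function(i) pool[i])
    }
    names(members) <- cfg$slopes

    traits <- data.frame(
      species = pool,
      taxon_group = ifelse(stats::runif(n_pool) < cfg$insectivore_prob,
                           "insectivore", "rodent"),
      endemic = stats::runif(n_pool) < cfg$endemic_prob,
      stringsAsFactors = FALSE
    )

    elevs <- band_elevations(cfg$base_elevation, cfg$band_step, cfg$n_bands)
    p_detect <- 1 - (1 - cfg$detection_prob)^cfg$trap_nights_per_band

    truth_ranges <- list()
    cap_rows <- list()
    for (sl in cfg$slopes) {
      for (sp in members[[sl]]) {
        rg <- draw_range(cfg)
        bands_occ <- seq.int(rg[["start"]], length.out = rg[["size"]])
        truth_ranges[[length(truth_ranges) + 1L]] <- data.frame(
          species = sp, slope = sl,
          start_band = rg[["start"]],
          end_band = rg[["start"]] + rg[["size"]] - 1L,
          range_size = rg[["size"]], stringsAsFactors = FALSE
        )
        for (b in bands_occ) {
          abund <- stats::rpois(1L, cfg$abundance_mean)
          detected <- stats::rbinom(1L, abund, p_detect)
          if (detected == 0L) next
          in_dry <- stats::rbinom(1L, detected, 0.5)
          for (season in c("dry", "wet")) {
            cnt <- if (season == "dry") in_dry else detected - in_dry
            if (cnt > 0L) {
              cap_rows[[length(cap_rows) + 1L]] <- data.frame(
                species = sp, slope = sl, elevation = elevs[b],
                season = season, count = cnt, stringsAsFactors = FALSE
              )
            }
          }
        }
      }
    }
    captures <- if (length(cap_rows)) do.call(rbind, cap_rows) else
      data.frame(species = character(), slope = character(),
                 elevation = numeric(), season = character(),
                 count = integer(), stringsAsFactors = FALSE)

    cc <- cfg$covariate_coefs
    ns <- cfg$noise_sd
    cov_rows <- lapply(cfg$slopes, function(sl) {
      de <- elevs - cfg$base_elevation
      mat <- cc$mat_base + cc$mat_lapse * de +
        stats::rnorm(cfg$n_bands, 0, ns$mat)
      mah <- cc$mah_base + cc$mah_trend * de +
        stats::rnorm(cfg$n_bands, 0, ns$mah)
      ndvi <- cc$ndvi_intercept + cc$ndvi_mat * mat + cc$ndvi_mah * mah +
        stats::rnorm(cfg$n_bands, 0, ns$ndvi)
      ndvi <- pmin(1, pmax(-1, ndvi))
      psr <- pmax(1, round(cc$psr_base + cc$psr_trend * de +
                             stats::rnorm(cfg$n_bands, 0, ns$psr)))
      data.frame(
        slope = sl, elevation = elevs, area = cc$area[[sl]],
        MAT = mat, MAH = mah, NDVI = ndvi, PSR = psr,
        trap_nights = cfg$trap_nights_per_band, stringsAsFactors = FALSE
      )
    })
    covariates <- do.call(rbind, cov_rows)
    rownames(covariates) <- NULL

    structure(list(
      captures = captures, traits = traits, covariates = covariates,
      truth = list(ranges = do.call(rbind, truth_ranges),
                   coefs = cc, seed = cfg$seed, config = cfg)
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  cat("  slopes:   ", paste(unique(x$covariates$slope), collapse = ", "), "\n")
  cat("  bands:    ", length(unique(x$covariates$elevation)), "per slope\n")
  cat("  species:  ", nrow(x$traits), "in pool;",
      nrow(x$truth$ranges), "slope-level ranges\n")
  cat("  captures: ", sum(x$captures$count), "individuals in",
      nrow(x$captures), "records\n")
  invisible(x)
}

#' Simulate richness from a known linear model
#'
#' Generates a richness vector `y = X beta + N(0, noise_sd^2)` from a
#' design table and named coefficients, for parameter-recovery experiments
#' on the driver-selection machinery. Coefficient names must match columns
#' of `design` (apply any log transforms to `design` first, exactly as the
#' analysis will); the name `"(Intercept)"` (or `"intercept"`) adds a
#' constant.
#'
#' @param design data frame of predictors, one row per slope x band.
#' @param coefficients named numeric vector of true effects.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @param integer_output if `TRUE`, round to non-negative integers.
#' @return numeric richness vector of length `nrow(design)`.
#' @export
generate_richness_from_model <- function(design, coefficients, noise_sd = 0,
                                         seed = 1L, integer_output = FALSE) {
  stopifnot(is.data.frame(design), noise_sd >= 0)
  nm <- names(coefficients)
  if (is.null(nm) || any(nm == "")) {
    stop("`coefficients` must be a fully named vector", call. = FALSE)
  }
  y <- rep(0, nrow(design))
  for (term in nm) {
    if (term %in% c("(Intercept)", "intercept")) {
      y <- y + coefficients[[term]]
    } else if (term %in% names(design)) {
      x <- design[[term]]
      if (!is.numeric(x)) stop("term `", term, "` is not numeric", call. = FALSE)
      y <- y + coefficients[[term]] * x
    } else {
      stop("unknown term `", term, "` not found in design", call. = FALSE)
    }
  }
  y <- with_seed(derive_seed(seed, "richness_model"),
                 y + stats::rnorm(nrow(design), 0, noise_sd))
  if (integer_output) y <- pmax(0, round(y))
  y
}
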