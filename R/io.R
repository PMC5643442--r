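## Reading, validation, and the end-to-end pipeline.
##
## All CSV files are comma-separated UTF-8 with a header row and "."
## decimals. Elevations in capture files are snapped to the nearest design
## band when within a tolerance (default +/- 25 m, matching trap stations
## spread a few tens of meters around each transect line).

#' Read and validate a captures file
#'
#' @param path CSV/TSV file with columns `species`, `slope`, `elevation`,
#'   `season`, `count`.
#' @param bands numeric vector of design band elevations.
#' @param tolerance snap tolerance in meters (default 25): an elevation is
#'   assigned to a band when within `tolerance` of it.
#' @return validated data frame with `elevation` snapped to band values.
#' @export
read_captures <- function(path, bands, tolerance = 25) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  req <- c("species", "slope", "elevation", "season", "count")
  unknown <- setdiff(names(d), req)
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("captures file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(unknown)) {
    stop("unknown column(s) in captures file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(d$elevation) || !is.numeric(d$count)) {
    bad <- which(is.na(suppressWarnings(as.numeric(d$elevation))) |
                   is.na(suppressWarnings(as.numeric(d$count))))
    stop("unparsable numeric value(s) at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(d$count < 0)) {
    stop("negative count at data row(s): ",
         paste(utils::head(which(d$count < 0), 5L), collapse = ", "),
         call. = FALSE)
  }
  bands <- sort(bands)
  nearest <- vapply(d$elevation, function(e) bands[which.min(abs(bands - e))],
                    numeric(1))
  off <- abs(d$elevation - nearest) > tolerance
  if (any(off)) {
    i <- which(off)[1L]
    stop("elevation ", d$elevation[i], " m (data row ", which(off)[1L],
         ") is outside the +/-", tolerance,
         " m tolerance of every design band", call. = FALSE)
  }
  d$elevation <- nearest
  d$count <- as.integer(d$count)
  d
}

#' Read and validate a traits file
#'
#' @param path CSV with columns `species`, `taxon_group`, `endemic`.
#' @return validated data frame (`endemic` coerced to logical).
#' @export
read_traits <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "taxon_group", "endemic")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("traits file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(d$species)) {
    stop("duplicate species in traits: ",
         d$species[anyDuplicated(d$species)], call. = FALSE)
  }
  bad <- !d$taxon_group %in% c("insectivore", "rodent")
  if (any(bad)) {
    stop("unknown taxon_group value(s): ",
         paste(unique(d$taxon_group[bad]), collapse = ", "), call. = FALSE)
  }
  d$endemic <- as.logical(d$endemic)
  d
}

#' Read and validate a band-covariates file
#'
#' One row per slope x band. Missing numeric cells are kept as `NA` and
#' reported in an attribute, never silently dropped.
#'
#' @param path CSV with columns `slope`, `elevation`, `area`, `MAT`,
#'   `MAH`, `NDVI`, `PSR` (extra columns such as `trap_nights` pass
#'   through).
#' @return validated data frame; `attr(, "n_missing")` counts flagged
#'   cells.
#' @export
read_covariates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("slope", "elevation", "area", "MAT", "MAH", "NDVI", "PSR")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("covariates file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(d$slope, d$elevation)
  if (anyDuplicated(key)) {
    stop("duplicate slope x band row: ", key[anyDuplicated(key)],
         call. = FALSE)
  }
  if (any(!is.na(d$NDVI) & (d$NDVI < -1 | d$NDVI > 1))) {
    stop("NDVI outside [-1, 1]", call. = FALSE)
  }
  if (any(!is.na(d$area) & d$area <= 0)) {
    stop("area must be positive", call. = FALSE)
  }
  n_missing <- sum(is.na(d[req[-1]]))
  attr(d, "n_missing") <- n_missing
  d
}

#' Write a synthetic dataset to a directory
#'
#' Writes `captures.csv`, `traits.csv`, `covariates.csv` and `truth.json`
#' (the generating ranges and seed).
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$captures, file.path(dir, "captures.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  truth <- dataset$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full gradient analysis pipeline
#'
#' Orchestrates the stages end to end for a set of species groups: build
#' interpolated ranges from captures, compute per-group richness, fit the
#' MDE null model per slope, fit polynomial trends, and run the
#' driver-selection chain (collinearity screen, all-subsets AICc ranking,
#' model averaging, VIF, Moran's I on the best model's residuals). With
#' the same configuration and seed the run is fully reproducible.
#'
#' @param captures,traits,covariates input data frames (e.g. from a
#'   [generate_dataset()] result or the `read_*` functions).
#' @param bands numeric vector of design band elevations; defaults to the
#'   sorted unique covariate elevations.
#' @param groups species groups to analyze.
#' @param n_sims MDE simulation count.
#' @param seed top-level seed; per-stage streams are derived from it.
#' @param screen_threshold,keep_priority collinearity-screen settings.
#' @param cum_weight confidence-set mass for model averaging.
#' @param out_dir optional directory; when given, CSV/JSON artifacts and a
#'   plain-text log (seed, config hash, package version) are written.
#' @return a list (class `gradient_report`) with per-group results:
#'   `richness`, `mde` (per slope), `mde_fit` (per slope), `trend` (per
#'   slope), `selection` (`candidate_model_set`, best fit, averaged model,
#'   VIF, Moran's I), plus `screen` and `meta`.
#' @export
run_pipeline <- function(captures, traits, covariates, bands = NULL,
                         groups = c("total", "insectivores", "rodents",
                                    "large_ranged", "small_ranged",
                                    "endemic", "non_endemic"),
                         n_sims = 5000L, seed = 1L,
                         screen_threshold = 0.7,
                         keep_priority = c("NDVI", "PSR", "MAT", "MAH"),
                         cum_weight = 0.95, out_dir = NULL) {
  if (is.null(bands)) bands <- sort(unique(covariates$elevation))
  groups <- match.arg(groups, .group_labels, several.ok = TRUE)
  ranges <- build_ranges(captures, bands)
  slopes <- unique(covariates$slope)

  ## Collinearity screen on the environmental covariates (natural scale).
  screen <- correlation_screen(
    covariates[, intersect(c("area", "MAT", "MAH", "NDVI", "PSR"),
                           names(covariates))],
    threshold = screen_threshold, keep_priority = c("area", keep_priority))

  cov_ord <- covariates[order(covariates$slope, covariates$elevation), ,
                        drop = FALSE]

  results <- list()
  for (g in groups) {
    rich <- group_richness(ranges, traits, group = g, mode = "interpolated")
    rich_obs <- group_richness(ranges, traits, group = g, mode = "observed")
    per_slope <- list()
    mde_pred_all <- rep(NA_real_, nrow(cov_ord))
    for (sl in slopes) {
      rsub <- filter_group(ranges[ranges$slope == sl, , drop = FALSE],
                           traits, g)
      robs <- rich$richness[rich$slope == sl][order(rich$elevation[rich$slope == sl])]
      if (nrow(rsub) == 0L) {
        per_slope[[sl]] <- list(mde = NULL, mde_fit = NULL, trend = NULL)
        next
      }
      mde <- simulate_mde(rsub$range_size, m = length(bands),
                          n_sims = n_sims,
                          seed = derive_seed(seed, paste("mde", g, sl)))
      fit <- if (all(mde$mean_richness > 0) && stats::sd(robs) > 0)
        fit_observed_to_mde(robs, mde$mean_richness) else NULL
      trend <- if (stats::sd(robs) > 0)
        compare_polynomials(bands, robs) else NULL
      per_slope[[sl]] <- list(mde = mde, mde_fit = fit, trend = trend)
      idx <- which(cov_ord$slope == sl)
      mde_pred_all[idx[order(cov_ord$elevation[idx])]] <- mde$mean_richness
    }

    ## Driver selection pooled over slopes, global model
    ## slope * (MDE + screened covariates)
    design <- build_design(cov_ord, mde = mde_pred_all)
    rich_ord <- rich$richness[match(paste(cov_ord$slope, cov_ord$elevation),
                                    paste(rich$slope, rich$elevation))]
    mains <- c("slope", "MDE", screen$retained)
    inter <- paste0("slope:", setdiff(mains, "slope"))
    selection <- NULL
    if (stats::sd(rich_ord) > 0) {
      cms <- suppressWarnings(
        candidate_model_set(rich_ord, design, mains, inter))
      best <- select_best(cms)
      avg <- model_average(cms, cum_weight = cum_weight)
      best_terms <- setdiff(best$terms, "(Intercept)")
      vifs <- if (length(setdiff(best_terms, "slope")) +
                  ("slope" %in% best_terms) >= 2) {
        cols <- design[, c(intersect(best_terms, names(design))), drop = FALSE]
        if (ncol(cols) >= 2) vif(cols) else NULL
      } else NULL
      sw <- build_spatial_weights(cov_ord, scheme = "chain")
      moran <- morans_i(best$residuals, sw)
      selection <- list(candidates = cms, best = best, averaged = avg,
                        vif = vifs, moran = moran)
    }
    results[[g]] <- list(richness = rich, richness_observed = rich_obs,
                         per_slope = per_slope, selection = selection)
  }

  meta <- list(
    seed = seed, n_sims = n_sims, bands = bands, groups = groups,
    package_version = as.character(utils::packageVersion("elevdiv")),
    config_hash = config_hash(list(bands = bands, groups = groups,
                                   n_sims = n_sims, seed = seed,
                                   screen_threshold = screen_threshold,
                                   cum_weight = cum_weight))
  )
  report <- structure(list(groups = results, screen = screen, meta = meta),
                      class = "gradient_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

## Emit the report bundle as CSV/JSON artifacts plus a run log.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- report$meta
  for (g in names(report$groups)) {
    res <- report$groups[[g]]
    utils::write.csv(res$richness, file.path(out_dir,
                                             paste0("richness_", g, ".csv")),
                     row.names = FALSE)
    for (sl in names(res$per_slope)) {
      mde <- res$per_slope[[sl]]$mde
      if (is.null(mde)) next
      utils::write.csv(
        data.frame(band = seq_len(mde$m), mean = mde$mean_richness,
                   ci_low = mde$ci_low, ci_high = mde$ci_high,
                   analytic = mde$analytic_expectation),
        file.path(out_dir, paste0("mde_", g, "_", sl, ".csv")),
        row.names = FALSE)
    }
    if (!is.null(res$selection)) {
      utils::write.csv(res$selection$candidates$table,
                       file.path(out_dir, paste0("models_", g, ".csv")),
                       row.names = FALSE)
      best <- res$selection$best
      jsonlite::write_json(
        list(terms = best$terms,
             coefficients = as.list(best$coefficients),
             r_squared = best$r_squared, aicc = best$aicc,
             moran_i = res$selection$moran$I,
             moran_p = res$selection$moran$p,
             seed = meta$seed, config_hash = meta$config_hash),
        file.path(out_dir, paste0("best_model_", g, ".json")),
        auto_unbox = TRUE, digits = NA)
      utils::write.csv(
        data.frame(term = names(res$selection$averaged$importance),
                   importance = unname(res$selection$averaged$importance)),
        file.path(out_dir, paste0("importance_", g, ".csv")),
        row.names = FALSE)
    }
  }
  writeLines(c(
    paste("elevdiv", meta$package_version),
    paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste("seed:", meta$seed),
    paste("config_hash:", meta$config_hash),
    paste("n_sims:", meta$n_sims),
    paste("groups:", paste(meta$groups, collapse = ", "))
  ), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Read a run configuration file
#'
#' YAML or JSON, holding any subset of [run_pipeline()]'s arguments plus
#' either input paths (`captures`, `traits`, `covariates`) or a
#' `simulate` block of [gradient_sim_config()] overrides.
#'
#' @param path configuration file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
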