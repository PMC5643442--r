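## Elevational ranges, interpolated richness, and species grouping.

#' Build elevational ranges from capture records
#'
#' Collapses capture (or sighting) records into one elevational range per
#' species x slope. A band counts as occupied when it has at least one
#' record with `count > 0`. The interpolated range fills every band between
#' a species' lowest and highest detections, on the assumption that a
#' species detected both above and below a band is present in it.
#'
#' @param captures data frame with columns `species`, `slope`, `elevation`,
#'   and `count` (a `season` column is allowed and ignored here).
#' @param bands numeric vector of the design band elevations (m), sorted.
#' @return a data frame of class `elev_ranges`, one row per species x slope
#'   with presence: `species`, `slope`, `min_band`, `max_band` (band
#'   indices), `range_size` (interpolated band count), `range_extent`
#'   (meters, `range_size * band_step`), and list-columns
#'   `observed_bands` / `interpolated_bands` (band indices). The band
#'   elevations are kept in `attr(, "bands")`.
#' @examples
#' caps <- data.frame(species = "a", slope = "west",
#'                    elevation = c(2000, 2600), count = 1)
#' build_ranges(caps, bands = seq(1800, 2800, by = 200))
#' @export
build_ranges <- function(captures, bands) {
  stopifnot(is.data.frame(captures), is.numeric(bands), length(bands) >= 1)
  req <- c("species", "slope", "elevation", "count")
  missing_cols <- setdiff(req, names(captures))
  if (length(missing_cols)) {
    stop("captures lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bands <- sort(bands)
  bad <- which(!(captures$elevation %in% bands))
  if (length(bad)) {
    stop("capture row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         " at elevation(s) not in the band design (e.g. ",
         captures$elevation[bad[1L]], " m)", call. = FALSE)
  }
  present <- captures[captures$count > 0, , drop = FALSE]
  if (nrow(present) == 0L) {
    out <- data.frame(species = character(), slope = character(),
                      min_band = integer(), max_band = integer(),
                      range_size = integer(), range_extent = numeric())
    out$observed_bands <- list()
    out$interpolated_bands <- list()
    return(structure(out, bands = bands, class = c("elev_ranges", "data.frame")))
  }
  key <- interaction(present$species, present$slope, drop = TRUE, sep = "\r")
  pieces <- split(present, key)
  rows <- lapply(pieces, function(d) {
    obs <- sort(unique(match(d$elevation, bands)))
    interp <- seq.int(min(obs), max(obs))
    df <- data.frame(species = d$species[1L], slope = d$slope[1L],
                     min_band = min(obs), max_band = max(obs),
                     range_size = length(interp),
                     stringsAsFactors = FALSE)
    df$observed_bands <- list(obs)
    df$interpolated_bands <- list(interp)
    df
  })
  out <- do.call(rbind, rows)
  step <- if (length(bands) > 1L) stats::median(diff(bands)) else NA_real_
  out$range_extent <- out$range_size * step
  out <- out[order(out$slope, out$species),
             c("species", "slope", "min_band", "max_band", "range_size",
               "range_extent", "observed_bands", "interpolated_bands")]
  rownames(out) <- NULL
  structure(out, bands = bands, class = c("elev_ranges", "data.frame"))
}

#' Interpolate presence across range gaps
#'
#' Replaces each species' occupied-band set by the full interval between
#' its lowest and highest occupied bands. Idempotent; ranges already
#' contiguous are unchanged.
#'
#' @param ranges an `elev_ranges` object from [build_ranges()].
#' @return the same object with `observed_bands` replaced by the
#'   interpolated interval (and `min_band`/`max_band`/`range_size`
#'   recomputed, which leaves them unchanged).
#' @export
interpolate_presence <- function(ranges) {
  stopifnot(inherits(ranges, "elev_ranges"))
  ranges$observed_bands <- lapply(seq_len(nrow(ranges)), function(i) {
    obs <- ranges$observed_bands[[i]]
    seq.int(min(obs), max(obs))
  })
  ranges$interpolated_bands <- ranges$observed_bands
  ranges$min_band <- vapply(ranges$observed_bands, min, integer(1))
  ranges$max_band <- vapply(ranges$observed_bands, max, integer(1))
  ranges$range_size <- vapply(ranges$observed_bands, length, integer(1))
  ranges
}

#' Split species into large- and small-ranged classes
#'
#' A species is large-ranged when its interpolated range size (in bands)
#' exceeds the median range size of the reference pool; ties at the median
#' are classed small. By default the median is computed per slope over that
#' slope's species; `pooled = TRUE` uses one median over all ranges.
#'
#' @param ranges an `elev_ranges` object.
#' @param pooled use a single pooled median instead of per-slope medians.
#' @return `ranges` with an added character column `size_class`
#'   (`"large"`/`"small"`).
#' @export
classify_range_size <- function(ranges, pooled = FALSE) {
  stopifnot(inherits(ranges, "elev_ranges"), nrow(ranges) >= 1L)
  if (pooled) {
    med <- stats::median(ranges$range_size)
    ranges$size_class <- ifelse(ranges$range_size > med, "large", "small")
  } else {
    ranges$size_class <- NA_character_
    for (sl in unique(ranges$slope)) {
      i <- ranges$slope == sl
      med <- stats::median(ranges$range_size[i])
      ranges$size_class[i] <- ifelse(ranges$range_size[i] > med, "large", "small")
    }
  }
  ranges
}

.group_labels <- c("total", "insectivores", "rodents", "large_ranged",
                   "small_ranged", "endemic", "non_endemic")

## Subset an elev_ranges object to one species group.
filter_group <- function(ranges, traits, group, pooled_median = FALSE) {
  group <- match.arg(group, .group_labels)
  if (group %in% c("large_ranged", "small_ranged") &&
      is.null(ranges$size_class)) {
    ranges <- classify_range_size(ranges, pooled = pooled_median)
  }
  if (group %in% c("insectivores", "rodents", "endemic", "non_endemic")) {
    missing_sp <- setdiff(ranges$species, traits$species)
    if (length(missing_sp)) {
      stop("species missing from traits: ",
           paste(utils::head(missing_sp, 5L), collapse = ", "), call. = FALSE)
    }
    tg <- traits$taxon_group[match(ranges$species, traits$species)]
    en <- traits$endemic[match(ranges$species, traits$species)]
  }
  keep <- switch(group,
    total        = rep(TRUE, nrow(ranges)),
    insectivores = tg == "insectivore",
    rodents      = tg == "rodent",
    large_ranged = ranges$size_class == "large",
    small_ranged = ranges$size_class == "small",
    endemic      = en,
    non_endemic  = !en
  )
  ranges[keep, , drop = FALSE]
}

#' Per-band species richness of a group
#'
#' Counts, at every band of every slope, the species of a group whose
#' range covers the band, using either the raw occupied-band sets
#' (`mode = "observed"`) or the gap-filled intervals
#' (`mode = "interpolated"`).
#'
#' @param ranges an `elev_ranges` object.
#' @param traits data frame with `species`, `taxon_group`
#'   (`"insectivore"`/`"rodent"`), `endemic` (logical); required for
#'   taxonomic and endemism groups.
#' @param group one of `"total"`, `"insectivores"`, `"rodents"`,
#'   `"large_ranged"`, `"small_ranged"`, `"endemic"`, `"non_endemic"`.
#' @param mode `"interpolated"` (default) or `"observed"`.
#' @param pooled_median passed to [classify_range_size()] for the
#'   range-size groups.
#' @return a data frame of class `richness_profile`: `slope`, `band`
#'   (index), `elevation`, `richness`, with the group and mode in
#'   attributes.
#' @export
group_richness <- function(ranges, traits = NULL,
                           group = "total",
                           mode = c("interpolated", "observed"),
                           pooled_median = FALSE) {
  stopifnot(inherits(ranges, "elev_ranges"))
  mode <- match.arg(mode)
  bands <- attr(ranges, "bands")
  sub <- filter_group(ranges, traits, group, pooled_median)
  col <- if (mode == "interpolated") "interpolated_bands" else "observed_bands"
  slopes <- unique(ranges$slope)
  out <- do.call(rbind, lapply(slopes, function(sl) {
    rr <- sub[sub$slope == sl, , drop = FALSE]
    rich <- vapply(seq_along(bands), function(b) {
      sum(vapply(rr[[col]], function(set) b %in% set, logical(1)))
    }, integer(1))
    data.frame(slope = sl, band = seq_along(bands), elevation = bands,
               richness = rich, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, group = group, mode = mode,
            class = c("richness_profile", "data.frame"))
}

#' Sorensen similarity between two assemblages
#'
#' `100 * 2 * shared / (s1 + s2)`, the classic presence-based similarity
#' of two species lists, expressed as a percentage.
#'
#' @param s1,s2 species counts of the two assemblages.
#' @param shared number of species occurring in both.
#' @return similarity in percent, in \[0, 100\].
#' @examples
#' sorensen_index(27, 33, 23)  # 76.7
#' @export
sorensen_index <- function(s1, s2, shared) {
  stopifnot(s1 >= 0, s2 >= 0, shared >= 0)
  if (s1 + s2 <= 0) stop("both assemblages are empty", call. = FALSE)
  if (shared > min(s1, s2)) {
    stop("`shared` cannot exceed the smaller assemblage", call. = FALSE)
  }
  100 * 2 * shared / (s1 + s2)
}

#' Overall trapping success
#'
#' Captures per 100 trap-nights.
#'
#' @param total_captures number of individuals captured.
#' @param total_trap_nights total effort in trap-nights (> 0).
#' @return percent trap success.
#' @examples
#' trap_success(2006, 25470)  # 7.88
#' @export
trap_success <- function(total_captures, total_trap_nights) {
  stopifnot(total_captures >= 0)
  if (total_trap_nights <= 0) stop("trap-nights must be > 0", call. = FALSE)
  100 * total_captures / total_trap_nights
}

#' Normalized difference vegetation index
#'
#' `(nir - red) / (nir + red)` elementwise. Pixels with a zero denominator
#' are returned as `NA` with a warning rather than an error, matching how
#' masked or water pixels are usually handled.
#'
#' @param nir,red near-infrared and red surface reflectances (scalars or
#'   equal-length vectors).
#' @return NDVI values in \[-1, 1\].
#' @export
compute_ndvi <- function(nir, red) {
  stopifnot(is.numeric(nir), is.numeric(red))
  denom <- nir + red
  out <- (nir - red) / denom
  zero <- !is.na(denom) & denom == 0
  if (any(zero)) {
    warning(sum(zero), " element(s) with nir + red == 0 set to NA")
    out[zero] <- NA_real_
  }
  out
}

#' Pearson correlation between richness and abundance
#'
#' Standard product-moment correlation with the two-sided t-test p-value,
#' used to ask whether band richness tracks the number of individuals.
#'
#' @param richness,abundance equal-length numeric vectors (n >= 3), each
#'   with non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
richness_abundance_correlation <- function(richness, abundance) {
  stopifnot(length(richness) == length(abundance), length(richness) >= 3)
  if (stats::sd(richness) == 0 || stats::sd(abundance) == 0) {
    stop("correlation undefined: an input is constant", call. = FALSE)
  }
  ct <- stats::cor.test(richness, abundance, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(richness))
}
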