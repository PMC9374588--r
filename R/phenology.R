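#' Seasonality: median capture day of year
#'
#' @param dates numeric day-of-year values (one per captured individual).
#' @return the sample median (mean of the middle two for even n).
#' @export
seasonality_raw <- function(dates) {
  dates <- dates[is.finite(dates)]
  if (!length(dates)) stop("no dates")
  median(dates)
}

#' Phenological breadth: 10th-90th percentile span of capture dates
#'
#' Quantiles use linear interpolation between order statistics (R's type 7,
#' the default convention); the choice shifts breadth by a few days across
#' conventions, so it is configurable and recorded by the pipeline.
#'
#' @param dates numeric day-of-year values.
#' @param type quantile type passed to [stats::quantile()] (default 7).
#' @return `q90 - q10` in days (>= 0).
#' @export
breadth_raw <- function(dates, type = 7) {
  dates <- dates[is.finite(dates)]
  if (!length(dates)) stop("no dates")
  q <- quantile(dates, c(0.1, 0.9), type = type, names = FALSE)
  q[2] - q[1]
}

#' Sample-size-corrected phenology by repeated subsampling
#'
#' To compare species with very different catch sizes, draws `n_sub`
#' capture dates without replacement, computes seasonality and breadth on
#' the draw, repeats `n_reps` times, and averages — so every species'
#' statistics are effectively computed at the same sample size.
#'
#' @param dates numeric day-of-year values; must have at least `n_sub`.
#' @param n_sub draw size (default 30, the focal-species threshold).
#' @param n_reps number of draws averaged (default 500).
#' @param seed optional seed.
#' @param type quantile convention for breadth.
#' @return list of class `phenology_stats`: `n_individuals`, `seasonality`,
#'   `breadth`, `n_sub`, `n_reps`.
#' @export
subsampled_phenology <- function(dates, n_sub = 30, n_reps = 500,
                                 seed = NULL, type = 7) {
  dates <- dates[is.finite(dates)]
  n <- length(dates)
  if (n < n_sub) {
    stop("species excluded: ", n, " individuals < n_sub = ", n_sub)
  }
  stats <- with_seed(seed, {
    res <- matrix(0, n_reps, 2)
    for (r in seq_len(n_reps)) {
      draw <- dates[sample.int(n, n_sub)]
      res[r, ] <- c(median(draw),
                    diff(quantile(draw, c(0.1, 0.9), type = type,
                                  names = FALSE)))
    }
    colMeans(res)
  })
  structure(list(n_individuals = n, seasonality = stats[1],
                 breadth = stats[2], n_sub = n_sub, n_reps = n_reps),
            class = "phenology_stats")
}

#' Per-species phenology table for focal species
#'
#' Applies [subsampled_phenology()] to every species with at least `min_n`
#' individuals; species below the threshold are listed with `NA` statistics
#' and a reason code.
#'
#' @param specimens a `specimen_table`.
#' @param min_n minimum individuals for subsampled statistics (default 30).
#' @param n_sub,n_reps subsampling settings.
#' @param seed optional seed (one stream across species, applied in
#'   alphabetical species order for reproducibility).
#' @param type quantile convention.
#' @return data frame: `species`, `n_individuals`, `seasonality`,
#'   `breadth`, `included`, `reason`.
#' @export
phenology_table <- function(specimens, min_n = 30, n_sub = 30, n_reps = 500,
                            seed = NULL, type = 7) {
  stopifnot(inherits(specimens, "specimen_table"))
  by_sp <- split(specimens$day_of_year, specimens$species)
  by_sp <- by_sp[order(names(by_sp))]
  with_seed(seed, {
    rows <- lapply(names(by_sp), function(sp) {
      d <- by_sp[[sp]]
      if (length(d) < min_n) {
        return(data.frame(species = sp, n_individuals = length(d),
                          seasonality = NA_real_, breadth = NA_real_,
                          included = FALSE, reason = "below_min_n",
                          stringsAsFactors = FALSE))
      }
      ph <- subsampled_phenology(d, n_sub = n_sub, n_reps = n_reps,
                                 seed = NULL, type = type)
      data.frame(species = sp, n_individuals = ph$n_individuals,
                 seasonality = ph$seasonality, breadth = ph$breadth,
                 included = TRUE, reason = "", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Monthly capture-percentage matrix
#'
#' For each species, the percentage of its individuals captured in each
#' month (rows sum to 100) — the numeric backbone of a phenology heatmap.
#'
#' @param specimens a `specimen_table`.
#' @param species optional subset/order of species (default: all, sorted).
#' @return species x month matrix of percentages.
#' @export
month_capture_matrix <- function(specimens, species = NULL) {
  stopifnot(inherits(specimens, "specimen_table"))
  months <- attr(specimens, "season_months")
  species <- species %||% sort(unique(specimens$species))
  tab <- table(factor(specimens$species, levels = species),
               factor(specimens$month, levels = months))
  m <- unclass(tab)
  100 * m / rowSums(m)
}
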