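#' Nonlinear trend fit on a cubic regression-spline basis with 5 knots
#'
#' Least-squares fit of `y` on a natural cubic spline in `x` with `k` knots
#' placed at quantiles of the distinct `x` values (2 boundary + `k - 2`
#' interior). Unpenalized, so the fit is deterministic; with the small
#' numbers of distinct periods in monitoring data (6 years, 7 months) a
#' 5-knot curve closely tracks the per-period means. If fewer than `k`
#' distinct `x` values are available the basis is reduced (flagged), down
#' to a straight line for 2 distinct values.
#'
#' @param x period values (e.g. month or year), numeric.
#' @param y replicate metric values.
#' @param k number of knots (default 5).
#' @return list of class `trend_fit`: `coefficients`, `fitted`,
#'   `adjusted_r2`, `p_value` (overall F test), `f_statistic`, `k_used`,
#'   `reduced`, `model` (the `lm` object).
#' @export
fit_spline_trend <- function(x, y, k = 5) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("need at least 2 distinct x values")
  k_used <- min(k, length(ux))
  reduced <- k_used < k
  if (k_used >= 3) {
    qs <- quantile(ux, probs = seq(0, 1, length.out = k_used), type = 7)
    basis <- splines::ns(x, knots = qs[-c(1, k_used)],
                         Boundary.knots = qs[c(1, k_used)])
  } else {
    basis <- matrix(x, dimnames = list(NULL, "linear"))
  }
  p <- ncol(basis)
  if (length(y) <= p + 1) stop("too few observations for the spline basis")
  fit <- lm(y ~ basis)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(coefficients = coef(fit), fitted = unname(fit$fitted.values),
                 adjusted_r2 = sm$adj.r.squared,
                 p_value = unname(pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE)),
                 f_statistic = unname(fstat[1]),
                 k_used = k_used, reduced = reduced, model = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("spline trend (%d knots%s): F = %.2f, p = %.3g, adj R2 = %.3f\n",
              x$k_used, if (x$reduced) ", reduced" else "", x$f_statistic,
              x$p_value, x$adjusted_r2))
  invisible(x)
}

# trend class from sign and p, thresholds .1 / .05 (".01" flagged as strong)
classify_trend_ <- function(slope, p) {
  if (!is.finite(p) || p > 0.1) return("stable")
  dir <- if (slope < 0) "decline" else "increase"
  if (p > 0.05) paste("weak", dir) else dir
}

#' Standardized per-species abundance trend
#'
#' Yearly abundances are standardized to mean 0 and sample standard
#' deviation 1, regressed on calendar year by OLS, and the slope multiplied
#' by 5 (the span of a 6-year study) to give the predicted change over the
#' study in standard-deviation units. Species with no year-to-year
#' variation get slope 0, a missing p-value and class "stable" (flagged).
#'
#' @param counts_by_year per-year total captures of one species.
#' @param years matching calendar years (>= 3).
#' @param species optional species label carried into the result.
#' @return one-row data frame: `species`, `slope_sd_per_year`,
#'   `change_5yr`, `p_value`, `class` (stable / weak decline / weak
#'   increase / decline / increase), `strong` (p <= .01), `zero_variance`,
#'   `total_abundance`, `yearly_cv`.
#' @export
species_trend <- function(counts_by_year, years, species = NA_character_) {
  ok <- is.finite(counts_by_year) & is.finite(years)
  y <- counts_by_year[ok]; yr <- years[ok]
  if (length(y) < 3) stop("need at least 3 years of data")
  s <- sd(y)
  if (s == 0) {
    return(data.frame(species = species, slope_sd_per_year = 0,
                      change_5yr = 0, p_value = NA_real_, class = "stable",
                      strong = FALSE, zero_variance = TRUE,
                      total_abundance = sum(y), yearly_cv = yearly_cv(y),
                      stringsAsFactors = FALSE))
  }
  z <- (y - mean(y)) / s
  fit <- lm(z ~ yr)
  slope <- unname(coef(fit)[2])
  p <- summary(fit)$coefficients[2, 4]
  data.frame(species = species, slope_sd_per_year = slope,
             change_5yr = 5 * slope, p_value = p,
             class = classify_trend_(slope, p),
             strong = is.finite(p) && p <= 0.01, zero_variance = FALSE,
             total_abundance = sum(y), yearly_cv = yearly_cv(y),
             stringsAsFactors = FALSE)
}

#' Per-species trend table for all (focal) species
#'
#' Yearly abundance is the species' total captures summed over all sites and
#' traps per year; years without captures count as zero. Species with fewer
#' than `min_total` individuals overall are excluded (the focal-species
#' filter; 30 in the motivating design).
#'
#' @param specimens a `specimen_table`.
#' @param years years spanning the study (default: observed range).
#' @param min_total focal-species minimum total abundance (default 30).
#' @return data frame with one [species_trend()] row per focal species.
#' @export
species_trend_table <- function(specimens, years = NULL, min_total = 30) {
  stopifnot(inherits(specimens, "specimen_table"))
  dt <- data.table::as.data.table(as.data.frame(specimens))
  years <- years %||% seq(min(dt$year), max(dt$year))
  tab <- dt[, .N, by = .(species, year)]
  totals <- tab[, .(total = sum(N)), by = species]
  focal <- totals$species[totals$total >= min_total]
  rows <- lapply(sort(focal), function(sp) {
    counts <- setNames(rep(0, length(years)), years)
    obs <- tab[tab$species == sp, ]
    counts[as.character(obs$year)] <- obs$N
    species_trend(counts, years, species = sp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize trend classes across species
#'
#' @param trends a trend table from [species_trend_table()].
#' @return data frame: `class`, `n`, `proportion` (over all focal species),
#'   with attribute `evidence` giving the fractions with any evidence of
#'   decline (weak or stronger), any increase, and stable.
#' @export
classify_trends <- function(trends) {
  cls <- factor(trends$class,
                levels = c("stable", "weak decline", "decline",
                           "weak increase", "increase"))
  tab <- as.data.frame(table(class = cls), stringsAsFactors = FALSE)
  names(tab) <- c("class", "n")
  tab$proportion <- tab$n / nrow(trends)
  structure(tab, evidence = c(
    decline = mean(cls %in% c("weak decline", "decline")),
    increase = mean(cls %in% c("weak increase", "increase")),
    stable = mean(cls == "stable")))
}

#' Diagnostics: does abundance (or its variability) predict change?
#'
#' Pearson correlations of species' total abundance, and of their yearly
#' CV, against the predicted 5-year change, each with a two-sided t-test —
#' the power diagnostics reported alongside species trends. Returns `NA`
#' when either variable has no variation.
#'
#' @param trends a trend table from [species_trend_table()].
#' @return data frame: `predictor`, `r`, `p_value`, `n`.
#' @export
abundance_change_correlation <- function(trends) {
  one <- function(x, label) {
    ok <- is.finite(x) & is.finite(trends$change_5yr)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(trends$change_5yr[ok]) == 0) {
      return(data.frame(predictor = label, r = NA_real_, p_value = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    }
    ct <- cor.test(x[ok], trends$change_5yr[ok])
    data.frame(predictor = label, r = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  }
  rbind(one(trends$total_abundance, "total_abundance"),
        one(trends$yearly_cv, "yearly_cv"))
}

#' Fit spline trends for every metric of a biodiversity summary
#'
#' Mirrors the "effect of month / effect of year on each biodiversity
#' metric" model table: one 5-knot spline fit per metric column.
#'
#' @param summary_df output of [month_summary()] or [year_summary()].
#' @param period_col `"month"` or `"year"`.
#' @param k knots (default 5).
#' @return data frame: `metric`, `f_statistic`, `p_value`, `adjusted_r2`.
#' @export
metric_trend_table <- function(summary_df, period_col, k = 5) {
  metrics <- setdiff(names(summary_df), c("group", period_col))
  rows <- lapply(metrics, function(m) {
    ok <- is.finite(summary_df[[m]])
    fit <- fit_spline_trend(summary_df[[period_col]][ok], summary_df[[m]][ok],
                            k = k)
    data.frame(metric = m, f_statistic = fit$f_statistic,
               p_value = fit$p_value, adjusted_r2 = fit$adjusted_r2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
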