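#' Inverse Simpson's diversity
#'
#' Effective number of equally-abundant species, \eqn{D = 1/\sum p_i^2} with
#' \eqn{p_i = n_i/N}. Bounded between 1 and the observed richness; returns
#' `NA` for an all-zero vector, where the index is undefined.
#'
#' @param counts non-negative abundance vector.
#' @return effective species number, or `NA_real_` if `sum(counts) == 0`.
#' @export
#' @examples
#' inverse_simpson(c(5, 5, 5, 5)) # 4: four equally common species
inverse_simpson <- function(counts) {
  check_counts(counts)
  N <- sum(counts)
  if (N == 0) return(NA_real_)
  p <- counts / N
  1 / sum(p^2)
}

#' Community evenness
#'
#' Default is Simpson evenness \eqn{D/S} (inverse Simpson divided by
#' richness), consistent with the pipeline's diversity metric; equals 1 iff
#' all species present are equally abundant. Pielou's
#' \eqn{J = H'/\ln S} is available as an alternative.
#'
#' @param counts non-negative abundance vector.
#' @param method `"simpson"` (default) or `"pielou"`.
#' @return evenness in (0, 1]; `NA` for an all-zero vector.
#' @export
evenness <- function(counts, method = c("simpson", "pielou")) {
  method <- match.arg(method)
  check_counts(counts)
  N <- sum(counts)
  if (N == 0) return(NA_real_)
  S <- sum(counts > 0)
  if (method == "simpson") return(inverse_simpson(counts) / S)
  if (S == 1) return(1)                 # single species: maximally even
  p <- counts[counts > 0] / N
  -sum(p * log(p)) / log(S)
}

#' Analytic (individual-based) rarefied richness
#'
#' Hypergeometric expectation of the number of species in a random
#' subsample of `n` individuals drawn without replacement:
#' \deqn{E[S_n] = \sum_i \left[1 - \binom{N - n_i}{n} / \binom{N}{n}\right]}
#' computed on the log scale for numerical stability.
#'
#' @param counts non-negative integer abundances.
#' @param n subsample size, `1 <= n <= sum(counts)`.
#' @return expected species count.
#' @export
rarefied_richness <- function(counts, n) {
  check_counts(counts)
  N <- sum(counts)
  if (length(n) != 1 || n < 1 || n > N) {
    stop("`n` must be a single value in [1, sum(counts)]")
  }
  ni <- counts[counts > 0]
  # log C(N-ni, n) - log C(N, n); impossible draws (N-ni < n) contribute 1
  term <- ifelse(N - ni < n, 0, exp(lchoose(N - ni, n) - lchoose(N, n)))
  sum(1 - term)
}

#' Species accumulation curve over individuals
#'
#' Mean cumulative number of distinct species against the number of
#' individuals sampled, averaged over `n_perm` random orderings of the
#' individuals. Pointwise in expectation this equals
#' [rarefied_richness()] at the same subsample size.
#'
#' @param specimens a `specimen_table`, or a character vector of per
#'   individual species labels.
#' @param n_perm number of random orderings to average (default 100).
#' @param at optional integer vector of sample sizes to report (default:
#'   every individual).
#' @param seed optional seed for reproducibility.
#' @return data frame with `individuals` and `species` (mean cumulative
#'   richness).
#' @export
accumulation_curve <- function(specimens, n_perm = 100, at = NULL,
                               seed = NULL) {
  labels <- if (inherits(specimens, "specimen_table")) specimens$species
            else as.character(specimens)
  N <- length(labels)
  stopifnot(N >= 1, n_perm >= 1)
  at <- if (is.null(at)) seq_len(N) else sort(unique(as.integer(at)))
  stopifnot(all(at >= 1), all(at <= N))
  f <- factor(labels)
  acc <- with_seed(seed, {
    total <- numeric(length(at))
    for (p in seq_len(n_perm)) {
      perm <- f[sample.int(N)]
      cum <- cumsum(!duplicated(perm))
      total <- total + cum[at]
    }
    total / n_perm
  })
  data.frame(individuals = at, species = acc)
}

#' Rarefied richness per month, pooling all sites and years
#'
#' For the "species per n individuals" month contrast, counts are pooled
#' across all sites, traps and years within each month before analytic
#' rarefaction — standardizing richness across months with very different
#' catch sizes. Months with fewer than `n` individuals get `NA`.
#'
#' @param specimens a `specimen_table`.
#' @param n standard subsample size (e.g. 900 individuals).
#' @return data frame: `month`, `individuals`, `richness`,
#'   `rarefied_richness`.
#' @export
month_rarefaction <- function(specimens, n) {
  stopifnot(inherits(specimens, "specimen_table"))
  months <- sort(unique(specimens$month))
  rows <- lapply(months, function(m) {
    counts <- table(specimens$species[specimens$month == m])
    N <- sum(counts)
    data.frame(month = m, individuals = N, richness = sum(counts > 0),
               rarefied_richness = if (N >= n)
                 rarefied_richness(as.numeric(counts), n) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Percent-change effect size between two means
#'
#' Standardized as the difference between a pair of means divided by the
#' overall mean of the variable, times 100 — comparable across variables
#' measured on different scales.
#'
#' @param m_low,m_high the two means being contrasted (sign of the result
#'   is `m_high - m_low`).
#' @param m_overall the variable's overall mean (must be nonzero).
#' @return percent change (signed).
#' @export
#' @examples
#' percent_change(21, 168, 76) # 193.42...: +193% rounded to integer percent
percent_change <- function(m_low, m_high, m_overall) {
  if (!is.finite(m_overall) || m_overall == 0) {
    stop("overall mean must be nonzero")
  }
  100 * (m_high - m_low) / m_overall
}

#' Yearly coefficient of variation
#'
#' `100 * sd/mean` with the sample (n-1) standard deviation; `NA` when the
#' mean is zero (undefined).
#'
#' @param values numeric vector (e.g. one total per year).
#' @return CV in percent, or `NA_real_`.
#' @export
yearly_cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * sd(values) / m
}

# metric battery applied to one count row
unit_metrics_ <- function(counts) {
  c(abundance = sum(counts),
    richness = sum(counts > 0),
    diversity = inverse_simpson(counts),
    evenness = evenness(counts))
}

# internal two-step averaging shared by month_summary / year_summary.
# ses: optional per-unit vector (same order as cm$units) folded through the
# same averaging as the other metrics.
summarise_cm_ <- function(cm, period_col, average_years, ses = NULL) {
  stopifnot(inherits(cm, "community_matrix"))
  if (is.null(cm$units$group)) {
    stop("community matrix has no site grouping; use attach_grouping()")
  }
  vals <- t(apply(cm$counts, 1, unit_metrics_))
  long <- data.table::data.table(cm$units, vals)
  if (!is.null(ses)) {
    stopifnot(length(ses) == nrow(cm$units))
    long$ses_mpd <- ses
  }
  metrics <- intersect(c("abundance", "richness", "diversity", "evenness",
                         "ses_mpd"), names(long))
  if (average_years) {
    # metric per (site, period, year) -> mean over years (NA metrics from
    # zero units excluded) -> mean over sites within group
    step1 <- long[, lapply(.SD, function(v) mean(v, na.rm = TRUE)),
                  by = c("site_id", "group", period_col), .SDcols = metrics]
  } else {
    step1 <- long
  }
  out <- data.table::as.data.table(step1)[
    , lapply(.SD, function(v) mean(v, na.rm = TRUE)),
    by = c("group", period_col), .SDcols = metrics]
  out <- as.data.frame(out)
  for (m in metrics) out[[m]][is.nan(out[[m]])] <- NA_real_
  out[order(out$group, out[[period_col]]), , drop = FALSE]
}

#' Month-scheme biodiversity summary (4 replicates per month)
#'
#' Computes each metric per (site, month, year), averages across years, then
#' averages sites within each site group — so each row is "the average
#' biodiversity value per site for a single month". Diversity and evenness
#' are undefined on zero-capture months and are excluded from the
#' year-averaging step; abundance and richness enter as 0.
#'
#' @param cm a month-scheme `community_matrix` with a grouping attached.
#' @param ses_mpd optional per-unit SES-MPD vector (one per row of
#'   `cm$units`, e.g. from [ses_mpd_units()]), averaged alongside.
#' @return data frame: `group`, `month`, `abundance`, `richness`,
#'   `diversity`, `evenness` (and `ses_mpd` if supplied).
#' @export
month_summary <- function(cm, ses_mpd = NULL) {
  if (!identical(attr(cm, "scheme"), "month")) {
    stop("expected a month-scheme community matrix")
  }
  summarise_cm_(cm, "month", average_years = TRUE, ses = ses_mpd)
}

#' Year-scheme biodiversity summary (4 replicates per year)
#'
#' Metrics are computed per (site, year) on counts already summed across
#' months, then averaged over sites within each group — "the total
#' biodiversity value per site for a single year".
#'
#' @param cm a year-scheme `community_matrix` with a grouping attached.
#' @param ses_mpd optional per-unit SES-MPD vector, averaged alongside.
#' @return data frame: `group`, `year`, metrics as in [month_summary()].
#' @export
year_summary <- function(cm, ses_mpd = NULL) {
  if (!identical(attr(cm, "scheme"), "year")) {
    stop("expected a year-scheme community matrix")
  }
  summarise_cm_(cm, "year", average_years = FALSE, ses = ses_mpd)
}
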