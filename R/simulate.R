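#' Configuration for the synthetic monitoring-data simulator
#'
#' Defaults describe the motivating study design: 144 species in 30 genera
#' and 5 families, 8 sites in 4 groups with 2 traps each, weekly collections
#' April-October (days 91-304) for 2014-2019, a steep lognormal
#' rank-abundance law rescaled to an expected 26,716 individuals, per-species
#' Gaussian activity windows, and (optionally) per-species log-linear year
#' trends.
#'
#' @param n_species,n_genera,n_families community dimensions.
#' @param n_sites,n_groups,traps_per_site sampling design.
#' @param years integer vector of sampling years.
#' @param season_days length-2 day-of-year interval trapped each year.
#' @param abundance list: `meanlog`, `sdlog` of the lognormal from which
#'   relative per-species totals are drawn.
#' @param total_individuals expected grand total of captures; relative
#'   abundances are rescaled to this.
#' @param peak_range uniform range (day of year) for species peak activity
#'   \eqn{\mu_s}.
#' @param spread_range uniform range (days) for activity spread
#'   \eqn{\sigma_s}.
#' @param site_sd standard deviation (log scale) of multiplicative site
#'   effects.
#' @param trend list: `b_mean`, `b_sd` for per-species log-linear year
#'   multipliers \eqn{b_s}; `decline_frac` of species are overridden to
#'   `decline_b`.
#' @param trait_effect list: `trait` (name of a simulated trait or `NULL`)
#'   and `beta`, a linear effect of the centered trait added to \eqn{b_s}
#'   before specimens are drawn (default 0: traits carry no signal).
#' @param genus_skew gamma shape controlling how unevenly species spread
#'   over genera (smaller = more skewed; some genera speciose).
#' @param seed master seed; all stages draw from named substreams of it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 144, n_genera = 30, n_families = 5,
                       n_sites = 8, n_groups = 4, traps_per_site = 2,
                       years = 2014:2019, season_days = c(91, 304),
                       abundance = list(meanlog = 2.1, sdlog = 2.5),
                       total_individuals = 26716,
                       peak_range = c(115, 280), spread_range = c(8, 35),
                       site_sd = 0.3,
                       trend = list(b_mean = 0, b_sd = 0,
                                    decline_frac = 0, decline_b = -0.25),
                       trait_effect = list(trait = NULL, beta = 0),
                       genus_skew = 0.6,
                       seed = 1) {
  cfg <- list(n_species = n_species, n_genera = n_genera,
              n_families = n_families, n_sites = n_sites, n_groups = n_groups,
              traps_per_site = traps_per_site, years = as.integer(years),
              season_days = as.integer(season_days), abundance = abundance,
              total_individuals = total_individuals, peak_range = peak_range,
              spread_range = spread_range, site_sd = site_sd, trend = trend,
              trait_effect = trait_effect, genus_skew = genus_skew,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_species >= 1, n_genera >= 2, n_families >= 1,
              n_sites >= 1, n_groups >= 1, traps_per_site >= 1,
              length(years) >= 1, length(season_days) == 2,
              season_days[1] >= 1, season_days[2] <= 366,
              season_days[1] < season_days[2],
              total_individuals > 0, site_sd >= 0,
              spread_range[1] > 0)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a genus-level ultrametric phylogeny
#'
#' Pure-birth tree over the configured genera (all tip depths equal by
#' construction); genus tips are labelled `Genus01`, ... and families are
#' assigned by cutting the cophenetic distance dendrogram into
#' `n_families` clades, so families are (approximately) monophyletic.
#'
#' @param config a [sim_config()].
#' @param seed seed (default: the `"tree"` substream of the master seed).
#' @return list: `tree` (ape phylo), `genus_family` (named character vector
#'   genus -> family).
#' @export
simulate_tree <- function(config, seed = substream_seed(config$seed, "tree")) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    tree <- ape::rphylo(config$n_genera, birth = 1, death = 0)
    tree$tip.label <- sprintf("Genus%02d", seq_len(config$n_genera))
    k_fam <- min(config$n_families, config$n_genera)
    fam <- if (k_fam == 1) {
      rep(1L, config$n_genera)
    } else {
      d <- as.dist(ape::cophenetic.phylo(tree))
      stats::cutree(stats::hclust(d, method = "average"), k = k_fam)
    }
    list(tree = tree,
         genus_family = setNames(sprintf("Family%d", fam), tree$tip.label))
  })
}

# internal: draw the per-species ground-truth parameters (genus/family
# membership, expected totals, activity window, year trend).
simulate_species_params <- function(config, genus_family,
                                    seed = substream_seed(config$seed, "params")) {
  with_seed(seed, {
    n <- config$n_species
    genera <- names(genus_family)
    gw <- rgamma(length(genera), shape = config$genus_skew)
    genus <- sample(genera, n, replace = TRUE, prob = gw / sum(gw))
    idx <- stats::ave(seq_len(n), genus, FUN = seq_along)
    species <- sprintf("%s sp%02d", genus, idx)

    rel <- rlnorm(n, config$abundance$meanlog, config$abundance$sdlog)
    lambda_total <- rel * config$total_individuals / sum(rel)

    b <- rnorm(n, config$trend$b_mean, config$trend$b_sd)
    n_decl <- round(config$trend$decline_frac * n)
    declining <- rep(FALSE, n)
    if (n_decl > 0) {
      declining[sample.int(n, n_decl)] <- TRUE
      b[declining] <- config$trend$decline_b
    }
    site_effect <- rlnorm(config$n_sites, -config$site_sd^2 / 2, config$site_sd)
    list(
      species = data.frame(
        species = species, genus = genus,
        family = unname(genus_family[genus]),
        lambda_total = lambda_total,
        mu = runif(n, config$peak_range[1], config$peak_range[2]),
        sigma = runif(n, config$spread_range[1], config$spread_range[2]),
        b = b, declining = declining,
        stringsAsFactors = FALSE),
      site_effect = setNames(site_effect,
                             sprintf("S%d", seq_len(config$n_sites)))
    )
  })
}

#' Simulate species traits (and optionally inject a trait -> trend effect)
#'
#' Binary traits (sociality, diet specialization, below-ground nesting) are
#' Bernoulli(0.5); body length is lognormal around 9 mm. If
#' `config$trait_effect$beta` is nonzero, `beta * (trait - mean(trait))` is
#' added to each species' year-trend coefficient \eqn{b_s} in the returned
#' truth, so specimens simulated afterwards carry the trait signal.
#'
#' @param config a [sim_config()].
#' @param truth a `sim_truth` from [simulate_specimens()]/internal params
#'   (its `$species` table supplies the species list).
#' @param seed seed (default: `"traits"` substream).
#' @return list: `traits` (trait table data frame), `truth` (updated).
#' @export
simulate_traits <- function(config, truth,
                            seed = substream_seed(config$seed, "traits")) {
  stopifnot(inherits(config, "sim_config"))
  sp <- truth$species
  with_seed(seed, {
    n <- nrow(sp)
    traits <- data.frame(
      species = sp$species,
      body_length_mm = rlnorm(n, log(9), 0.35),
      social = rbinom(n, 1, 0.5),
      diet_specialist = rbinom(n, 1, 0.5),
      below_ground_nesting = rbinom(n, 1, 0.5),
      stringsAsFactors = FALSE
    )
    te <- config$trait_effect
    beta <- te$beta %||% 0
    if (!is.null(te$trait) && beta != 0) {
      x <- traits[[te$trait]]
      if (is.null(x)) stop("unknown trait for effect injection: ", te$trait)
      truth$species$b <- truth$species$b + beta * (x - mean(x))
      truth$trait_beta <- setNames(beta, te$trait)
    } else {
      truth$trait_beta <- setNames(0, te$trait %||% "none")
    }
    list(traits = traits, truth = truth)
  })
}

# weekly sampling grid over the configured season: start day, length, midpoint
season_weeks <- function(config) {
  d0 <- config$season_days[1]; d1 <- config$season_days[2]
  start <- seq(d0, d1, by = 7)
  len <- pmin(7, d1 - start + 1)
  data.frame(start = start, len = len, mid = start + (len - 1) / 2)
}

#' Simulate a specimen table from the generative model
#'
#' For each species s, site i, trap, year y and collection week w the catch is
#' \deqn{count \sim Poisson(A_s\, e^{b_s (y - \bar y)}\, site_i\, k_w(s))}
#' where \eqn{A_s} spreads the species' expected total evenly over
#' site-trap-years and \eqn{k_w(s)} is a discretized Gaussian activity
#' window (weekly weights proportional to the normal density at the week
#' midpoint, normalized to sum to 1 within the season). Counts are expanded
#' to one row per individual with a capture date uniform within the week.
#'
#' @param config a [sim_config()].
#' @param truth optional truth list (from a previous stage, e.g. after
#'   [simulate_traits()] injected a trait effect); if `NULL`, species
#'   parameters are drawn from the config's substreams.
#' @param seed seed (default: `"specimens"` substream).
#' @return list: `specimens` (a validated `specimen_table`), `truth`
#'   (`sim_truth`: `$species` parameter table with realized totals,
#'   `$site_effect`, `$expected_total` per species).
#' @export
simulate_specimens <- function(config, truth = NULL,
                               seed = substream_seed(config$seed, "specimens")) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) {
    gf <- simulate_tree(config)$genus_family
    truth <- simulate_species_params(config, gf)
  }
  sp <- truth$species
  wk <- season_weeks(config)
  years <- config$years
  ybar <- mean(years)
  n_sp <- nrow(sp); n_wk <- nrow(wk)

  # weekly kernel, species x week, rows sum to 1
  kern <- outer(seq_len(n_sp), seq_len(n_wk), function(i, w) {
    dnorm(wk$mid[w], sp$mu[i], sp$sigma[i]) * wk$len[w]
  })
  rs <- rowSums(kern)
  if (any(rs <= 0)) stop("degenerate config: a species has zero in-season ",
                         "activity weight")
  kern <- kern / rs

  A <- sp$lambda_total / (config$n_sites * config$traps_per_site * length(years))
  grid <- expand.grid(species_i = seq_len(n_sp), site_i = seq_len(config$n_sites),
                      trap = seq_len(config$traps_per_site),
                      year_i = seq_along(years), week_i = seq_len(n_wk),
                      KEEP.OUT.ATTRS = FALSE)
  lambda <- A[grid$species_i] *
    exp(sp$b[grid$species_i] * (years[grid$year_i] - ybar)) *
    truth$site_effect[grid$site_i] *
    kern[cbind(grid$species_i, grid$week_i)]
  if (sum(lambda) <= 0) stop("degenerate config: zero expected total catch")

  specimens <- with_seed(seed, {
    counts <- rpois(length(lambda), lambda)
    keep <- counts > 0
    g <- grid[keep, , drop = FALSE]
    n_rows <- counts[keep]
    rows <- g[rep(seq_len(nrow(g)), n_rows), , drop = FALSE]
    doy <- wk$start[rows$week_i] +
      floor(runif(nrow(rows)) * wk$len[rows$week_i])
    year <- years[rows$year_i]
    df <- data.frame(
      specimen_id = sprintf("sim%06d", seq_len(nrow(rows))),
      species = sp$species[rows$species_i],
      genus = sp$genus[rows$species_i],
      family = sp$family[rows$species_i],
      site_id = names(truth$site_effect)[rows$site_i],
      trap_id = sprintf("T%d", rows$trap),
      date = as.Date(doy - 1, origin = paste0(year, "-01-01")),
      stringsAsFactors = FALSE
    )
    season_months <- sort(unique(as.integer(format(
      as.Date(config$season_days - 1, origin = "2015-01-01"), "%m"))))
    season_months <- seq(min(season_months), max(season_months))
    as_specimen_table(df, season_months = season_months)
  })
  truth$expected_total <- expected_species_totals(config, truth)
  truth$config <- config
  class(truth) <- "sim_truth"
  list(specimens = specimens, truth = truth)
}

#' Analytic expected per-species totals under the simulator
#'
#' Closed-form expectation of each species' grand total implied by the
#' generative model (sums the Poisson intensity over sites, traps, years and
#' weeks); used by recovery tests to compare simulated means against the
#' model's bookkeeping.
#'
#' @param config a [sim_config()].
#' @param truth truth list carrying `$species` and `$site_effect`.
#' @return named numeric vector of expected totals, one per species.
#' @export
expected_species_totals <- function(config, truth) {
  sp <- truth$species
  years <- config$years
  A <- sp$lambda_total / (config$n_sites * config$traps_per_site * length(years))
  year_sum <- vapply(sp$b, function(b) sum(exp(b * (years - mean(years)))),
                     numeric(1))
  setNames(A * year_sum * sum(truth$site_effect) * config$traps_per_site,
           sp$species)
}

#' Default site -> group mapping for a simulated design
#'
#' Consecutive sites are paired into groups (8 sites -> 4 groups by
#' default), mirroring the "sites closer than 900 m are averaged" rule.
#'
#' @param config a [sim_config()].
#' @return a [site_grouping()].
#' @export
simulate_grouping <- function(config) {
  sites <- sprintf("S%d", seq_len(config$n_sites))
  groups <- sprintf("G%d", ceiling(seq_len(config$n_sites) /
                                     (config$n_sites / config$n_groups)))
  site_grouping(setNames(groups, sites))
}

#' Simulate a complete monitoring dataset with ground truth
#'
#' Orchestrates tree, species parameters, traits (with optional trait ->
#' trend effect) and specimen simulation, each from a named substream of the
#' master seed.
#'
#' @param config a [sim_config()].
#' @return list: `specimens`, `tree`, `genus_family`, `traits`, `truth`,
#'   `grouping`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tr <- simulate_tree(config)
  truth <- simulate_species_params(config, tr$genus_family)
  tt <- simulate_traits(config, truth)
  sim <- simulate_specimens(config, tt$truth)
  list(specimens = sim$specimens, tree = tr$tree,
       genus_family = tr$genus_family, traits = tt$traits,
       truth = sim$truth, grouping = simulate_grouping(config))
}
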