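#' Configuration for a full pipeline run
#'
#' Collects paths (or simulation settings), the study constants (season
#' months, site grouping, focal threshold, p-value class cutoffs) and all
#' Monte-Carlo settings. One master seed fans out to named substreams per
#' stage ([substream_seed()]), so changing the draw count of one stage
#' never changes another stage's randomness.
#'
#' @param simulate if `TRUE` (default) data come from [simulate_dataset()];
#'   otherwise `specimens_path` (+ optional `tree_path`, `traits_path`,
#'   `schema`) are read.
#' @param sim list of [sim_config()] overrides for simulation mode.
#' @param specimens_path,tree_path,traits_path input files for real data.
#' @param schema column mapping for [read_specimens()].
#' @param grouping named site -> group map; defaults to the simulated
#'   design's pairing in simulation mode (required for real data).
#' @param season_months trapping season (default April-October).
#' @param seed master seed.
#' @param n_null SES-MPD null draws per unit.
#' @param n_perm perMANOVA permutations.
#' @param n_restarts NMDS random restarts.
#' @param n_sub,n_reps phenology subsampling settings.
#' @param knots spline knots for trend fits.
#' @param min_focal focal-species minimum total abundance.
#' @param accum_perm permutations for the accumulation curve.
#' @param out_dir optional directory; if set, [run_all()] writes the CSV
#'   bundle there.
#' @return a `run_config` list.
#' @export
run_config <- function(simulate = TRUE, sim = list(), specimens_path = NULL,
                       tree_path = NULL, traits_path = NULL,
                       schema = default_schema(), grouping = NULL,
                       season_months = 4:10, seed = 1, n_null = 999,
                       n_perm = 999, n_restarts = 20, n_sub = 30,
                       n_reps = 500, knots = 5, min_focal = 30,
                       accum_perm = 50, out_dir = NULL) {
  stopifnot(n_null >= 100, n_perm >= 1, n_restarts >= 1, n_sub >= 1,
            n_reps >= 1, knots >= 2, min_focal >= 1)
  cfg <- list(simulate = simulate, sim = sim, specimens_path = specimens_path,
              tree_path = tree_path, traits_path = traits_path,
              schema = schema, grouping = grouping,
              season_months = as.integer(season_months),
              seed = as.integer(seed), n_null = n_null, n_perm = n_perm,
              n_restarts = n_restarts, n_sub = n_sub, n_reps = n_reps,
              knots = knots, min_focal = min_focal, accum_perm = accum_perm,
              out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' The on-disk format mirrors [run_config()] arguments (JSON rather than
#' YAML so the pipeline needs no extra parser dependency).
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$grouping <- unlist(raw$grouping)
  if (!is.null(raw$schema)) raw$schema <- do.call(default_schema, as.list(raw$schema))
  do.call(run_config, raw)
}

# run one stage under tryCatch, recording status
stage_ <- function(bundle, name, expr) {
  res <- tryCatch(list(value = force(expr), error = NULL),
                  error = function(e) list(value = NULL,
                                           error = conditionMessage(e)))
  bundle$status[[name]] <- if (is.null(res$error)) "ok" else
    paste0("failed: ", res$error)
  bundle$tables[[name]] <- res$value
  bundle
}

#' Run the full monitoring analysis pipeline
#'
#' Ingest (or simulate) -> community matrices -> diversity summaries +
#' accumulation -> phylogenetic structure (graft, SES-MPD) -> composition
#' (Bray-Curtis, NMDS, perMANOVA) -> trend fits and per-species trends ->
#' phenology -> trait models. Deterministic given the master seed. Stage
#' failures are recorded in `$status` and independent downstream stages
#' still run.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   `c("metrics", "phylo", "composition", "trends", "phenology", "traits")`
#'   to run (data ingestion and matrix construction always run).
#' @return a `report_bundle`: `tables` (per-stage results), `status`,
#'   `manifest` (config, seeds, package version).
#' @export
run_all <- function(config = run_config(),
                    stages = c("metrics", "phylo", "composition", "trends",
                               "phenology", "traits")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  seeds <- sapply(c("sim", "graft", "nulls", "perm", "nmds", "phenology",
                    "accum"),
                  function(s) substream_seed(config$seed, s))
  bundle <- structure(list(tables = list(), status = list(),
                           manifest = list(config = unclass(config),
                                           substream_seeds = as.list(seeds),
                                           package_version =
                                             as.character(utils::packageVersion("beemon")))),
                      class = "report_bundle")

  # --- data ---------------------------------------------------------------
  if (config$simulate) {
    sim_args <- config$sim
    sim_args$seed <- sim_args$seed %||% seeds[["sim"]]
    scfg <- do.call(sim_config, sim_args)
    dat <- simulate_dataset(scfg)
    specimens <- dat$specimens
    genus_tree <- dat$tree
    traits <- dat$traits
    grouping <- config$grouping %||% dat$grouping
    bundle$tables$truth <- dat$truth
  } else {
    if (is.null(config$specimens_path)) stop("specimens_path required")
    specimens <- read_specimens(config$specimens_path, schema = config$schema,
                                season_months = config$season_months)
    genus_tree <- if (!is.null(config$tree_path)) read_newick(config$tree_path)
    traits <- if (!is.null(config$traits_path)) read_traits(config$traits_path)
    if (is.null(config$grouping)) stop("grouping required for real data")
    grouping <- config$grouping
  }
  grouping <- site_grouping(grouping)
  bundle$tables$specimens <- specimens
  month_cm <- build_month_matrix(specimens, grouping)
  year_cm <- build_year_matrix(specimens, grouping)
  bundle$status$data <- "ok"

  # --- phylo (before metrics so SES can be folded into summaries) ---------
  species_tree <- NULL
  ses_month <- ses_year <- NULL
  if ("phylo" %in% stages && !is.null(genus_tree)) {
    bundle <- stage_(bundle, "phylo", {
      gt <- force_ultrametric(genus_tree)
      sbg <- unique(data.frame(species = specimens$species,
                               genus = specimens$genus,
                               stringsAsFactors = FALSE))
      # the stage expression evaluates in run_all()'s frame, so these
      # assignments update the pipeline-level objects used downstream
      species_tree <- graft_species(gt, sbg, seed = seeds[["graft"]])
      dmat <- cophenetic_matrix(species_tree)
      ses_month <- ses_mpd_units(month_cm, dmat, n_null = config$n_null,
                                 seed = seeds[["nulls"]])
      ses_year <- ses_mpd_units(year_cm, dmat,
                                n_null = config$n_null,
                                seed = substream_seed(config$seed,
                                                      "nulls_year"))
      list(ses_month = ses_month, ses_year = ses_year,
           graft_seed = seeds[["graft"]])
    })
  }

  if ("metrics" %in% stages) {
    bundle <- stage_(bundle, "metrics", {
      list(month_summary = month_summary(month_cm,
                                         ses_mpd = ses_month$ses),
           year_summary = year_summary(year_cm, ses_mpd = ses_year$ses),
           accumulation = accumulation_curve(
             specimens, n_perm = config$accum_perm,
             at = unique(round(seq(1, nrow(specimens), length.out = 200))),
             seed = seeds[["accum"]]))
    })
  }

  if ("composition" %in% stages) {
    bundle <- stage_(bundle, "composition", {
      out <- list()
      for (scheme in c("month", "year")) {
        cmz <- composition_matrix(specimens, grouping, scheme = scheme)
        d <- bray_curtis(cmz)
        ord <- nmds(d, k = 2, n_restarts = config$n_restarts,
                    seed = substream_seed(config$seed,
                                          paste0("nmds_", scheme)))
        pm <- permanova(d, cmz$units[[scheme]], n_perm = config$n_perm,
                        seed = substream_seed(config$seed,
                                              paste0("perm_", scheme)))
        out[[scheme]] <- list(units = cmz$units, dissim = d,
                              ordination = ord, permanova = pm)
      }
      out
    })
  }

  if ("trends" %in% stages) {
    bundle <- stage_(bundle, "trends", {
      ms <- bundle$tables$metrics$month_summary
      ys <- bundle$tables$metrics$year_summary
      sp_tr <- species_trend_table(specimens, min_total = config$min_focal)
      list(month_models = if (!is.null(ms))
             metric_trend_table(ms, "month", k = config$knots),
           year_models = if (!is.null(ys))
             metric_trend_table(ys, "year", k = config$knots),
           species_trends = sp_tr,
           classes = classify_trends(sp_tr),
           diagnostics = abundance_change_correlation(sp_tr))
    })
  }

  if ("phenology" %in% stages) {
    bundle <- stage_(bundle, "phenology", {
      ph <- phenology_table(specimens, min_n = config$min_focal,
                            n_sub = config$n_sub, n_reps = config$n_reps,
                            seed = seeds[["phenology"]])
      focal <- ph$species[ph$included]
      list(phenology = ph,
           month_capture = month_capture_matrix(specimens, species = focal))
    })
  }

  if ("traits" %in% stages && !is.null(traits)) {
    bundle <- stage_(bundle, "traits", {
      tr_tab <- bundle$tables$trends$species_trends %||%
        species_trend_table(specimens, min_total = config$min_focal)
      ph <- bundle$tables$phenology$phenology
      if (!is.null(ph)) {
        traits <- merge(traits, ph[ph$included,
                                   c("species", "seasonality", "breadth")],
                        by = "species", all.x = TRUE)
      }
      trait_models(tr_tab, traits, tree = species_tree)
    })
  }

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle stages:\n")
  for (s in names(x$status)) cat(sprintf("  %-12s %s\n", s, x$status[[s]]))
  invisible(x)
}

#' Write a report bundle as tidy CSV files plus a JSON manifest
#'
#' @param bundle a `report_bundle` from [run_all()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  }
  tb <- bundle$tables
  if (!is.null(tb$metrics)) {
    w(tb$metrics$month_summary, "month_summary")
    w(tb$metrics$year_summary, "year_summary")
    w(tb$metrics$accumulation, "accumulation_curve")
  }
  if (!is.null(tb$phylo)) {
    w(tb$phylo$ses_month, "ses_mpd_month_units")
    w(tb$phylo$ses_year, "ses_mpd_year_units")
  }
  if (!is.null(tb$composition)) {
    for (scheme in names(tb$composition)) {
      cz <- tb$composition[[scheme]]
      w(cbind(cz$units, cz$ordination$points,
              stress = cz$ordination$stress),
        paste0("nmds_", scheme))
      pm <- cz$permanova
      w(data.frame(scheme = scheme, pseudo_F = pm$pseudo_F,
                   r_squared = pm$r_squared, p_value = pm$p_value,
                   n_perm = pm$n_perm),
        paste0("permanova_", scheme))
    }
  }
  if (!is.null(tb$trends)) {
    if (!is.null(tb$trends$month_models)) w(tb$trends$month_models, "month_models")
    if (!is.null(tb$trends$year_models)) w(tb$trends$year_models, "year_models")
    w(tb$trends$species_trends, "species_trends")
    w(tb$trends$classes, "trend_classes")
    w(tb$trends$diagnostics, "trend_diagnostics")
  }
  if (!is.null(tb$phenology)) {
    w(tb$phenology$phenology, "phenology")
    w(as.data.frame(tb$phenology$month_capture), "month_capture_percent")
  }
  if (!is.null(tb$traits)) w(tb$traits, "trait_models")
  jsonlite::write_json(c(bundle$manifest, list(status = bundle$status)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(dir)
}
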