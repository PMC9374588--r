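#' Default column schema for specimen tables
#'
#' Maps the fields the pipeline needs onto the column names found in the
#' input file. Every value can be remapped, so arbitrary delimited exports
#' (e.g. a data repository download with different headers) can be read by
#' supplying `schema = default_schema(species = "Species.Name", ...)`.
#' `genus` and `family` entries may name absent columns: genus then falls
#' back to the first token of the binomial and family to `NA`.
#'
#' @param ... named overrides, e.g. `date = "CollectionDate"`.
#' @return named character vector mapping internal field -> file column.
#' @export
default_schema <- function(...) {
  schema <- c(
    specimen_id = "specimen_id",
    species     = "species",
    genus       = "genus",
    family      = "family",
    site_id     = "site_id",
    trap_id     = "trap_id",
    date        = "date"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(schema))
    if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    schema[names(overrides)] <- overrides
  }
  schema
}

#' Read and validate a specimen-level occurrence table
#'
#' One row per captured individual. Rows lacking a species-level
#' identification (empty or `NA` species) are dropped and counted, as are
#' rows with unparseable dates (an error is raised if these exceed
#' `max_bad_date_frac` of the file) and rows dated outside the configured
#' sampling season. Calendar fields (`year`, `month`, `day_of_year`) are
#' derived from the parsed date.
#'
#' @param path delimited text file with one row per specimen.
#' @param schema column mapping from [default_schema()].
#' @param sep field separator (default `","`).
#' @param date_format passed to [as.Date()].
#' @param season_months integer months regarded as the trapping season
#'   (default April-October, `4:10`).
#' @param max_bad_date_frac maximum tolerated fraction of unparseable dates.
#' @return a `specimen_table` data frame with columns `specimen_id`,
#'   `species`, `genus`, `family`, `site_id`, `trap_id`, `date`, `year`,
#'   `month`, `day_of_year`; attributes `n_dropped_species`,
#'   `n_dropped_date`, `n_dropped_season` count removed rows.
#' @export
read_specimens <- function(path, schema = default_schema(), sep = ",",
                           date_format = "%Y-%m-%d", season_months = 4:10,
                           max_bad_date_frac = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  required <- c("species", "site_id", "trap_id", "date")
  missing_cols <- required[!schema[required] %in% names(raw)]
  if (length(missing_cols)) {
    stop("schema error: required column(s) not in file: ",
         paste(schema[missing_cols], collapse = ", "))
  }
  get_col <- function(field, default = NA_character_) {
    col <- schema[[field]]
    if (col %in% names(raw)) as.character(raw[[col]]) else rep(default, nrow(raw))
  }
  df <- data.frame(
    specimen_id = get_col("specimen_id", default = ""),
    species     = get_col("species"),
    genus       = get_col("genus"),
    family      = get_col("family"),
    site_id     = get_col("site_id"),
    trap_id     = get_col("trap_id"),
    date_raw    = get_col("date"),
    stringsAsFactors = FALSE
  )
  if (all(df$specimen_id == "" | is.na(df$specimen_id))) {
    df$specimen_id <- sprintf("spec%06d", seq_len(nrow(df)))
  }
  as_specimen_table(df, date_format = date_format,
                    season_months = season_months,
                    max_bad_date_frac = max_bad_date_frac)
}

#' Validate a raw specimen data frame
#'
#' Applies the same filtering and derivation rules as [read_specimens()] to
#' an in-memory data frame (used by the simulator and by tests). Species
#' identity is the exact binomial after whitespace normalization; no fuzzy
#' matching is attempted.
#'
#' @param df data frame with at least `species`, `site_id`, `trap_id` and
#'   either a `date` / `date_raw` column or `year` + `day_of_year`.
#' @inheritParams read_specimens
#' @return a validated `specimen_table`.
#' @export
as_specimen_table <- function(df, date_format = "%Y-%m-%d",
                              season_months = 4:10, max_bad_date_frac = 0.05) {
  stopifnot(is.data.frame(df), nrow(df) > 0)
  df$species <- trimws(gsub("\\s+", " ", as.character(df$species)))

  keep <- !is.na(df$species) & df$species != ""
  n_dropped_species <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) stop("no identified specimens remain after filtering")

  if (!"date" %in% names(df) || !inherits(df$date, "Date")) {
    raw <- if ("date_raw" %in% names(df)) df$date_raw else df$date
    df$date <- as.Date(as.character(raw), format = date_format)
  }
  bad_date <- is.na(df$date)
  n_dropped_date <- sum(bad_date)
  if (n_dropped_date / nrow(df) > max_bad_date_frac) {
    stop(sprintf("%d of %d rows (%.1f%%) have unparseable dates",
                 n_dropped_date, nrow(df), 100 * n_dropped_date / nrow(df)))
  }
  df <- df[!bad_date, , drop = FALSE]
  df$date_raw <- NULL

  df$year <- as.integer(format(df$date, "%Y"))
  df$month <- as.integer(format(df$date, "%m"))
  df$day_of_year <- as.integer(format(df$date, "%j"))

  in_season <- df$month %in% season_months
  n_dropped_season <- sum(!in_season)
  df <- df[in_season, , drop = FALSE]
  if (nrow(df) == 0) stop("no specimens within the configured season months")

  first_token <- sub("\\s.*$", "", df$species)
  if (!"genus" %in% names(df) || all(is.na(df$genus))) {
    df$genus <- first_token
  } else {
    df$genus <- as.character(df$genus)
    mism <- !is.na(df$genus) & df$genus != first_token
    if (any(mism)) {
      warning(sum(mism), " record(s) have a genus differing from the first ",
              "token of the binomial; keeping the genus column as given")
    }
    df$genus[is.na(df$genus)] <- first_token[is.na(df$genus)]
  }
  if (!"family" %in% names(df)) df$family <- NA_character_
  df$site_id <- as.character(df$site_id)
  df$trap_id <- as.character(df$trap_id)

  rownames(df) <- NULL
  ord <- c("specimen_id", "species", "genus", "family", "site_id", "trap_id",
           "date", "year", "month", "day_of_year")
  df <- df[, c(ord, setdiff(names(df), ord)), drop = FALSE]
  structure(df,
            class = c("specimen_table", "data.frame"),
            season_months = as.integer(season_months),
            n_dropped_species = n_dropped_species,
            n_dropped_date = n_dropped_date,
            n_dropped_season = n_dropped_season)
}

#' Define a site -> site-group mapping
#'
#' Sampling locations closer together than a stated distance are pooled into
#' site groups, the study's replicate unit (8 locations -> 4 groups in the
#' motivating design).
#'
#' @param map named character vector: `names(map)` are `site_id`s, values
#'   are group labels.
#' @return validated named character vector of class `site_grouping`.
#' @export
#' @examples
#' site_grouping(c(S1 = "G1", S2 = "G1", S3 = "G2", S4 = "G2"))
site_grouping <- function(map) {
  map <- unlist(map)
  if (is.null(names(map)) || any(names(map) == "") || anyNA(map)) {
    stop("grouping must be a fully named vector site_id -> group")
  }
  if (anyDuplicated(names(map))) stop("duplicate site_id in grouping")
  structure(as.character(setNames(as.character(map), names(map))),
            names = names(map), class = "site_grouping")
}

# internal: tabulate specimens into a units x species count matrix.
# `unit_cols` defines the aggregation scheme; the unit grid is completed so
# that zero-capture (site, period) combinations appear as explicit zero rows.
build_matrix_ <- function(specimens, unit_cols, season_months, years) {
  dt <- data.table::as.data.table(as.data.frame(specimens))
  species <- sort(unique(dt$species))
  if (is.null(years)) years <- sort(unique(dt$year))
  grid_args <- list(site_id = sort(unique(dt$site_id)), year = as.integer(years))
  if ("month" %in% unit_cols) grid_args$month <- as.integer(season_months)
  units <- do.call(expand.grid,
                   c(grid_args[unit_cols],
                     list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  units <- units[do.call(order, units), , drop = FALSE]
  rownames(units) <- NULL

  counts <- matrix(0L, nrow = nrow(units), ncol = length(species),
                   dimnames = list(NULL, species))
  tab <- dt[, .N, by = c(unit_cols, "species")]
  key_unit <- do.call(paste, c(units[unit_cols], sep = "\r"))
  key_tab <- do.call(paste, c(as.data.frame(tab)[unit_cols], sep = "\r"))
  ri <- match(key_tab, key_unit)
  if (anyNA(ri)) stop("specimens outside the configured unit grid (check ",
                      "`years`/`season_months`)")
  ci <- match(tab$species, species)
  counts[cbind(ri, ci)] <- tab$N
  structure(list(units = units, counts = counts, species = species),
            class = "community_matrix")
}

#' Build per-(site, month, year) community matrices
#'
#' Counts are pooled over the traps within each site. Every (site, month,
#' year) cell of the season grid is emitted, including explicit all-zero
#' rows for zero-capture site-months, because downstream month averages
#' across years must include zero months.
#'
#' @param specimens a `specimen_table`.
#' @param grouping optional [site_grouping()]; if given, a `group` column is
#'   attached to the unit metadata.
#' @param season_months months forming the unit grid (defaults to the
#'   table's validated season).
#' @param years years forming the unit grid (default: observed range).
#' @return a `community_matrix`: list with `units` (unit metadata data
#'   frame), `counts` (units x species integer matrix), `species`.
#' @export
build_month_matrix <- function(specimens, grouping = NULL,
                               season_months = NULL, years = NULL) {
  stopifnot(inherits(specimens, "specimen_table"))
  season_months <- season_months %||% attr(specimens, "season_months")
  cm <- build_matrix_(specimens, c("site_id", "month", "year"),
                      season_months, years)
  attr(cm, "scheme") <- "month"
  if (!is.null(grouping)) cm <- attach_grouping(cm, grouping)
  cm
}

#' Build per-(site, year) community matrices
#'
#' Pools all months within a site-year (the "sum across months, then compute
#' metrics per year" scheme). Zero-capture site-years are emitted as
#' explicit zero rows.
#'
#' @inheritParams build_month_matrix
#' @return a `community_matrix` with scheme `"year"`.
#' @export
build_year_matrix <- function(specimens, grouping = NULL,
                              season_months = NULL, years = NULL) {
  stopifnot(inherits(specimens, "specimen_table"))
  season_months <- season_months %||% attr(specimens, "season_months")
  cm <- build_matrix_(specimens, c("site_id", "year"), season_months, years)
  attr(cm, "scheme") <- "year"
  if (!is.null(grouping)) cm <- attach_grouping(cm, grouping)
  cm
}

#' Attach a site grouping to a community matrix
#' @param cm a `community_matrix`.
#' @param grouping a [site_grouping()].
#' @return `cm` with a `group` column in `cm$units`.
#' @export
attach_grouping <- function(cm, grouping) {
  stopifnot(inherits(cm, "community_matrix"))
  grouping <- site_grouping(grouping)
  missing_sites <- setdiff(cm$units$site_id, names(grouping))
  if (length(missing_sites)) {
    stop("site(s) not in grouping: ", paste(missing_sites, collapse = ", "))
  }
  cm$units$group <- unname(grouping[cm$units$site_id])
  cm
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix [%s scheme]: %d units x %d species, %d individuals\n",
              attr(x, "scheme") %||% "?", nrow(x$counts), ncol(x$counts),
              sum(x$counts)))
  invisible(x)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin validation wrapper around [ape::read.tree()]: requires branch
#' lengths, unique tip labels and non-negative edge lengths. Polytomies are
#' allowed.
#'
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in '", path,
                                            "': ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in '", path, "'")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree lacks branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("tree has negative or non-finite branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Read a species trait table
#'
#' Expects one row per species with columns `species`, `body_length_mm`,
#' `social`, `diet_specialist`, `below_ground_nesting` (binary traits coded
#' 0/1). Extra columns are kept.
#'
#' @param path CSV file.
#' @return data frame keyed by species.
#' @export
read_traits <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(tr)) stop("trait table needs a `species` column")
  if (anyDuplicated(tr$species)) stop("duplicate species in trait table")
  for (b in intersect(c("social", "diet_specialist", "below_ground_nesting"),
                      names(tr))) {
    if (!all(tr[[b]] %in% c(0, 1, NA))) stop("trait `", b, "` must be coded 0/1")
  }
  tr
}

#' Write a community matrix as tidy CSV
#'
#' One row per (unit, species) with the unit metadata columns repeated;
#' zero counts are kept so the file round-trips the full unit grid.
#'
#' @param cm a `community_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "community_matrix"))
  long <- data.frame(
    cm$units[rep(seq_len(nrow(cm$units)), times = length(cm$species)), ,
             drop = FALSE],
    species = rep(cm$species, each = nrow(cm$units)),
    count = as.vector(cm$counts),
    row.names = NULL
  )
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
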