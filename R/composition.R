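#' Build composition units by pooling counts
#'
#' Composition analyses use one abundance vector per (site group, month)
#' — counts summed across years — or per (site group, year) — counts summed
#' across months — mirroring the replicate structure of the month/year
#' biodiversity summaries. All-zero units are dropped (they carry no
#' composition information and Bray-Curtis is undefined on them).
#'
#' @param specimens a `specimen_table`.
#' @param grouping a [site_grouping()].
#' @param scheme `"month"` or `"year"`.
#' @return a `community_matrix` whose units are (group, month) or
#'   (group, year).
#' @export
composition_matrix <- function(specimens, grouping,
                               scheme = c("month", "year")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(specimens, "specimen_table"))
  grouping <- site_grouping(grouping)
  dt <- data.table::as.data.table(as.data.frame(specimens))
  missing_sites <- setdiff(dt$site_id, names(grouping))
  if (length(missing_sites)) {
    stop("site(s) not in grouping: ", paste(missing_sites, collapse = ", "))
  }
  dt$group <- grouping[dt$site_id]
  period <- if (scheme == "month") "month" else "year"
  tab <- dt[, .N, by = c("group", period, "species")]
  species <- sort(unique(dt$species))
  units <- unique(as.data.frame(tab)[c("group", period)])
  units <- units[order(units$group, units[[period]]), , drop = FALSE]
  rownames(units) <- NULL
  counts <- matrix(0L, nrow(units), length(species),
                   dimnames = list(NULL, species))
  ri <- match(paste(tab$group, tab[[period]]),
              paste(units$group, units[[period]]))
  counts[cbind(ri, match(tab$species, species))] <- tab$N
  structure(list(units = units, counts = counts, species = species),
            class = "community_matrix", scheme = paste0("composition_", scheme))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}: 0 for
#' identical abundance vectors, 1 for disjoint ones.
#'
#' @param x a `community_matrix` or a units x species numeric matrix.
#' @return symmetric matrix in \[0, 1\] with zero diagonal; unit metadata
#'   (if available) is carried in attribute `units`.
#' @export
bray_curtis <- function(x) {
  units <- NULL
  if (inherits(x, "community_matrix")) {
    units <- x$units
    x <- x$counts
  }
  x <- as.matrix(x)
  check_counts(as.vector(x))
  zero <- rowSums(x) == 0
  if (any(zero)) {
    labs <- if (!is.null(units)) {
      apply(units[zero, , drop = FALSE], 1, paste, collapse = "/")
    } else which(zero)
    stop("Bray-Curtis undefined for all-zero unit(s): ",
         paste(labs, collapse = ", "))
  }
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
    }
  }
  attr(d, "units") <- units
  d
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes stress-1 with monotone regression of configuration distances
#' on the dissimilarities (via [vegan::monoMDS()], global model), taking
#' the best of one metric (principal coordinates) start and `n_restarts`
#' random starts. Deterministic given `seed`.
#'
#' @param dissim symmetric dissimilarity matrix (or `dist`).
#' @param k embedding dimension (default 2).
#' @param n_restarts random restarts in addition to the metric start.
#' @param maxit iterations per start.
#' @param seed optional seed.
#' @return list of class `nmds_ordination`: `points` (n x k), `stress`,
#'   `n_restarts`, `converged`.
#' @export
nmds <- function(dissim, k = 2, n_restarts = 20, maxit = 500, seed = NULL) {
  d <- as.dist(dissim)
  n <- attr(d, "Size")
  if (n < k + 2) stop("need at least k + 2 units for a k-dimensional NMDS")
  with_seed(seed, {
    inits <- vector("list", n_restarts + 1)
    pco <- cmdscale(d, k = k)
    if (ncol(pco) < k) {
      pco <- cbind(pco, matrix(rnorm(n * (k - ncol(pco)), sd = 1e-4), n))
    }
    inits[[1]] <- pco
    for (r in seq_len(n_restarts)) inits[[r + 1]] <- matrix(rnorm(n * k), n, k)
    best <- NULL
    for (init in inits) {
      fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                            maxit = maxit)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    structure(list(points = best$points, stress = best$stress,
                   n_restarts = n_restarts,
                   converged = isTRUE(best$icause %in% c(3, 4)) ||
                     best$iters < maxit),
              class = "nmds_ordination")
  })
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS: %d points, k = %d, stress-1 = %.4f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# within-group sum of squares from a squared-dissimilarity matrix
ss_within_ <- function(d2, idx_by_group) {
  sum(vapply(idx_by_group, function(ix) sum(d2[ix, ix]) / (2 * length(ix)),
             numeric(1)))
}

#' One-factor perMANOVA (permutational multivariate ANOVA)
#'
#' Partitions the total sum of squared dissimilarities
#' (\eqn{SS_T = \sum_{i<j} d_{ij}^2 / N}) into among- and within-group
#' components using group sizes; the pseudo-F is
#' \eqn{(SS_A/(a-1)) / (SS_W/(N-a))} and its p-value comes from `n_perm`
#' unrestricted permutations of the group labels:
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}.
#'
#' @param dissim symmetric dissimilarity matrix (or `dist`).
#' @param groups group label per unit (>= 2 groups).
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed.
#' @return list of class `permanova_result`: `pseudo_F`, `r_squared`,
#'   `p_value`, `n_perm`, `df`, `ss` (among/within/total).
#' @export
permanova <- function(dissim, groups, n_perm = 999, seed = NULL) {
  d2 <- as.matrix(dissim)^2
  N <- nrow(d2)
  groups <- as.factor(groups)
  stopifnot(length(groups) == N, nlevels(droplevels(groups)) >= 2)
  groups <- droplevels(groups)
  a <- nlevels(groups)
  if (N - a < 1) stop("no residual degrees of freedom")
  ss_total <- sum(d2) / (2 * N)
  idx0 <- split(seq_len(N), groups)
  ss_w <- ss_within_(d2, idx0)
  ss_a <- ss_total - ss_w
  f_obs <- (ss_a / (a - 1)) / (ss_w / (N - a))
  sizes <- lengths(idx0)
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm <- sample.int(N)
      idx <- split(perm, rep.int(seq_len(a), sizes))
      sw <- ss_within_(d2, idx)
      ((ss_total - sw) / (a - 1)) / (sw / (N - a))
    }, numeric(1))
  })
  structure(list(pseudo_F = f_obs, r_squared = ss_a / ss_total,
                 p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
                 n_perm = n_perm, df = c(among = a - 1, within = N - a),
                 ss = c(among = ss_a, within = ss_w, total = ss_total)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("perMANOVA: F(%d,%d) = %.3f, R2 = %.3f, p = %.4g (%d perms)\n",
              x$df[1], x$df[2], x$pseudo_F, x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}
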