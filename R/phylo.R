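#' Force a tree to be ultrametric by terminal-edge extension
#'
#' Every terminal edge is lengthened so that all tips sit at the original
#' maximum root-to-tip depth. Topology and internal edges are untouched.
#' (An alternative to non-negative least-squares adjustment; SES-MPD
#' conclusions are invariant to the overall branch-length scale, and this
#' rule is deterministic and idempotent.)
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return an ultrametric `phylo`.
#' @export
force_ultrametric <- function(tree) {
  validate_tree(tree)
  depths <- ape::node.depth.edgelength(tree)
  n_tip <- length(tree$tip.label)
  target <- max(depths[seq_len(n_tip)])
  term <- match(seq_len(n_tip), tree$edge[, 2])
  add <- target - depths[seq_len(n_tip)]
  if (any(add < -1e-8 * target)) stop("negative terminal extension")
  tree$edge.length[term] <- tree$edge.length[term] + pmax(add, 0)
  tree
}

# is the tree ultrametric to relative tolerance?
is_ultrametric_ <- function(tree, tol = 1e-8) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(d)) <= tol * max(d)
}

# random coalescent subtree over `species`, root age drawn-to at most `u`:
# m-1 merge events at sorted uniform ages in (0, u); returns a phylo whose
# tips are at age 0 and whose root.edge tops the stem up to exactly age u.
coalescent_subtree_ <- function(species, u) {
  m <- length(species)
  ages <- sort(runif(m - 1, 0, u))
  # placeholder labels survive the Newick round-trip (binomials contain
  # spaces); real names are restored on the parsed tree below
  lin_txt <- sprintf("t%d", seq_len(m))
  lin_age <- numeric(m)
  for (j in seq_len(m - 1)) {
    pick <- sample.int(length(lin_txt), 2)
    a <- pick[1]; b <- pick[2]
    txt <- sprintf("(%s:%.12g,%s:%.12g)",
                   lin_txt[a], ages[j] - lin_age[a],
                   lin_txt[b], ages[j] - lin_age[b])
    lin_txt <- c(lin_txt[-pick], txt)
    lin_age <- c(lin_age[-pick], ages[j])
  }
  tr <- ape::read.tree(text = sprintf("%s:%.12g;", lin_txt, u - lin_age))
  tr$tip.label <- species[as.integer(sub("^t", "", tr$tip.label))]
  tr
}

#' Graft species as random subtrees under their genus tips
#'
#' Each genus tip of an ultrametric genus-level tree is replaced by a random
#' bifurcating subtree of that genus' species, bound at a uniform random
#' point along the genus terminal edge; within-genus node heights are
#' uniform below the attachment point (successive random coalescence).
#' Relationships below the genus level are therefore random, but the
#' between-genus backbone — which dominates MPD — is preserved, and the
#' result remains ultrametric. Genera whose genus is absent from the tree
#' are dropped with a warning; genus tips with no species keep their tip.
#'
#' @param genus_tree ultrametric `phylo` with genus tip labels.
#' @param species_by_genus either a named list genus -> character vector of
#'   species, or a data frame with `species` and `genus` columns.
#' @param seed optional seed; the graft is deterministic given it.
#' @return a species-level ultrametric `phylo`.
#' @export
graft_species <- function(genus_tree, species_by_genus, seed = NULL) {
  validate_tree(genus_tree)
  if (!is_ultrametric_(genus_tree, tol = 1e-6)) {
    warning("genus tree is not ultrametric; consider force_ultrametric()")
  }
  if (is.data.frame(species_by_genus)) {
    species_by_genus <- split(as.character(species_by_genus$species),
                              as.character(species_by_genus$genus))
  }
  species_by_genus <- species_by_genus[order(names(species_by_genus))]
  absent <- setdiff(names(species_by_genus), genus_tree$tip.label)
  if (length(absent)) {
    warning("genus/genera not in tree, species dropped: ",
            paste(absent, collapse = ", "))
    species_by_genus <- species_by_genus[!names(species_by_genus) %in% absent]
  }
  with_seed(seed, {
    tree <- genus_tree
    for (gen in names(species_by_genus)) {
      spp <- unique(species_by_genus[[gen]])
      if (length(spp) == 0) next
      tip <- match(gen, tree$tip.label)
      if (length(spp) == 1) {
        tree$tip.label[tip] <- spp
        next
      }
      edge_i <- match(tip, tree$edge[, 2])
      L <- tree$edge.length[edge_i]
      u <- runif(1, 0, L)
      sub <- coalescent_subtree_(spp, u)
      tree <- ape::bind.tree(tree, sub, where = tip, position = u)
      tree <- ape::drop.tip(tree, gen, collapse.singles = TRUE)
    }
    validate_tree(tree)
  })
}

#' Patristic (cophenetic) distance matrix
#'
#' Tip-to-tip path-length distances; plumbing for MPD.
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric species x species matrix with zero diagonal.
#' @export
cophenetic_matrix <- function(tree) {
  validate_tree(tree)
  ape::cophenetic.phylo(tree)
}

#' Mean pairwise distance (MPD) of a community
#'
#' Unweighted mean patristic distance over all unordered pairs of distinct
#' species present (presence-based; abundance weighting deliberately not
#' used by the pipeline).
#'
#' @param community character vector of species present (or a logical/0-1
#'   vector over `rownames(dist)`).
#' @param dist a [cophenetic_matrix()].
#' @return mean distance, or `NA_real_` for fewer than 2 species.
#' @export
mpd <- function(community, dist) {
  if (!is.character(community)) {
    community <- rownames(dist)[as.logical(community)]
  }
  community <- unique(community)
  miss <- setdiff(community, rownames(dist))
  if (length(miss)) stop("species not in distance matrix: ",
                         paste(head(miss, 5), collapse = ", "))
  k <- length(community)
  if (k < 2) return(NA_real_)
  m <- dist[community, community]
  sum(m) / (k * (k - 1))
}

#' Standardized effect size of MPD under an equal-richness null
#'
#' Compares observed MPD with the distribution of MPD over `n_null` uniform
#' random draws of the same number of species from the pool:
#' `ses = (mpd_obs - null_mean)/null_sd`. Negative values indicate
#' phylogenetic clustering (less evolutionary distance among co-occurring
#' species than random), positive values an even/overdispersed community.
#'
#' @param community species present (character vector).
#' @param dist a [cophenetic_matrix()] over the pool.
#' @param pool species pool to draw nulls from (default: all rows of
#'   `dist`).
#' @param n_null number of null communities (>= 100; default 999).
#' @param seed optional seed.
#' @return list of class `ses_result`: `mpd_obs`, `null_mean`, `null_sd`,
#'   `ses`, `n_null`, `degenerate` (TRUE when the null has zero variance,
#'   in which case `ses` is reported as 0).
#' @export
ses_mpd <- function(community, dist, pool = rownames(dist), n_null = 999,
                    seed = NULL) {
  stopifnot(n_null >= 100)
  community <- unique(as.character(community))
  if (!all(community %in% pool)) stop("community must be a subset of the pool")
  k <- length(community)
  obs <- mpd(community, dist)
  if (is.na(obs)) {
    return(structure(list(mpd_obs = NA_real_, null_mean = NA_real_,
                          null_sd = NA_real_, ses = NA_real_, n_null = n_null,
                          degenerate = TRUE), class = "ses_result"))
  }
  pm <- dist[pool, pool]
  P <- length(pool)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      idx <- sample.int(P, k)
      s <- pm[idx, idx]
      sum(s) / (k * (k - 1))
    }, numeric(1))
  })
  mu <- mean(nulls); sdev <- sd(nulls)
  degenerate <- !is.finite(sdev) || sdev == 0
  structure(list(mpd_obs = obs, null_mean = mu, null_sd = sdev,
                 ses = if (degenerate) 0 else (obs - mu) / sdev,
                 n_null = n_null, degenerate = degenerate),
            class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf("SES-MPD: obs %.4f, null %.4f +/- %.4f, ses %.3f (n_null %d%s)\n",
              x$mpd_obs, x$null_mean, x$null_sd, x$ses, x$n_null,
              if (x$degenerate) ", degenerate null" else ""))
  invisible(x)
}

#' Per-unit SES-MPD table for a community matrix
#'
#' Runs [ses_mpd()] on every unit (row) of a community matrix against a
#' common species pool — by default every species in the matrix that is on
#' the tree. Species absent from the distance matrix are ignored with a
#' single warning. Units with fewer than 2 scorable species get `NA`.
#'
#' @param cm a `community_matrix`.
#' @param dist a [cophenetic_matrix()] for the species tree.
#' @param pool null-model pool (default: matrix species present on the tree).
#' @param n_null null draws per unit.
#' @param seed optional seed (one stream across all units).
#' @return data frame: unit metadata plus `mpd_obs`, `null_mean`,
#'   `null_sd`, `ses`, `n_null`, `degenerate`.
#' @export
ses_mpd_units <- function(cm, dist, pool = NULL, n_null = 999, seed = NULL) {
  stopifnot(inherits(cm, "community_matrix"))
  on_tree <- cm$species %in% rownames(dist)
  if (!all(on_tree)) {
    warning(sum(!on_tree), " species not on the tree are ignored for SES-MPD")
  }
  pool <- pool %||% cm$species[on_tree]
  rows <- with_seed(seed, {
    lapply(seq_len(nrow(cm$counts)), function(i) {
      comm <- cm$species[cm$counts[i, ] > 0 & on_tree]
      r <- if (length(comm) >= 2) {
        ses_mpd(comm, dist, pool = pool, n_null = n_null, seed = NULL)
      } else {
        list(mpd_obs = NA_real_, null_mean = NA_real_, null_sd = NA_real_,
             ses = NA_real_, n_null = n_null, degenerate = TRUE)
      }
      as.data.frame(unclass(r))
    })
  })
  cbind(cm$units, do.call(rbind, rows))
}
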