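#' Brownian-motion covariance from a phylogeny
#'
#' Under Brownian trait evolution the covariance between two species equals
#' their shared root-to-tip path length; the diagonal holds tip depths
#' (equal on an ultrametric tree).
#'
#' @param tree a `phylo` with branch lengths (ideally ultrametric).
#' @param species optional subset (and ordering) of tip labels.
#' @return symmetric positive semi-definite covariance matrix.
#' @export
brownian_cov <- function(tree, species = NULL) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  if (!is.null(species)) {
    miss <- setdiff(species, rownames(C))
    if (length(miss)) stop("species not in tree: ",
                           paste(head(miss, 5), collapse = ", "))
    C <- C[species, species]
  }
  C
}

# generalized least squares core shared by pgls_fit / ols_fit
gls_core_ <- function(y, X, C, jitter_flag = FALSE) {
  n <- length(y)
  Ci <- tryCatch(chol2inv(chol(C)), error = function(e) NULL)
  if (is.null(Ci)) {
    C <- C + diag(1e-8 * mean(diag(C)), n)
    Ci <- chol2inv(chol(C))
    jitter_flag <- TRUE
  }
  XtCi <- crossprod(X, Ci)
  bread <- solve(XtCi %*% X)
  beta <- drop(bread %*% (XtCi %*% y))
  resid <- y - drop(X %*% beta)
  df <- n - ncol(X)
  sigma2 <- drop(crossprod(resid, Ci %*% resid)) / df
  se <- sqrt(diag(bread) * sigma2)
  t_stat <- beta / se
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  list(beta = beta, se = se, t = t_stat, p = p, df = df,
       jittered = jitter_flag)
}

#' Phylogenetic generalized least squares (Brownian motion) for one trait
#'
#' GLS regression of species' 5-year change on a single trait with error
#' covariance proportional to the Brownian covariance of the phylogeny:
#' \eqn{\hat\beta = (X^T C^{-1} X)^{-1} X^T C^{-1} y} with an intercept.
#' When `C` is proportional to the identity (a star phylogeny with equal
#' depths) the estimates coincide with OLS. A tiny ridge jitter is applied
#' (and flagged) if `C` is numerically singular.
#'
#' @param y named response vector (e.g. `change_5yr`), names = species.
#' @param x named single-trait predictor, same species.
#' @param cov Brownian covariance from [brownian_cov()] covering the
#'   species.
#' @param trait name reported in the result.
#' @return one-row data frame: `trait`, `method`, `coefficient`,
#'   `t_statistic`, `p_value`, `n`, `jittered`.
#' @export
pgls_fit <- function(y, x, cov, trait = "trait") {
  sp <- names(y)
  if (is.null(sp) || is.null(names(x))) stop("y and x must be named by species")
  if (!setequal(sp, names(x))) stop("y and x cover different species")
  if (!all(sp %in% rownames(cov))) stop("covariance does not cover all species")
  x <- x[sp]
  C <- cov[sp, sp]
  if (length(y) < 3) stop("need at least 3 species")
  if (sd(x) == 0) stop("no variation in predictor `", trait, "`")
  X <- cbind(`(Intercept)` = 1, trait = as.numeric(x))
  g <- gls_core_(as.numeric(y), X, C)
  data.frame(trait = trait, method = "pgls_brownian",
             coefficient = g$beta[2], t_statistic = g$t[2],
             p_value = g$p[2], n = length(y), jittered = g$jittered,
             stringsAsFactors = FALSE)
}

#' Ordinary least squares for one trait (no phylogenetic correction)
#'
#' The non-phylogenetic companion model, fit with [stats::lm()] so the two
#' routes are independent implementations.
#'
#' @inheritParams pgls_fit
#' @return one-row data frame as in [pgls_fit()] with `method = "ols"`.
#' @export
ols_fit <- function(y, x, trait = "trait") {
  if (length(y) < 3) stop("need at least 3 species")
  if (sd(x) == 0) stop("no variation in predictor `", trait, "`")
  fit <- lm(as.numeric(y) ~ as.numeric(x))
  sm <- summary(fit)$coefficients
  data.frame(trait = trait, method = "ols", coefficient = sm[2, 1],
             t_statistic = sm[2, 3], p_value = sm[2, 4], n = length(y),
             jittered = FALSE, stringsAsFactors = FALSE)
}

#' Fit single-trait models (PGLS and OLS) for species' change in abundance
#'
#' For each trait column, regresses the species' predicted 5-year change on
#' the trait, once with Brownian PGLS on the supplied species-level tree
#' and once with plain OLS. Single-predictor models by default (matching
#' the motivating analysis); body length is log-transformed unless
#' disabled. Species missing from the tree or with missing trait values are
#' dropped per model.
#'
#' @param trends trend table from [species_trend_table()] (needs `species`
#'   and `change_5yr`).
#' @param traits trait table (needs `species` plus trait columns).
#' @param tree species-level tree for PGLS; `NULL` skips PGLS.
#' @param trait_cols trait columns to test (default: phenology + the four
#'   natural-history traits, intersected with what is present).
#' @param log_body_length log-transform `body_length_mm` (default TRUE).
#' @return data frame of one-row fits stacked (trait x method).
#' @export
trait_models <- function(trends, traits, tree = NULL, trait_cols = NULL,
                         log_body_length = TRUE) {
  dat <- merge(trends[c("species", "change_5yr")], traits, by = "species")
  default_cols <- c("seasonality", "breadth", "body_length_mm", "social",
                    "diet_specialist", "below_ground_nesting")
  trait_cols <- trait_cols %||% intersect(default_cols, names(dat))
  if (!length(trait_cols)) stop("no trait columns to test")
  C <- NULL
  if (!is.null(tree)) {
    keep <- dat$species %in% tree$tip.label
    if (!all(keep)) {
      warning(sum(!keep), " species not on tree dropped from PGLS")
    }
    C <- brownian_cov(tree, dat$species[keep])
  }
  rows <- list()
  for (tr in trait_cols) {
    x <- dat[[tr]]
    if (tr == "body_length_mm" && log_body_length) x <- log(x)
    ok <- is.finite(x) & is.finite(dat$change_5yr)
    y <- setNames(dat$change_5yr[ok], dat$species[ok])
    xv <- setNames(x[ok], dat$species[ok])
    rows[[paste0(tr, "_ols")]] <- ols_fit(y, xv, trait = tr)
    if (!is.null(C)) {
      on_tree <- names(y) %in% rownames(C)
      rows[[paste0(tr, "_pgls")]] <-
        pgls_fit(y[on_tree], xv[on_tree], C, trait = tr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
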